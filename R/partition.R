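#' Barcode-rank curve of per-barcode UMI totals
#'
#' Sorts barcodes by decreasing total UMI count; ties are broken by barcode
#' string order so the curve is deterministic.
#'
#' @param counts A features x barcodes count matrix.
#' @return A `RankCurve`: data frame with columns `rank` (1-based), `barcode`
#'   and `total` (non-increasing).
#' @export
barcode_rank_curve <- function(counts) {
  check(ncol(counts) >= 2, "need at least 2 barcodes to rank")
  totals <- Matrix::colSums(counts)
  check(any(totals > 0), "all barcodes have zero UMIs: no rankable signal")
  ord <- order(-totals, colnames(counts), method = "radix")
  curve <- data.frame(rank = seq_along(ord),
                      barcode = colnames(counts)[ord],
                      total = unname(totals[ord]),
                      stringsAsFactors = FALSE)
  class(curve) <- c("RankCurve", "data.frame")
  curve
}

#' Locate the inflection point of a barcode-rank curve
#'
#' Finds the rank of steepest descent of log10(total) against log10(rank):
#' the knee separating cell-containing from empty droplets. The derivative
#' is evaluated on the distinct-total (run-length collapsed) curve — the
#' deeply tied tail of a UMI rank curve otherwise produces spurious
#' derivative spikes — then smoothed by a centred moving average before the
#' minimum is taken, restricted to candidate ranks in
#' `[min_cells, max_cells]`. Barcodes with rank `<=` the returned value are
#' candidate cells. The result is invariant to uniform scaling of the
#' totals.
#'
#' @param curve A [barcode_rank_curve()].
#' @param smoothing_window Width of the moving-average window (in distinct
#'   steps of the collapsed curve); default 11.
#' @param min_cells,max_cells Search bounds for the returned rank.
#' @param slope_threshold A drop is only accepted where the smoothed
#'   log-log derivative falls below this value; a curve with no such drop
#'   raises an error advising a manual cutoff.
#' @return The 1-based inflection rank.
#' @export
find_inflection <- function(curve, smoothing_window = 11,
                            min_cells = 100, max_cells = Inf,
                            slope_threshold = -2) {
  totals <- curve$total[curve$total > 0]
  check(length(totals) >= 2, "fewer than 2 barcodes with nonzero totals")

  r <- rle(totals)
  edge_rank <- cumsum(r$lengths)       # last rank at each distinct total
  vals <- r$values
  check(length(vals) >= 2,
        "no local steep drop found (curve is flat); supply a manual cutoff")

  # slope between consecutive distinct totals, attributed to the rank just
  # before the drop (the last barcode of the upper plateau)
  slope <- diff(log10(vals)) / diff(log10(edge_rank))
  cand_rank <- edge_rank[-length(edge_rank)]

  # centred moving average with a shrinking window at the curve ends, so
  # unsmoothed tail spikes cannot outrank the knee
  w <- max(1L, as.integer(smoothing_window))
  h <- (w - 1L) %/% 2L
  n <- length(slope)
  if (h > 0L && n > 1L) {
    cs <- c(0, cumsum(slope))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    slope_sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  } else {
    slope_sm <- slope
  }

  ok <- cand_rank >= min_cells & cand_rank <= max_cells
  check(any(ok), "no candidate ranks within [min_cells, max_cells]")
  # locate the drop on the smoothed curve, then refine to the steepest raw
  # step near it (radius 2w: averaging over w steps can displace the argmin
  # of an asymmetric descent by up to ~w)
  i0 <- which(ok)[which.min(slope_sm[ok])]
  near <- which(ok & abs(seq_along(slope) - i0) <= 2L * w)
  idx <- near[which.min(slope[near])]
  check(slope[idx] <= slope_threshold,
        "no local steep drop found (min log-log slope %.3f > threshold %.3f); supply a manual cutoff",
        slope[idx], slope_threshold)
  cand_rank[idx]
}

#' Partition barcodes into cell-containing and empty droplets
#'
#' Barcodes at or above the inflection rank of the RNA barcode-rank curve
#' are classed as cells; every other barcode is an empty droplet. When the
#' experiment has no RNA modality the ADT totals are used instead (with a
#' message).
#'
#' @param experiment A `DropletExperiment`.
#' @param inflection_rank Optional precomputed rank; when `NULL` it is
#'   computed via [find_inflection()].
#' @param ... Passed to [find_inflection()].
#' @return The experiment with `meta$droplet_class` set to `"cell"` or
#'   `"empty"` for every barcode.
#' @export
partition_droplets <- function(experiment, inflection_rank = NULL, ...) {
  modality <- if (!is.null(experiment$rna)) {
    experiment$rna
  } else {
    message("partition_droplets: no RNA modality; falling back to ADT totals")
    experiment$adt
  }
  curve <- barcode_rank_curve(modality)
  if (is.null(inflection_rank)) {
    inflection_rank <- find_inflection(curve, ...)
  }
  check(is_count_scalar(inflection_rank) && inflection_rank >= 1,
        "inflection_rank must be a positive integer")
  cells <- curve$barcode[seq_len(min(inflection_rank, nrow(curve)))]
  experiment$meta$droplet_class <-
    ifelse(experiment$meta$barcode %in% cells, "cell", "empty")
  n_empty <- sum(experiment$meta$droplet_class == "empty")
  if (n_empty == 0) warning("partition produced zero empty droplets")
  message(sprintf("partition_droplets: %d cell / %d empty barcodes",
                  sum(experiment$meta$droplet_class == "cell"), n_empty))
  attr(experiment, "inflection_rank") <- inflection_rank
  experiment
}

#' Remove low-quality cells
#'
#' Cells must express at least `min_genes` genes and carry a mitochondrial
#' read percentage strictly below `max_mito_pct`; failing cells are
#' re-labelled `"removed"` so they contribute to neither the cell nor the
#' empty-droplet pool (see Details for the alternative).
#'
#' @details The empty pool is defined as barcodes below the inflection
#'   point; QC-removed barcodes sit above it but are not intact cells.
#'   By default they are excluded from both pools; set
#'   `removed_to_empty = TRUE` to count them as empty droplets instead.
#'
#' @param experiment A partitioned `DropletExperiment` with an RNA modality.
#' @param min_genes Minimum detected genes per cell (default 60).
#' @param max_mito_pct Cells at or above this mitochondrial percentage are
#'   removed (default 15).
#' @param mito_prefix Gene-name prefix identifying mitochondrial genes.
#' @param removed_to_empty Reclassify failing cells as `"empty"` rather
#'   than `"removed"`.
#' @return The experiment, with failing cells re-labelled; the kept cell
#'   barcodes are in `attr(, "qc_kept")`.
#' @export
qc_filter <- function(experiment, min_genes = 60, max_mito_pct = 15,
                      mito_prefix = "MT-", removed_to_empty = FALSE) {
  check(!is.null(experiment$rna), "qc_filter requires an RNA modality")
  is_cell <- experiment$meta$droplet_class == "cell"
  check(any(is_cell), "no cells to filter; run partition_droplets first")
  cells <- experiment$meta$barcode[is_cell]
  rna <- experiment$rna[, cells, drop = FALSE]

  n_genes <- Matrix::colSums(rna > 0)
  mito <- startsWith(rownames(rna), mito_prefix)
  if (!any(mito)) {
    warning(sprintf("no gene names start with '%s'; mitochondrial criterion skipped",
                    mito_prefix))
    mito_pct <- rep(0, length(cells))
  } else {
    tot <- Matrix::colSums(rna)
    mito_pct <- ifelse(tot > 0, 100 * Matrix::colSums(rna[mito, , drop = FALSE]) / tot, 0)
  }
  keep <- n_genes >= min_genes & mito_pct < max_mito_pct
  fail_bc <- cells[!keep]
  experiment$meta$droplet_class[experiment$meta$barcode %in% fail_bc] <-
    if (removed_to_empty) "empty" else "removed"
  message(sprintf("qc_filter: removed %d of %d cells", length(fail_bc),
                  length(cells)))
  attr(experiment, "qc_kept") <- cells[keep]
  experiment
}

#' Assign cells to samples from hashtag-oligo counts
#'
#' A simple ratio-based demultiplexer: a cell is assigned to its top HTO
#' when that HTO has at least `min_umis` counts and dominates the runner-up
#' by `dominance_ratio`; it is a cross-sample doublet when two HTOs are
#' both credible, and negative otherwise.
#'
#' @param experiment A partitioned `DropletExperiment` with an HTO modality.
#' @param dominance_ratio Required top/second count ratio (default 3).
#' @param min_umis Minimum credible HTO count (default 10).
#' @return The experiment with `meta$sample` set for cell barcodes to an
#'   HTO feature name, `"doublet"` or `"negative"`.
#' @export
demux_hto <- function(experiment, dominance_ratio = 3, min_umis = 10) {
  check(!is.null(experiment$hto), "demux_hto requires an HTO modality")
  if (nrow(experiment$hto) == 1L) {
    warning("single-HTO panel: cells can only be sample_1 or negative")
  }
  is_cell <- experiment$meta$droplet_class == "cell"
  cells <- experiment$meta$barcode[is_cell]
  hto <- as.matrix(experiment$hto[, cells, drop = FALSE])

  assign_one <- function(v) {
    ord <- order(-v)
    top <- v[ord[1]]
    second <- if (length(v) > 1L) v[ord[2]] else 0
    if (top >= min_umis && (second == 0 || top / second >= dominance_ratio)) {
      rownames(hto)[ord[1]]
    } else if (top >= min_umis && second >= min_umis &&
               top / second < dominance_ratio) {
      "doublet"
    } else {
      "negative"
    }
  }
  assignments <- apply(hto, 2, assign_one)
  experiment$meta$sample[match(cells, experiment$meta$barcode)] <- assignments
  experiment
}
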