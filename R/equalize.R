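#' Equalize cell-type composition across conditions
#'
#' For each cell type shared by all conditions, keeps the minimum
#' per-condition count of that type, sampled uniformly without replacement.
#' Cell types absent from one or more conditions are dropped with a
#' warning. The result is deterministic given the seed.
#'
#' @param cells Data frame with columns `barcode`, `condition`, `cell_type`.
#' @param conditions Optional subset of conditions to equalize (default:
#'   all present).
#' @param seed Integer seed.
#' @return A `SelectionResult`: list with `kept` (data frame of selected
#'   rows), `counts` (cell type x condition kept counts) and `seed`.
#' @export
equalize_celltypes <- function(cells, conditions = NULL, seed = 1) {
  check(all(c("barcode", "condition", "cell_type") %in% names(cells)),
        "cells must have columns barcode, condition, cell_type")
  if (is.null(conditions)) conditions <- unique(cells$condition)
  cells <- cells[cells$condition %in% conditions & !is.na(cells$cell_type), ,
                 drop = FALSE]

  tab <- table(cells$cell_type, cells$condition)
  shared <- rownames(tab)[apply(tab[, conditions, drop = FALSE] > 0, 1, all)]
  dropped <- setdiff(rownames(tab), shared)
  if (length(dropped) > 0) {
    warning(sprintf("cell type(s) absent from some condition dropped: %s",
                    paste(dropped, collapse = ", ")))
  }
  check(length(shared) > 0, "no cell types shared by all conditions")

  kept <- with_seed(seed, {
    parts <- list()
    for (ct in sort(shared)) {
      n_keep <- min(tab[ct, conditions])
      for (cond in conditions) {
        idx <- which(cells$cell_type == ct & cells$condition == cond)
        take <- if (length(idx) == n_keep) idx else sample(idx, n_keep)
        parts[[paste(ct, cond)]] <- cells[sort(take), , drop = FALSE]
      }
    }
    do.call(rbind, parts)
  })
  rownames(kept) <- NULL
  counts <- table(kept$cell_type, kept$condition)
  structure(list(kept = kept, counts = counts, seed = seed),
            class = "SelectionResult")
}

#' Match cells between two samples in a shared embedding
#'
#' Within each cluster, every cell of the smaller sample is greedily paired
#' with its nearest unused Euclidean neighbour in the larger sample, cells
#' being processed in a seed-shuffled order; each neighbour is used at most
#' once, so per-cluster counts come out equal.
#'
#' @param coords Numeric matrix of embedding coordinates (cells x dims),
#'   rownames = barcodes.
#' @param clusters Cluster label per cell.
#' @param samples Sample label per cell; exactly two distinct values.
#' @param seed Integer seed controlling the processing order.
#' @return A `SelectionResult` whose `kept` data frame has columns
#'   `barcode`, `condition` (sample), `cell_type` (cluster) and `pair` id.
#' @export
match_in_embedding <- function(coords, clusters, samples, seed = 1) {
  check(is.matrix(coords) && is.numeric(coords), "coords must be a numeric matrix")
  check(nrow(coords) == length(clusters) && nrow(coords) == length(samples),
        "dimension mismatch between coords, clusters and samples")
  sm <- unique(samples)
  check(length(sm) == 2, "exactly two samples required")
  if (is.null(rownames(coords))) {
    rownames(coords) <- paste0("cell", seq_len(nrow(coords)))
  }

  pairs <- with_seed(seed, {
    out <- list()
    pair_id <- 0L
    for (cl in sort(unique(clusters))) {
      in_cl <- which(clusters == cl)
      a <- in_cl[samples[in_cl] == sm[1]]
      b <- in_cl[samples[in_cl] == sm[2]]
      if (length(a) == 0 || length(b) == 0) next
      if (length(a) <= length(b)) { small <- a; big <- b } else { small <- b; big <- a }
      small <- small[sample.int(length(small))]
      used <- rep(FALSE, length(big))
      for (i in small) {
        d2 <- colSums((t(coords[big, , drop = FALSE]) - coords[i, ])^2)
        d2[used] <- Inf
        j <- which.min(d2)
        used[j] <- TRUE
        pair_id <- pair_id + 1L
        out[[pair_id]] <- data.frame(
          barcode = c(rownames(coords)[i], rownames(coords)[big[j]]),
          condition = c(samples[i], samples[big[j]]),
          cell_type = cl, pair = pair_id, dist = unname(sqrt(d2[j])),
          stringsAsFactors = FALSE)
      }
    }
    out
  })
  kept <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(barcode = character(), condition = character(),
               cell_type = character(), pair = integer(), dist = numeric())
  rownames(kept) <- NULL
  counts <- table(kept$cell_type, kept$condition)
  structure(list(kept = kept, counts = counts, seed = seed),
            class = "SelectionResult")
}

#' Thin a count matrix to an exact UMI total
#'
#' Draws a uniform subsample of the matrix's UMIs without replacement
#' (multivariate hypergeometric), so the thinned total equals
#' `target_total` exactly and every entry is bounded by its original value.
#' This emulates the paper-style read down-sampling at the UMI level; for
#' saturation-sensitive comparisons `mode = "reads"` first inflates each
#' UMI to a Poisson number of reads (mean `reads_per_umi`), thins the
#' reads, and re-collapses to UMIs (the target total then applies to
#' reads).
#'
#' @param m A count matrix.
#' @param target_total Desired total (UMIs, or reads for `mode = "reads"`).
#' @param seed Integer seed.
#' @param mode `"umi"` (exact hypergeometric thinning, default) or
#'   `"reads"` (two-stage read-level thinning).
#' @param reads_per_umi Mean reads per molecule for `mode = "reads"`.
#' @return The thinned count matrix.
#' @export
thin_counts <- function(m, target_total, seed = 1, mode = c("umi", "reads"),
                        reads_per_umi = 4) {
  mode <- match.arg(mode)
  validate_count_matrix(m)
  total <- sum(m)
  check(target_total >= 0, "target_total must be >= 0")

  if (mode == "reads") {
    check(reads_per_umi >= 1, "reads_per_umi must be >= 1")
    return(with_seed(seed, {
      mm <- methods::as(m, "CsparseMatrix")
      n_umi <- as.integer(mm@x)
      entry_of_umi <- rep(seq_along(n_umi), n_umi)
      # every observed UMI carries >= 1 read
      reads_per_mol <- 1L + rpois(sum(n_umi), reads_per_umi - 1)
      total_reads <- sum(reads_per_mol)
      check(target_total <= total_reads,
            "target_total (%g) exceeds simulated read total (%g)",
            target_total, total_reads)
      # uniform subsample of reads == sequential hypergeometric over molecules
      draws_left <- target_total
      remaining <- total_reads
      kept_reads <- integer(length(reads_per_mol))
      for (i in seq_along(reads_per_mol)) {
        if (draws_left == 0) break
        remaining <- remaining - reads_per_mol[i]
        k <- rhyper(1, reads_per_mol[i], remaining, draws_left)
        kept_reads[i] <- k
        draws_left <- draws_left - k
      }
      # a molecule survives collapse iff >= 1 of its reads survives
      surv <- tabulate(entry_of_umi[kept_reads > 0], nbins = length(n_umi))
      mm@x <- as.numeric(surv)
      Matrix::drop0(mm)
    }))
  }

  check(target_total <= total, "target_total (%g) exceeds matrix total (%g)",
        target_total, total)
  with_seed(seed, hyper_thin(methods::as(m, "CsparseMatrix"), target_total))
}

# sequential conditional hypergeometric draws over the nonzero entries:
# entry i receives Hypergeometric(m = c_i, n = remaining, k = draws_left)
hyper_thin <- function(mm, target_total) {
  x <- mm@x
  total <- sum(x)
  draws_left <- target_total
  remaining <- total
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (draws_left == 0) break
    remaining <- remaining - x[i]
    k <- rhyper(1, x[i], remaining, draws_left)
    out[i] <- k
    draws_left <- draws_left - k
  }
  mm@x <- out
  Matrix::drop0(mm)
}

#' Sequencing saturation
#'
#' The 10x convention: `1 - n_umis / n_reads`, the fraction of reads that
#' re-observed an already-seen molecule.
#'
#' @param n_reads Total reads (> 0).
#' @param n_umis Unique molecules observed (`<= n_reads`).
#' @return Fraction in `[0, 1]`.
#' @examples
#' sequencing_saturation(1000, 230)  # 0.77
#' @export
sequencing_saturation <- function(n_reads, n_umis) {
  check(is.numeric(n_reads) && is.numeric(n_umis), "inputs must be numeric")
  check(all(n_reads > 0), "n_reads must be > 0")
  check(all(n_umis >= 0), "n_umis must be >= 0")
  check(all(n_umis <= n_reads), "n_umis cannot exceed n_reads")
  1 - n_umis / n_reads
}

#' Write a SelectionResult as CSV (barcode, condition, kept)
#' @param selection A `SelectionResult`.
#' @param path Output file.
#' @export
write_selection_csv <- function(selection, path) {
  utils::write.csv(selection$kept, path, row.names = FALSE)
  invisible(path)
}
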