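#' Detection threshold from empty-droplet background
#'
#' The positive/negative gate for a marker is derived from its ambient
#' signal: the empirical quantile (linear interpolation) of the marker's
#' counts across empty droplets, floored at `floor`. A cell is called
#' positive when its count is strictly greater than the threshold.
#'
#' @param empty_counts Numeric vector of the marker's counts in empty
#'   droplets.
#' @param quantile Background quantile defining the gate (default 0.99).
#' @param floor Minimum threshold (default 1).
#' @return UMI threshold `T`.
#' @export
detection_threshold <- function(empty_counts, quantile = 0.99, floor = 1) {
  check(is.numeric(quantile) && length(quantile) == 1L &&
          quantile > 0 && quantile < 1, "quantile must be in (0, 1)")
  if (length(empty_counts) < 100) {
    warning(sprintf("only %d empty droplets (< 100); threshold floored",
                    length(empty_counts)))
    if (length(empty_counts) == 0) return(floor)
  }
  max(floor, q_interp(empty_counts, quantile))
}

#' Per-antibody metric suite at one condition
#'
#' Computes, for one marker of a partitioned experiment:
#' * `total_umis_cells` — summed UMIs over cell-containing droplets;
#' * `q90_expressing` — 90th-percentile count within the expressing
#'   cluster (by default the cell type with the highest per-cell mean);
#' * `detection_threshold` and `positive_fraction` (gate from empty
#'   droplets, see [detection_threshold()]);
#' * `snr` — median count among positive cells minus median among
#'   negative cells (0 when no cell is positive);
#' * `umis_per_positive_pct` — the marker's share of all panel UMIs in
#'   cells, as a percentage, divided by its number of positive cells
#'   (`NA` when no cell is positive); with
#'   `per_positive_denominator = "marker"` the numerator is instead the
#'   marker's own cell-UMI total;
#' * `background_pct` — percentage of the marker's UMIs found in empty
#'   droplets;
#' * `freq_cells`, `freq_empty`, `freq_ratio` — the marker's frequency
#'   among panel UMIs within each compartment and their ratio (`NA` when
#'   the marker is absent from empty droplets).
#'
#' @param experiment A partitioned `DropletExperiment`.
#' @param marker Marker name.
#' @param expressing_cluster Optional cell-type label; default: panel
#'   override if present, else highest per-cell mean.
#' @param sample Optional sample label restricting the cell pool (pooled
#'   lanes); empty droplets are always shared.
#' @param quantile,floor Gate parameters passed to [detection_threshold()].
#' @param per_positive_denominator `"panel"` (default) or `"marker"`.
#' @return One-row `MarkerMetrics` data frame.
#' @export
marker_metrics <- function(experiment, marker, expressing_cluster = NULL,
                           sample = NULL, quantile = 0.99, floor = 1,
                           per_positive_denominator = c("panel", "marker")) {
  per_positive_denominator <- match.arg(per_positive_denominator)
  check(marker %in% rownames(experiment$adt), "unknown marker '%s'", marker)
  meta <- experiment$meta
  is_cell <- meta$droplet_class == "cell"
  if (!is.null(sample)) {
    is_cell <- is_cell & !is.na(meta$sample) & meta$sample == sample
  }
  check(any(is_cell), "no cells%s in experiment",
        if (is.null(sample)) "" else sprintf(" for sample '%s'", sample))
  is_empty <- meta$droplet_class == "empty"

  cell_bc <- meta$barcode[is_cell]
  empty_bc <- meta$barcode[is_empty]
  adt_cells <- experiment$adt[, cell_bc, drop = FALSE]
  adt_empty <- experiment$adt[, empty_bc, drop = FALSE]

  counts <- as.numeric(adt_cells[marker, ])
  empty_counts <- as.numeric(adt_empty[marker, ])

  thr <- detection_threshold(empty_counts, quantile = quantile, floor = floor)
  pos <- counts > thr
  n_pos <- sum(pos)
  snr <- if (n_pos == 0) 0 else median(counts[pos]) - median0(counts[!pos])

  # expressing cluster: panel override, else highest per-cell mean
  if (is.null(expressing_cluster)) {
    override <- experiment$panel$expected_expressing_cluster[
      experiment$panel$name == marker]
    if (length(override) == 1L && !is.na(override)) {
      expressing_cluster <- override
    }
  }
  cts <- meta$cell_type[is_cell]
  if (is.null(expressing_cluster)) {
    if (all(is.na(cts))) {
      expressing_cluster <- NA_character_
      q90 <- q_interp(counts, 0.90)
    } else {
      means <- tapply(counts, cts, mean)
      expressing_cluster <- names(means)[which.max(means)]
    }
  }
  if (!is.na(expressing_cluster)) {
    in_cl <- !is.na(cts) & cts == expressing_cluster
    check(any(in_cl), "no cells in expressing cluster '%s'", expressing_cluster)
    q90 <- q_interp(counts[in_cl], 0.90)
  }

  total_cells <- sum(counts)
  total_empty <- sum(empty_counts)
  panel_cells <- sum(adt_cells)
  panel_empty <- sum(adt_empty)

  upp <- if (n_pos == 0) NA_real_ else if (per_positive_denominator == "panel") {
    100 * (total_cells / panel_cells) / n_pos
  } else {
    total_cells / n_pos
  }
  freq_cells <- total_cells / panel_cells
  freq_empty <- if (panel_empty > 0) total_empty / panel_empty else NA_real_
  out <- data.frame(
    marker = marker,
    condition_id = experiment$condition$condition_id,
    expressing_cluster = expressing_cluster,
    total_umis_cells = total_cells,
    q90_expressing = q90,
    detection_threshold = thr,
    positive_fraction = n_pos / length(counts),
    n_positive = n_pos,
    snr = snr,
    umis_per_positive_pct = upp,
    background_pct = if (total_cells + total_empty > 0) {
      100 * total_empty / (total_empty + total_cells)
    } else NA_real_,
    freq_cells = freq_cells,
    freq_empty = freq_empty,
    freq_ratio = if (!is.na(freq_empty) && freq_empty > 0) {
      freq_cells / freq_empty
    } else NA_real_,
    stringsAsFactors = FALSE)
  class(out) <- c("MarkerMetrics", "data.frame")
  out
}

#' Titration response between a reference and a diluted condition
#'
#' Log2 responses are computed with a pseudocount so zero counts at low
#' depth stay finite: `log2((ref + pc) / (dil + pc))` for the total-UMI
#' and 90th-percentile metrics. `linearity_deviation` measures distance
#' from the ideal proportional response `log2(dilution_factor)`.
#'
#' @param ref,dil `MarkerMetrics` rows for the same marker.
#' @param dilution_factor Fold dilution between the two conditions (> 1).
#' @param pseudocount Added to both sides of each ratio (default 1).
#' @return A `TitrationRecord`: list with the two metric rows, the
#'   dilution factor, named `log2_response` and `linearity_deviation`
#'   vectors (elements `total_umis_cells`, `q90_expressing`).
#' @export
titration_response <- function(ref, dil, dilution_factor, pseudocount = 1) {
  check(ref$marker == dil$marker,
        "marker mismatch: '%s' vs '%s'", ref$marker, dil$marker)
  check(dilution_factor > 1, "dilution_factor must be > 1")
  resp <- c(
    total_umis_cells = log2((ref$total_umis_cells + pseudocount) /
                              (dil$total_umis_cells + pseudocount)),
    q90_expressing = log2((ref$q90_expressing + pseudocount) /
                            (dil$q90_expressing + pseudocount)))
  structure(list(marker = ref$marker, ref = ref, dil = dil,
                 dilution_factor = dilution_factor,
                 log2_response = resp,
                 linearity_deviation = abs(resp - log2(dilution_factor))),
            class = "TitrationRecord")
}

#' @export
print.TitrationRecord <- function(x, ...) {
  cat(sprintf(
    "TitrationRecord %s (DF%g): log2 response total %.2f, q90 %.2f (ideal %.2f)\n",
    x$marker, x$dilution_factor, x$log2_response[["total_umis_cells"]],
    x$log2_response[["q90_expressing"]], log2(x$dilution_factor)))
  invisible(x)
}

#' Metric and titration-response tables across conditions
#'
#' Computes [marker_metrics()] for every marker of every experiment, and
#' [titration_response()] of each non-reference condition against the
#' reference, giving one metrics row per (marker, condition) and one
#' response row per (marker, condition pair), in deterministic panel and
#' input order.
#'
#' @param experiments Named list of partitioned `DropletExperiment`
#'   objects sharing a panel; the first is the reference condition.
#' @param samples Optional named character vector mapping condition name
#'   to the sample label of a pooled lane (passed to [marker_metrics()]).
#' @param ... Passed to [marker_metrics()].
#' @return List with data frames `metrics` and `responses`, plus
#'   `records`, the underlying `TitrationRecord` objects keyed
#'   `"<marker>|<condition>"`.
#' @export
metrics_table <- function(experiments, samples = NULL, ...) {
  check(length(experiments) >= 1, "need at least one experiment")
  if (is.null(names(experiments))) {
    names(experiments) <- vapply(experiments,
                                 function(e) e$condition$condition_id, "")
  }
  markers <- rownames(experiments[[1]]$adt)
  for (e in experiments) {
    check(setequal(rownames(e$adt), markers),
          "experiments have disjoint or differing panels")
  }

  metrics <- do.call(rbind, unlist(recursive = FALSE, lapply(
    names(experiments), function(cond) {
      lapply(markers, function(mk) {
        marker_metrics(experiments[[cond]], mk,
                       sample = if (!is.null(samples)) samples[[cond]] else NULL,
                       ...)
      })
    })))

  records <- list()
  responses <- NULL
  if (length(experiments) > 1) {
    ref_name <- names(experiments)[1]
    ref_df <- experiments[[ref_name]]$condition$dilution_factor
    for (cond in names(experiments)[-1]) {
      dfact <- experiments[[cond]]$condition$dilution_factor / ref_df
      for (mk in markers) {
        ref <- metrics[metrics$marker == mk & metrics$condition_id ==
                         experiments[[ref_name]]$condition$condition_id, ]
        dil <- metrics[metrics$marker == mk & metrics$condition_id ==
                         experiments[[cond]]$condition$condition_id, ]
        rec <- titration_response(ref, dil, dfact)
        records[[paste(mk, cond, sep = "|")]] <- rec
        responses <- rbind(responses, data.frame(
          marker = mk, condition_ref = ref$condition_id,
          condition_dil = dil$condition_id, dilution_factor = dfact,
          log2_response_total = rec$log2_response[["total_umis_cells"]],
          log2_response_q90 = rec$log2_response[["q90_expressing"]],
          linearity_deviation_q90 = rec$linearity_deviation[["q90_expressing"]],
          stringsAsFactors = FALSE))
      }
    }
  }
  rownames(metrics) <- NULL
  list(metrics = metrics, responses = responses, records = records)
}
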