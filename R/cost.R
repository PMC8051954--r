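#' Antibody reagent cost of staining one sample
#'
#' `cost = sum(concentration_ug_ml) * volume_ul / 1000 * price_usd_per_ug`.
#' The default price corresponds to a list price of 325 USD per 10 ug of
#' conjugated antibody.
#'
#' @param panel An `AntibodyPanel`, or a numeric vector of per-marker
#'   concentrations in ug/mL.
#' @param volume_ul Staining volume in microlitres.
#' @param price_usd_per_ug Price per microgram (default 32.5).
#' @param condition Condition id or [staining_condition()] used to look up
#'   concentrations when `panel` is an `AntibodyPanel` (default `"DF1"`).
#' @return Cost in USD per sample.
#' @examples
#' panel_cost(rep(10, 52), volume_ul = 100)  # 1690
#' @export
panel_cost <- function(panel, volume_ul, price_usd_per_ug = 32.5,
                       condition = "DF1") {
  conc <- if (inherits(panel, "AntibodyPanel")) {
    panel_concentration(panel, condition)
  } else {
    panel
  }
  check(is.numeric(conc) && all(conc >= 0), "concentrations must be >= 0")
  check(is.numeric(volume_ul) && volume_ul > 0, "volume_ul must be > 0")
  check(is.numeric(price_usd_per_ug) && price_usd_per_ug > 0,
        "price_usd_per_ug must be > 0")
  sum(conc) * (volume_ul / 1000) * price_usd_per_ug
}

#' Fold and percent change between two quantities
#'
#' Values are reported unrounded; round only at the presentation layer
#' (whole percents, one-decimal folds).
#'
#' @param before Reference value (> 0).
#' @param after Comparison value (>= 0; must be > 0 for the fold change).
#' @return List with `fold_change = before / after` and
#'   `percent_change = 100 * (after - before) / before`.
#' @examples
#' comparison_stats(761350, 474404)$percent_change  # -37.69...
#' @export
comparison_stats <- function(before, after) {
  check(is.numeric(before) && length(before) == 1L && before > 0,
        "before must be a single value > 0")
  check(is.numeric(after) && length(after) == 1L && after >= 0,
        "after must be a single value >= 0")
  check(after > 0, "after must be > 0 for a finite fold change")
  list(fold_change = before / after,
       percent_change = 100 * (after - before) / before)
}

#' Sequencing-read allocation across the panel
#'
#' From a per-condition metrics table, the share of total panel UMIs each
#' marker consumes, split into cell-borne and empty-droplet ("wasted")
#' fractions, plus the overall background share
#' `sum(empty) / (sum(empty) + sum(cells))`.
#'
#' @param metrics `MarkerMetrics` data frame for all markers at one
#'   condition (as from [metrics_table()]).
#' @return List with `per_marker` (data frame: `marker`, `total_share`,
#'   `cell_share`, `wasted_share`) and `background_share`.
#' @export
read_allocation <- function(metrics) {
  check(is.data.frame(metrics) && nrow(metrics) > 0, "empty metrics table")
  check(length(unique(metrics$condition_id)) == 1L,
        "metrics must come from a single condition")
  cell_umis <- metrics$total_umis_cells
  # invert background_pct to recover the empty totals
  empty_umis <- ifelse(metrics$background_pct < 100,
                       cell_umis * metrics$background_pct /
                         (100 - metrics$background_pct),
                       NA_real_)
  # markers with all UMIs in empties: recover via freq_empty
  if (anyNA(empty_umis)) {
    known <- !is.na(empty_umis)
    if (!any(known)) {
      # pure-background panel: only relative shares are defined
      return(list(per_marker = data.frame(marker = metrics$marker,
                                          total_share = metrics$freq_empty,
                                          cell_share = 0,
                                          wasted_share = metrics$freq_empty,
                                          stringsAsFactors = FALSE),
                  background_share = 1))
    }
    panel_empty <- sum(empty_umis[known]) / sum(metrics$freq_empty[known])
    empty_umis[!known] <- metrics$freq_empty[!known] * panel_empty
  }
  grand <- sum(cell_umis) + sum(empty_umis)
  check(grand > 0, "no UMIs in metrics table")
  per_marker <- data.frame(marker = metrics$marker,
                           total_share = (cell_umis + empty_umis) / grand,
                           cell_share = cell_umis / grand,
                           wasted_share = empty_umis / grand,
                           stringsAsFactors = FALSE)
  list(per_marker = per_marker,
       background_share = sum(empty_umis) / grand)
}

#' Chip-loading cell concentration
#'
#' @param target_cells Cells to load (> 0).
#' @param load_volume_ul Loading volume in microlitres (> 0).
#' @return Cells per microlitre, rounded to the nearest integer (>= 1).
#' @examples
#' loading_concentration(41645, 31.7)  # 1314
#' @export
loading_concentration <- function(target_cells, load_volume_ul) {
  check(is.numeric(target_cells) && target_cells > 0,
        "target_cells must be > 0")
  check(is.numeric(load_volume_ul) && load_volume_ul > 0,
        "load_volume_ul must be > 0")
  conc <- round(target_cells / load_volume_ul)
  check(conc >= 1, "loading concentration rounds to < 1 cell/uL")
  conc
}
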