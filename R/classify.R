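#' Decision boundaries for titration-response classification
#'
#' The five response categories are qualitative in origin; this config
#' makes every boundary explicit and tunable:
#' * `r_min` — minimal |log2 response| of the 90th-percentile signal to
#'   count as responding to dilution (default 0.5);
#' * `s_min` — minimal signal-to-noise (median positive minus median
#'   negative, UMIs) for positive/negative separation (default 5);
#' * `f_min` — minimal positive fraction regarded as a real population
#'   (default 0.005);
#' * `u_min` — positive fraction above which a marker counts as
#'   ubiquitously expressed (default 0.90);
#' * `b_high` — background percentage marking a background-dominated
#'   marker (default 50);
#' * `e_max` — maximal share of panel cell-UMIs for a "no signal" marker
#'   (default 0.002);
#' * `t_low` — detection threshold (UMIs) below which the gate offers
#'   little headroom (default 3).
#'
#' @param r_min,s_min,f_min,u_min,b_high,e_max,t_low See above.
#' @return A `ClassifierConfig` list.
#' @export
classifier_config <- function(r_min = 0.5, s_min = 5, f_min = 0.005,
                              u_min = 0.90, b_high = 50, e_max = 0.002,
                              t_low = 3) {
  check(r_min >= 0, "r_min must be >= 0")
  check(s_min >= 0, "s_min must be >= 0")
  check(f_min >= 0 && f_min <= 1, "f_min must be in [0, 1]")
  check(u_min > 0 && u_min <= 1, "u_min must be in (0, 1]")
  check(b_high >= 0 && b_high <= 100, "b_high must be in [0, 100]")
  check(e_max >= 0 && e_max <= 1, "e_max must be in [0, 1]")
  check(t_low >= 0, "t_low must be >= 0")
  structure(list(r_min = r_min, s_min = s_min, f_min = f_min, u_min = u_min,
                 b_high = b_high, e_max = e_max, t_low = t_low),
            class = "ClassifierConfig")
}

#' Classify a marker's dilution response (categories A-E)
#'
#' Ordered decision rules over a [titration_response()] record; the first
#' match wins, so a ubiquitous, linearly responding marker is D rather
#' than B:
#' * **D** — ubiquitously expressed: positive fraction at reference
#'   `>= u_min` with separation (`snr >= s_min`);
#' * **E** — no functional signal: `snr < s_min` at both conditions and a
#'   negligible share of panel cell-UMIs (`< e_max`);
#' * **A** — saturated / absent / obscured: |log2 q90 response| `< r_min`
#'   while either never separating or background-dominated
#'   (`background_pct >= b_high`);
#' * **B** — responds but keeps separating at both conditions;
#' * **C** — responds and separation degrades on dilution (`snr` falls
#'   below `s_min`, or the diluted gate sits at `<= t_low` UMIs);
#' * `"review"` otherwise.
#'
#' @param record A `TitrationRecord`.
#' @param config A [classifier_config()].
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"review"`.
#' @export
classify_marker <- function(record, config = classifier_config()) {
  check(inherits(record, "TitrationRecord"), "record must be a TitrationRecord")
  ref <- record$ref
  dil <- record$dil
  r <- record$log2_response[["q90_expressing"]]
  sep_ref <- ref$snr >= config$s_min
  sep_dil <- dil$snr >= config$s_min

  if (ref$positive_fraction >= config$u_min && sep_ref) return("D")
  if (!sep_ref && !sep_dil && ref$freq_cells < config$e_max) return("E")
  if (abs(r) < config$r_min &&
      ((!sep_ref && !sep_dil) || ref$background_pct >= config$b_high)) {
    return("A")
  }
  if (r >= config$r_min && sep_ref && sep_dil) return("B")
  if (r >= config$r_min && sep_ref &&
      (!sep_dil || dil$detection_threshold <= config$t_low)) {
    return("C")
  }
  "review"
}

#' Concentration recommendation for a classified marker
#'
#' Default actions per category: **A** reduce to a quarter (background
#' dominates, reducing is always right); **B** halve (separation is kept,
#' so signal is bought cheaper); **C** keep (or reduce mildly to 0.8x when
#' the reference gate is well above `2 * t_low`); **D** quarter and flag
#' for dropping (ubiquitous markers rarely justify their reads); **E**
#' triple and flag for review (possible non-functional antibody or absent
#' epitope); `"review"` keep.
#'
#' @param category Category letter from [classify_marker()].
#' @param current_conc Current concentration, ug/mL.
#' @param record The underlying `TitrationRecord` (used in the rationale).
#' @param config A [classifier_config()].
#' @param multipliers Named numeric overrides of the default multipliers.
#' @return A `Recommendation`: one-row data frame with `marker`,
#'   `category`, `action`, `multiplier`, `new_concentration`,
#'   `drop_suggested`, `review_flag`, `rationale`.
#' @export
recommend_adjustment <- function(category, current_conc, record,
                                 config = classifier_config(),
                                 multipliers = NULL) {
  defaults <- c(A = 0.25, B = 0.5, C = 1.0, D = 0.25, E = 3.0, review = 1.0)
  if (!is.null(multipliers)) defaults[names(multipliers)] <- multipliers
  check(category %in% names(defaults), "unknown category '%s'", category)
  mult <- unname(defaults[category])
  action <- switch(category,
                   A = "reduce", B = "reduce", C = "keep", D = "reduce",
                   E = "increase", review = "review")
  drop_suggested <- category == "D"
  review_flag <- category %in% c("E", "review")
  if (category == "C" && record$ref$detection_threshold > 2 * config$t_low &&
      is.null(multipliers)) {
    mult <- 0.8
    action <- "reduce"
  }
  rationale <- sprintf(
    "category %s: log2 q90 response %.2f, snr %g -> %g, background %.1f%%, positive fraction %.3f",
    category, record$log2_response[["q90_expressing"]],
    record$ref$snr, record$dil$snr, record$ref$background_pct,
    record$ref$positive_fraction)
  out <- data.frame(marker = record$marker, category = category,
                    action = action, multiplier = mult,
                    new_concentration = current_conc * mult,
                    drop_suggested = drop_suggested,
                    review_flag = review_flag,
                    rationale = rationale, stringsAsFactors = FALSE)
  class(out) <- c("Recommendation", "data.frame")
  out
}

#' Classify every marker of a metrics table
#'
#' @param tbl Output of [metrics_table()] (with responses).
#' @param panel The `AntibodyPanel` (for current concentrations).
#' @param condition The reference [staining_condition()] (for
#'   concentration lookup).
#' @param config A [classifier_config()].
#' @return Data frame of one [recommend_adjustment()] row per marker.
#' @export
classify_panel <- function(tbl, panel, condition,
                           config = classifier_config()) {
  check(length(tbl$records) > 0, "metrics table has no titration records")
  conc <- panel_concentration(panel, condition)
  recs <- lapply(tbl$records, function(rec) {
    cat_ <- classify_marker(rec, config)
    recommend_adjustment(cat_, conc[[rec$marker]], rec, config)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Reconcile per-tissue categories for one marker
#'
#' A marker separating well in any tissue is not non-functional; ties are
#' resolved by the priority D > B > C > A > E (then `"review"`).
#'
#' @param categories Character vector of per-tissue category letters.
#' @return The reconciled category.
#' @export
reconcile_categories <- function(categories) {
  priority <- c("D", "B", "C", "A", "E", "review")
  hit <- priority[priority %in% categories]
  check(length(hit) > 0, "no recognizable categories in input")
  hit[1]
}

#' Apply recommendations to a panel
#'
#' Scales each marker's concentration by its recommended multiplier in a
#' new condition column; markers whose drop was confirmed are removed.
#' An audit log of old vs new concentrations is attached as
#' `attr(, "audit")`.
#'
#' @param panel An `AntibodyPanel`.
#' @param recommendations Output of [classify_panel()]; must cover every
#'   panel marker.
#' @param condition_id Condition whose concentrations are adjusted
#'   (default `"DF1"`).
#' @param new_condition_id Name of the adjusted condition column (default
#'   `"adjusted"`).
#' @param confirm_drops Character vector of markers whose drop suggestion
#'   is confirmed (removed from the output panel).
#' @return The adjusted `AntibodyPanel`.
#' @export
adjust_panel <- function(panel, recommendations, condition_id = "DF1",
                         new_condition_id = "adjusted",
                         confirm_drops = character()) {
  missing <- setdiff(panel$name, recommendations$marker)
  check(length(missing) == 0, "missing recommendation for marker(s): %s",
        paste(missing, collapse = ", "))
  idx <- match(panel$name, recommendations$marker)
  old <- panel[[paste0("concentration_", condition_id)]]
  check(!is.null(old), "panel has no column for condition '%s'", condition_id)
  new <- old * recommendations$multiplier[idx]
  panel[[paste0("concentration_", new_condition_id)]] <- new
  audit <- data.frame(marker = panel$name, old_concentration = old,
                      new_concentration = new,
                      multiplier = recommendations$multiplier[idx],
                      dropped = panel$name %in% confirm_drops,
                      stringsAsFactors = FALSE)
  if (length(confirm_drops) > 0) {
    message(sprintf("adjust_panel: dropping confirmed marker(s): %s",
                    paste(intersect(panel$name, confirm_drops), collapse = ", ")))
    panel <- panel[!panel$name %in% confirm_drops, , drop = FALSE]
  }
  attr(panel, "audit") <- audit
  panel
}
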