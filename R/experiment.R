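#' Describe one staining condition
#'
#' A staining condition records the four titration variables: the panel-wide
#' dilution factor relative to the starting concentrations (DF1 = starting),
#' the staining volume, the number of cells present at staining, and the
#' tissue of origin.
#'
#' @param condition_id Condition label, e.g. `"DF1"`.
#' @param dilution_factor Positive number; 1 means starting concentration,
#'   4 means every antibody at one quarter of it.
#' @param volume_ul Staining volume in microlitres.
#' @param cells_stained Number of cells present at staining.
#' @param tissue Tissue label (e.g. `"PBMC"`).
#' @return A `StainingCondition` object.
#' @export
staining_condition <- function(condition_id, dilution_factor = 1,
                               volume_ul = 25, cells_stained = 1e6,
                               tissue = "PBMC") {
  check(is.character(condition_id) && length(condition_id) == 1L,
        "condition_id must be a single string")
  check(is.numeric(dilution_factor) && dilution_factor > 0,
        "dilution_factor must be > 0")
  check(is.numeric(volume_ul) && volume_ul > 0, "volume_ul must be > 0")
  check(is.numeric(cells_stained) && cells_stained > 0,
        "cells_stained must be > 0")
  structure(list(condition_id = condition_id,
                 dilution_factor = dilution_factor,
                 volume_ul = volume_ul,
                 cells_stained = cells_stained,
                 tissue = tissue),
            class = "StainingCondition")
}

#' @export
print.StainingCondition <- function(x, ...) {
  cat(sprintf("StainingCondition '%s': DF%g, %g uL, %g cells, tissue %s\n",
              x$condition_id, x$dilution_factor, x$volume_ul,
              x$cells_stained, x$tissue))
  invisible(x)
}

#' Construct an antibody panel sheet
#'
#' A panel is a data frame with one row per marker carrying the staining
#' concentration for each condition (columns `concentration_<condition_id>`,
#' in ug/mL), an isotype-control flag and an optional expected expressing
#' cell type used when computing 90th-percentile signal.
#'
#' @param name Character vector of unique marker names.
#' @param concentrations Named list (or single numeric vector) of per-marker
#'   concentrations in ug/mL; names are condition ids. A single unnamed
#'   vector is stored under condition `"DF1"`.
#' @param is_isotype_control Logical vector (recycled).
#' @param expected_expressing_cluster Optional character vector of cell-type
#'   labels (NA = choose automatically).
#' @return An `AntibodyPanel` data frame.
#' @export
antibody_panel <- function(name, concentrations,
                           is_isotype_control = FALSE,
                           expected_expressing_cluster = NA_character_) {
  check(!anyDuplicated(name), "marker names must be unique")
  if (!is.list(concentrations)) concentrations <- list(DF1 = concentrations)
  check(!is.null(names(concentrations)) && all(nzchar(names(concentrations))),
        "concentrations must be a named list keyed by condition id")
  panel <- data.frame(name = as.character(name),
                      is_isotype_control = rep_len(is_isotype_control, length(name)),
                      expected_expressing_cluster =
                        rep_len(expected_expressing_cluster, length(name)),
                      stringsAsFactors = FALSE)
  for (cond in names(concentrations)) {
    conc <- rep_len(concentrations[[cond]], length(name))
    check(all(conc >= 0), "concentrations must be >= 0")
    panel[[paste0("concentration_", cond)]] <- conc
  }
  class(panel) <- c("AntibodyPanel", "data.frame")
  panel
}

#' Look up per-marker concentrations for one condition
#'
#' Falls back to the `concentration_DF1` column scaled by a staining
#' condition's dilution factor when the panel has no dedicated column for
#' that condition.
#'
#' @param panel An `AntibodyPanel`.
#' @param condition A condition id string or a [staining_condition()].
#' @return Named numeric vector of ug/mL concentrations.
#' @export
panel_concentration <- function(panel, condition) {
  if (inherits(condition, "StainingCondition")) {
    col <- paste0("concentration_", condition$condition_id)
    if (!col %in% names(panel)) {
      base <- panel[["concentration_DF1"]]
      check(!is.null(base),
            "panel has neither a column for condition '%s' nor a DF1 column",
            condition$condition_id)
      return(setNames(base / condition$dilution_factor, panel$name))
    }
  } else {
    col <- paste0("concentration_", condition)
  }
  check(col %in% names(panel), "panel has no column '%s'", col)
  setNames(panel[[col]], panel$name)
}

#' Read / write a panel sheet CSV
#'
#' Columns: `name`, one `concentration_<condition_id>` per condition,
#' `is_isotype_control`, optional `expected_expressing_cluster`.
#'
#' @param path CSV file.
#' @return An `AntibodyPanel`.
#' @export
read_panel_csv <- function(path) {
  check(file.exists(path), "missing file: '%s'", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check("name" %in% names(df), "panel sheet must have a 'name' column")
  conc_cols <- grep("^concentration_", names(df), value = TRUE)
  check(length(conc_cols) > 0, "panel sheet has no concentration_<condition> column")
  if (is.null(df$is_isotype_control)) df$is_isotype_control <- FALSE
  if (is.null(df$expected_expressing_cluster)) {
    df$expected_expressing_cluster <- NA_character_
  }
  conc <- lapply(conc_cols, function(cc) df[[cc]])
  names(conc) <- sub("^concentration_", "", conc_cols)
  antibody_panel(df$name, conc, as.logical(df$is_isotype_control),
                 df$expected_expressing_cluster)
}

#' @rdname read_panel_csv
#' @param panel An `AntibodyPanel` to write.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Assemble a droplet experiment from aligned modalities
#'
#' Restricts all modalities to their shared barcodes (reporting the number
#' dropped), checks that the panel covers every ADT feature (optionally
#' after stripping a vendor conjugate suffix such as `"-TotalSeqC"`), and
#' initializes the per-barcode droplet class to `"unassigned"`.
#'
#' @param adt ADT count matrix (features x barcodes).
#' @param panel An [antibody_panel()] covering all ADT features.
#' @param condition A [staining_condition()].
#' @param rna,hto Optional RNA / hashtag count matrices on the same barcode
#'   universe.
#' @param metadata Optional data frame with a `barcode` column plus any of
#'   `cell_type`, `sample`, embedding coordinate columns.
#' @param strip_suffix Optional suffix removed from ADT feature names before
#'   matching panel marker names.
#' @return A `DropletExperiment`: list with elements `adt`, `rna`, `hto`,
#'   `panel`, `condition` and a per-barcode `meta` data frame
#'   (`barcode`, `droplet_class`, `sample`, `cell_type`).
#' @export
build_experiment <- function(adt, panel, condition, rna = NULL, hto = NULL,
                             metadata = NULL, strip_suffix = NULL) {
  validate_count_matrix(adt)
  check(inherits(panel, "AntibodyPanel"), "panel must be an AntibodyPanel")
  check(inherits(condition, "StainingCondition"),
        "condition must be a StainingCondition")

  if (!is.null(strip_suffix) && nzchar(strip_suffix)) {
    rownames(adt) <- sub(paste0(gsub("([^[:alnum:]])", "\\\\\\1", strip_suffix), "$"),
                         "", rownames(adt))
  }
  missing <- setdiff(rownames(adt), panel$name)
  check(length(missing) == 0,
        "ADT features absent from panel: %s", paste(missing, collapse = ", "))

  shared <- colnames(adt)
  for (mod in list(rna, hto)) {
    if (!is.null(mod)) shared <- intersect(shared, colnames(mod))
  }
  n_all <- length(unique(c(colnames(adt),
                           if (!is.null(rna)) colnames(rna),
                           if (!is.null(hto)) colnames(hto))))
  dropped <- n_all - length(shared)
  if (dropped > 0) {
    message(sprintf("build_experiment: %d barcode(s) not shared by all modalities dropped",
                    dropped))
  }
  check(length(shared) > 0, "modalities share no barcodes")
  shared <- sort(shared)

  adt <- adt[, shared, drop = FALSE]
  if (!is.null(rna)) { validate_count_matrix(rna); rna <- rna[, shared, drop = FALSE] }
  if (!is.null(hto)) { validate_count_matrix(hto); hto <- hto[, shared, drop = FALSE] }

  meta <- data.frame(barcode = shared,
                     droplet_class = "unassigned",
                     sample = NA_character_,
                     cell_type = NA_character_,
                     stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    check("barcode" %in% names(metadata), "metadata must have a 'barcode' column")
    idx <- match(meta$barcode, metadata$barcode)
    for (col in setdiff(names(metadata), "barcode")) {
      meta[[col]] <- metadata[[col]][idx]
    }
    if (is.null(meta$droplet_class) || all(is.na(meta$droplet_class))) {
      meta$droplet_class <- "unassigned"
    }
    meta$droplet_class[is.na(meta$droplet_class)] <- "unassigned"
  }
  rownames(meta) <- NULL

  structure(list(adt = adt, rna = rna, hto = hto, panel = panel,
                 condition = condition, meta = meta),
            class = "DropletExperiment")
}

#' @export
print.DropletExperiment <- function(x, ...) {
  cls <- table(x$meta$droplet_class)
  cat(sprintf("DropletExperiment: %d ADT markers x %d barcodes (%s)\n",
              nrow(x$adt), ncol(x$adt),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", ")))
  cat(sprintf("  modalities: ADT%s%s; condition %s\n",
              if (!is.null(x$rna)) " + RNA" else "",
              if (!is.null(x$hto)) " + HTO" else "",
              x$condition$condition_id))
  invisible(x)
}

#' Restrict an experiment to a barcode subset
#'
#' @param experiment A `DropletExperiment`.
#' @param barcodes Barcodes to keep.
#' @return The restricted `DropletExperiment`.
#' @export
subset_experiment <- function(experiment, barcodes) {
  check(all(barcodes %in% experiment$meta$barcode),
        "unknown barcodes in subset")
  experiment$adt <- experiment$adt[, barcodes, drop = FALSE]
  if (!is.null(experiment$rna)) {
    experiment$rna <- experiment$rna[, barcodes, drop = FALSE]
  }
  if (!is.null(experiment$hto)) {
    experiment$hto <- experiment$hto[, barcodes, drop = FALSE]
  }
  experiment$meta <- experiment$meta[match(barcodes, experiment$meta$barcode), ,
                                     drop = FALSE]
  rownames(experiment$meta) <- NULL
  experiment
}

#' Split a pooled (hashed) lane into per-condition experiments
#'
#' In a pooled lane several staining conditions share one droplet
#' partition; every condition keeps the full set of empty droplets (they
#' are a common ambient readout) while cell-containing droplets are divided
#' by their sample assignment.
#'
#' @param experiment A partitioned `DropletExperiment` with `meta$sample`
#'   filled for cell barcodes.
#' @param conditions Named list of [staining_condition()] objects keyed by
#'   sample label.
#' @return Named list of `DropletExperiment` objects, one per condition.
#' @export
split_lane <- function(experiment, conditions) {
  check(!is.null(names(conditions)) && all(nzchar(names(conditions))),
        "conditions must be a named list keyed by sample label")
  empty_bc <- experiment$meta$barcode[experiment$meta$droplet_class == "empty"]
  lapply(setNames(names(conditions), names(conditions)), function(s) {
    cell_bc <- experiment$meta$barcode[
      experiment$meta$droplet_class == "cell" &
        !is.na(experiment$meta$sample) & experiment$meta$sample == s]
    out <- subset_experiment(experiment, c(cell_bc, empty_bc))
    out$condition <- conditions[[s]]
    out
  })
}
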