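#' Free-antibody concentration at binding equilibrium
#'
#' Single-site equilibrium binding with ligand depletion. With total
#' antibody concentration `C_tot`, total epitope concentration `R_tot`
#' (same units) and dissociation constant `Kd`, the free concentration is
#' the unique non-negative root of
#' `C_free^2 + (R_tot + Kd - C_tot) * C_free - Kd * C_tot = 0`,
#' computed in the cancellation-stable closed form. Epitope occupancy is
#' `C_free / (C_free + Kd)`. This is the simplest model that exhibits a
#' saturation plateau, a linear low-concentration range, and the
#' staining-volume and cell-number dependence of antibody signal.
#'
#' @param c_tot Total antibody concentration (ug/mL), vectorized.
#' @param r_tot Total epitope concentration (ug/mL antibody-equivalents).
#' @param kd Dissociation constant (ug/mL), > 0.
#' @return Free antibody concentration `C_free` (same shape as inputs).
#' @examples
#' free_antibody_equilibrium(1, 0, 0.1)        # no depletion: C_free = C_tot
#' free_antibody_equilibrium(1, 0.5, 1e-12)    # stoichiometric: ~ 0.5
#' @export
free_antibody_equilibrium <- function(c_tot, r_tot, kd) {
  check(all(c_tot >= 0) && all(r_tot >= 0), "concentrations must be >= 0")
  check(all(kd > 0), "kd must be > 0")
  b <- r_tot + kd - c_tot
  disc <- sqrt(b^2 + 4 * kd * c_tot)
  # root = (-b + disc) / 2; rewritten via the conjugate when b >= 0 to
  # avoid catastrophic cancellation at small Kd
  ifelse(b >= 0, 2 * kd * c_tot / (b + disc), (disc - b) / 2)
}

#' Epitope occupancy at a given free-antibody concentration
#' @param c_free Free antibody concentration (ug/mL).
#' @param kd Dissociation constant (ug/mL).
#' @return Occupancy in `[0, 1)`.
#' @export
binding_occupancy <- function(c_free, kd) {
  c_free / (c_free + kd)
}

#' Total epitope concentration of a staining reaction
#'
#' Converts an epitope copy number per cell into the antibody-equivalent
#' mass concentration seen by the binding equilibrium, using an IgG
#' molecular weight of 150 kDa.
#'
#' @param cells_stained Cells present at staining.
#' @param epitopes_per_cell Mean epitope copies per stained cell.
#' @param volume_ul Staining volume in microlitres.
#' @param mw_da Molecular weight used for the conversion (default 150 kDa).
#' @return Concentration in ug/mL.
#' @export
epitope_concentration <- function(cells_stained, epitopes_per_cell, volume_ul,
                                  mw_da = 150000) {
  avogadro <- 6.02214076e23
  mol <- cells_stained * epitopes_per_cell / avogadro
  mol / (volume_ul * 1e-6) * mw_da * 1000
}

#' Specify one simulated marker
#'
#' @param name Marker name.
#' @param concentration_ug_ml Staining concentration at the starting
#'   condition (DF1), ug/mL.
#' @param kd_ug_ml Dissociation constant, ug/mL.
#' @param epitopes_per_cell Named numeric vector of epitope copies per
#'   cell by cell type; unnamed types default to 0 copies.
#' @param ground_truth_category Optional A-E label for archetypes.
#' @return A `MarkerSpec` list.
#' @export
marker_spec <- function(name, concentration_ug_ml, kd_ug_ml,
                        epitopes_per_cell = numeric(),
                        ground_truth_category = NA_character_) {
  check(kd_ug_ml > 0, "kd must be > 0")
  check(concentration_ug_ml >= 0, "concentration must be >= 0")
  check(all(epitopes_per_cell >= 0), "epitope counts must be >= 0")
  structure(list(name = name, concentration_ug_ml = concentration_ug_ml,
                 kd_ug_ml = kd_ug_ml, epitopes_per_cell = epitopes_per_cell,
                 ground_truth_category = ground_truth_category),
            class = "MarkerSpec")
}

#' Simulation configuration
#'
#' Defaults describe a hashed titration lane: a handful of immune cell
#' types, a few hundred captured cells per condition vastly outnumbered by
#' empty droplets, a small fraction of post-equilibrium free antibody
#' surviving the washes into the emulsion, and finite sequencing depth.
#'
#' @param cell_type_proportions Named proportions summing to 1.
#' @param n_cells Captured cells per condition.
#' @param n_empty Empty droplets in the lane.
#' @param capture_efficiency Probability that a bound antibody molecule is
#'   captured and counted, in (0, 1].
#' @param wash_retention Fraction `w` of free antibody surviving washes
#'   into the emulsion, in \[0, 1\].
#' @param ambient_scale Expected ambient molecules per droplet per unit of
#'   retained free concentration (ug/mL).
#' @param reads_per_umi Mean sequencing reads per molecule; a molecule is
#'   detected with probability `1 - exp(-reads_per_umi)`.
#' @param n_rna_genes,rna_umis_cell,rna_umis_empty,mito_frac RNA-lite
#'   generator: gene count (including 10 `MT-` genes), mean totals for
#'   cells and empties, mitochondrial weight share.
#' @param hto_signal,hto_ambient Mean own-sample and ambient HTO counts.
#' @param seed Integer seed; all draws come from one stream.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(cell_type_proportions = c(Tcell = 0.4, Bcell = 0.2,
                                                 Myeloid = 0.3, NK = 0.1),
                       n_cells = 500, n_empty = 5000,
                       capture_efficiency = 2e-3, wash_retention = 0.05,
                       ambient_scale = 16, reads_per_umi = 1.5,
                       n_rna_genes = 200, rna_umis_cell = 800,
                       rna_umis_empty = 10, mito_frac = 0.05,
                       hto_signal = 60, hto_ambient = 0.5, seed = 1) {
  check(abs(sum(cell_type_proportions) - 1) < 1e-8,
        "cell type proportions must sum to 1")
  check(!is.null(names(cell_type_proportions)), "cell types must be named")
  check(n_cells >= 1, "n_cells must be >= 1")
  check(n_empty >= 0, "n_empty must be >= 0")
  check(capture_efficiency > 0 && capture_efficiency <= 1,
        "capture_efficiency must be in (0, 1]")
  check(wash_retention >= 0 && wash_retention <= 1,
        "wash_retention must be in [0, 1]")
  check(ambient_scale >= 0, "ambient_scale must be >= 0")
  check(reads_per_umi > 0, "reads_per_umi must be > 0")
  check(n_rna_genes > 10, "need more than 10 genes")
  structure(list(cell_type_proportions = cell_type_proportions,
                 n_cells = n_cells, n_empty = n_empty,
                 capture_efficiency = capture_efficiency,
                 wash_retention = wash_retention,
                 ambient_scale = ambient_scale,
                 reads_per_umi = reads_per_umi,
                 n_rna_genes = n_rna_genes, rna_umis_cell = rna_umis_cell,
                 rna_umis_empty = rna_umis_empty, mito_frac = mito_frac,
                 hto_signal = hto_signal, hto_ambient = hto_ambient,
                 seed = seed),
            class = "SimConfig")
}

marker_theta <- function(spec, config, condition) {
  types <- names(config$cell_type_proportions)
  epi <- setNames(rep(0, length(types)), types)
  known <- intersect(names(spec$epitopes_per_cell), types)
  epi[known] <- spec$epitopes_per_cell[known]
  mean_epi <- sum(epi * config$cell_type_proportions)
  c_tot <- spec$concentration_ug_ml / condition$dilution_factor
  r_tot <- epitope_concentration(condition$cells_stained, mean_epi,
                                 condition$volume_ul)
  c_free <- free_antibody_equilibrium(c_tot, r_tot, spec$kd_ug_ml)
  list(epitopes = epi, c_tot = c_tot, r_tot = r_tot, c_free = c_free,
       occupancy = binding_occupancy(c_free, spec$kd_ug_ml))
}

#' Simulate a pooled (hashed) droplet lane with ground truth
#'
#' Each condition's cells are stained separately (own equilibrium, so
#' dilution, staining volume and cell number act through the binding
#' model), then pooled into one lane: every droplet — cell-containing or
#' empty — receives ambient molecules from a single shared pool
#' proportional to the mean retained free-antibody concentration across
#' the pooled conditions, which is why background-dominated markers show
#' no apparent dilution response. Counts are Poisson molecules thinned
#' binomially with detection probability `1 - exp(-reads_per_umi)`.
#'
#' @param markers List of [marker_spec()] objects.
#' @param config A [sim_config()].
#' @param conditions Named list of [staining_condition()] objects; names
#'   are the HTO sample labels.
#' @return List with `experiment` (a `DropletExperiment` whose metadata
#'   carries cell-type labels but unassigned droplet classes/samples) and
#'   `truth` (`markers`: per marker x condition equilibrium truth and
#'   ambient expectations; `droplets`: true class/sample per barcode;
#'   `background_share`: realized fraction of ADT UMIs in truly empty
#'   droplets).
#' @export
simulate_lane <- function(markers, config, conditions) {
  check(length(markers) >= 1, "need at least one marker")
  check(inherits(config, "SimConfig"), "config must be a sim_config()")
  check(length(conditions) >= 1 && !is.null(names(conditions)),
        "conditions must be a named list")
  for (cond in conditions) {
    check(inherits(cond, "StainingCondition"),
          "conditions must be StainingCondition objects")
  }
  types <- names(config$cell_type_proportions)
  check(length(types) > 0, "zero cell types")
  marker_names <- vapply(markers, `[[`, "", "name")
  check(!anyDuplicated(marker_names), "marker names must be unique")

  with_seed(config$seed, {
    n_cond <- length(conditions)
    n_cells_total <- config$n_cells * n_cond
    n_total <- n_cells_total + config$n_empty
    p_detect <- 1 - exp(-config$reads_per_umi)

    # equilibrium per marker x condition; shared ambient pool
    eq <- lapply(markers, function(sp) {
      lapply(conditions, function(cond) marker_theta(sp, config, cond))
    })
    names(eq) <- marker_names
    ambient_mol <- vapply(eq, function(e) {
      config$ambient_scale * config$wash_retention *
        mean(vapply(e, `[[`, 0, "c_free"))
    }, 0)

    # droplet layout: cells of each condition and empties, shuffled
    barcodes <- sprintf("BC%06d", seq_len(n_total))
    slots <- sample(n_total)
    cell_slots <- slots[seq_len(n_cells_total)]
    empty_slots <- slots[-seq_len(n_cells_total)]
    true_class <- rep("empty", n_total)
    true_class[cell_slots] <- "cell"
    true_sample <- rep(NA_character_, n_total)
    true_sample[cell_slots] <- rep(names(conditions), each = config$n_cells)
    cell_type <- rep(NA_character_, n_total)
    cell_type[cell_slots] <- sample(types, n_cells_total, replace = TRUE,
                                    prob = config$cell_type_proportions)

    # ADT counts
    adt <- matrix(0, length(markers), n_total,
                  dimnames = list(marker_names, barcodes))
    for (m in seq_along(markers)) {
      lam <- rep(ambient_mol[m], n_total)
      e <- eq[[m]]
      spec_lam <- vapply(seq_along(cell_slots), function(i) {
        s <- true_sample[cell_slots[i]]
        e[[s]]$epitopes[[cell_type[cell_slots[i]]]] * e[[s]]$occupancy *
          config$capture_efficiency
      }, 0)
      lam[cell_slots] <- lam[cell_slots] + spec_lam
      molecules <- rpois(n_total, lam)
      adt[m, ] <- rbinom(n_total, molecules, p_detect)
    }

    # HTO counts
    hto <- matrix(rpois(n_cond * n_total, config$hto_ambient), n_cond, n_total,
                  dimnames = list(names(conditions), barcodes))
    for (j in seq_len(n_cond)) {
      own <- which(true_sample == names(conditions)[j])
      hto[j, own] <- hto[j, own] + rpois(length(own), config$hto_signal)
    }

    # RNA-lite: enough structure for rank-curve partitioning and QC
    n_mito <- 10L
    genes <- c(sprintf("G%03d", seq_len(config$n_rna_genes - n_mito)),
               paste0("MT-", seq_len(n_mito)))
    w <- 1 / (seq_len(config$n_rna_genes - n_mito) + 10)
    w <- w / sum(w) * (1 - config$mito_frac)
    w <- c(w, rep(config$mito_frac / n_mito, n_mito))
    totals <- numeric(n_total)
    totals[cell_slots] <- stats::rnbinom(n_cells_total, mu = config$rna_umis_cell,
                                         size = 8)
    totals[empty_slots] <- rpois(config$n_empty, config$rna_umis_empty)
    rna <- matrix(rpois(length(genes) * n_total, outer(w, totals)),
                  length(genes), n_total, dimnames = list(genes, barcodes))

    conc <- vapply(markers, `[[`, 0, "concentration_ug_ml")
    conc_list <- lapply(conditions, function(cond) conc / cond$dilution_factor)
    names(conc_list) <- vapply(conditions, `[[`, "", "condition_id")
    if (!"DF1" %in% names(conc_list)) conc_list$DF1 <- conc
    panel <- antibody_panel(marker_names, conc_list)

    metadata <- data.frame(barcode = barcodes, cell_type = cell_type,
                           stringsAsFactors = FALSE)
    experiment <- suppressMessages(build_experiment(
      count_matrix(adt), panel, conditions[[1]],
      rna = count_matrix(rna), hto = count_matrix(hto), metadata = metadata))

    truth_markers <- do.call(rbind, lapply(seq_along(markers), function(m) {
      do.call(rbind, lapply(names(conditions), function(s) {
        e <- eq[[m]][[s]]
        data.frame(marker = marker_names[m], sample = s,
                   condition_id = conditions[[s]]$condition_id,
                   c_tot = e$c_tot, r_tot = e$r_tot, c_free = e$c_free,
                   occupancy = e$occupancy,
                   ambient_molecules = ambient_mol[m],
                   ambient_observed = ambient_mol[m] * p_detect,
                   ground_truth_category = markers[[m]]$ground_truth_category,
                   stringsAsFactors = FALSE)
      }))
    }))
    truth_droplets <- data.frame(barcode = barcodes, true_class = true_class,
                                 true_sample = true_sample,
                                 cell_type = cell_type,
                                 stringsAsFactors = FALSE)
    empty_bc <- barcodes[true_class == "empty"]
    bg_share <- sum(adt[, empty_bc]) / max(1, sum(adt))

    list(experiment = experiment,
         truth = list(markers = truth_markers, droplets = truth_droplets,
                      background_share = bg_share),
         conditions = conditions, config = config)
  })
}

#' Simulate a single staining condition
#'
#' The one-condition special case of [simulate_lane()].
#'
#' @inheritParams simulate_lane
#' @param condition A [staining_condition()].
#' @return As [simulate_lane()].
#' @export
simulate_experiment <- function(markers, config, condition) {
  simulate_lane(markers, config,
                setNames(list(condition), condition$condition_id))
}

#' Archetype marker panel with ground-truth categories
#'
#' A deterministic panel of ten markers, two per response category, whose
#' binding parameters are chosen so that a simulated fourfold titration
#' reproduces each category's defining behaviour under the default
#' [sim_config()] and 50 uL / 1e6-cell staining conditions:
#' * **A** — 10 ug/mL, high ambient load; positive signal absent
#'   (`archA1`) or saturated and obscured by background (`archA2`);
#' * **B** — 0.16 ug/mL in the linear range, strongly cell-type-specific
#'   epitopes; separation survives dilution;
#' * **C** — 0.05 ug/mL on sparse epitopes; separation collapses at DF4;
#' * **D** — ubiquitous epitopes on every cell type;
#' * **E** — negligible epitope load at low concentration (no functional
#'   signal).
#'
#' @return List of [marker_spec()] objects.
#' @export
archetype_panel <- function() {
  list(
    marker_spec("archA1", 10, 0.15, c(), "A"),
    marker_spec("archA2", 10, 0.15, c(Myeloid = 2e4), "A"),
    marker_spec("archB1", 0.16, 0.5, c(Tcell = 2e5), "B"),
    marker_spec("archB2", 0.16, 0.5, c(Bcell = 2e5, Myeloid = 2e5), "B"),
    marker_spec("archC1", 0.05, 0.5, c(Bcell = 8e4), "C"),
    marker_spec("archC2", 0.05, 0.5, c(NK = 1e5), "C"),
    marker_spec("archD1", 0.5, 0.15,
                c(Tcell = 3e5, Bcell = 3e5, Myeloid = 3e5, NK = 3e5), "D"),
    marker_spec("archD2", 1.25, 0.15,
                c(Tcell = 2e5, Bcell = 2e5, Myeloid = 2e5, NK = 2e5), "D"),
    marker_spec("archE1", 0.025, 0.5, c(), "E"),
    marker_spec("archE2", 0.05, 0.5,
                c(Tcell = 100, Bcell = 100, Myeloid = 100, NK = 100), "E"))
}
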