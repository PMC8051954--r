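#' Titration plot for one marker
#'
#' Draws, per condition: the marker's UMI count against descending cell
#' rank on a zero-preserving `log10(count + 1)` axis, a marginal count
#' histogram, the detection threshold as a horizontal line, and a
#' cell-type strip ordered by rank showing which cell types carry the
#' signal. Total cell-UMIs are annotated per condition. Every figure gets
#' a machine-readable sidecar CSV of the plotted values (same path with
#' `.csv` substituted), so plots are testable without image comparison.
#'
#' @param experiments Named list of partitioned `DropletExperiment`
#'   objects (one per condition).
#' @param marker Marker name.
#' @param out_path Figure file (`.png` or `.svg` by extension).
#' @param thresholds Optional named numeric per condition; computed via
#'   [detection_threshold()] when missing.
#' @return Invisibly, list with `figure` and `sidecar` paths.
#' @export
titration_plot <- function(experiments, marker, out_path, thresholds = NULL) {
  check(length(experiments) >= 1, "need at least one condition")
  if (is.null(names(experiments))) {
    names(experiments) <- vapply(experiments,
                                 function(e) e$condition$condition_id, "")
  }
  check(marker %in% rownames(experiments[[1]]$adt),
        "unknown marker '%s'", marker)

  plot_data <- do.call(rbind, lapply(names(experiments), function(cond) {
    e <- experiments[[cond]]
    is_cell <- e$meta$droplet_class == "cell"
    check(any(is_cell), "condition '%s' has no cells", cond)
    bc <- e$meta$barcode[is_cell]
    counts <- as.numeric(e$adt[marker, bc])
    ord <- order(-counts, bc)
    thr <- if (!is.null(thresholds) && cond %in% names(thresholds)) {
      thresholds[[cond]]
    } else {
      empty_bc <- e$meta$barcode[e$meta$droplet_class == "empty"]
      detection_threshold(as.numeric(e$adt[marker, empty_bc]))
    }
    data.frame(condition = cond, rank = seq_along(ord),
               barcode = bc[ord], count = counts[ord],
               cell_type = e$meta$cell_type[is_cell][ord],
               threshold = thr, total_umis = sum(counts),
               stringsAsFactors = FALSE)
  }))

  sidecar <- sub("\\.[a-zA-Z]+$", ".csv", out_path)
  utils::write.csv(plot_data, sidecar, row.names = FALSE)

  totals <- unique(plot_data[, c("condition", "total_umis")])
  main <- ggplot2::ggplot(plot_data,
                          ggplot2::aes(x = .data$rank,
                                       y = log10(.data$count + 1),
                                       colour = .data$condition)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = log10(.data$threshold + 1),
                                     colour = .data$condition),
                        linetype = "dashed") +
    ggplot2::labs(title = marker,
                  subtitle = paste(sprintf("%s: %d UMIs", totals$condition,
                                           totals$total_umis),
                                   collapse = "; "),
                  x = "cell rank", y = "log10(UMI + 1)") +
    ggplot2::theme_minimal()
  hist <- ggplot2::ggplot(plot_data,
                          ggplot2::aes(x = log10(.data$count + 1),
                                       fill = .data$condition)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.5) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
  strip <- ggplot2::ggplot(plot_data,
                           ggplot2::aes(x = .data$rank, y = .data$condition,
                                        fill = .data$cell_type)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = NULL, y = NULL, fill = "cell type") +
    ggplot2::theme_minimal()
  fig <- patchwork::wrap_plots(A = main, B = hist, C = strip,
                               design = "AAAB\nCCCC", heights = c(4, 1))
  ggplot2::ggsave(out_path, fig, width = 8, height = 6, dpi = 120)
  invisible(list(figure = out_path, sidecar = sidecar))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full titration pipeline
#'
#' Orchestrates partition -> QC -> HTO demultiplexing -> per-condition
#' split -> metrics -> classification -> panel adjustment -> cost, from a
#' single config, and writes `partition.csv`, `metrics.csv`,
#' `responses.csv`, `recommendations.csv`, `adjusted_panel.csv`,
#' `cost.csv`, optional `figures/`, and a run log (`run.log` +
#' `config_echo.yaml`) sufficient to reproduce the run bit-identically.
#'
#' @param config A list, or path to a YAML file, with keys:
#'   * `conditions`: list of [staining_condition()] argument lists
#'     (named by sample label);
#'   * either `simulation` (argument list for [sim_config()], plus
#'     optional `markers = "archetype"`) or `inputs` (paths `adt_dir`,
#'     optional `rna_dir`, `hto_dir`, `panel_csv`, `metadata_csv`);
#'   * optional `partition` ([find_inflection()] overrides), `demux`,
#'     `classifier` ([classifier_config()] overrides), `figures`
#'     (logical), `seed`.
#' @param out_dir Output directory.
#' @return Invisibly, list with the output directory, the per-condition
#'   experiments, the metrics table and the recommendations.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check(is.list(config), "config must be a list or YAML path")
  check(!is.null(config$conditions), "config missing key 'conditions'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  conditions <- lapply(config$conditions, function(a) {
    do.call(staining_condition, a)
  })
  if (is.null(names(conditions)) || !all(nzchar(names(conditions)))) {
    names(conditions) <- vapply(conditions, `[[`, "", "condition_id")
  }

  sim <- NULL
  if (!is.null(config$simulation)) {
    sim <- pipeline_stage("simulate", {
      sim_args <- config$simulation
      markers <- if (is.null(sim_args$markers) ||
                     identical(sim_args$markers, "archetype")) {
        archetype_panel()
      } else {
        lapply(sim_args$markers, function(m) do.call(marker_spec, m))
      }
      sim_args$markers <- NULL
      if (!is.null(config$seed)) sim_args$seed <- config$seed
      simulate_lane(markers, do.call(sim_config, sim_args), conditions)
    })
    experiment <- sim$experiment
  } else {
    experiment <- pipeline_stage("read_inputs", {
      inp <- config$inputs
      check(!is.null(inp), "config missing key 'simulation' or 'inputs'")
      check(!is.null(inp$panel_csv), "config missing key 'inputs$panel_csv'")
      check(!is.null(inp$adt_dir), "config missing key 'inputs$adt_dir'")
      metadata <- if (!is.null(inp$metadata_csv)) {
        utils::read.csv(inp$metadata_csv, stringsAsFactors = FALSE)
      } else NULL
      build_experiment(
        read_counts_mtx(inp$adt_dir), read_panel_csv(inp$panel_csv),
        conditions[[1]],
        rna = if (!is.null(inp$rna_dir)) read_counts_mtx(inp$rna_dir),
        hto = if (!is.null(inp$hto_dir)) read_counts_mtx(inp$hto_dir),
        metadata = metadata, strip_suffix = inp$strip_suffix)
    })
  }

  experiment <- pipeline_stage("partition", {
    suppressMessages(do.call(partition_droplets,
                             c(list(experiment), config$partition)))
  })
  if (!is.null(experiment$rna)) {
    experiment <- pipeline_stage("qc", suppressMessages(qc_filter(experiment)))
  }
  if (!is.null(experiment$hto) && length(conditions) > 1) {
    experiment <- pipeline_stage("demux", {
      do.call(demux_hto, c(list(experiment), config$demux))
    })
  } else {
    experiment$meta$sample[experiment$meta$droplet_class == "cell"] <-
      names(conditions)[1]
  }
  utils::write.csv(experiment$meta, file.path(out_dir, "partition.csv"),
                   row.names = FALSE)

  experiments <- pipeline_stage("split", split_lane(experiment, conditions))
  tbl <- pipeline_stage("metrics", metrics_table(experiments))
  utils::write.csv(tbl$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(tbl$responses)) {
    utils::write.csv(tbl$responses, file.path(out_dir, "responses.csv"),
                     row.names = FALSE)
  }

  recommendations <- NULL
  if (length(experiments) > 1) {
    recommendations <- pipeline_stage("classify", {
      cc <- do.call(classifier_config,
                    if (is.null(config$classifier)) list() else config$classifier)
      classify_panel(tbl, experiment$panel, experiments[[1]]$condition, cc)
    })
    utils::write.csv(recommendations,
                     file.path(out_dir, "recommendations.csv"),
                     row.names = FALSE)
    adjusted <- pipeline_stage("adjust", {
      adjust_panel(experiment$panel, recommendations,
                   condition_id = conditions[[1]]$condition_id)
    })
    write_panel_csv(adjusted, file.path(out_dir, "adjusted_panel.csv"))

    cost <- pipeline_stage("cost", {
      vol <- conditions[[1]]$volume_ul
      before <- panel_cost(experiment$panel, vol,
                           condition = conditions[[1]]$condition_id)
      after <- panel_cost(adjusted, vol, condition = "adjusted")
      cmp <- comparison_stats(before, after)
      data.frame(cost_before_usd = before, cost_after_usd = after,
                 fold_change = cmp$fold_change,
                 percent_change = cmp$percent_change)
    })
    utils::write.csv(cost, file.path(out_dir, "cost.csv"), row.names = FALSE)
  }

  if (isTRUE(config$figures)) {
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    for (mk in rownames(experiment$adt)) {
      pipeline_stage(paste0("figure:", mk), {
        suppressMessages(titration_plot(
          experiments, mk, file.path(fig_dir, paste0(mk, ".png"))))
      })
    }
  }

  yaml::write_yaml(config, file.path(out_dir, "config_echo.yaml"))
  writeLines(c(sprintf("adtiter %s | R %s",
                       as.character(utils::packageVersion("adtiter")),
                       paste(R.version$major, R.version$minor, sep = ".")),
               sprintf("seed: %s",
                       if (is.null(config$seed)) "none" else config$seed),
               sprintf("conditions: %s",
                       paste(names(conditions), collapse = ", ")),
               sprintf("outputs: %s",
                       paste(list.files(out_dir), collapse = ", "))),
             file.path(out_dir, "run.log"))

  invisible(list(out_dir = out_dir, experiments = experiments,
                 metrics = tbl, recommendations = recommendations,
                 truth = if (!is.null(sim)) sim$truth))
}
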