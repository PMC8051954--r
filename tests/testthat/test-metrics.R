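test_that("detection_threshold floors at 1 and tracks the background quantile", {
  expect_warning(t0 <- detection_threshold(rep(0, 50)), "empty")
  expect_equal(t0, 1)
  counts <- c(rep(0, 900), rep(5, 100))    # 99th percentile is 5
  expect_equal(detection_threshold(counts), 5)
  expect_equal(detection_threshold(counts, quantile = 0.5), 1)  # floor
  expect_error(detection_threshold(counts, quantile = 1.2), "quantile")
  expect_error(detection_threshold(counts, quantile = 0), "quantile")
})

test_that("marker_metrics computes the documented field suite", {
  # mkA in cells: {10, 10, 0, 0}; empties all zero so T = 1
  # mkB carries the rest of the panel signal
  adt_cells <- matrix(c(10, 10, 0, 0,
                        10, 10, 10, 10), 2, 4, byrow = TRUE)
  adt_empty <- matrix(c(0, 0, 0, 0,
                        1, 1, 1, 1), 2, 4, byrow = TRUE)
  e <- fix_experiment(adt_cells, adt_empty)
  mm <- suppressWarnings(marker_metrics(e, "mkA"))
  expect_equal(mm$positive_fraction, 0.5)
  expect_equal(mm$snr, 10)
  expect_equal(mm$detection_threshold, 1)
  expect_equal(mm$total_umis_cells, 20)
  expect_equal(mm$background_pct, 0)
  # umis_per_positive_pct: (20/60 panel UMIs) * 100 / 2 positives
  expect_equal(mm$umis_per_positive_pct, 100 * (20 / 60) / 2)

  expect_error(marker_metrics(e, "nope"), "unknown marker")
})

test_that("background and frequency metrics follow their definitions", {
  # mkA: 40 UMIs in cells, 60 in empties -> background 60%
  adt_cells <- matrix(c(10, 10, 10, 10,
                        240, 240, 240, 240), 2, 4, byrow = TRUE)
  adt_empty <- matrix(c(15, 15, 15, 15,
                        60, 60, 60, 60), 2, 4, byrow = TRUE)
  e <- fix_experiment(adt_cells, adt_empty)
  mm <- suppressWarnings(marker_metrics(e, "mkA"))
  expect_equal(mm$background_pct, 60)
  # freq_cells = 40/1000, freq_empty = 60/300
  expect_equal(mm$freq_cells, 0.04)
  expect_equal(mm$freq_empty, 0.2)
  expect_equal(mm$freq_ratio, 0.2)

  mmB <- suppressWarnings(marker_metrics(e, "mkB"))
  # frequencies sum to 1 over the panel
  expect_equal(mm$freq_cells + mmB$freq_cells, 1, tolerance = 1e-9)
  expect_equal(mm$freq_empty + mmB$freq_empty, 1, tolerance = 1e-9)
})

test_that("freq_ratio matches the worked two-marker example", {
  # marker A: 50/1000 cell-UMIs and 10/1000 empty-UMIs -> ratio 5
  adt_cells <- matrix(c(25, 25, 0, 0,
                        475, 475, 0, 0), 2, 4, byrow = TRUE)
  adt_empty <- matrix(c(5, 5, 0, 0,
                        495, 495, 0, 0), 2, 4, byrow = TRUE)
  e <- fix_experiment(adt_cells, adt_empty)
  mm <- suppressWarnings(marker_metrics(e, "mkA"))
  expect_equal(mm$freq_ratio, 5)
})

test_that("titration_response handles pseudocounts and linearity deviation", {
  ref <- data.frame(marker = "mk", total_umis_cells = 400, q90_expressing = 40)
  dil <- data.frame(marker = "mk", total_umis_cells = 100, q90_expressing = 10)
  rec <- titration_response(ref, dil, 4)
  expect_equal(rec$log2_response[["q90_expressing"]], log2(41 / 11))
  expect_equal(rec$linearity_deviation[["q90_expressing"]],
               abs(log2(41 / 11) - 2))

  same <- titration_response(ref, ref, 4)
  expect_equal(unname(same$log2_response), c(0, 0))

  zero <- data.frame(marker = "mk", total_umis_cells = 0, q90_expressing = 0)
  ref15 <- data.frame(marker = "mk", total_umis_cells = 15, q90_expressing = 15)
  expect_equal(titration_response(ref15, zero, 4)$log2_response[["q90_expressing"]],
               4)

  other <- data.frame(marker = "other", total_umis_cells = 1, q90_expressing = 1)
  expect_error(titration_response(ref, other, 4), "mismatch")
  expect_error(titration_response(ref, dil, 1), "dilution_factor")
})

test_that("metrics_table emits one metrics row per marker x condition plus responses", {
  sim <- fix_lane(seed = 3, n_cells = 150, n_empty = 1200)
  e <- suppressMessages(partition_droplets(sim$experiment))
  e$meta$sample <- sim$truth$droplets$true_sample[
    match(e$meta$barcode, sim$truth$droplets$barcode)]
  exps <- split_lane(e, fix_conditions())
  tbl <- metrics_table(exps)
  expect_equal(nrow(tbl$metrics), 2 * 10)
  expect_equal(nrow(tbl$responses), 10)

  # single condition: metric rows only
  tbl1 <- metrics_table(exps[1])
  expect_equal(nrow(tbl1$metrics), 10)
  expect_null(tbl1$responses)

  # frequencies sum to 1 within each condition; totals conserved
  for (cond in unique(tbl$metrics$condition_id)) {
    sub <- tbl$metrics[tbl$metrics$condition_id == cond, ]
    expect_equal(sum(sub$freq_cells), 1, tolerance = 1e-9)
    expect_equal(sum(sub$freq_empty), 1, tolerance = 1e-9)
  }

  # deterministic: same seed, bit-identical tables
  sim2 <- fix_lane(seed = 3, n_cells = 150, n_empty = 1200)
  e2 <- suppressMessages(partition_droplets(sim2$experiment))
  e2$meta$sample <- sim2$truth$droplets$true_sample[
    match(e2$meta$barcode, sim2$truth$droplets$barcode)]
  tbl2 <- metrics_table(split_lane(e2, fix_conditions()))
  expect_identical(tbl$metrics, tbl2$metrics)
  expect_identical(tbl$responses, tbl2$responses)
})

test_that("ambient load drives the detection threshold monotonically", {
  mk <- list(marker_spec("hiAmb", 10, 0.15, c()),
             marker_spec("loAmb", 0.5, 0.15, c()))
  sim <- simulate_experiment(mk, sim_config(n_cells = 200, n_empty = 2000,
                                            seed = 5),
                             staining_condition("DF1", 1, 50, 1e6))
  e <- sim$experiment
  e$meta$droplet_class <- sim$truth$droplets$true_class
  t_hi <- detection_threshold(as.numeric(
    e$adt["hiAmb", e$meta$droplet_class == "empty"]))
  t_lo <- detection_threshold(as.numeric(
    e$adt["loAmb", e$meta$droplet_class == "empty"]))
  expect_gt(t_hi, t_lo)
})

test_that("marker UMIs are conserved across the cell/empty partition", {
  sim <- fix_lane(seed = 9, n_cells = 100, n_empty = 800)
  e <- suppressMessages(partition_droplets(sim$experiment))
  total <- Matrix::rowSums(e$adt)
  cells <- Matrix::rowSums(e$adt[, e$meta$droplet_class == "cell", drop = FALSE])
  empty <- Matrix::rowSums(e$adt[, e$meta$droplet_class == "empty", drop = FALSE])
  expect_equal(unname(total), unname(cells + empty))
})
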