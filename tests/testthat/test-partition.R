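test_that("barcode_rank_curve sorts descending with lexicographic tie-break", {
  m <- fix_counts(c(5, 10, 1), "g", c("a", "b", "c"))
  curve <- barcode_rank_curve(m)
  expect_identical(curve$barcode, c("b", "a", "c"))
  expect_identical(curve$total, c(10, 5, 1))

  ties <- fix_counts(c(3, 3, 3), "g", c("z", "a", "m"))
  expect_identical(barcode_rank_curve(ties)$barcode, c("a", "m", "z"))

  zeros <- fix_counts(c(0, 0), "g", c("a", "b"))
  expect_error(barcode_rank_curve(zeros), "zero")
})

test_that("find_inflection pins a step curve at the plateau edge", {
  m <- fix_counts(c(rep(1000, 100), rep(1, 900)), "g", sprintf("b%04d", 1:1000))
  curve <- barcode_rank_curve(m)
  expect_equal(find_inflection(curve), 100)
  # invariant to uniform scaling of totals
  m10 <- count_matrix(as.matrix(m) * 10, rownames(m), colnames(m))
  expect_equal(find_inflection(barcode_rank_curve(m10)), 100)
})

test_that("find_inflection matches a brute-force derivative scan on a logistic curve", {
  # two plateaus (10^3 and 10^1) with a logistic transition centred at rank 300
  r <- 1:5000
  totals <- round(10^(3 - 2 / (1 + exp(-(r - 300) / 25))))
  curve <- structure(data.frame(rank = r, barcode = sprintf("b%05d", r),
                                total = totals),
                     class = c("RankCurve", "data.frame"))
  found <- find_inflection(curve, smoothing_window = 11)

  # oracle: exhaustive scan of the unsmoothed discrete log-log derivative
  # over the distinct-value curve
  rl <- rle(totals[totals > 0])
  edge <- cumsum(rl$lengths)
  slope <- diff(log10(rl$values)) / diff(log10(edge))
  cand <- edge[-length(edge)]
  ok <- cand >= 100
  oracle <- cand[ok][which.min(slope[ok])]
  expect_lte(abs(found - oracle), 11)
})

test_that("flat curves are rejected as having no inflection", {
  m <- fix_counts(rep(7, 200), "g", sprintf("b%03d", 1:200))
  expect_error(find_inflection(barcode_rank_curve(m)), "flat|steep")
})

test_that("partition_droplets splits cells/empties exhaustively", {
  m <- fix_counts(c(rep(1000, 100), rep(1, 900)), "g", sprintf("b%04d", 1:1000))
  panel <- antibody_panel("g", list(DF1 = 1))
  e <- suppressMessages(build_experiment(
    m, panel, staining_condition("DF1", 1, 50, 1e6)))
  e <- suppressMessages(partition_droplets(e, min_cells = 50))
  expect_equal(sum(e$meta$droplet_class == "cell"), 100)
  expect_equal(sum(e$meta$droplet_class == "empty"), 900)

  expect_warning(
    suppressMessages(partition_droplets(e, inflection_rank = 1000)),
    "zero empty")
})

test_that("partition recovers simulated cell counts and ambient distribution", {
  sim <- fix_lane(seed = 11)
  e <- suppressMessages(partition_droplets(sim$experiment))
  n_cells_true <- sum(sim$truth$droplets$true_class == "cell")
  n_cells_est <- sum(e$meta$droplet_class == "cell")
  expect_lt(abs(n_cells_est - n_cells_true) / n_cells_true, 0.02)

  # partition is exhaustive
  expect_setequal(unique(e$meta$droplet_class), c("cell", "empty"))

  # empty-droplet counts for an ambient-heavy marker are indistinguishable
  # from a fresh ambient-only draw (the simulator's ground truth mechanism)
  empty_bc <- e$meta$barcode[e$meta$droplet_class == "empty"]
  obs <- as.numeric(e$adt["archA1", empty_bc])
  lam <- sim$truth$markers$ambient_observed[
    sim$truth$markers$marker == "archA1"][1]
  ref <- withr::with_seed(99, rpois(length(obs), lam))
  expect_gt(stats::wilcox.test(obs, ref)$p.value, 0.01)
})

test_that("qc_filter applies the gene and mitochondrial thresholds", {
  # 100 genes incl MT-1; four cells crafted around the QC boundaries
  genes <- c(sprintf("G%02d", 1:99), "MT-1")
  cells <- matrix(0, 100, 4, dimnames = list(genes, sprintf("c%d", 1:4)))
  cells[1:59, 1] <- 1                    # 59 genes -> removed
  cells[1:60, 2] <- 1                    # 60 genes, 0% mito -> kept
  cells[1:60, 3] <- 10; cells[100, 3] <- 105   # 14.9% mito -> kept
  cells[1:60, 4] <- 10; cells[100, 4] <- 115   # 16.1% mito -> removed
  empties <- matrix(0, 100, 2, dimnames = list(genes, c("e1", "e2")))
  empties[1, ] <- 1
  rna <- count_matrix(cbind(cells, empties))
  adt <- fix_counts(rep(1, 6), "mk", colnames(rna))
  panel <- antibody_panel("mk", list(DF1 = 1))
  e <- suppressMessages(build_experiment(
    adt, panel, staining_condition("DF1", 1, 50, 1e6), rna = rna))
  e$meta$droplet_class <- rep(c("cell", "empty"), c(4, 2))

  e2 <- suppressMessages(qc_filter(e))
  expect_identical(attr(e2, "qc_kept"), c("c2", "c3"))
  expect_identical(e2$meta$droplet_class,
                   c("removed", "cell", "cell", "removed", "empty", "empty"))
  # exhaustive partition including removed
  expect_equal(sum(table(e2$meta$droplet_class)), 6)

  e3 <- e
  rownames(e3$rna) <- c(sprintf("G%02d", 1:99), "X-1")
  expect_warning(suppressMessages(qc_filter(e3)), "mitochondrial")

  # config switch: removed barcodes may be counted as empty instead
  e4 <- suppressMessages(qc_filter(e, removed_to_empty = TRUE))
  expect_identical(e4$meta$droplet_class,
                   c("empty", "cell", "cell", "empty", "empty", "empty"))
})

test_that("demux_hto applies the dominance rules", {
  hto <- fix_counts(c(100, 50, 4,
                      2, 45, 1,
                      1, 2, 0), c("HTO1", "HTO2", "HTO3"), c("c1", "c2", "c3"))
  adt <- fix_counts(rep(1, 3), "mk", colnames(hto))
  panel <- antibody_panel("mk", list(DF1 = 1))
  e <- suppressMessages(build_experiment(
    adt, panel, staining_condition("DF1", 1, 50, 1e6), hto = hto))
  e$meta$droplet_class <- "cell"
  e <- demux_hto(e)
  expect_identical(e$meta$sample, c("HTO1", "doublet", "negative"))

  single <- e
  single$hto <- single$hto[1, , drop = FALSE]
  expect_warning(demux_hto(single), "single-HTO")
})
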