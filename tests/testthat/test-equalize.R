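make_cells <- function(spec) {
  # spec: named list condition -> named vector cell_type -> n
  do.call(rbind, lapply(names(spec), function(cond) {
    do.call(rbind, lapply(names(spec[[cond]]), function(ct) {
      n <- spec[[cond]][[ct]]
      data.frame(barcode = sprintf("%s_%s_%03d", cond, ct, seq_len(n)),
                 condition = cond, cell_type = ct, stringsAsFactors = FALSE)
    }))
  }))
}

test_that("equalize_celltypes keeps the per-type minimum across conditions", {
  cells <- make_cells(list(c1 = c(T = 100, B = 50), c2 = c(T = 80, B = 60)))
  sel <- equalize_celltypes(cells, seed = 3)
  expect_equal(as.vector(sel$counts["T", c("c1", "c2")]), c(80, 80))
  expect_equal(as.vector(sel$counts["B", c("c1", "c2")]), c(50, 50))
  # composition identical across conditions by construction
  expect_true(all(sel$counts[, "c1"] == sel$counts[, "c2"]))
  # deterministic given seed, different otherwise
  sel2 <- equalize_celltypes(cells, seed = 3)
  expect_identical(sel$kept, sel2$kept)
  sel3 <- equalize_celltypes(cells, seed = 4)
  expect_false(identical(sel$kept, sel3$kept))
})

test_that("equalize_celltypes keeps everything for identical conditions and drops unshared types", {
  cells <- make_cells(list(c1 = c(T = 10, B = 5), c2 = c(T = 10, B = 5)))
  sel <- equalize_celltypes(cells, seed = 1)
  expect_equal(nrow(sel$kept), nrow(cells))

  cells2 <- rbind(cells, data.frame(barcode = "c1_NK_001", condition = "c1",
                                    cell_type = "NK"))
  expect_warning(sel2 <- equalize_celltypes(cells2, seed = 1), "NK")
  expect_false("NK" %in% sel2$kept$cell_type)
  expect_equal(sum(sel2$kept$condition == "c1"),
               sum(sel2$kept$condition == "c2"))

  cells3 <- make_cells(list(c1 = c(T = 5), c2 = c(B = 5)))
  expect_error(suppressWarnings(equalize_celltypes(cells3)), "shared")
})

test_that("match_in_embedding pairs nearest unused neighbours", {
  # identical coordinates: every small-sample cell matches at distance zero
  coords <- matrix(rep(cbind(1:5, 1:5), 2), ncol = 2)
  rownames(coords) <- sprintf("c%02d", 1:10)
  sel <- match_in_embedding(coords, rep("cl1", 10),
                            rep(c("s1", "s2"), each = 5), seed = 1)
  expect_equal(nrow(sel$kept), 10)
  expect_true(all(sel$kept$dist[!is.na(sel$kept$dist)] == 0))

  # cluster sizes (3, 10) -> 3 matched pairs
  set.seed(5)
  coords2 <- matrix(rnorm(26), ncol = 2)
  rownames(coords2) <- sprintf("d%02d", 1:13)
  sel2 <- match_in_embedding(coords2, rep("cl1", 13),
                             rep(c("s1", "s2"), c(3, 10)), seed = 1)
  expect_equal(as.vector(table(sel2$kept$condition)[c("s1", "s2")]),
               c(3L, 3L))

  expect_error(match_in_embedding(coords2, rep("cl1", 12),
                                  rep("s1", 13)), "mismatch")
  expect_error(match_in_embedding(coords2, rep("cl1", 13), rep("s1", 13)),
               "two samples")
})

test_that("greedy matching total distance is near the canonical-order greedy oracle", {
  n_small <- 20; n_big <- 50
  coords <- withr::with_seed(42, matrix(rnorm((n_small + n_big) * 2), ncol = 2))
  rownames(coords) <- sprintf("e%03d", seq_len(n_small + n_big))
  samples <- rep(c("s1", "s2"), c(n_small, n_big))
  sel <- match_in_embedding(coords, rep("cl", n_small + n_big), samples,
                            seed = 7)
  got <- sum(sel$kept$dist[!duplicated(sel$kept$pair)])

  # brute-force greedy oracle, processing small-sample cells in input order
  small <- which(samples == "s1"); big <- which(samples == "s2")
  used <- rep(FALSE, length(big)); oracle <- 0
  for (i in small) {
    d <- sqrt(colSums((t(coords[big, ]) - coords[i, ])^2))
    d[used] <- Inf
    j <- which.min(d); used[j] <- TRUE; oracle <- oracle + d[j]
  }
  expect_lt(abs(got - oracle) / oracle, 0.10)
})

test_that("thin_counts hits the target exactly and never inflates entries", {
  m <- fix_counts(c(100, 300, 0, 7), c("f1", "f2"), c("b1", "b2"))
  expect_identical(as.matrix(thin_counts(m, sum(m), seed = 1)), as.matrix(m))
  expect_equal(sum(thin_counts(m, 0, seed = 1)), 0)
  expect_error(thin_counts(m, sum(m) + 1, seed = 1), "exceeds")

  for (s in 1:5) {
    th <- thin_counts(m, 200, seed = s)
    expect_equal(sum(th), 200)
    expect_true(all(as.matrix(th) <= as.matrix(m)))
  }
})

test_that("thinned means match the hypergeometric expectation", {
  m <- fix_counts(c(100, 300), "f1", c("b1", "b2"))
  n_rep <- 2000
  kept1 <- vapply(seq_len(n_rep),
                  function(s) as.matrix(thin_counts(m, 200, seed = s))[1, 1], 0)
  # entry 1 ~ Hypergeometric(m=100, n=300, k=200): mean 50
  mu <- 200 * 100 / 400
  v <- 200 * 0.25 * 0.75 * (400 - 200) / (400 - 1)
  se <- sqrt(v / n_rep)
  expect_lt(abs(mean(kept1) - mu), 3 * se)
})

test_that("two-stage thinning equals direct thinning in distribution", {
  m <- fix_counts(c(9, 4, 0, 2, 8, 1, 5, 0, 3), paste0("f", 1:3), paste0("b", 1:3))
  n_rep <- 1000
  two <- vapply(seq_len(n_rep), function(s) {
    as.matrix(thin_counts(thin_counts(m, 20, seed = s), 10, seed = s + n_rep))[1, 1]
  }, 0)
  direct <- vapply(seq_len(n_rep), function(s) {
    as.matrix(thin_counts(m, 10, seed = s + 2L * n_rep))[1, 1]
  }, 0)
  expect_gt(stats::wilcox.test(two, direct, exact = FALSE)$p.value, 0.01)
})

test_that("read-mode thinning collapses back to no more than the original UMIs", {
  m <- fix_counts(c(50, 10, 0, 40), c("f1", "f2"), c("b1", "b2"))
  th <- thin_counts(m, 150, seed = 2, mode = "reads", reads_per_umi = 3)
  expect_true(all(as.matrix(th) <= as.matrix(m)))
  expect_identical(as.matrix(thin_counts(m, 150, seed = 2, mode = "reads")),
                   as.matrix(thin_counts(m, 150, seed = 2, mode = "reads")))
})

test_that("sequencing saturation follows the 10x convention", {
  expect_equal(sequencing_saturation(1000, 230), 0.77)
  expect_equal(sequencing_saturation(500, 500), 0)
  expect_equal(sequencing_saturation(100, 0), 1)
  expect_error(sequencing_saturation(100, 101), "exceed")
  expect_error(sequencing_saturation(0, 0), "> 0")
})
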