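test_that("assign_clusters_by_score splits tails by quantile", {
  scores <- stats::setNames(as.numeric(0:9), paste0("s", 0:9))
  d <- assign_clusters_by_score(scores, 0.2, 0.2)
  expect_setequal(design_a <- names(d$labels[d$labels == "A"]), c("s0", "s1"))
  expect_setequal(names(d$labels[d$labels == "B"]), c("s8", "s9"))
  # exhaustive split leaves nothing unused
  d2 <- assign_clusters_by_score(scores, 0.5, 0.5)
  expect_false(any(d2$labels == "unused"))
  # degenerate scores are fatal
  expect_error(assign_clusters_by_score(stats::setNames(rep(1, 10),
                                                        paste0("s", 1:10))),
               "degenerate|fewer")
})

test_that("wilcoxon_two_sided reproduces hand-enumerated exact p-values", {
  expect_equal(wilcoxon_two_sided(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_two_sided(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_two_sided(1, 2), 1)
  expect_equal(wilcoxon_two_sided(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_true(is.na(wilcoxon_two_sided(numeric(0), 1:3)))
  expect_true(is.na(wilcoxon_two_sided(c(NA, NA), 1:3)))
})

test_that("wilcoxon_two_sided matches enumeration for tie-free small samples", {
  set.seed(42)
  for (n in 1:4) for (m in 1:4) {
    a <- stats::rnorm(n)
    b <- stats::rnorm(m)
    expect_equal(wilcoxon_two_sided(a, b), oracle_wilcoxon_exact(a, b),
                 tolerance = 1e-12, info = paste(n, m))
  }
})

test_that("differential_table computes median deltas and flags bad rows", {
  mat <- rbind(good = c(1, 1, 1, 3, 3, 5),
               missingA = c(NA, NA, NA, 1, 2, 3),
               constant = rep(2, 6))
  colnames(mat) <- paste0("s", 1:6)
  design <- cluster_design(colnames(mat), rep(c("A", "B"), each = 3))
  d <- suppressMessages(differential_table(mat, design))
  expect_equal(d$delta[d$row_key == "good"], 2)
  expect_true(is.na(d$p_value[d$row_key == "missingA"]))
  expect_equal(d$delta[d$row_key == "constant"], 0)
  expect_equal(d$p_value[d$row_key == "constant"], 1)
  expect_true(all(d$q_value >= d$p_value, na.rm = TRUE))
  # design disjoint from the matrix is fatal
  bad_design <- cluster_design(paste0("x", 1:4), rep(c("A", "B"), each = 2))
  expect_error(differential_table(mat, bad_design), "cover")
})

test_that("normalize_ptm divides or subtracts the parent protein", {
  expr <- rbind(PROT1 = c(4, 2), PROT2 = c(0, 3))
  colnames(expr) <- c("s1", "s2")
  ptm <- rbind("PROT1:Y10:phosphorylation" = c(8, 1),
               "PROT2:S2:phosphorylation" = c(5, 6),
               "GHOST:S1:phosphorylation" = c(1, 1))
  colnames(ptm) <- c("s1", "s2")
  out <- suppressMessages(normalize_ptm(ptm, expr, "ratio"))
  expect_equal(nrow(out), 2L)  # GHOST dropped
  expect_equal(out["PROT1:Y10:phosphorylation", ], c(s1 = 2, s2 = 0.5))
  expect_true(is.na(out["PROT2:S2:phosphorylation", "s1"]))  # protein <= 0
  out2 <- suppressMessages(normalize_ptm(ptm, expr, "difference"))
  expect_equal(out2["PROT1:Y10:phosphorylation", ], c(s1 = 4, s2 = -1))
  expect_error(normalize_ptm(ptm, expr[, character(0), drop = FALSE]),
               "share no sample")
})

test_that("rank_statistic matches closed-form Beta CDFs for n <= 3", {
  expect_equal(rank_statistic(0.3), 0.3, tolerance = 1e-12)
  expect_equal(rank_statistic(c(0.1, 0.5)),
               min(1 - 0.9^2, 0.5^2), tolerance = 1e-12)
  expect_equal(rank_statistic(c(1, 1, 1)), 1, tolerance = 1e-12)
  p <- c(0.2, 0.4, 0.9)
  closed <- min(1 - (1 - p[1])^3, 3 * p[2]^2 - 2 * p[2]^3, p[3]^3)
  expect_equal(rank_statistic(p), closed, tolerance = 1e-12)
})

test_that("rank_statistic_pvalue is calibrated and deterministic", {
  p1 <- rank_statistic_pvalue(0.3, n_mc = 20000, seed = 5)
  expect_equal(p1, 0.3, tolerance = 0.02)
  expect_equal(rank_statistic_pvalue(c(1, 1, 1), n_mc = 2000, seed = 5), 1)
  expect_identical(rank_statistic_pvalue(c(0.1, 0.5), n_mc = 2000, seed = 9),
                   rank_statistic_pvalue(c(0.1, 0.5), n_mc = 2000, seed = 9))
  expect_gt(rank_statistic_pvalue(rep(1e-8, 4), n_mc = 2000, seed = 1), 0)
  expect_error(rank_statistic_pvalue(numeric(0)), "no p-values")
})

test_that("rank_statistic_pvalue agrees with an independent Monte-Carlo oracle", {
  set.seed(77)
  for (i in 1:8) {
    n <- sample(2:8, 1)
    pv <- stats::runif(n)
    mine <- rank_statistic_pvalue(pv, n_mc = 4000, seed = 11)
    theirs <- oracle_rank_pvalue(pv, n_mc = 20000, seed = 1234 + i)
    se <- sqrt(mine * (1 - mine) * (1 / 4000 + 1 / 20000))
    expect_lt(abs(mine - theirs), 3 * se + 1e-3)
  }
})

test_that("combine_lri_pvalue multiplies and is monotone", {
  expect_equal(combine_lri_pvalue(1, 1, 1), 1)
  expect_equal(combine_lri_pvalue(0.1, 0.2, 0.05), 0.001)
  expect_equal(combine_lri_pvalue(0, 0.5, 0.5), 0)
  expect_true(is.na(combine_lri_pvalue(NA, 0.5, 0.5)))
  set.seed(3)
  for (i in 1:20) {
    p <- stats::runif(3)
    bigger <- pmin(1, p + stats::runif(3, 0, 1 - p))
    expect_gte(combine_lri_pvalue(bigger[1], bigger[2], bigger[3]),
               combine_lri_pvalue(p[1], p[2], p[3]))
  }
})

test_that("bh_adjust equals the textbook step-up and passes NA through", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  mixed <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(mixed[2]))
  expect_equal(mixed[c(1, 3)], oracle_bh(c(0.01, 0.04)))
  set.seed(8)
  for (i in 1:25) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-14)
  }
})

test_that("calibrate_product is the exact null CDF of a uniform product", {
  expect_equal(calibrate_product(1, 3), 1)
  expect_equal(calibrate_product(0, 3), 0)
  expect_equal(calibrate_product(0.5, 1), 0.5)
  # closed form for k = 2: x(1 - ln x)
  x <- 0.1
  expect_equal(calibrate_product(x, 2), x * (1 - log(x)), tolerance = 1e-12)
  # calibrated product of uniforms is uniform
  set.seed(12)
  prod3 <- stats::runif(20000) * stats::runif(20000) * stats::runif(20000)
  cal <- calibrate_product(prod3, 3)
  expect_equal(mean(cal <= 0.05), 0.05, tolerance = 0.01)
  expect_equal(mean(cal <= 0.5), 0.5, tolerance = 0.02)
})
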