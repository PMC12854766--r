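test_that("dose transform is -log10", {
  expect_equal(neglog10_dose(1), 0)
  expect_equal(neglog10_dose(10), -1)
  expect_equal(neglog10_dose(50), -1.69897, tolerance = 1e-5)
  expect_error(neglog10_dose(0), "dose")
  expect_error(neglog10_dose(-3), "dose")
})

test_that("pearson_r matches hand computation and errors on constants", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1)
  got <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(got$r, 0.8)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
})

test_that("sample-size threshold is 2/sqrt(n)", {
  expect_equal(sample_size_threshold(400), 0.1)
  expect_equal(sample_size_threshold(100), 0.2)
  expect_equal(sample_size_threshold(50), 2 / sqrt(50))
  expect_error(sample_size_threshold(0), "n")
})

test_that("bh_fdr matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p))
  }
  # permutation invariance
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("fisher_z_ci gives the closed-form normal interval", {
  ci <- fisher_z_ci(0, 28)
  expect_equal(ci$lo, -tanh(qnorm(0.975) / 5), tolerance = 1e-12)
  expect_equal(ci$hi, tanh(qnorm(0.975) / 5), tolerance = 1e-12)
  expect_equal(ci$hi, 0.3731, tolerance = 1e-4)
  # width shrinks with n
  w <- vapply(c(1e3, 1e4), function(n) {
    ci <- fisher_z_ci(0, n); ci$hi - ci$lo
  }, numeric(1))
  expect_lt(w[2], w[1])
  # asymmetric toward zero for r = 0.5
  ci5 <- fisher_z_ci(0.5, 28)
  expect_true(ci5$lo < 0.5 && 0.5 < ci5$hi)
  expect_gt(0.5 - ci5$lo, ci5$hi - 0.5)
  d <- fisher_z_ci(1, 10)
  expect_true(d$degenerate)
  expect_equal(c(d$lo, d$hi), c(1, 1))
})

test_that("bootstrap_ci is seeded, degenerate-safe, and covers", {
  x <- 1:20
  ci <- bootstrap_ci(x, x + 0, seed = 3)
  expect_equal(c(ci$lo, ci$hi), c(1, 1))
  set.seed(1); x1 <- rnorm(30); y1 <- rnorm(30)
  expect_identical(bootstrap_ci(x1, y1, seed = 4),
                   bootstrap_ci(x1, y1, seed = 4))
  # coverage at r = 0.5, n = 200 over 40 repeats
  set.seed(11)
  hits <- 0
  for (i in 1:40) {
    z <- rnorm(200); e <- rnorm(200)
    x <- z; y <- 0.5 * z + sqrt(1 - 0.25) * e
    ci <- bootstrap_ci(x, y, n_boot = 400, seed = i)
    hits <- hits + (ci$lo <= 0.5 && 0.5 <= ci$hi)
  }
  expect_gte(hits / 40, 0.9)
})

test_that("rank_group_test picks Wilcoxon without ties, BM with ties", {
  r <- rank_group_test(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$test_used, "wilcoxon")
  expect_equal(r$p, 0.1)
  r2 <- suppressWarnings(rank_group_test(c(1, 2, 2), c(2, 5, 6)))
  expect_identical(r2$test_used, "brunner_munzel")
  r3 <- suppressWarnings(rank_group_test(c(1, 2, 3, 4), c(1, 2, 3, 4)))
  expect_gt(r3$p, 0.9)
  expect_error(rank_group_test(1, c(1, 2)), "at least 2")
})

test_that("Brunner-Munzel matches an independent reference", {
  # values frozen from an independent implementation (scipy.stats
  # brunnermunzel, t distribution, two-sided)
  cases <- list(
    list(x = c(1, 2, 2, 4, 5), y = c(2, 3, 3, 3, 6),
         stat = 0.6815093369, p = 0.5203047876),
    list(x = c(1.5, 2, 2, 3), y = c(2, 2, 4, 5, 6),
         stat = 2.0380986615, p = 0.0833498250),
    list(x = c(10, 12, 12, 14, 15, 18), y = c(9, 12, 13, 16, 16, 17, 19),
         stat = 0.6920456654, p = 0.5035140822))
  for (cs in cases) {
    got <- toxhier:::brunner_munzel(cs$x, cs$y)
    expect_equal(got$statistic, cs$stat, tolerance = 1e-9)
    expect_equal(got$p, cs$p, tolerance = 1e-9)
  }
})

test_that("rank_biserial matches exhaustive pairwise enumeration", {
  expect_equal(rank_biserial(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(rank_biserial(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rank_biserial(c(1, 2, 3), c(2, 3, 4)), -5 / 9,
               tolerance = 1e-12)
  expect_error(rank_biserial(numeric(), 1:3), "nonempty")
  # exhaustive small-instance oracle, all group sizes <= 6, integer
  # values with ties
  set.seed(5)
  for (i in 1:300) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    toxic <- sample(1:4, n1, replace = TRUE)
    nontoxic <- sample(1:4, n2, replace = TRUE)
    expect_equal(rank_biserial(toxic, nontoxic),
                 rrb_oracle(toxic, nontoxic), tolerance = 1e-12)
  }
})

test_that("retain_pair applies all criteria and is monotone in r", {
  expect_true(retain_pair(0.15, 0.01, 400, "continuous"))
  expect_false(retain_pair(0.15, 0.01, 100, "continuous"))
  expect_false(retain_pair(-0.5, 1e-6, 1000, "continuous"))
  expect_false(retain_pair(0.15, 0.06, 400, "continuous"))
  expect_true(retain_pair(0.05, 0.01, 1000, "binary"))
  expect_false(retain_pair(-0.05, 0.01, 1000, "binary"))
  expect_false(retain_pair(0.05, 0.06, 1000, "binary"))
  # monotone: larger effect never flips retained -> rejected
  for (kind in c("continuous", "binary")) {
    rs <- seq(-0.5, 0.9, by = 0.05)
    kept <- vapply(rs, retain_pair, logical(1), q = 0.01, n = 400,
                   kind = kind)
    expect_true(all(diff(kept) >= 0))
  }
})

test_that("associate_pathways + build_m3 recover a planted association", {
  set.seed(21)
  n <- 400
  scores <- matrix(rnorm(4 * n), 4,
                   dimnames = list(paste0("PW0", 1:4), paste0("c", 1:n)))
  ep <- tibble::tibble(
    endpoint_id = "acute", kind = "continuous",
    chemical_id = paste0("c", 1:n),
    value = 0.5 * scores[1, ] + sqrt(0.75) * rnorm(n))
  assoc <- associate_pathways(scores, ep)
  expect_s3_class(assoc, "tbl_df")
  expect_equal(nrow(assoc), 4)
  expect_true(assoc$retained[assoc$pathway_id == "PW01"])
  expect_false(any(assoc$retained[assoc$pathway_id != "PW01"]))
  m3 <- build_m3(assoc)
  expect_identical(unname(m3$binarized[, 1]), c(1, 0, 0, 0))

  # binary endpoint goes through the rank path
  epb <- tibble::tibble(
    endpoint_id = "hep", kind = "binary",
    chemical_id = paste0("c", 1:n),
    value = as.numeric(scores[2, ] + rnorm(n) > 0))
  ab <- associate_pathways(scores, epb)
  expect_true(all(ab$test_used %in% c("wilcoxon", "brunner_munzel")))
  expect_true(ab$retained[ab$pathway_id == "PW02"])

  # bootstrap CIs requested for one endpoint
  a2 <- associate_pathways(scores, ep, bootstrap_endpoints = "acute",
                           n_boot = 200, seed = 2)
  expect_true(all(is.finite(a2$boot_lo)))
  expect_true(all(a2$boot_lo <= a2$stat & a2$stat <= a2$boot_hi))
})
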