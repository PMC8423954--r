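test_that("2-SD filter follows the a-priori single-pass rule", {
  # zero-SD input: nothing removed
  expect_equal(remove_outliers_2sd(rep(1, 5))$removed, integer())
  # mean 14, SD 8.944: |30 - 14| = 16 < 17.89, survives
  r <- remove_outliers_2sd(c(10, 10, 10, 10, 30))
  expect_equal(r$removed, integer())
  # mean 1, SD 3.162: |10 - 1| = 9 > 6.32, removed
  r <- remove_outliers_2sd(c(rep(0, 9), 10))
  expect_equal(r$removed, 10L)
  expect_equal(r$values, rep(0, 9))
  # single pass: the filter is not iterated even if survivors shift the SD
  x <- c(rep(0, 20), 5, 100)
  r <- remove_outliers_2sd(x)
  expect_equal(r$removed, 22L)
  expect_true(5 %in% r$values)
  # order preserved
  x <- c(3, 1, 2)
  expect_equal(remove_outliers_2sd(x)$values, x)
})

test_that("composite-normality test is calibrated and has power", {
  set.seed(101)
  # size: false-rejection rate at alpha = 0.05 must not exceed its nominal
  # level beyond Monte-Carlo error (anticonservativeness is the failure mode
  # the simulated null guards against)
  p_norm <- replicate(200, ks_normality(rnorm(200))$p_value)
  expect_lte(mean(p_norm <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  p_exp <- replicate(100, ks_normality(rexp(200))$p_value)
  expect_gte(mean(p_exp < 0.05), 0.95)
  # identical input -> identical p (internal seed fixed)
  x <- rnorm(30)
  expect_identical(ks_normality(x)$p_value, ks_normality(x)$p_value)
  # too-small samples are flagged, not tested
  r <- ks_normality(c(1, 2, 3, 4))
  expect_true(r$too_small)
  expect_true(is.na(r$p_value))
})

test_that("normality p-values agree with the Lilliefors reference", {
  skip_if_not_installed("nortest")
  set.seed(7)
  for (i in 1:20) {
    x <- if (i %% 2) rnorm(40) else rexp(40)
    p_pkg <- ks_normality(x)$p_value
    p_ref <- nortest::lillie.test(x)$p.value
    # same decision at alpha = 0.05 and broadly similar p
    expect_equal(p_pkg <= 0.05, p_ref <= 0.05)
    expect_lt(abs(p_pkg - p_ref), 0.12)
  }
})

test_that("Fisher's LSD planned contrasts match hand computation", {
  r <- anova_fisher_lsd(list(g1 = c(1, 2, 3), g2 = c(2, 3, 4), g3 = c(6, 7, 8)),
                        contrasts = list(c("g1", "g3")))
  expect_equal(r$contrasts$t, -5 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$contrasts$df, 6)
  expect_equal(r$contrasts$p, 2 * pt(-5 / sqrt(2 / 3), 6), tolerance = 1e-12)
  expect_equal(r$contrasts$p, 0.00087, tolerance = 0.01)
})

test_that("LSD with two groups is exactly the pooled-variance t-test", {
  set.seed(20)
  for (i in 1:50) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    lsd <- anova_fisher_lsd(list(a = a, b = b), contrasts = list(c("a", "b")))
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(lsd$contrasts$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(lsd$contrasts$p, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("LSD degenerate cases behave", {
  g <- list(a = c(1, 1), b = c(1, 1), c = c(1, 1), d = c(1, 1))
  expect_error(anova_fisher_lsd(g, list(c("a", "b"))), "zero within-group")
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3), d = c(1, 2, 3))
  r <- anova_fisher_lsd(g, list(c("a", "b"), c("a", "c")))
  expect_equal(r$contrasts$p, c(1, 1))
})

test_that("Welch's t matches hand computation and is antisymmetric", {
  r <- welch_t(1:5, 2:6)
  expect_equal(r$t, -1, tolerance = 1e-12)
  expect_equal(r$df, 8, tolerance = 1e-12)
  expect_equal(r$p, 0.3466, tolerance = 1e-3)
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(0.3, 0.4, 2.8)
  r1 <- welch_t(x, y); r2 <- welch_t(y, x)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  expect_equal(welch_t(c(1, 1, 1), c(1, 1))$t, 0)
})

test_that("Mann-Whitney matches brute-force enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_true(r$exact)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$p, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5, mean = runif(1, 0, 2))
    expect_equal(mann_whitney_u(a, b)$p, oracle_mw_exact_p(a, b),
                 tolerance = 1e-12)
  }
  # rank invariance: monotone relabeling leaves (U, p) unchanged
  a <- c(0.1, 0.5, 2.5, 3); b <- c(0.7, 1.9, 4.2, 5.5)
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(exp(a), exp(b))
  expect_equal(r1$U, r2$U)
  expect_equal(r1$p, r2$p)
})

test_that("two-stage FDR equals the looped oracle on random p-vectors", {
  set.seed(11)
  for (i in 1:1000) {
    m <- sample(5:40, 1)
    # a mix of null and signal p-values
    p <- c(runif(m), rbeta(sample(0:10, 1), 0.2, 5))
    r <- bky_fdr(p, q = 0.05)
    expect_identical(r$reject, oracle_two_stage_bh(p, 0.05))
  }
})

test_that("adaptive FDR rejects at least as much as plain BH when stage 1 is informative", {
  set.seed(12)
  checked <- 0
  for (i in 1:1000) {
    p <- c(runif(15), rbeta(8, 0.2, 4))
    r <- bky_fdr(p, q = 0.05)
    if (r$r1 > 0 && r$r1 < length(p)) {
      bh <- p.adjust(p, method = "BH") <= 0.05
      expect_true(all(r$reject[bh]))
      checked <- checked + 1
    }
  }
  expect_gt(checked, 500)
})

test_that("two-stage FDR edge cases", {
  expect_equal(bky_fdr(numeric())$reject, logical())
  expect_true(all(bky_fdr(rep(1e-9, 10))$reject))
  expect_false(any(bky_fdr(seq(0.9, 1, length.out = 10))$reject))
})

test_that("realized FDR on all-null families stays at or below q", {
  set.seed(13)
  any_rej <- replicate(500, any(bky_fdr(runif(15), q = 0.05)$reject))
  # on an all-null family the FDP is 1 when anything is rejected
  mc_err <- 2 * sqrt(0.05 * 0.95 / 500)
  expect_lte(mean(any_rej), 0.05 + mc_err)
})

test_that("Cohen's d follows the pooled-SD first-minus-second convention", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- rnorm(8); b <- rnorm(10, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_equal(cohens_d(3 * a, 3 * b), cohens_d(a, b), tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled SD")
})

test_that("post-hoc power matches the Monte-Carlo oracle and is monotone", {
  expect_equal(posthoc_power(0, 10, 10), 0.05, tolerance = 1e-6)
  grid <- list(c(2, 12, 14), c(1, 10, 10), c(0.8, 16, 16))
  for (g in grid) {
    mc <- oracle_power_mc(g[1], g[2], g[3], nsim = 2e5, seed = 99 + g[2])
    expect_equal(posthoc_power(g[1], g[2], g[3]), mc, tolerance = 0.005 / mc)
  }
  # strictly increasing in |d| and in n
  ds <- seq(0.2, 3, by = 0.4)
  pw <- vapply(ds, posthoc_power, numeric(1), n_a = 10, n_b = 10)
  expect_true(all(diff(pw) > 0))
  ns <- seq(4, 30, by = 2)
  pw <- vapply(ns, function(n) posthoc_power(1, n, n), numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_error(posthoc_power(1, 10, 10, alpha = 2), "alpha")
})

test_that("Pearson correlation matches the closed form", {
  x <- c(0.7, 1.1, 2.3, 3.1, 4.4, 5.2, 6.8, 7.1, 8.9, 9.3)
  y <- c(1.3, 0.8, 2.9, 2.2, 5.1, 4.4, 6.2, 7.9, 8.1, 9.8)
  r <- pearson_r(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$r, r_direct, tolerance = 1e-12)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 10)), "zero variance")
})

test_that("proportional volume is a scale-invariant ratio", {
  expect_equal(proportional_volume(10, 100)$ratio, 0.1)
  expect_equal(proportional_volume(10, 100)$percent, 10)
  expect_equal(proportional_volume(7, 7)$ratio, 1)
  expect_equal(proportional_volume(3 * 11, 3 * 97)$ratio,
               proportional_volume(11, 97)$ratio)
  expect_error(proportional_volume(-1, 10), "positive")
})
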