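test_that("flat chi-square response gives zero slope and unit intercept", {
  p <- manual_panel(matrix(1, 1000, 1), l2 = rep(c(1, 2, 3, 4), 250))
  f <- estimate_h2(p, "T1", n_blocks = 50, weights = "uniform")
  expect_equal(f$h2, 0, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$se_h2, 0, tolerance = 1e-10)
})

test_that("unweighted free-intercept fit equals the textbook OLS closed form", {
  st <- simulate_sumstats(small_single(seed = 11))
  p <- as_harmonized_panel(st)
  f <- estimate_h2(p, "TRAIT1", weights = "uniform")
  x <- p$N[, 1] * p$ld$EUR / p$M$EUR
  y <- p$Z[, 1]^2
  slope_ols <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_ols <- mean(y) - slope_ols * mean(x)
  expect_equal(f$h2, slope_ols, tolerance = 1e-10)
  expect_equal(f$intercept, intercept_ols, tolerance = 1e-10)
})

test_that("constant LD scores are a degenerate design for a free intercept", {
  p <- manual_panel(matrix(rnorm(1000), 1000, 1), l2 = rep(2, 1000))
  expect_error(estimate_h2(p, "T1", n_blocks = 50),
               class = "transgsem_degenerate_error")
  # but the constrained-intercept fit is defined, with non-negative SE
  f <- estimate_h2(p, "T1", n_blocks = 50, intercept = "fixed")
  expect_true(is.finite(f$h2))
  expect_gte(f$se_h2, 0)
})

test_that("h2 is recovered across seeds", {
  est <- vapply(1:6, function(s) {
    estimate_h2(quick_panel(small_single(h2 = 0.4, seed = s)), "TRAIT1")$h2
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.4), 0.03)
})

test_that("a trait paired with itself gives rg = 1 and unit intercept", {
  st <- simulate_sumstats(small_single(h2 = 0.4, seed = 21))
  Z <- cbind(A = st$sumstats[[1]]$Z, B = st$sumstats[[1]]$Z)
  p <- manual_panel(Z, N = 50000,
                    l2 = st$panels$pop1$L2, M = st$panels$M)
  f <- estimate_rg(p, "A", "B")
  expect_equal(f$rg, 1, tolerance = 1e-6)
  expect_lt(abs(f$intercept - 1), 3 * f$se_intercept + 0.05)
})

test_that("independent null traits give rg within 3 SE of zero", {
  sc <- synthetic_scenario(c("A", "B"), c("EUR", "EUR"),
                           lambda = matrix(0, 2, 1), psi = matrix(1, 1, 1),
                           h2 = c(0.4, 0.4), n = c(5e4, 5e4),
                           design = small_design(), seed = 22)
  f <- estimate_rg(quick_panel(sc), "A", "B")
  expect_lt(abs(f$rg), 3 * f$se_rg)
})

test_that("rg with sample overlap recovers rg and the overlap intercept", {
  res <- vapply(1:6, function(s) {
    p <- quick_panel(small_pair(rg = 0.5, overlap_frac = 0.3, rho_ph = 0.3,
                                seed = 100 + s))
    f <- estimate_rg(p, "TRAIT1", "TRAIT2")
    c(f$rg, f$intercept)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 0.5), 0.05)
  # target intercept 0.3 * 15000 / 50000; wide MC band at this compact M
  se_mean <- stats::sd(res[2, ]) / sqrt(ncol(res))
  expect_lt(abs(mean(res[2, ]) - 0.09), 3 * se_mean + 0.02)
})

test_that("negating one trait's Z negates rho_g and rg but not h2", {
  st <- simulate_sumstats(small_pair(rg = 0.5, seed = 31))
  p1 <- as_harmonized_panel(st)
  st$sumstats[[2]]$Z <- -st$sumstats[[2]]$Z
  p2 <- as_harmonized_panel(st)
  f1 <- estimate_rg(p1, "TRAIT1", "TRAIT2")
  f2 <- estimate_rg(p2, "TRAIT1", "TRAIT2")
  expect_equal(f2$rho_g, -f1$rho_g, tolerance = 1e-12)
  expect_equal(f2$rg, -f1$rg, tolerance = 1e-12)
  expect_equal(f2$h2_2, f1$h2_2, tolerance = 1e-12)
})

test_that("non-positive heritability yields a missing rg with a reason", {
  # chi-square decreasing in the LD score forces a negative h2 slope
  l2 <- rep(c(1, 3), 500)
  z <- sqrt(ifelse(l2 == 1, 3, 1))
  p <- manual_panel(cbind(A = z, B = rnorm(1000)), l2 = l2)
  f <- estimate_rg(p, "A", "B", n_blocks = 50)
  expect_lt(f$h2_1, 0)
  expect_true(is.na(f$rg))
  expect_match(f$reason, "non-positive")
})

test_that("block jackknife matches closed forms", {
  # constant statistic: SE = 0
  bj <- block_jackknife(rep(3.14, 400), function(x) mean(x), n_blocks = 40)
  expect_equal(bj$se, 0, tolerance = 1e-12)

  # delete-one-block means of equal blocks average back to the full mean
  set.seed(5)
  x <- rnorm(400)
  bj2 <- block_jackknife(x, function(v) mean(v), n_blocks = 40)
  expect_equal(mean(bj2$delete_values), bj2$estimate, tolerance = 1e-12)
  expect_equal(colMeans(bj2$pseudovalues), bj2$estimate, tolerance = 1e-12)

  # IID normal mean: jackknife SE tracks sigma / sqrt(n)
  set.seed(6)
  ses <- vapply(1:60, function(i) {
    block_jackknife(rnorm(2000), function(v) mean(v), n_blocks = 200)$se
  }, numeric(1))
  expect_lt(abs(mean(ses) - 1 / sqrt(2000)), 0.1 / sqrt(2000))

  expect_error(block_jackknife(1:10, mean, n_blocks = 11),
               class = "transgsem_block_error")
})
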