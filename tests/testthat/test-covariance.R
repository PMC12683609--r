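test_that("dimensional contract: 9 traits give a 45 x 45 V with provenance", {
  p <- quick_panel(small_fourfactor9(seed = 13))
  sv <- build_S_V(p, n_blocks = 100)
  expect_equal(dim(sv$S), c(9, 9))
  expect_equal(dim(sv$V), c(45, 45))
  expect_equal(sv$S, t(sv$S))
  expect_equal(sv$V, t(sv$V), tolerance = 1e-12)
  expect_true(all(diag(sv$V) >= 0))
  # estimator provenance per cell
  expect_equal(sv$provenance["SCZ_EUR", "SCZ_EUR"], "ldsc_h2")
  expect_equal(sv$provenance["SCZ_EUR", "BD1_EUR"], "ldsc_rg")
  expect_equal(sv$provenance["SCZ_EUR", "SCZ_EAS"], "trans_rg")
  # vech ordering is the documented column-major lower triangle
  idx <- vech_index(3)
  expect_equal(idx$row, c(1, 2, 3, 2, 3, 3))
  expect_equal(idx$col, c(1, 1, 1, 2, 2, 3))
})

test_that("a single trait reduces V to the squared univariate jackknife SE", {
  p <- quick_panel(small_single(seed = 14))
  sv <- build_S_V(p, n_blocks = 100)
  f <- estimate_h2(p, "TRAIT1", n_blocks = 100)
  expect_equal(dim(sv$V), c(1, 1))
  expect_equal(sv$V[1, 1], f$se_h2^2, tolerance = 1e-10)
  expect_equal(sv$S[1, 1], f$h2, tolerance = 1e-12)
})

test_that("independent traits show no sampling coupling between their h2 cells", {
  devs <- vapply(1:10, function(s) {
    sc <- synthetic_scenario(c("A", "B"), c("EUR", "EUR"),
                             lambda = matrix(0, 2, 1), psi = matrix(1, 1, 1),
                             h2 = c(0.4, 0.4), n = c(5e4, 5e4),
                             design = small_design(), seed = 300 + s)
    sv <- build_S_V(quick_panel(sc), n_blocks = 100)
    # correlation between cells (1,1) and (2,2) of S
    sv$V[1, 3] / sqrt(sv$V[1, 1] * sv$V[3, 3])
  }, numeric(1))
  se <- stats::sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 3 * se + 0.05)
})

test_that("smooth_to_psd matches the brute-force eigen-clip projection", {
  set.seed(8)
  A <- matrix(rnorm(36), 6); A <- A + t(A)
  eps <- 1e-6
  sm <- smooth_to_psd(A, eps = eps, correlation = FALSE)
  e <- eigen(A, symmetric = TRUE)
  oracle <- e$vectors %*% diag(pmax(e$values, eps)) %*% t(e$vectors)
  expect_equal(unname(sm), oracle, tolerance = 1e-12, ignore_attr = TRUE)

  # PSD input with min eigenvalue above eps is untouched
  B <- crossprod(matrix(rnorm(36), 6)) + diag(6)
  expect_equal(unname(smooth_to_psd(B, correlation = FALSE)), B,
               tolerance = 1e-12, ignore_attr = TRUE)

  # indefinite correlation matrix is repaired above the floor
  C <- matrix(c(1, 1.2, 1.2, 1), 2)
  smC <- smooth_to_psd(C, eps = eps)
  expect_gte(min(eigen(smC, symmetric = TRUE)$values), eps * (1 - 1e-6))
  expect_equal(diag(smC), c(1, 1))

  expect_error(smooth_to_psd(matrix(1:6, 2, 3)), class = "transgsem_input_error")
})

test_that("standardize rescales S and V consistently", {
  # closed form: cov 3 with variances 4 and 9 gives correlation 0.5
  p <- quick_panel(small_pair(seed = 15))
  sv <- build_S_V(p, n_blocks = 100)
  sv$S <- matrix(c(4, 3, 3, 9), 2, dimnames = dimnames(sv$S))
  std <- standardize(sv)
  expect_equal(std$S_corr[1, 2], 0.5)
  expect_equal(diag(std$S_corr), c(1, 1), ignore_attr = TRUE)

  # already correlation-scale input is an identity transform (fixed scale)
  sv$S <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = dimnames(sv$S))
  V0 <- sv$V
  std2 <- standardize(sv, v_method = "delta")
  expect_equal(std2$S_corr, sv$S)
  expect_equal(std2$V_corr, V0, tolerance = 1e-12)

  # non-positive diagonal names the trait
  sv$S <- matrix(c(-0.1, 0, 0, 1), 2, dimnames = dimnames(sv$S))
  expect_error(standardize(sv), "TRAIT1", class = "transgsem_input_error")
})

test_that("standardized V variants agree with the direct rg jackknife", {
  p <- quick_panel(scenario_pair(rg = 0.5, seed = 16))
  sv <- build_S_V(p, n_blocks = 200)
  f <- estimate_rg(p, "TRAIT1", "TRAIT2", n_blocks = 200)
  # off-diagonal cell (2,1) is vech position 2: the jackknife-standardized
  # V reproduces the bivariate fit's own rg jackknife exactly
  std_j <- standardize(sv, v_method = "jackknife")
  expect_equal(sqrt(std_j$V_corr[2, 2]), f$se_rg, tolerance = 1e-10)
  # the fixed-scale delta variant is close but not identical: it drops the
  # normalization noise, here a conservative approximation
  std_d <- standardize(sv, v_method = "delta")
  ratio <- sqrt(std_d$V_corr[2, 2]) / f$se_rg
  expect_gt(ratio, 0.7); expect_lt(ratio, 1.6)
  # diagonal (heritability) cells coincide across variants by construction
  expect_equal(std_j$V_corr[1, 1], std_d$V_corr[1, 1], tolerance = 1e-12)
})

test_that("S_corr recovery on the full-size preset is nearly unbiased", {
  truth <- true_cov_structure(scenario_fourfactor9())$S_corr_obs
  devs <- sapply(1:12, function(s) {
    p <- quick_panel(scenario_fourfactor9(seed = 400 + s))
    standardize(build_S_V(p))$S_corr - truth
  })
  expect_lt(max(abs(rowMeans(devs))), 0.03)
})
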