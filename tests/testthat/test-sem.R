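traits9 <- c("SCZ_EUR", "SCZ_EAS", "SCZ_JPN", "BD1_EUR", "BD2_EUR",
             "BD1_JPN", "BD2_JPN", "MDD_EUR", "MDD_EAS")

test_that("the bundled four-factor model parses with the intended pattern", {
  spec <- parse_model(model_file("fourfactor9"), traits9)
  expect_s3_class(spec, "factor_model_spec")
  expect_equal(length(spec$factors), 4)
  bd2 <- dplyr::filter(spec$loadings, trait == "BD2_JPN", free)
  expect_equal(nrow(bd2), 2)           # cross-loads on F1 and F2
  bd1j <- dplyr::filter(spec$loadings, trait == "BD1_JPN", free)
  expect_setequal(bd1j$factor, c("F3", "F4"))
  expect_equal(spec$q, 12 + 6 + 9)
  expect_equal(spec$tstar, 45)
})

test_that("model text errors are specific", {
  expect_error(parse_model("factor F1: NOT_A_TRAIT", traits9),
               class = "transgsem_name_error")
  expect_error(parse_model("covary F1 F2", traits9),
               class = "transgsem_model_error")
  expect_error(parse_model("", traits9), class = "transgsem_model_error")
  # over-parameterized: more free parameters than moments
  txt <- c(paste0("factor F", 1:7, ": ", paste(traits9[1:3], collapse = " ")),
           "covary all")
  expect_error(parse_model(txt, traits9[1:3]),
               class = "transgsem_identification_error")
})

test_that("the saturated model has q = t* and fits any PSD target exactly", {
  spec <- model_saturated(traits9[1:4])
  expect_equal(spec$q, 10)
  expect_equal(spec$tstar - spec$q, 0)
  p <- quick_panel(small_fourfactor9(seed = 19))
  std <- standardize(build_S_V(p, n_blocks = 100))
  S4 <- smooth_to_psd(std$S_corr[1:4, 1:4])
  V4 <- std$V_corr[c(1, 2, 3, 4, 10, 11, 12, 18, 19, 25),
                   c(1, 2, 3, 4, 10, 11, 12, 18, 19, 25)]
  fit <- fit_dwls(spec, S4, V4)
  expect_lt(fit$chisq, 1e-8)
  expect_lt(fit$srmr, 1e-8)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$df, 0)
})

test_that("the one-factor triad solution matches the closed form", {
  lam <- c(0.8, 0.7, 0.6)
  S <- tcrossprod(lam); diag(S) <- 1
  dimnames(S) <- list(c("A", "B", "C"), c("A", "B", "C"))
  fit <- fit_dwls("factor F1: A B C", S, diag(0.01, 6))
  r12 <- S[1, 2]; r13 <- S[1, 3]; r23 <- S[2, 3]
  expect_equal(fit$Lambda["A", 1], sqrt(r12 * r13 / r23), tolerance = 1e-6)
  expect_equal(fit$Lambda["B", 1], sqrt(r12 * r23 / r13), tolerance = 1e-6)
  expect_equal(fit$Lambda["C", 1], sqrt(r13 * r23 / r12), tolerance = 1e-6)
})

test_that("noiseless four-factor truth is recovered to 1e-3 with signs", {
  sc <- scenario_fourfactor9()
  tr <- true_cov_structure(sc)
  fit <- fit_dwls(parse_model(model_file("fourfactor9"), traits9),
                  tr$S_corr, diag(0.001, 45))
  expect_lt(max(abs(fit$Lambda - tr$lambda)), 1e-3)
  expect_lt(max(abs(fit$Psi - tr$psi)), 1e-3)
  expect_lt(fit$Lambda["BD2_JPN", "F1"], 0)    # negative cross-loading sign
  expect_true(fit$converged)
})

test_that("the sandwich reduces to (D'WD)^-1 when V matches the weights", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  S <- tcrossprod(lam); diag(S) <- 1
  dimnames(S) <- list(LETTERS[1:4], LETTERS[1:4])
  V <- diag(0.02, 10)
  fit <- fit_dwls("factor F1: A B C D", S, V)
  sw <- transgsem:::sandwich_cov(fit$spec, fit$theta, V)
  J <- sw$jacobian
  naive <- solve(crossprod(J, J / diag(V)))
  expect_equal(sw$cov, naive, tolerance = 1e-8)
})

test_that("fixed parameters are excluded from the parameter table", {
  lam <- c(0.8, 0.7, 0.6)
  S <- tcrossprod(lam); diag(S) <- 1
  dimnames(S) <- list(c("A", "B", "C"), c("A", "B", "C"))
  fit <- fit_dwls(c("factor F1: A B C", "fix F1->A 0.8"), S, diag(0.01, 6))
  expect_false(any(fit$params$type == "loading" & fit$params$rhs == "A"))
  expect_equal(fit$spec$q, 2 + 3)
  expect_equal(fit$Lambda["A", 1], 0.8)
})

test_that("fit indices follow their definitions on a hand-checked example", {
  p <- quick_panel(small_fourfactor9(seed = 23))
  std <- standardize(build_S_V(p, n_blocks = 100))
  S4 <- smooth_to_psd(std$S_corr[c(1, 4, 8, 9), c(1, 4, 8, 9)])
  vpos <- transgsem:::vech_index(9)
  keep <- which(vpos$row %in% c(1, 4, 8, 9) & vpos$col %in% c(1, 4, 8, 9))
  V4 <- std$V_corr[keep, keep]
  fit <- fit_dwls("factor F1: SCZ_EUR BD1_EUR MDD_EUR MDD_EAS", S4, V4)
  # independent spreadsheet-style recomputation from s, sigma-hat, V,
  # with the pseudo-inverse built from an SVD at the documented relative
  # tolerance (1e-12 of the largest singular value)
  s <- fit$s; sig <- transgsem:::vech(fit$implied)
  r <- s - sig
  sv_ <- svd(V4)
  pos <- sv_$d > max(sv_$d) * 1e-12
  Vp <- sv_$v[, pos, drop = FALSE] %*% (t(sv_$u[, pos, drop = FALSE]) / sv_$d[pos])
  chisq <- drop(t(r) %*% Vp %*% r)
  q <- fit$spec$q
  expect_equal(fit$chisq, chisq, tolerance = 1e-8)
  expect_equal(fit$df, 10 - q)
  expect_equal(fit$srmr, sqrt(mean(r^2)), tolerance = 1e-8)
  expect_equal(fit$aic, chisq + 2 * q, tolerance = 1e-8)
  r_i <- s - ifelse(transgsem:::vech_index(4)$row ==
                      transgsem:::vech_index(4)$col, s, 0)
  chisq_i <- drop(t(r_i) %*% Vp %*% r_i)
  cfi <- 1 - max(chisq - fit$df, 0) /
    max(chisq_i - (10 - 4), chisq - fit$df, 0)
  expect_equal(fit$cfi, min(max(cfi, 0), 1), tolerance = 1e-8)
})

test_that("an independence target model has CFI = 0 by construction", {
  p <- quick_panel(small_fourfactor9(seed = 29))
  std <- standardize(build_S_V(p, n_blocks = 100))
  Ssm <- smooth_to_psd(std$S_corr)
  txt <- c("factor F1: SCZ_EUR",
           paste0("fix F1->", traits9, " 0"))
  fit <- fit_dwls(parse_model(txt, traits9), Ssm, std$V_corr)
  expect_equal(fit$cfi, 0, tolerance = 1e-10)
})

test_that("model comparison ranks by AIC with ties broken by parameters", {
  p <- quick_panel(small_fourfactor9(seed = 31))
  std <- standardize(build_S_V(p, n_blocks = 100))
  Ssm <- smooth_to_psd(std$S_corr)
  f4 <- fit_dwls(parse_model(model_file("fourfactor9"), traits9), Ssm, std$V_corr)
  f3 <- fit_dwls(parse_model(model_file("threefactor9"), traits9), Ssm, std$V_corr)
  cmp <- compare_models(four = f4, three = f3)
  expect_equal(cmp$delta_aic[1], 0)
  expect_equal(cmp$aic, sort(cmp$aic))
  # identical fits: delta 0, fewer-parameter tie-break is stable
  cmp2 <- compare_models(a = f4, b = f4)
  expect_equal(cmp2$delta_aic, c(0, 0))
  # mismatched inputs are rejected
  p2 <- quick_panel(small_fourfactor9(seed = 32))
  std2 <- standardize(build_S_V(p2, n_blocks = 100))
  g <- fit_dwls(parse_model(model_file("fourfactor9"), traits9),
                smooth_to_psd(std2$S_corr), std2$V_corr)
  expect_error(compare_models(f4, g), class = "transgsem_input_error")
})

test_that("restricted model is preferred over saturated when it fits exactly", {
  lam <- c(0.8, 0.7, 0.6, 0.5)
  S <- tcrossprod(lam); diag(S) <- 1
  dimnames(S) <- list(LETTERS[1:4], LETTERS[1:4])
  V <- diag(0.02, 10)
  f1 <- fit_dwls("factor F1: A B C D", S, V)
  fs <- fit_dwls(model_saturated(LETTERS[1:4]), S, V)
  cmp <- compare_models(onefactor = f1, saturated = fs)
  expect_equal(cmp$model[1], "onefactor")
})

test_that("trait reordering permutes but does not change the solution", {
  sc <- scenario_fourfactor9()
  tr <- true_cov_structure(sc)
  perm <- c(9, 3, 5, 1, 7, 2, 8, 4, 6)
  Sp <- tr$S_corr[perm, perm]
  fit1 <- fit_dwls(parse_model(model_file("fourfactor9"), traits9),
                   tr$S_corr, diag(0.001, 45))
  fit2 <- fit_dwls(parse_model(model_file("fourfactor9"), rownames(Sp)),
                   Sp, diag(0.001, 45))
  expect_equal(fit2$Lambda[traits9, ], fit1$Lambda[traits9, ], tolerance = 1e-6)
})

test_that("standardized solution has unit implied variances with free residuals", {
  p <- quick_panel(small_fourfactor9(seed = 37))
  std <- standardize(build_S_V(p, n_blocks = 100))
  fit <- fit_dwls(parse_model(model_file("fourfactor9"), traits9),
                  smooth_to_psd(std$S_corr), std$V_corr)
  expect_lt(max(abs(diag(fit$implied) - 1)), 1e-6)
  stdsol <- standardized_solution(fit)
  expect_equal(stdsol$Lambda, unname(fit$Lambda), tolerance = 1e-6,
               ignore_attr = TRUE)
})
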