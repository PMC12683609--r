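#' Define a synthetic two-population GWAS scenario
#'
#' A scenario fixes everything the generator needs: trait labels with their
#' population assignment, a standardized latent factor model (loadings
#' `lambda`, factor correlation matrix `psi`, residual genetic variances
#' computed so that the implied genetic correlation matrix has unit
#' diagonal), per-trait SNP heritability and GWAS sample size, within-
#' population sample overlap, the cross-population effect correlation
#' applied to cross-ancestry cells, the LD block design, and the seed.
#'
#' @param traits Character vector of trait labels (e.g. "SCZ_EUR").
#' @param population Character vector, one of two population labels per
#'   trait (e.g. "EUR"/"EAS"); at most two distinct values.
#' @param lambda T x K standardized loading matrix (rows = traits).
#' @param psi K x K factor correlation matrix (unit diagonal, PSD).
#' @param h2 Per-trait SNP heritability on the observed scale, in (0, 1].
#' @param n Per-trait GWAS sample size.
#' @param design An [ld_block_design()].
#' @param overlap Optional tibble with columns `trait1`, `trait2`,
#'   `n_overlap`, `rho_ph` describing within-population sample overlap.
#' @param rho_ge Cross-population genetic-effect correlation applied to
#'   cross-ancestry covariance cells; scalar or T x T matrix. Default 1.
#' @param n_jackknife Number of jackknife blocks the generator aligns its
#'   variant ordering with (default 200).
#' @param seed Mandatory integer seed.
#' @param factors Optional factor names (default F1..FK).
#' @return A `synthetic_scenario` object.
#' @export
synthetic_scenario <- function(traits, population, lambda, psi, h2, n, design,
                               overlap = NULL, rho_ge = 1, n_jackknife = 200,
                               seed, factors = NULL) {
  if (missing(seed) || !length(seed) || is.na(seed)) {
    abort("seed is mandatory", class = "transgsem_scenario_error")
  }
  T_ <- length(traits)
  lambda <- as.matrix(lambda)
  psi <- check_symmetric(as.matrix(psi), "psi")
  K <- ncol(lambda)
  stopifnot(nrow(lambda) == T_, nrow(psi) == K,
            length(population) == T_, length(h2) == T_, length(n) == T_)
  if (length(unique(population)) > 2) {
    abort("at most two populations are supported", class = "transgsem_scenario_error")
  }
  if (max(abs(diag(psi) - 1)) > 1e-10) {
    abort("psi must have unit diagonal", class = "transgsem_scenario_error")
  }
  if (min(eigen(psi, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    abort("psi must be positive semidefinite", class = "transgsem_scenario_error")
  }
  if (any(h2 <= 0 | h2 > 1)) {
    abort("h2 must lie in (0, 1]", class = "transgsem_scenario_error")
  }
  common <- lambda %*% psi %*% t(lambda)
  theta <- 1 - diag(common)
  if (any(theta < -1e-8)) {
    abort(sprintf("communality exceeds 1 for trait %s", traits[which.min(theta)]),
          class = "transgsem_scenario_error")
  }
  theta <- pmax(theta, 0)
  if (is.null(overlap)) {
    overlap <- tibble(trait1 = character(), trait2 = character(),
                      n_overlap = numeric(), rho_ph = numeric())
  }
  overlap <- as_tibble(overlap)
  for (i in seq_len(nrow(overlap))) {
    t1 <- match(overlap$trait1[i], traits); t2 <- match(overlap$trait2[i], traits)
    if (is.na(t1) || is.na(t2)) abort("overlap names an unknown trait",
                                      class = "transgsem_scenario_error")
    if (population[t1] != population[t2]) {
      abort("sample overlap is only allowed within a population",
            class = "transgsem_scenario_error")
    }
    if (overlap$n_overlap[i] > min(n[t1], n[t2])) {
      abort("n_overlap exceeds a trait's sample size", class = "transgsem_scenario_error")
    }
  }
  if (length(rho_ge) == 1) rho_ge <- matrix(rho_ge, T_, T_)
  rho_ge <- check_symmetric(as.matrix(rho_ge), "rho_ge")
  factors <- factors %||% paste0("F", seq_len(K))
  dimnames(lambda) <- list(traits, factors)
  dimnames(psi) <- list(factors, factors)
  structure(list(traits = traits, population = population, lambda = lambda,
                 psi = psi, theta = setNames(theta, traits),
                 h2 = setNames(h2, traits), n = setNames(n, traits),
                 design = design, overlap = overlap, rho_ge = rho_ge,
                 n_jackknife = as.integer(n_jackknife), seed = as.integer(seed)),
            class = "synthetic_scenario")
}

default_design <- function(n_blocks = 2000, block_size = 10) {
  ld_block_design(n_blocks, block_size,
                  r1 = c(0.10, 0.30, 0.50, 0.65, 0.75),
                  r2 = c(0.15, 0.35, 0.45, 0.60, 0.70))
}

#' Preset scenario: nine psychiatric traits, four latent factors
#'
#' The default study conditions: nine GWAS traits (SCZ, BD1, BD2, MDD
#' measured in European and East Asian/Japanese samples), a four-factor
#' standardized loading structure with correlated factors -- a European
#' psychosis factor, an Asian psychosis factor (on which BD2_JPN carries a
#' small negative cross-loading from the European factor), a BD factor and
#' an MDD factor -- M = 20,000 variants in 2,000 LD blocks, N = 50,000 per
#' trait, and modest within-population sample overlap.
#'
#' @param seed Integer seed (default 1).
#' @param n Per-trait sample size (default 50,000).
#' @param design LD design (default 2,000 blocks of 10 variants with a cycle
#'   of intra-block correlations).
#' @return A `synthetic_scenario`.
#' @export
scenario_fourfactor9 <- function(seed = 1, n = 50000, design = default_design()) {
  traits <- c("SCZ_EUR", "SCZ_EAS", "SCZ_JPN", "BD1_EUR", "BD2_EUR",
              "BD1_JPN", "BD2_JPN", "MDD_EUR", "MDD_EAS")
  population <- c("EUR", "EAS", "EAS", "EUR", "EUR", "EAS", "EAS", "EUR", "EAS")
  K <- 4
  lambda <- matrix(0, 9, K, dimnames = list(traits, paste0("F", 1:K)))
  lambda["SCZ_EUR", "F1"] <- 0.85
  lambda["BD1_EUR", "F1"] <- 0.55
  lambda["BD2_JPN", "F1"] <- -0.25   # small negative cross-loading
  lambda["SCZ_EAS", "F2"] <- 0.80
  lambda["SCZ_JPN", "F2"] <- 0.75
  lambda["BD2_JPN", "F2"] <- 0.65
  lambda["BD1_EUR", "F3"] <- 0.35
  lambda["BD2_EUR", "F3"] <- 0.70
  lambda["BD1_JPN", "F3"] <- 0.40
  lambda["BD1_JPN", "F4"] <- 0.45
  lambda["MDD_EUR", "F4"] <- 0.80
  lambda["MDD_EAS", "F4"] <- 0.70
  psi <- matrix(c(1.00, 0.50, 0.45, 0.30,
                  0.50, 1.00, 0.35, 0.25,
                  0.45, 0.35, 1.00, 0.50,
                  0.30, 0.25, 0.50, 1.00), 4, 4)
  h2 <- c(0.23, 0.20, 0.21, 0.18, 0.12, 0.15, 0.13, 0.07, 0.06)
  overlap <- tibble(trait1 = c("BD1_EUR", "SCZ_EUR", "BD1_JPN"),
                    trait2 = c("BD2_EUR", "MDD_EUR", "BD2_JPN"),
                    n_overlap = c(15000, 10000, 12000),
                    rho_ph = c(0.20, 0.10, 0.15))
  synthetic_scenario(traits, population, lambda, psi, h2,
                     n = rep(n, 9), design = design, overlap = overlap,
                     rho_ge = 1, seed = seed)
}

#' Preset scenario: one trait, one population
#'
#' Minimal scenario for heritability-recovery studies: a single trait whose
#' genetic signal is a lone unit-loading factor.
#'
#' @param h2 True heritability (default 0.4).
#' @param n Sample size (default 50,000).
#' @param seed Integer seed.
#' @param design LD design.
#' @return A `synthetic_scenario`.
#' @export
scenario_single <- function(h2 = 0.4, n = 50000, seed = 1, design = default_design()) {
  synthetic_scenario(traits = "TRAIT1", population = "EUR",
                     lambda = matrix(1, 1, 1), psi = matrix(1, 1, 1),
                     h2 = h2, n = n, design = design, seed = seed)
}

#' Preset scenario: a pair of traits
#'
#' Two traits sharing one latent factor, either in the same population
#' (optionally with overlapping samples) or split across the two
#' populations (optionally with an effect correlation below one).  The true
#' genetic correlation between the traits is `rg` (times `rho_ge` on the
#' observation scale when the pair is cross-population).
#'
#' @param rg True genetic correlation between the two traits (default 0.5).
#' @param h2 Length-2 (or scalar) heritabilities (default 0.4).
#' @param n Length-2 (or scalar) sample sizes (default 50,000).
#' @param cross_population If TRUE the traits sit in different populations.
#' @param overlap_frac Shared-sample fraction for a within-population pair.
#' @param rho_ph Phenotypic correlation among the shared samples.
#' @param rho_ge Cross-population effect correlation (default 1).
#' @param seed Integer seed.
#' @param design LD design.
#' @return A `synthetic_scenario`.
#' @export
scenario_pair <- function(rg = 0.5, h2 = 0.4, n = 50000, cross_population = FALSE,
                          overlap_frac = 0, rho_ph = 0, rho_ge = 1, seed = 1,
                          design = default_design()) {
  h2 <- rep_len(h2, 2); n <- rep_len(n, 2)
  if (rg < 0 || rg > 1) abort("scenario_pair needs rg in [0, 1]",
                              class = "transgsem_scenario_error")
  lam <- sqrt(rg)
  lambda <- matrix(c(lam, lam), 2, 1)
  population <- if (cross_population) c("EUR", "EAS") else c("EUR", "EUR")
  overlap <- NULL
  if (overlap_frac > 0) {
    if (cross_population) abort("no cross-population sample overlap",
                                class = "transgsem_scenario_error")
    overlap <- tibble(trait1 = "TRAIT1", trait2 = "TRAIT2",
                      n_overlap = overlap_frac * min(n), rho_ph = rho_ph)
  }
  synthetic_scenario(traits = c("TRAIT1", "TRAIT2"), population = population,
                     lambda = lambda, psi = matrix(1, 1, 1), h2 = h2, n = n,
                     design = design, overlap = overlap, rho_ge = rho_ge,
                     seed = seed)
}

#' True covariance structure implied by a scenario
#'
#' Evaluates the scenario's factor model: the true genetic correlation
#' matrix `S_corr = lambda psi lambda' + theta`, the covariance-scale matrix
#' `S_cov` obtained by scaling with `sqrt(h2_t h2_u)` (cross-ancestry cells
#' additionally multiplied by `rho_ge`), and the observation-scale
#' correlation matrix `S_corr_obs` (equal to `S_corr` when `rho_ge = 1`).
#'
#' @param scenario A `synthetic_scenario`.
#' @return A `truth_record` with the matrices above plus `h2`, `rg`,
#'   `lambda`, `psi`, `theta`, `seed`.
#' @export
true_cov_structure <- function(scenario) {
  sc <- scenario
  S_corr <- sc$lambda %*% sc$psi %*% t(sc$lambda) + diag(sc$theta, length(sc$traits))
  dimnames(S_corr) <- list(sc$traits, sc$traits)
  if (max(abs(diag(S_corr) - 1)) > 1e-10) {
    abort("internal error: S_corr diagonal is not 1", class = "transgsem_scenario_error")
  }
  cross <- outer(sc$population, sc$population, `!=`)
  atten <- ifelse(cross, sc$rho_ge, 1)
  S_corr_obs <- S_corr * atten
  S_cov <- S_corr_obs * sqrt(outer(sc$h2, sc$h2))
  dimnames(S_cov) <- dimnames(S_corr_obs) <- dimnames(S_corr)
  structure(list(S_corr = S_corr, S_corr_obs = S_corr_obs, S_cov = S_cov,
                 h2 = sc$h2, rg = S_corr, lambda = sc$lambda, psi = sc$psi,
                 theta = sc$theta, seed = sc$seed),
            class = "truth_record")
}
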