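#' Simulate GWAS summary statistics from a scenario
#'
#' Draws, independently for every variant j, the T-vector of Z-scores from a
#' zero-mean multivariate normal whose covariance follows the LD score
#' regression moment conditions:
#' `Cov[z_t, z_u] = sqrt(N_t N_u) * l_j(t,u) * S_cov[t,u] / M + delta(t,u)`,
#' where `l_j(t,u)` is the within-population LD score of the pair's
#' population (or the cross-population LD score for a cross-ancestry pair)
#' and `delta` is 1 on the diagonal, `rho_ph * N_s / sqrt(N_t N_u)` for
#' overlapping within-population pairs, and 0 across populations.  Sampling
#' Z-scores directly from the moment model (rather than simulating
#' genotypes) makes LD score regression consistent by construction, so
#' parameter-recovery checks are sharp.
#'
#' @param scenario A [synthetic_scenario()].
#' @param scramble If TRUE, exercise harmonization: a fraction of records
#'   get A1/A2 swapped (Z negated), a fraction strand-flipped, and a
#'   fraction of variants get strand-ambiguous allele pairs.
#' @param scramble_frac,flip_frac Per-record swap / strand-flip
#'   probabilities (defaults 0.2).
#' @param ambiguous_frac Fraction of variants given ambiguous (A/T) alleles
#'   (default 0.05).
#' @return A `synthetic_study`: named list of sumstats tibbles
#'   (SNP, A1, A2, Z, N), the LD `panels`, the `truth` record, the
#'   jackknife `blocks` vector, and the scenario.
#' @export
simulate_sumstats <- function(scenario, scramble = FALSE, scramble_frac = 0.2,
                              flip_frac = 0.2, ambiguous_frac = 0.05) {
  sc <- scenario
  set.seed(sc$seed)
  panels <- build_ld_panels(sc$design)
  truth <- true_cov_structure(sc)
  T_ <- length(sc$traits)
  M <- sc$design$M
  Nv <- sc$n

  # fixed additive part: intercept matrix Delta
  Delta <- diag(1, T_)
  for (i in seq_len(nrow(sc$overlap))) {
    t1 <- match(sc$overlap$trait1[i], sc$traits)
    t2 <- match(sc$overlap$trait2[i], sc$traits)
    d <- sc$overlap$rho_ph[i] * sc$overlap$n_overlap[i] / sqrt(Nv[t1] * Nv[t2])
    Delta[t1, t2] <- Delta[t2, t1] <- d
  }

  same_pop <- outer(sc$population, sc$population, `==`)
  pop1 <- unique(sc$population)[1]
  scaleN <- sqrt(outer(Nv, Nv)) / M

  # one covariance matrix per distinct LD regime (r1, r2) pair
  m1 <- sc$design$m - 1
  regime <- match(paste(sc$design$r1, sc$design$r2),
                  unique(paste(sc$design$r1, sc$design$r2)))
  blk <- rep(seq_len(sc$design$n_blocks), each = sc$design$m)
  Z <- matrix(0, M, T_, dimnames = list(NULL, sc$traits))
  for (p in unique(regime)) {
    b <- which(regime == p)[1]
    l_within <- 1 + m1 * c(sc$design$r1[b], sc$design$r2[b])^2
    l_cross <- 1 + m1 * sc$design$r1[b] * sc$design$r2[b]
    lpop <- ifelse(sc$population == pop1, l_within[1], l_within[2])
    # same-pop pairs share that population's LD score; cross pairs use l_cross
    Lmat <- ifelse(same_pop, (outer(lpop, lpop, `+`)) / 2, l_cross)
    Sigma <- scaleN * Lmat * truth$S_cov + Delta
    ev <- eigen(Sigma, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(abs(ev$values))) {
      Rimp <- Sigma / sqrt(outer(diag(Sigma), diag(Sigma)))
      off <- abs(Rimp); diag(off) <- 0
      ij <- which(off == max(off), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "per-variant covariance not positive semidefinite in LD regime %d; worst pair %s / %s (implied correlation %.3f)",
        p, sc$traits[ij[1]], sc$traits[ij[2]], Rimp[ij[1], ij[2]]),
        class = "transgsem_simulation_error")
    }
    root <- t(ev$vectors %*% (t(ev$vectors) * sqrt(pmax(ev$values, 0))))
    rows <- which(regime[blk] == p)
    Z[rows, ] <- matrix(rnorm(length(rows) * T_), ncol = T_) %*% root
  }

  snp <- variant_ids(M)
  a1 <- rep("A", M); a2 <- rep("G", M)
  ambig <- integer(0)
  if (scramble && ambiguous_frac > 0) {
    ambig <- sample.int(M, size = round(ambiguous_frac * M))
  }
  comp <- c(A = "T", T = "A", C = "G", G = "C")

  sumstats <- lapply(seq_len(T_), function(t) {
    tb <- tibble(SNP = snp, A1 = a1, A2 = a2, Z = Z[, t], N = Nv[t])
    if (scramble) {
      swap <- stats::runif(M) < scramble_frac
      flip <- stats::runif(M) < flip_frac
      tmp <- tb$A1[swap]; tb$A1[swap] <- tb$A2[swap]; tb$A2[swap] <- tmp
      tb$Z[swap] <- -tb$Z[swap]
      tb$A1[flip] <- comp[tb$A1[flip]]
      tb$A2[flip] <- comp[tb$A2[flip]]
      if (length(ambig)) { tb$A1[ambig] <- "A"; tb$A2[ambig] <- "T" }
    }
    tb
  })
  names(sumstats) <- sc$traits

  structure(list(
    sumstats = sumstats,
    panels = panels,
    truth = truth,
    scenario = sc,
    blocks = assign_blocks(M, sc$n_jackknife),
    traits = tibble(trait = sc$traits, population = sc$population)
  ), class = "synthetic_study")
}

#' Assemble a harmonized panel directly from a synthetic study
#'
#' Convenience constructor that skips the file round trip: stacks the
#' study's Z-scores, sample sizes and LD scores into the aligned panel the
#' estimators consume.
#'
#' @param study A `synthetic_study` from [simulate_sumstats()].
#' @return A `harmonized_panel`.
#' @export
as_harmonized_panel <- function(study) {
  sc <- study$scenario
  pops <- unique(sc$population)
  panels <- list()
  panels[[pops[1]]] <- study$panels$pop1
  if (length(pops) > 1) panels[[pops[2]]] <- study$panels$pop2
  panels[["cross"]] <- study$panels$cross
  Ms <- setNames(as.list(rep(study$panels$M, length(panels))), names(panels))
  new_harmonized_panel(
    snp = study$sumstats[[1]]$SNP,
    Z = do.call(cbind, lapply(study$sumstats, `[[`, "Z")),
    N = do.call(cbind, lapply(study$sumstats, `[[`, "N")),
    traits = study$traits,
    ld = lapply(panels, `[[`, "L2"),
    M = Ms
  )
}
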