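# Small fixtures built in code.  The compact LD design keeps unit tests
# fast; acceptance checks in test-acceptance.R use the full-size presets.

small_design <- function(n_blocks = 400, m = 5) {
  ld_block_design(n_blocks, m,
                  r1 = c(0.1, 0.3, 0.5, 0.65, 0.75),
                  r2 = c(0.15, 0.35, 0.45, 0.60, 0.70))
}

small_single <- function(h2 = 0.4, seed = 1, n = 50000) {
  scenario_single(h2 = h2, n = n, seed = seed, design = small_design())
}

small_pair <- function(seed = 1, ...) {
  scenario_pair(seed = seed, design = small_design(), ...)
}

small_fourfactor9 <- function(seed = 1) {
  scenario_fourfactor9(seed = seed, design = small_design())
}

quick_panel <- function(scenario, ...) {
  as_harmonized_panel(simulate_sumstats(scenario, ...))
}

# panel holding explicitly given Z columns over a trivial LD landscape
manual_panel <- function(Z, N = 50000, l2 = NULL, population = NULL, M = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z); Tt <- ncol(Z)
  traits <- tibble::tibble(
    trait = colnames(Z) %||% paste0("T", seq_len(Tt)),
    population = population %||% rep("EUR", Tt))
  l2 <- l2 %||% rep(2, n)
  pops <- unique(traits$population)
  ld <- stats::setNames(rep(list(l2), length(pops)), pops)
  ld$cross <- l2
  Ms <- stats::setNames(as.list(rep(M %||% n, length(ld))), names(ld))
  transgsem:::new_harmonized_panel(
    snp = sprintf("s%07d", seq_len(n)),
    Z = Z, N = matrix(N, n, Tt), traits = traits, ld = ld, M = Ms)
}

`%||%` <- rlang::`%||%`

expect_no_na <- function(x) expect_false(anyNA(x))
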