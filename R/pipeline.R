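#' Path to a bundled factor model specification
#'
#' @param name "fourfactor9" or "threefactor9".
#' @return File path of the model text.
#' @export
model_file <- function(name = c("fourfactor9", "threefactor9")) {
  name <- match.arg(name)
  system.file("extdata", "models", paste0(name, ".model"),
              package = "transgsem", mustWork = TRUE)
}

pipeline_config_defaults <- function() {
  list(scenario = "fourfactor9", seed = 1, n_blocks = 200,
       efa_k = c(3, 4, 5), smoothing_eps = 1e-6,
       models = list(fourfactor9 = model_file("fourfactor9"),
                     threefactor9 = model_file("threefactor9")))
}

resolve_scenario <- function(config) {
  sc <- config$scenario
  if (inherits(sc, "synthetic_scenario")) return(sc)
  if (identical(sc, "fourfactor9")) return(scenario_fourfactor9(seed = config$seed))
  abort(sprintf("unknown scenario '%s'", sc), class = "transgsem_config_error")
}

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(unname(h), basename(paths))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> write/munge -> LDSC -> trans-ancestry -> (S, V)
#' -> standardize/smooth -> EFA scan -> confirmatory DWLS fits -> report,
#' writing every stage artifact plus a reproducibility manifest (config
#' hash and per-file md5 hashes) under `outdir`.  Rerunning with the same
#' configuration and seed reproduces identical hashes.
#'
#' @param config List (or YAML file path) with entries `scenario`
#'   ("fourfactor9" or a `synthetic_scenario`), `seed`, `n_blocks`,
#'   `efa_k`, `smoothing_eps`, and `models` (named list of model text
#'   paths).  Missing entries take defaults.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the manifest and all stage results.
#' @export
run_pipeline <- function(config = list(), outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(pipeline_config_defaults(), config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = "transgsem",
                   version = as.character(utils::packageVersion("transgsem")),
                   seed = config$seed,
                   config_hash = substr(rlang::hash(config[setdiff(names(config), "scenario")]), 1, 16),
                   stages = list())
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "transgsem_pipeline_error", parent = e)
    })
  }

  # -- simulate -----------------------------------------------------------
  sc <- resolve_scenario(config)
  study <- stage("simulate", function() simulate_sumstats(sc))
  ssdir <- file.path(outdir, "sumstats")
  dir.create(ssdir, showWarnings = FALSE)
  ss_paths <- vapply(names(study$sumstats), function(tr) {
    p <- file.path(ssdir, paste0(tr, ".sumstats.tsv"))
    write_sumstats(study$sumstats[[tr]], p)
    p
  }, character(1))
  pops <- unique(sc$population)
  panel_paths <- character(0)
  panel_objs <- list()
  for (nm in c(pops, "cross")) {
    src <- switch(nm, cross = study$panels$cross,
                  if (nm == pops[1]) study$panels$pop1 else study$panels$pop2)
    p <- file.path(ssdir, paste0("ldscore_", nm, ".tsv"))
    attr(src, "M") <- study$panels$M
    write_ld_panel(src, p)
    panel_paths <- c(panel_paths, p, paste0(p, ".M"))
    panel_objs[[nm]] <- src
  }
  manifest$stages$simulate <- list(status = "ok", n_traits = length(ss_paths),
                                   M = study$panels$M,
                                   files = hash_files(c(ss_paths, panel_paths)))

  # -- munge: read back, harmonize, QC, merge -----------------------------
  panel <- stage("munge", function() {
    tabs <- lapply(ss_paths, read_sumstats)
    names(tabs) <- names(ss_paths)
    tabs <- harmonize(tabs)
    tabs <- lapply(tabs, qc_filter, min_maf = NULL, min_info = NULL)
    panels <- lapply(panel_objs, function(p) { attr(p, "M") <- study$panels$M; p })
    merge_panel(tabs, panels, study$traits)
  })
  manifest$stages$munge <- list(status = "ok", n_variants = nrow(panel$Z))

  # -- LDSC + trans-ancestry: S and V -------------------------------------
  structure_cov <- stage("buildsv", function() build_S_V(panel, n_blocks = config$n_blocks))
  h2_tbl <- dplyr::bind_rows(lapply(structure_cov$h2_fits, glance))
  readr::write_tsv(h2_tbl, file.path(outdir, "h2_estimates.tsv"), progress = FALSE)
  rg_tbl <- tidy(standardize(structure_cov))
  readr::write_tsv(rg_tbl, file.path(outdir, "genetic_correlations.tsv"), progress = FALSE)
  S_path <- file.path(outdir, "S_cov.tsv"); V_path <- file.path(outdir, "V.tsv")
  readr::write_tsv(as.data.frame(structure_cov$S), S_path, progress = FALSE)
  readr::write_tsv(as.data.frame(structure_cov$V), V_path, progress = FALSE)
  writeLines(rownames(structure_cov$S), file.path(outdir, "S_labels.txt"))
  manifest$stages$buildsv <- list(
    status = "ok", n_blocks = structure_cov$n_blocks,
    files = hash_files(c(file.path(outdir, "h2_estimates.tsv"),
                         file.path(outdir, "genetic_correlations.tsv"),
                         S_path, V_path)))

  # -- standardize + smooth ----------------------------------------------
  std <- stage("standardize", function() standardize(structure_cov))
  S_sm <- smooth_to_psd(std$S_corr, eps = config$smoothing_eps)
  manifest$stages$standardize <- list(status = "ok",
                                      smoothing_delta = attr(S_sm, "max_delta"))

  # -- EFA ----------------------------------------------------------------
  efa_summary <- stage("efa", function() efa_scan(S_sm, config$efa_k))
  readr::write_tsv(efa_summary, file.path(outdir, "efa_scan.tsv"), progress = FALSE)
  manifest$stages$efa <- list(status = "ok",
                              files = hash_files(file.path(outdir, "efa_scan.tsv")))

  # -- SEM ----------------------------------------------------------------
  fits <- stage("sem", function() {
    purrr::imap(config$models, function(path, nm) {
      fit_dwls(parse_model(path, rownames(S_sm)), S_sm, std$V_corr,
               seed = config$seed)
    })
  })
  comparison <- compare_models(fits)
  readr::write_tsv(comparison, file.path(outdir, "model_comparison.tsv"), progress = FALSE)
  best <- fits[[comparison$model[1]]]
  readr::write_tsv(tidy(best), file.path(outdir, "best_model_parameters.tsv"),
                   progress = FALSE)
  manifest$stages$sem <- list(
    status = "ok", best_model = comparison$model[1],
    files = hash_files(c(file.path(outdir, "model_comparison.tsv"),
                         file.path(outdir, "best_model_parameters.tsv"))))

  # -- report -------------------------------------------------------------
  results <- list(config = config, scenario = sc, truth = study$truth,
                  panel = panel, structure = structure_cov, standardized = std,
                  S_smoothed = S_sm, efa = efa_summary, fits = fits,
                  comparison = comparison)
  report_path <- stage("report", function() write_report(results, file.path(outdir, "report.txt")))
  manifest$stages$report <- list(status = "ok", files = hash_files(report_path))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

#' Write the human-readable analysis report
#'
#' A text report with the heritability table, the genetic correlation
#' matrix, the EFA scan summary, the model comparison, and the best model's
#' standardized path estimates.
#'
#' @param results Result list from [run_pipeline()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_report <- function(results, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  fmt_mat <- function(M, digits = 3) {
    utils::capture.output(print(round(M, digits)))
  }
  w("Multivariate genetic architecture report")
  w("========================================")
  w("")
  w("Traits: %s", paste(results$structure$traits$trait, collapse = ", "))
  w("Variants: %d; jackknife blocks: %d", results$structure$n_snp,
    results$structure$n_blocks)
  w("")
  w("Heritability estimates (observed scale)")
  h2 <- dplyr::bind_rows(lapply(results$structure$h2_fits, function(f) {
    tibble(trait = f$trait, h2 = round(f$h2, 4), se = round(f$se_h2, 4),
           intercept = round(f$intercept, 3))
  }))
  writeLines(utils::capture.output(print(as.data.frame(h2), row.names = FALSE)), con)
  w("")
  w("Genetic correlation matrix (standardized S)")
  writeLines(fmt_mat(results$standardized$S_corr), con)
  w("")
  w("EFA scan")
  writeLines(utils::capture.output(print(as.data.frame(results$efa), row.names = FALSE)), con)
  w("")
  w("Model comparison (AIC ascending)")
  writeLines(utils::capture.output(print(as.data.frame(results$comparison), row.names = FALSE)), con)
  w("")
  best_name <- results$comparison$model[1]
  best <- results$fits[[best_name]]
  w("Best model: %s  [chi2(%d) = %.3f, CFI = %.3f, SRMR = %.3f, AIC = %.1f]",
    best_name, best$df, best$chisq, best$cfi, best$srmr, best$aic)
  w("Standardized path estimates (sandwich SEs)")
  pt <- dplyr::mutate(best$params, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3)))
  writeLines(utils::capture.output(print(as.data.frame(pt), row.names = FALSE)), con)
  invisible(path)
}
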