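#' Parse a confirmatory factor model specification
#'
#' The plain-text grammar has one declaration per line:
#' \preformatted{
#'   factor F1: SCZ_EUR BD1_EUR BD2_JPN   # traits loading on F1
#'   covary F1 F2                         # free factor covariance
#'   covary all                           # free all factor covariances
#'   fix F1->BD2_JPN -0.25                # fix a loading
#'   resid SCZ_EUR 0                      # fix a residual variance
#' }
#' Factor variances are fixed to 1 for identification; residual variances
#' are free by default; factor covariances not declared `covary` are fixed
#' at 0.  `#` starts a comment.
#'
#' @param text Model text (single string, character vector of lines, or a
#'   file path).
#' @param traits Character vector of trait labels in the target matrix;
#'   every trait named in the model must appear here.
#' @return A `factor_model_spec` with the parameter table and free
#'   parameter count `q`.
#' @export
parse_model <- function(text, traits) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text)
  }
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("empty model text", class = "transgsem_model_error")

  factors <- list()
  covary <- character(0)
  covary_all <- FALSE
  fixes <- tibble(factor = character(), trait = character(), value = numeric())
  resid_fix <- tibble(trait = character(), value = numeric())

  for (ln in lines) {
    if (grepl("^factor\\s", ln)) {
      m <- regmatches(ln, regexec("^factor\\s+(\\S+)\\s*:\\s*(.*)$", ln))[[1]]
      if (length(m) < 3) abort(sprintf("cannot parse line: %s", ln),
                               class = "transgsem_model_error")
      factors[[m[2]]] <- strsplit(trimws(m[3]), "\\s+")[[1]]
    } else if (grepl("^covary\\s+all$", ln)) {
      covary_all <- TRUE
    } else if (grepl("^covary\\s", ln)) {
      pr <- strsplit(ln, "\\s+")[[1]][-1]
      if (length(pr) != 2) abort(sprintf("covary needs two factors: %s", ln),
                                 class = "transgsem_model_error")
      covary <- c(covary, paste(sort(pr), collapse = "~"))
    } else if (grepl("^fix\\s", ln)) {
      m <- regmatches(ln, regexec("^fix\\s+(\\S+?)\\s*->\\s*(\\S+)\\s+(\\S+)$", ln))[[1]]
      if (length(m) < 4) abort(sprintf("cannot parse line: %s", ln),
                               class = "transgsem_model_error")
      fixes <- dplyr::bind_rows(fixes, tibble(factor = m[2], trait = m[3],
                                              value = as.numeric(m[4])))
    } else if (grepl("^resid\\s", ln)) {
      p <- strsplit(ln, "\\s+")[[1]][-1]
      if (length(p) != 2) abort(sprintf("resid needs a trait and a value: %s", ln),
                                class = "transgsem_model_error")
      resid_fix <- dplyr::bind_rows(resid_fix, tibble(trait = p[1], value = as.numeric(p[2])))
    } else {
      abort(sprintf("unrecognized model line: %s", ln), class = "transgsem_model_error")
    }
  }
  if (!length(factors)) abort("model declares no factors", class = "transgsem_model_error")

  fnames <- names(factors)
  all_named <- unique(c(unlist(factors), fixes$trait, resid_fix$trait))
  unknown <- setdiff(all_named, traits)
  if (length(unknown)) {
    abort(sprintf("unknown trait name(s): %s", paste(unknown, collapse = ", ")),
          class = "transgsem_name_error")
  }
  bad_f <- setdiff(fixes$factor, fnames)
  if (length(bad_f)) abort(sprintf("fix names unknown factor: %s", bad_f[1]),
                           class = "transgsem_model_error")

  # loading table: union of factor-line traits and explicit fixes
  loadings <- dplyr::bind_rows(purrr::imap(factors, function(tr, f) {
    tibble(factor = f, trait = tr)
  }))
  loadings$free <- TRUE
  loadings$value <- NA_real_
  for (i in seq_len(nrow(fixes))) {
    hit <- loadings$factor == fixes$factor[i] & loadings$trait == fixes$trait[i]
    if (any(hit)) {
      loadings$free[hit] <- FALSE; loadings$value[hit] <- fixes$value[i]
    } else {
      loadings <- dplyr::bind_rows(loadings, tibble(
        factor = fixes$factor[i], trait = fixes$trait[i],
        free = FALSE, value = fixes$value[i]))
    }
  }

  K <- length(fnames)
  psi_free <- matrix(FALSE, K, K, dimnames = list(fnames, fnames))
  if (covary_all) {
    psi_free[] <- TRUE
  } else {
    for (pr in covary) {
      ab <- strsplit(pr, "~", fixed = TRUE)[[1]]
      if (!all(ab %in% fnames)) abort(sprintf("covary names unknown factor: %s", pr),
                                      class = "transgsem_model_error")
      psi_free[ab[1], ab[2]] <- psi_free[ab[2], ab[1]] <- TRUE
    }
  }
  diag(psi_free) <- FALSE  # factor variances fixed to 1

  resid <- tibble(trait = traits, free = TRUE, value = NA_real_)
  for (i in seq_len(nrow(resid_fix))) {
    hit <- resid$trait == resid_fix$trait[i]
    resid$free[hit] <- FALSE
    resid$value[hit] <- resid_fix$value[i]
  }

  Tt <- length(traits)
  tstar <- Tt * (Tt + 1) / 2
  q <- sum(loadings$free) + sum(psi_free[lower.tri(psi_free)]) + sum(resid$free)
  if (q > tstar) {
    abort(sprintf("model has %d free parameters but only %d observed moments", q, tstar),
          class = "transgsem_identification_error")
  }
  structure(list(traits = traits, factors = fnames, loadings = loadings,
                 psi_free = psi_free, resid = resid, q = q, tstar = tstar),
            class = "factor_model_spec")
}

#' @export
print.factor_model_spec <- function(x, ...) {
  cat(sprintf("<factor_model_spec> %d traits, %d factors, q = %d free parameters (df = %d)\n",
              length(x$traits), length(x$factors), x$q, x$tstar - x$q))
  invisible(x)
}

#' Saturated model for a trait set
#'
#' One factor per trait with a free loading, all factor covariances free,
#' residual variances fixed at 0: exactly t* free parameters, df = 0.
#'
#' @param traits Character vector of trait labels.
#' @return A `factor_model_spec`.
#' @export
model_saturated <- function(traits) {
  fl <- paste0("factor G", seq_along(traits), ": ", traits)
  rl <- paste0("resid ", traits, " 0")
  parse_model(c(fl, "covary all", rl), traits)
}

# free-parameter vector layout: loadings, then lower-tri psi, then residuals
param_table <- function(spec) {
  lo <- dplyr::filter(spec$loadings, .data$free)
  lo <- tibble(type = "loading", lhs = lo$factor, rhs = lo$trait)
  K <- length(spec$factors)
  ps <- NULL
  if (K > 1) {
    lowidx <- which(lower.tri(spec$psi_free), arr.ind = TRUE)
    keep <- spec$psi_free[lowidx]
    ps <- tibble(type = "psi", lhs = spec$factors[lowidx[keep, 2]],
                 rhs = spec$factors[lowidx[keep, 1]])
  }
  re <- dplyr::filter(spec$resid, .data$free)
  re <- tibble(type = "resid", lhs = re$trait, rhs = re$trait)
  dplyr::bind_rows(lo, ps, re)
}
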