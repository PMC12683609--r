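STRAND_COMP <- c(A = "T", T = "A", C = "G", G = "C")

is_ambiguous_pair <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & unname(STRAND_COMP[a1]) == a2
}

#' Read a GWAS summary-statistics table
#'
#' Reads a whitespace- or tab-delimited file (gzip transparently supported)
#' into the standard layout `SNP, A1, A2, Z, N` with optional `MAF` and
#' `INFO`.  Rows with missing or non-finite Z or N are dropped with a
#' message reporting the count.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping standard names
#'   to the file's column names, e.g. `c(SNP = "rsid", Z = "zscore")`.
#' @return A tibble of per-variant records.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path),
                                class = "transgsem_io_error")
  # base parser: correctly rounded doubles, so write/read round trips are exact
  tb <- as_tibble(utils::read.table(path, header = TRUE, sep = "",
                                    stringsAsFactors = FALSE, check.names = FALSE))
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% names(tb)) {
        abort(sprintf("mapped column '%s' absent from %s", column_map[[std]], path),
              class = "transgsem_schema_error")
      }
      names(tb)[names(tb) == column_map[[std]]] <- std
    }
  }
  required <- c("SNP", "A1", "A2", "Z", "N")
  missing_cols <- setdiff(required, names(tb))
  if (length(missing_cols)) {
    abort(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "transgsem_schema_error")
  }
  keep <- intersect(c(required, "MAF", "INFO"), names(tb))
  tb <- dplyr::select(tb, dplyr::all_of(keep))
  tb <- dplyr::mutate(tb,
    SNP = as.character(.data$SNP),
    A1 = toupper(as.character(.data$A1)), A2 = toupper(as.character(.data$A2)),
    Z = as.numeric(.data$Z), N = as.numeric(.data$N))
  bad <- !is.finite(tb$Z) | !is.finite(tb$N) | tb$N <= 0
  if (any(bad)) {
    inform(sprintf("read_sumstats: dropped %d row(s) with missing/invalid Z or N", sum(bad)))
    tb <- tb[!bad, , drop = FALSE]
  }
  dup <- duplicated(tb$SNP)
  if (any(dup)) {
    abort(sprintf("duplicate variant id: %s", tb$SNP[which(dup)[1]]),
          class = "transgsem_schema_error")
  }
  tb
}

#' Write summary statistics in the standard munged layout
#'
#' @param table Sumstats tibble.
#' @param path Output path (.gz supported).
#' @return The path, invisibly.
#' @export
write_sumstats <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Read / write an LD score panel
#'
#' Panels use the `CHR SNP BP L2` layout with a sidecar `<path>.M` file
#' holding the reference variant count.
#'
#' @param path Panel file path.
#' @return A tibble with attribute `M`.
#' @export
read_ld_panel <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path),
                                class = "transgsem_io_error")
  tb <- as_tibble(utils::read.table(path, header = TRUE, sep = "",
                                    stringsAsFactors = FALSE, check.names = FALSE))
  need <- c("CHR", "SNP", "BP", "L2")
  if (!all(need %in% names(tb))) {
    abort(sprintf("LD panel %s must have columns %s", path, paste(need, collapse = " ")),
          class = "transgsem_schema_error")
  }
  mfile <- paste0(path, ".M")
  M <- if (file.exists(mfile)) as.integer(readLines(mfile, n = 1)) else nrow(tb)
  attr(tb, "M") <- M
  tb
}

#' @rdname read_ld_panel
#' @param panel LD panel tibble (optionally with attribute `M`).
#' @param M Reference variant count for the sidecar file.
#' @export
write_ld_panel <- function(panel, path, M = attr(panel, "M") %||% nrow(panel)) {
  readr::write_tsv(panel[, c("CHR", "SNP", "BP", "L2")], path, progress = FALSE)
  writeLines(as.character(M), paste0(path, ".M"))
  invisible(path)
}

harmonize_one <- function(tb, reference) {
  ref <- dplyr::select(reference, "SNP", ref_A1 = "A1", ref_A2 = "A2")
  x <- dplyr::left_join(tb, ref, by = "SNP")
  ambiguous <- is_ambiguous_pair(x$A1, x$A2)
  missing_ref <- is.na(x$ref_A1)
  fA1 <- unname(STRAND_COMP[x$A1]); fA2 <- unname(STRAND_COMP[x$A2])
  match_same <- !missing_ref & x$A1 == x$ref_A1 & x$A2 == x$ref_A2
  match_swap <- !missing_ref & x$A1 == x$ref_A2 & x$A2 == x$ref_A1
  match_flip <- !missing_ref & fA1 == x$ref_A1 & fA2 == x$ref_A2
  match_flip_swap <- !missing_ref & fA1 == x$ref_A2 & fA2 == x$ref_A1
  resolvable <- match_same | match_swap | match_flip | match_flip_swap
  irreconcilable <- !missing_ref & !ambiguous & !resolvable
  keep <- !ambiguous & !missing_ref & resolvable
  out <- x[keep, , drop = FALSE]
  negate <- (match_swap | match_flip_swap)[keep]
  out$Z[negate] <- -out$Z[negate]
  out$A1 <- out$ref_A1; out$A2 <- out$ref_A2
  out <- dplyr::select(out, -"ref_A1", -"ref_A2")
  log <- tibble(category = c("ambiguous", "missing_reference", "irreconcilable"),
                n = c(sum(ambiguous), sum(missing_ref & !ambiguous), sum(irreconcilable)))
  attr(out, "harmonize_log") <- log
  out
}

#' Harmonize allele coding across summary-statistics tables
#'
#' Aligns every table to a per-variant reference allele assignment: records
#' with swapped A1/A2 get their Z negated and alleles swapped; records on
#' the opposite strand (complement alleles) are mapped to the reference
#' strand; strand-ambiguous variants (A/T, C/G) and variants with
#' irreconcilable alleles are removed.  Removal counts per category are
#' attached as the `harmonize_log` attribute of each table.
#'
#' @param tables List of sumstats tibbles.
#' @param reference Optional tibble `SNP, A1, A2`; defaults to the first
#'   table's (non-ambiguous) assignments.
#' @return List of harmonized tibbles, same names as the input.
#' @export
harmonize <- function(tables, reference = NULL) {
  if (!length(tables)) abort("need at least one table", class = "transgsem_input_error")
  if (is.null(reference)) {
    first <- tables[[1]]
    reference <- first[!is_ambiguous_pair(first$A1, first$A2), c("SNP", "A1", "A2")]
  }
  out <- lapply(tables, harmonize_one, reference = reference)
  total <- sum(vapply(out, function(x) sum(attr(x, "harmonize_log")$n), numeric(1)))
  if (total > 0) inform(sprintf("harmonize: removed %d record(s) across %d table(s)",
                                total, length(out)))
  out
}

#' Quality-control filter for summary statistics
#'
#' Removes rows failing any active filter: minimum MAF and INFO (applied
#' only when those columns exist) and a maximum chi-square.  The default
#' chi-square cap follows the conventional per-variant rule
#' `max(80, 0.001 * N)`.
#'
#' @param table Sumstats tibble.
#' @param min_maf Minimum minor-allele frequency (default 0.01).
#' @param min_info Minimum imputation INFO (default 0.9).
#' @param max_chisq Chi-square cap; `NULL` (default) uses
#'   `max(80, 0.001 * N)` per variant; `Inf` disables.
#' @return Filtered tibble; removal counts in attribute `qc_log`.
#' @export
qc_filter <- function(table, min_maf = 0.01, min_info = 0.9, max_chisq = NULL) {
  drop_maf <- drop_info <- rep(FALSE, nrow(table))
  skipped <- character(0)
  if (!is.null(min_maf)) {
    if ("MAF" %in% names(table)) {
      maf <- pmin(table$MAF, 1 - table$MAF)
      drop_maf <- !is.na(maf) & maf < min_maf
    } else skipped <- c(skipped, "MAF")
  }
  if (!is.null(min_info)) {
    if ("INFO" %in% names(table)) {
      drop_info <- !is.na(table$INFO) & table$INFO < min_info
    } else skipped <- c(skipped, "INFO")
  }
  if (length(skipped)) {
    warn(sprintf("qc_filter: column(s) %s absent; filter(s) skipped",
                 paste(skipped, collapse = ", ")))
  }
  cap <- if (is.null(max_chisq)) pmax(80, 0.001 * table$N) else max_chisq
  drop_chi <- table$Z^2 > cap
  drop <- drop_maf | drop_info | drop_chi
  out <- table[!drop, , drop = FALSE]
  log <- tibble(category = c("maf", "info", "chisq"),
                n = c(sum(drop_maf), sum(drop_info), sum(drop_chi)))
  if (sum(drop) > 0) inform(sprintf("qc_filter: removed %d row(s)", sum(drop)))
  attr(out, "qc_log") <- log
  out
}

new_harmonized_panel <- function(snp, Z, N, traits, ld, M) {
  colnames(Z) <- colnames(N) <- traits$trait
  structure(list(snp = snp, Z = Z, N = N, traits = traits, ld = ld, M = M),
            class = "harmonized_panel")
}

#' Merge harmonized sumstats with LD score panels
#'
#' Intersects variant ids across all tables and panels, orders variants
#' deterministically (lexicographic by id, C locale), and stacks Z and N
#' into aligned matrices with the per-context LD scores attached.
#'
#' @param tables Named list of harmonized sumstats tibbles (names = traits).
#' @param ld_panels Named list of LD panel tibbles: one per population label
#'   plus, when two populations are present, a `cross` panel.
#' @param traits Tibble `trait, population` assigning each table to a
#'   population; populations must name entries of `ld_panels`.
#' @return A `harmonized_panel`.
#' @export
merge_panel <- function(tables, ld_panels, traits) {
  traits <- as_tibble(traits)
  stopifnot(all(c("trait", "population") %in% names(traits)))
  if (!setequal(names(tables), traits$trait)) {
    abort("tables and traits must name the same traits", class = "transgsem_input_error")
  }
  tables <- tables[traits$trait]
  pops <- unique(traits$population)
  need <- pops
  if (length(pops) > 1) need <- c(need, "cross")
  miss <- setdiff(need, names(ld_panels))
  if (length(miss)) {
    abort(sprintf("missing LD score context(s): %s", paste(miss, collapse = ", ")),
          class = "transgsem_context_error")
  }
  ids <- Reduce(intersect, c(lapply(tables, `[[`, "SNP"),
                             lapply(ld_panels[need], `[[`, "SNP")))
  if (!length(ids)) abort("empty variant intersection", class = "transgsem_input_error")
  ids <- sort_ids(ids)
  Z <- vapply(tables, function(tb) tb$Z[match(ids, tb$SNP)], numeric(length(ids)))
  N <- vapply(tables, function(tb) tb$N[match(ids, tb$SNP)], numeric(length(ids)))
  ld <- lapply(ld_panels[need], function(p) p$L2[match(ids, p$SNP)])
  M <- lapply(ld_panels[need], function(p) attr(p, "M") %||% nrow(p))
  new_harmonized_panel(ids, Z, N, traits, ld, M)
}

#' @export
print.harmonized_panel <- function(x, ...) {
  cat(sprintf("<harmonized_panel> %d variants x %d traits (%s)\n",
              nrow(x$Z), ncol(x$Z), paste(x$traits$trait, collapse = ", ")))
  invisible(x)
}

# LD score vector + reference count for a trait pair
pair_context <- function(panel, t1, t2) {
  p1 <- panel$traits$population[panel$traits$trait == t1]
  p2 <- panel$traits$population[panel$traits$trait == t2]
  cross <- p1 != p2
  key <- if (cross) "cross" else p1
  if (is.null(panel$ld[[key]])) {
    abort(sprintf("missing LD score context '%s' for pair %s / %s", key, t1, t2),
          class = "transgsem_context_error")
  }
  list(l2 = panel$ld[[key]], M = panel$M[[key]], cross = cross, key = key)
}
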