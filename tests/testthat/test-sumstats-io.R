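write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_sumstats reads, types, and drops invalid rows", {
  f <- write_lines_tmp(c("SNP A1 A2 Z N",
                         "rs1 A G 1.2 1000",
                         "rs2 C T -0.3 1000",
                         "rs3 A G 0.5 1000"))
  tb <- read_sumstats(f)
  expect_equal(nrow(tb), 3)
  expect_type(tb$Z, "double")

  f2 <- write_lines_tmp(c("SNP A1 A2 Z N",
                          paste("rs", 1:9, " A G 0.1 1000", sep = ""),
                          "rs10 A G NaN 1000"))
  expect_message(tb2 <- read_sumstats(f2), "dropped 1")
  expect_equal(nrow(tb2), 9)
})

test_that("schema violations are informative errors", {
  f <- write_lines_tmp(c("SNP A1 A2 N", "rs1 A G 1000"))
  expect_error(read_sumstats(f), "Z", class = "transgsem_schema_error")
  f2 <- write_lines_tmp(c("SNP A1 A2 Z N", "rs1 A G 1 1000", "rs1 A G 2 1000"))
  expect_error(read_sumstats(f2), "rs1", class = "transgsem_schema_error")
  # column_map renames
  f3 <- write_lines_tmp(c("rsid A1 A2 zscore N", "rs1 A G 1.5 1000"))
  tb <- read_sumstats(f3, column_map = c(SNP = "rsid", Z = "zscore"))
  expect_equal(tb$Z, 1.5)
})

test_that("scramble-mode output round-trips exactly through write and read", {
  st <- simulate_sumstats(small_pair(seed = 2), scramble = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(st$sumstats[[1]], f)
  back1 <- read_sumstats(f)
  expect_equal(as.data.frame(back1), as.data.frame(st$sumstats[[1]]),
               tolerance = NULL)  # bit-identical doubles
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(back1, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("harmonization applies swap, strand-flip, and removal rules", {
  ref <- tibble::tibble(SNP = c("rs1", "rs2", "rs3", "rs4"),
                        A1 = "A", A2 = "G")
  tb <- tibble::tibble(
    SNP = c("rs1", "rs2", "rs3", "rs4"),
    A1 = c("G", "T", "A", "A"),   # swapped; strand-flipped; ambiguous; bad
    A2 = c("A", "C", "T", "C"),
    Z = c(1.7, 0.5, 0.9, 0.2), N = 1000)
  out <- harmonize(list(x = tb), reference = ref)$x
  expect_equal(out$SNP, c("rs1", "rs2"))
  expect_equal(out$Z, c(-1.7, 0.5))           # swap negates, flip keeps
  expect_equal(out$A1, c("A", "A"))
  log <- attr(out, "harmonize_log")
  expect_equal(log$n[log$category == "ambiguous"], 1)
  expect_equal(log$n[log$category == "irreconcilable"], 1)
})

test_that("harmonization is idempotent and sign-consistent", {
  st <- simulate_sumstats(small_pair(seed = 3), scramble = TRUE)
  h1 <- suppressMessages(harmonize(st$sumstats))
  h2 <- suppressMessages(harmonize(h1))
  expect_equal(lapply(h2, as.data.frame), lapply(h1, as.data.frame),
               ignore_attr = TRUE)

  # negating all Z of one input and swapping its alleles is a no-op
  flipped <- st$sumstats
  flipped[[2]] <- dplyr::mutate(flipped[[2]], Z = -Z, tmp = A1, A1 = A2,
                                A2 = tmp, tmp = NULL)
  ha <- suppressMessages(harmonize(st$sumstats))
  hb <- suppressMessages(harmonize(flipped))
  expect_equal(lapply(ha, as.data.frame), lapply(hb, as.data.frame),
               ignore_attr = TRUE)
})

test_that("scrambled data harmonizes back to the clean generation", {
  clean <- simulate_sumstats(small_pair(seed = 6), scramble = FALSE)
  scram <- simulate_sumstats(small_pair(seed = 6), scramble = TRUE)
  ref <- clean$sumstats[[1]][, c("SNP", "A1", "A2")]
  fixed <- suppressMessages(harmonize(scram$sumstats, reference = ref))
  for (t_ in 1:2) {
    shared <- intersect(fixed[[t_]]$SNP, clean$sumstats[[t_]]$SNP)
    expect_gt(length(shared), 0.85 * nrow(clean$sumstats[[t_]]))
    expect_equal(fixed[[t_]]$Z[match(shared, fixed[[t_]]$SNP)],
                 clean$sumstats[[t_]]$Z[match(shared, clean$sumstats[[t_]]$SNP)])
  }
})

test_that("qc_filter applies the chi-square cap and warns on missing columns", {
  tb <- tibble::tibble(SNP = paste0("rs", 1:10), A1 = "A", A2 = "G",
                       Z = c(10, rnorm(9)), N = 1000)
  expect_warning(out <- qc_filter(tb, max_chisq = 80), "skipped")
  expect_false("rs1" %in% out$SNP)
  expect_equal(nrow(out), 9)
  # null data: removal fraction matches the chi-square tail
  set.seed(1)
  null_tb <- tibble::tibble(SNP = sprintf("s%05d", 1:20000), A1 = "A", A2 = "G",
                            Z = rnorm(20000), N = 1000)
  out2 <- suppressWarnings(suppressMessages(qc_filter(null_tb, max_chisq = 4)))
  frac <- 1 - nrow(out2) / nrow(null_tb)
  p_tail <- stats::pchisq(4, df = 1, lower.tail = FALSE)
  mc_se <- sqrt(p_tail * (1 - p_tail) / 20000)
  expect_lt(abs(frac - p_tail), 3 * mc_se)
})

test_that("merge_panel intersects, orders, and validates contexts", {
  st <- simulate_sumstats(small_pair(seed = 8))
  tabs <- st$sumstats
  # drop two variants from one table: intersection shrinks accordingly
  tabs[[1]] <- tabs[[1]][-c(5, 10), ]
  panels <- list(EUR = st$panels$pop1)
  attr(panels$EUR, "M") <- st$panels$M
  pan <- merge_panel(tabs, panels, tibble::tibble(
    trait = names(tabs), population = "EUR"))
  expect_equal(nrow(pan$Z), st$panels$M - 2)
  expect_identical(pan$snp, sort(pan$snp, method = "radix"))

  # cross-population pair without a cross panel: context error
  tr_cross <- tibble::tibble(trait = names(st$sumstats),
                             population = c("EUR", "EAS"))
  panels2 <- list(EUR = st$panels$pop1, EAS = st$panels$pop2)
  expect_error(merge_panel(st$sumstats, panels2, tr_cross),
               class = "transgsem_context_error")

  # full 9-trait synthetic scenario loses no variants
  st9 <- simulate_sumstats(small_fourfactor9(seed = 9))
  pan9 <- as_harmonized_panel(st9)
  expect_equal(nrow(pan9$Z), st9$panels$M)
})
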