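# Reading, validation, writing and harmonization of summary statistics.

write_toy_file <- function(df, path, sep = "\t") {
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

test_that("well-formed files parse row for row and alleles are upper-cased", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = 1,
                   POS = c(100, 200, 300), EA = c("a", "C", "g"),
                   NEA = c("g", "T", "a"), EAF = c(0.1, 0.5, 0.9),
                   BETA = c(0.05, -0.02, 0), SE = c(0.01, 0.01, 0.01),
                   P = c(5.7e-7, 0.0455, 1), N = 1000)
  path <- write_toy_file(df, tempfile(fileext = ".txt"))
  s <- read_sumstats(path, trait_name = "toy")
  expect_s3_class(s, "study_sumstats")
  expect_equal(nrow(s$records), 3)
  expect_equal(s$records$effect_allele, c("A", "C", "G"))
  expect_equal(s$records$beta, df$BETA)
})

test_that("rows violating record invariants are dropped and counted", {
  df <- mk_records(c("rs1", "rs2", "rs3"))
  df$se[2] <- 0
  path <- write_toy_file(df[, c("variant_id", "chrom", "pos",
                                "effect_allele", "other_allele", "eaf",
                                "beta", "se", "pvalue", "n")],
                         tempfile(fileext = ".txt"))
  dialect <- sumstats_dialect(variant_id = "variant_id", chrom = "chrom",
                              pos = "pos", effect_allele = "effect_allele",
                              other_allele = "other_allele", eaf = "eaf",
                              beta = "beta", se = "se", pvalue = "pvalue",
                              n = "n")
  expect_message(s <- read_sumstats(path, dialect, trait_name = "toy"),
                 "dropped")
  expect_equal(nrow(s$records), 2)
  expect_equal(s$n_dropped, 1L)
  expect_false("rs2" %in% s$records$variant_id)
})

test_that("dialect remapping with shuffled column order parses identically", {
  df <- data.frame(pval = c(5.7e-7, 0.0455), rsid = c("rs1", "rs2"),
                   stderr = 0.01, chr = "2", A2 = "G", A1 = "A",
                   effect = c(0.05, -0.02), bp = c(100, 200),
                   freq = c(0.2, 0.4))
  path <- write_toy_file(df, tempfile(fileext = ".csv"), sep = ",")
  dialect <- sumstats_dialect(variant_id = "rsid", chrom = "chr",
                              pos = "bp", effect_allele = "A1",
                              other_allele = "A2", eaf = "freq",
                              beta = "effect", se = "stderr",
                              pvalue = "pval")
  s <- read_sumstats(path, dialect, trait_name = "toy")
  direct <- mk_study(c("rs1", "rs2"), chrom = "2", pos = c(100, 200),
                     eaf = c(0.2, 0.4), beta = c(0.05, -0.02), se = 0.01)
  expect_equal(s$records[, c("variant_id", "chrom", "pos", "beta", "se")],
               direct$records[, c("variant_id", "chrom", "pos", "beta",
                                  "se")])
})

test_that("missing mandatory columns and empty files are hard errors", {
  df <- data.frame(SNP = "rs1", CHR = 1, POS = 1, EA = "A", NEA = "G",
                   BETA = 0.1, SE = 0.02)  # no P
  path <- write_toy_file(df, tempfile(fileext = ".txt"))
  expect_error(read_sumstats(path), "P")
  empty <- tempfile(fileext = ".txt")
  file.create(empty)
  expect_error(read_sumstats(empty), "empty")
})

test_that("write/read round-trips records bit-exactly, including gzip", {
  set.seed(11)
  s <- mk_study(paste0("rs", 1:20), pos = 1:20 * 1000,
                eaf = runif(20), beta = rnorm(20, 0, 0.07),
                se = runif(20, 0.005, 0.05), n = 5000)
  for (ext in c(".txt", ".txt.gz")) {
    path <- tempfile(fileext = ext)
    write_sumstats(s, path)
    s2 <- read_sumstats(path, trait_name = s$trait_name)
    expect_identical(s2$records$beta, s$records$beta)
    expect_identical(s2$records$se, s$records$se)
    expect_identical(s2$records$pvalue, s$records$pvalue)
    expect_identical(s2$records$eaf, s$records$eaf)
  }
})

test_that("harmonization keeps, flips, and drops variants per allele case", {
  a <- mk_study(c("v_same", "v_swap", "v_strand", "v_strandswap",
                  "v_incompat", "v_palin"),
                effect_allele = c("A", "A", "A", "A", "A", "A"),
                other_allele = c("G", "G", "G", "G", "G", "T"),
                eaf = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.45),
                beta = 0.1, se = 0.02)
  b <- mk_study(c("v_same", "v_swap", "v_strand", "v_strandswap",
                  "v_incompat", "v_palin"),
                effect_allele = c("A", "G", "T", "C", "A", "A"),
                other_allele = c("G", "A", "C", "T", "C", "T"),
                eaf = c(0.3, 0.3, 0.3, 0.7, 0.3, 0.45),
                beta = 0.2, se = 0.02)
  h <- harmonize_pair(a, b, drop_ambiguous_maf = 0.08)
  expect_setequal(h$variant_id, c("v_same", "v_swap", "v_strand",
                                  "v_strandswap"))
  hb <- setNames(h$beta_b, h$variant_id)
  expect_equal(unname(hb["v_same"]), 0.2)
  expect_equal(unname(hb["v_swap"]), -0.2)       # swap: sign flip
  expect_equal(unname(hb["v_strand"]), 0.2)      # strand only: keep
  expect_equal(unname(hb["v_strandswap"]), -0.2) # strand + swap: flip
  expect_equal(h$eaf_b[h$variant_id == "v_swap"], 0.7)
  lg <- attr(h, "log")
  expect_equal(lg$n_palindromic_dropped, 1L)
  expect_equal(lg$n_incompatible, 1L)
  # output orientation matches a exactly
  expect_equal(h$effect_allele,
               a$records$effect_allele[match(h$variant_id,
                                             a$records$variant_id)])
})

test_that("palindromic variants resolve by frequency outside the window", {
  a <- mk_study("v1", effect_allele = "A", other_allele = "T", eaf = 0.2)
  b_keep <- mk_study("v1", effect_allele = "A", other_allele = "T",
                     eaf = 0.22, beta = 0.3)
  b_flip <- mk_study("v1", effect_allele = "A", other_allele = "T",
                     eaf = 0.80, beta = 0.3)
  expect_equal(harmonize_pair(a, b_keep)$beta_b, 0.3)
  expect_equal(harmonize_pair(a, b_flip)$beta_b, -0.3)
  expect_equal(harmonize_pair(a, b_flip)$eaf_b, 0.2)
  # missing eaf cannot resolve strand -> dropped
  b_na <- b_keep
  b_na$records$eaf <- NA_real_
  expect_equal(nrow(harmonize_pair(a, b_na)), 0)
})

test_that("harmonization is idempotent and an involution under b-flips", {
  set.seed(42)
  sim <- simulate_region(30, scenario = "H4", seed = 7,
                         palindromic_frac = 0.2)
  a <- sim$trait1
  b <- sim$trait2
  # scramble half of b's rows to the opposite orientation
  flip <- seq(1, 30, by = 2)
  rb <- b$records
  tmp <- rb$effect_allele[flip]
  rb$effect_allele[flip] <- rb$other_allele[flip]
  rb$other_allele[flip] <- tmp
  rb$beta[flip] <- -rb$beta[flip]
  rb$eaf[flip] <- 1 - rb$eaf[flip]
  b_flipped <- b
  b_flipped$records <- rb

  h0 <- harmonize_pair(a, b)
  h1 <- harmonize_pair(a, b_flipped)
  expect_equal(h0, h1, ignore_attr = TRUE)

  # idempotence: re-harmonizing the harmonized b against a changes nothing
  b2 <- study_sumstats(
    data.frame(variant_id = h0$variant_id, chrom = h0$chrom, pos = h0$pos,
               effect_allele = h0$effect_allele,
               other_allele = h0$other_allele, eaf = h0$eaf_b,
               beta = h0$beta_b, se = h0$se_b, pvalue = h0$pvalue_b,
               n = h0$n_b, stringsAsFactors = FALSE),
    trait_name = "b2", validate = FALSE)
  h2 <- harmonize_pair(a, b2)
  expect_equal(h2$beta_b, h0$beta_b)
  expect_equal(h2$eaf_b, h0$eaf_b)
  expect_equal(nrow(h2), nrow(h0))
})
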