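# Pleiotropy triage steps, modality inference, druggability regrouping,
# and the composite verdict.

test_that("step 1 collects secondary traits below threshold, not itself", {
  empty <- data.frame(variant_id = character(), trait = character(),
                      pvalue = numeric())
  expect_equal(nrow(step1_secondary_traits("v1", "PROT1", empty)), 0)

  prot <- data.frame(variant_id = c("v1", "v1", "v1", "v2"),
                     trait = c("X", "Y", "PROT1", "Z"),
                     pvalue = c(1e-9, 1e-7, 1e-20, 1e-9))
  sec <- step1_secondary_traits("v1", "PROT1", prot)
  expect_equal(sec$trait, "X")       # Y above 5e-8, PROT1 self, Z other SNP
  expect_equal(sec$kind, "protein")
  expr <- data.frame(variant_id = "v1", trait = "E1", pvalue = 1e-10)
  sec2 <- step1_secondary_traits("v1", "PROT1", prot, expr)
  expect_setequal(sec2$trait, c("X", "E1"))
  expect_setequal(sec2$kind, c("protein", "expression"))
})

test_that("step 2 flags genes within the window of known risk loci", {
  genes <- data.frame(gene = c("A", "B", "C"), chrom = c("1", "1", "2"),
                      start = c(1.0e6, 9.0e6, 1.0e6),
                      end = c(1.1e6, 9.1e6, 1.1e6))
  loci <- data.frame(chrom = c("1", "1"), pos = c(1.5e6, 7.4e6))
  near <- step2_known_locus_proximity(genes, loci, window = 1e6)
  expect_true(near[["A"]])    # 0.4 Mb from a lead
  expect_false(near[["B"]])   # 1.5 Mb from the nearest lead
  expect_false(near[["C"]])   # different chromosome
})

test_that("step 3 tests each instrumented trait with a Bonferroni cutoff", {
  sec <- data.frame(source_instrument = c("v1", "v1", "v1"),
                    trait = c("X", "Y", "W"), kind = "protein",
                    assoc_p = 1e-9)
  db <- data.frame(trait = c("X", "Y"),
                   variant_id = c("ix", "iy"),
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   beta = c(0.5, 0.5), se = 0.03,
                   pvalue = 1e-50, kind = c("protein", "expression"))
  out <- mk_study(c("ix", "iy"), pos = c(1e6, 2e6),
                  beta = c(0.25, 0.001), se = c(0.01, 0.01),
                  trait_name = "HF")
  expect_message(res <- step3_secondary_mr(sec, out, db), "without a cis")
  expect_equal(attr(res, "threshold"), 0.05 / 2)  # W had no instrument
  expect_equal(nrow(res), 2)
  expect_true(res$significant[res$trait == "X"])   # Wald z = 25/0.02
  expect_false(res$significant[res$trait == "Y"])
  expect_equal(res$theta[res$trait == "X"], 0.25 / 0.5)
})

test_that("secondary MR under the null rejects at about the nominal rate", {
  set.seed(606)
  n_rep <- 400
  rejections <- 0L
  out_beta <- rnorm(n_rep, 0, 0.01)
  for (i in seq_len(n_rep)) {
    wr <- wald_ratio(0.5, 0.01, out_beta[i], 0.01)
    if (wr$pvalue < 0.05) rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / n_rep - 0.05),
            3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("step 4 maps shared pathways to vertical, disjoint to horizontal", {
  pw <- data.frame(gene = c("APOH", "APOH", "TP53", "SHARED1", "SHARED2"),
                   pathway_id = c("pwA", "pwB", "pwC", "pwA", "pwB"))
  # disjoint pathway sets -> horizontal
  v1 <- step4_pathway_concordance("APOH", "TP53", pw)
  expect_equal(v1$flag, "horizontal")
  expect_false(v1$evidence$shared_pathway)
  # unannotated secondary -> unknown
  v2 <- step4_pathway_concordance("APOH", "ZNF259", pw)
  expect_equal(v2$flag, "unknown")
  expect_true(is.na(v2$evidence$shared_pathway))
  # shared pathway -> vertical
  v3 <- step4_pathway_concordance("APOH", "SHARED1", pw)
  expect_equal(v3$flag, "vertical")
  # precedence horizontal > unknown > vertical, order-invariant
  secs <- c("SHARED1", "ZNF259", "TP53")
  v4 <- step4_pathway_concordance("APOH", secs, pw)
  v5 <- step4_pathway_concordance("APOH", rev(secs), pw)
  expect_equal(v4$flag, "horizontal")
  expect_equal(v5$flag, v4$flag)
  expect_equal(step4_pathway_concordance("APOH", c("SHARED1", "ZNF259"),
                                         pw)$flag, "unknown")
  # no significant secondaries at all -> none
  expect_equal(step4_pathway_concordance("APOH", character(0), pw)$flag,
               "none")
})

test_that("directionality concordance respects declared polarity", {
  # protective effect on outcome, lowers a harmful factor: concordant
  expect_equal(direction_concordance(-0.2, -0.1, rf_harmful = TRUE),
               "concordant")
  # protective on outcome, lowers a protective factor: discordant
  expect_equal(direction_concordance(-0.2, -0.1, rf_harmful = FALSE),
               "discordant")
  expect_equal(direction_concordance(0.2, 0.1, TRUE), "concordant")
  expect_true(is.na(direction_concordance(0, 0.1, TRUE)))
  expect_equal(direction_concordance(c(0.2, -0.2), c(0.1, 0.1),
                                     c(TRUE, TRUE)),
               c("concordant", "discordant"))
})

test_that("modality follows the odds-ratio direction", {
  expect_equal(infer_modality(1.19), "inhibitor")
  expect_equal(infer_modality(0.82), "agonist")
  expect_equal(infer_modality(1), "none")
  expect_error(infer_modality(-1))
})

test_that("bucket regrouping is total and matches the published scheme", {
  expect_equal(regroup_buckets(1, "small_molecule"), "licensed")
  expect_equal(regroup_buckets(1, "other"), "licensed")
  expect_equal(regroup_buckets(2, "antibody"), "clinical")
  expect_equal(regroup_buckets(3, "other"), "clinical")
  expect_equal(regroup_buckets(4, "small_molecule"), "preclinical")
  expect_equal(regroup_buckets(5, "antibody"), "predicted")
  expect_equal(regroup_buckets(7, "small_molecule"), "predicted")
  expect_equal(regroup_buckets(7, "antibody"), "non_druggable")
  expect_equal(regroup_buckets(9, "small_molecule"), "non_druggable")
  expect_equal(regroup_buckets(NA, "other"), "non_druggable")
  expect_error(regroup_buckets(10, "other"), "bucket")
  # totality: exactly one group for every declared input
  for (b in c(NA, 1:9))
    for (m in c("antibody", "small_molecule", "other"))
      expect_length(regroup_buckets(b, m), 1)
})

test_that("the verdict requires both FDR pass and colocalization", {
  v1 <- assemble_verdict("APOC3", adjusted_p = 1.35e-3,
                         coloc_class = "strong")
  expect_true(v1$candidate)
  v2 <- assemble_verdict("ABO", adjusted_p = 8.99e-3,
                         coloc_class = "none")
  expect_false(v2$candidate)
  v3 <- assemble_verdict("X", adjusted_p = 0.2, coloc_class = "strong")
  expect_false(v3$candidate)
  v4 <- assemble_verdict("Y")
  expect_false(v4$candidate)
  expect_true(is.na(v4$adjusted_p))
})

test_that("the published 16-gene screen yields 10 suggestive and 3 strong", {
  demo <- demo_published_example(quiet = TRUE)
  expect_equal(demo$n_fdr_pass, 16)
  expect_equal(sum(demo$table$candidate), 10)
  strong <- sum(demo$table$coloc_class == "strong" & demo$table$candidate)
  expect_equal(strong, 3)
  expect_setequal(demo$table$gene[demo$table$coloc_class == "strong"],
                  c("ITIH4", "APOC3", "APOH"))
  # modality worked examples
  expect_equal(demo$table$modality[demo$table$gene == "APOC3"],
               "inhibitor")
  expect_equal(demo$table$modality[demo$table$gene == "NAE1"], "agonist")
})
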