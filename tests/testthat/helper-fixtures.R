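# Shared fixtures: in-code record builders and independent oracles.

# Canonical record data.frame; p-values computed from |beta/se| so the
# validator's consistency check stays silent.
mk_records <- function(variant_id, chrom = "1", pos = seq_along(variant_id),
                       effect_allele = "A", other_allele = "G",
                       eaf = 0.3, beta = 0.1, se = 0.02, n = NA_real_) {
  k <- length(variant_id)
  df <- data.frame(variant_id = variant_id,
                   chrom = rep_len(chrom, k), pos = rep_len(pos, k),
                   effect_allele = rep_len(effect_allele, k),
                   other_allele = rep_len(other_allele, k),
                   eaf = rep_len(eaf, k), beta = rep_len(beta, k),
                   se = rep_len(se, k), n = rep_len(n, k),
                   stringsAsFactors = FALSE)
  df$pvalue <- 2 * pnorm(-abs(df$beta / df$se))
  df
}

mk_study <- function(..., trait_name = "toy") {
  study_sumstats(mk_records(...), trait_name = trait_name)
}

# Brute-force colocalization oracle: explicit enumeration of every
# single-causal-variant configuration, in plain arithmetic (no log-space
# tricks), independent of coloc_abf's implementation path.
coloc_enum_oracle <- function(beta1, se1, beta2, se2,
                              priors = coloc_priors()) {
  n <- length(beta1)
  L1 <- exp(log_abf(beta1, se1, priors$w1))
  L2 <- exp(log_abf(beta2, se2, priors$w2))
  h1 <- 0; h2 <- 0; h3 <- 0; h4 <- 0
  for (i in seq_len(n)) {
    h1 <- h1 + priors$p1 * L1[i]
    h2 <- h2 + priors$p2 * L2[i]
    h4 <- h4 + priors$p12 * L1[i] * L2[i]
    for (j in seq_len(n))
      if (i != j) h3 <- h3 + priors$p1 * priors$p2 * L1[i] * L2[j]
  }
  w <- c(1, h1, h2, h3, h4)
  setNames(w / sum(w), c("pp_h0", "pp_h1", "pp_h2", "pp_h3", "pp_h4"))
}

# Random small coloc instance with moderate z-scores (safe for the
# non-log-space oracle).
random_coloc_instance <- function(n_snps, seed) {
  set.seed(seed)
  list(beta1 = rnorm(n_snps, 0, 0.15), se1 = runif(n_snps, 0.02, 0.1),
       beta2 = rnorm(n_snps, 0, 0.15), se2 = runif(n_snps, 0.02, 0.1))
}

# One simulated gene packaged for the pipeline: pQTL study for the gene,
# the outcome-side records for the same region, and its annotation row.
sim_gene <- function(gene, scenario, seed, chrom, effect_z = 10,
                     n_snps = 50, causal1 = NULL, causal2 = NULL) {
  ld <- make_ld(n_snps, 0.9)
  ld$variant_ids <- paste0(gene, "_", ld$variant_ids)
  s <- simulate_region(n_snps, ld = ld, scenario = scenario,
                       effect_z = effect_z, seed = seed, chrom = chrom,
                       causal1 = causal1, causal2 = causal2)
  s$trait1$trait_name <- gene
  list(gene = gene, pqtl = s$trait1, outcome_records = s$trait2$records,
       annot = data.frame(gene = gene, chrom = chrom,
                          start = 10100000L, end = 10120000L,
                          stringsAsFactors = FALSE),
       truth = s$truth)
}
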