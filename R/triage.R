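# Four-step horizontal-pleiotropy assessment, risk-factor directionality
# concordance, agonist/inhibitor modality inference, druggability-bucket
# regrouping, and the per-gene composite verdict.
#
# The pleiotropy logic: a cis instrument that also moves other proteins
# or transcripts is only a threat to the MR interpretation when those
# secondary traits (i) independently associate with the outcome and
# (ii) sit on a biological pathway unrelated to the primary protein
# (horizontal pleiotropy). Secondary traits on a shared pathway are
# vertical (downstream) and do not invalidate the estimate.

#' Step 1: secondary traits associated with the instruments
#'
#' Finds all (instrument, trait) pairs with association `p < p_max` in
#' the supplied proteome/transcriptome association tables, excluding the
#' primary protein itself.
#'
#' @param instrument_ids Character vector of instrument variant ids.
#' @param primary Primary protein/gene name (self-associations excluded).
#' @param protein_assoc data.frame of pQTL cross-associations with
#'   columns `variant_id`, `trait`, `pvalue`.
#' @param expression_assoc Optional eQTL table, same columns.
#' @param p_max Association threshold (default 5e-8).
#' @return data.frame with `source_instrument`, `trait`, `kind`
#'   (`"protein"`/`"expression"`), `assoc_p`.
#' @export
step1_secondary_traits <- function(instrument_ids, primary, protein_assoc,
                                   expression_assoc = NULL, p_max = 5e-8) {
  pull <- function(tab, kind) {
    if (is.null(tab) || nrow(tab) == 0L)
      return(data.frame(source_instrument = character(),
                        trait = character(), kind = character(),
                        assoc_p = numeric(), stringsAsFactors = FALSE))
    hit <- tab$variant_id %in% instrument_ids & tab$pvalue < p_max &
      tab$trait != primary
    data.frame(source_instrument = tab$variant_id[hit],
               trait = tab$trait[hit], kind = kind,
               assoc_p = tab$pvalue[hit], stringsAsFactors = FALSE)
  }
  out <- rbind(pull(protein_assoc, "protein"),
               pull(expression_assoc, "expression"))
  rownames(out) <- NULL
  out
}

#' Step 2: proximity of genes to known outcome risk loci
#'
#' A gene is "near" a known locus when any known lead position lies
#' within `window` bp of the gene region (boundary-inclusive).
#'
#' @param genes data.frame with `gene`, `chrom`, `start`, `end`.
#' @param known_loci data.frame with `chrom`, `pos`.
#' @param window Proximity window in bp (default 1 Mb).
#' @return Named logical vector per gene (`NA`, with a message, for genes
#'   lacking coordinates).
#' @export
step2_known_locus_proximity <- function(genes, known_loci, window = 1e6) {
  out <- vapply(seq_len(nrow(genes)), function(i) {
    if (is.na(genes$start[i]) || is.na(genes$end[i]) ||
        is.na(genes$chrom[i])) return(NA)
    same <- known_loci$chrom == genes$chrom[i]
    if (!any(same)) return(FALSE)
    any(known_loci$pos[same] >= genes$start[i] - window &
          known_loci$pos[same] <= genes$end[i] + window)
  }, logical(1))
  names(out) <- genes$gene
  if (anyNA(out))
    message(sum(is.na(out)), " gene(s) lack coordinates in step 2")
  out
}

#' Step 3: two-sample MR of secondary traits against the outcome
#'
#' Each unique secondary trait is instrumented by its own lead cis
#' variant from `instrument_db` (pQTL preferred over eQTL when both are
#' present) and tested against the outcome by Wald ratio. Traits without
#' any cis instrument are excluded and logged. Significance uses a
#' Bonferroni threshold `0.05 / n`, with `n` the number of unique
#' secondary traits that had an instrument.
#'
#' @param secondary data.frame from [step1_secondary_traits()].
#' @param outcome [study_sumstats()] for the outcome.
#' @param instrument_db data.frame of lead cis instruments keyed by
#'   trait: columns `trait`, `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `kind`
#'   (`"protein"`/`"expression"`).
#' @param alpha Family-wise level before correction (default 0.05).
#' @return data.frame with one row per tested trait: `trait`,
#'   `variant_id`, `theta`, `se`, `pvalue`, `significant`; attribute
#'   `"threshold"` holds the Bonferroni cutoff.
#' @export
step3_secondary_mr <- function(secondary, outcome, instrument_db,
                               alpha = 0.05) {
  traits <- unique(secondary$trait)
  # prefer protein instruments over expression ones
  db <- instrument_db[order(match(instrument_db$kind,
                                  c("protein", "expression"))), ,
                      drop = FALSE]
  db <- db[!duplicated(db$trait), , drop = FALSE]
  have <- traits[traits %in% db$trait]
  dropped <- setdiff(traits, have)
  if (length(dropped))
    message(length(dropped), " secondary trait(s) without a cis instrument")
  n <- length(have)
  thr <- if (n > 0) alpha / n else NA_real_
  rows <- lapply(have, function(tr) {
    ins <- db[db$trait == tr, , drop = FALSE]
    expo <- study_sumstats(
      data.frame(variant_id = ins$variant_id, chrom = NA_character_,
                 pos = NA_integer_, effect_allele = ins$effect_allele,
                 other_allele = ins$other_allele, eaf = ins$eaf,
                 beta = ins$beta, se = ins$se, pvalue = ins$pvalue,
                 n = NA_real_, stringsAsFactors = FALSE),
      trait_name = tr, validate = FALSE)
    h <- harmonize_pair(expo, outcome)
    if (nrow(h) == 0L) return(NULL)
    wr <- wald_ratio(h$beta_a, h$se_a, h$beta_b, h$se_b)
    data.frame(trait = tr, variant_id = h$variant_id, theta = wr$theta,
               se = wr$se, pvalue = wr$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trait = character(), variant_id = character(),
                      theta = numeric(), se = numeric(),
                      pvalue = numeric(), stringsAsFactors = FALSE)
  out$significant <- out$pvalue < thr
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Step 4: pathway concordance and the pleiotropy verdict
#'
#' Maps each outcome-significant secondary gene to its pathways and
#' compares against the primary gene's pathways: sharing at least one
#' pathway is vertical-pleiotropy evidence; sharing none (both genes
#' annotated) is horizontal; a missing annotation on either side is
#' unknown. The gene-level flag takes the most conservative evidence
#' present: horizontal > unknown > vertical > none.
#'
#' @param primary_gene Primary gene symbol.
#' @param significant_secondary Character vector of secondary genes that
#'   passed step 3.
#' @param pathways data.frame with columns `gene`, `pathway_id`.
#' @return A `pleiotropy_verdict`: list with `gene`, `flag` (one of
#'   `"none"`, `"vertical"`, `"horizontal"`, `"unknown"`) and `evidence`
#'   (data.frame `trait`, `shared_pathway` with `NA` for unannotated).
#' @export
step4_pathway_concordance <- function(primary_gene, significant_secondary,
                                      pathways) {
  primary_pw <- pathways$pathway_id[pathways$gene == primary_gene]
  shared <- vapply(significant_secondary, function(g) {
    sec_pw <- pathways$pathway_id[pathways$gene == g]
    if (length(sec_pw) == 0L || length(primary_pw) == 0L) return(NA)
    length(intersect(primary_pw, sec_pw)) > 0
  }, logical(1))
  evidence <- data.frame(trait = significant_secondary,
                         shared_pathway = unname(shared),
                         stringsAsFactors = FALSE)
  flag <- if (any(!shared, na.rm = TRUE)) "horizontal"
          else if (anyNA(shared)) "unknown"
          else if (any(shared, na.rm = TRUE)) "vertical"
          else "none"
  structure(list(gene = primary_gene, flag = flag, evidence = evidence),
            class = "pleiotropy_verdict")
}

#' Directionality concordance with a risk factor
#'
#' For a harmful risk factor, an effect on the outcome is concordant when
#' the risk-factor association has the same sign; for a protective factor
#' the expected sign is reversed. Zero betas return `NA` (excluded from
#' concordance tallies).
#'
#' @param hf_beta MR effect on the outcome.
#' @param rf_beta MR effect on the risk factor.
#' @param rf_harmful Is the risk factor deleterious for the outcome?
#'   Declared, not inferred: polarity can be contestable (e.g. HDL-C).
#' @return `"concordant"`, `"discordant"`, or `NA` (vectorized).
#' @export
direction_concordance <- function(hf_beta, rf_beta, rf_harmful) {
  expected <- sign(rf_beta) * ifelse(rf_harmful, 1, -1)
  out <- ifelse(sign(hf_beta) == expected, "concordant", "discordant")
  out[hf_beta == 0 | rf_beta == 0] <- NA_character_
  out
}

#' Infer the therapeutic modality from the MR odds ratio
#'
#' OR > 1 (more protein, more risk) suggests an inhibitor; OR < 1
#' suggests an agonist; OR = 1 is uninformative.
#'
#' @param or_point MR odds ratio per unit increase in protein level.
#' @return `"inhibitor"`, `"agonist"` or `"none"` (vectorized).
#' @export
infer_modality <- function(or_point) {
  stopifnot(all(or_point > 0))
  ifelse(or_point > 1, "inhibitor",
         ifelse(or_point < 1, "agonist", "none"))
}

#' Regroup druggability tractability buckets
#'
#' Collapses the nine-tier tractability buckets into four groups:
#' bucket 1 (any modality) is `licensed`; buckets 2-3 are `clinical`;
#' buckets 4-5 are `preclinical` for small molecules and `predicted` for
#' antibodies; buckets 6-8 are `predicted` for small molecules; bucket 9,
#' a missing bucket, or any remaining combination is `non_druggable`.
#'
#' @param bucket Integer 1-9 or `NA` (vectorized).
#' @param modality_class `"antibody"`, `"small_molecule"` or `"other"`.
#' @return Character vector: `licensed`, `clinical`, `preclinical`,
#'   `predicted` or `non_druggable`.
#' @export
regroup_buckets <- function(bucket, modality_class = "other") {
  if (any(!is.na(bucket) & (bucket < 1 | bucket > 9)))
    stop("bucket must be in 1..9 or NA")
  n <- max(length(bucket), length(modality_class))
  bucket <- rep_len(bucket, n)
  modality_class <- rep_len(modality_class, n)
  out <- rep("non_druggable", n)
  out[!is.na(bucket) & bucket == 1] <- "licensed"
  out[!is.na(bucket) & bucket %in% 2:3] <- "clinical"
  out[!is.na(bucket) & bucket %in% 4:5 &
        modality_class == "small_molecule"] <- "preclinical"
  out[!is.na(bucket) & bucket %in% 4:5 &
        modality_class == "antibody"] <- "predicted"
  out[!is.na(bucket) & bucket %in% 6:8 &
        modality_class == "small_molecule"] <- "predicted"
  out
}

#' Assemble the per-gene triage verdict
#'
#' A gene is a candidate iff its FDR-adjusted MR p-value is below
#' `fdr_level` and its colocalization class is `suggestive` or `strong`.
#' Missing components are carried as explicit `NA` markers, never
#' defaulted.
#'
#' @param gene Gene symbol.
#' @param mr One-row [mr_estimate()] result (or `NULL`).
#' @param adjusted_p BH-adjusted MR p-value.
#' @param coloc_class From [classify_coloc()].
#' @param near_known_locus Logical from [step2_known_locus_proximity()].
#' @param pleiotropy_flag From [step4_pathway_concordance()].
#' @param modality From [infer_modality()].
#' @param druggability_group From [regroup_buckets()].
#' @param fdr_level FDR threshold (default 0.05).
#' @return One-row data.frame (`triage_verdict`).
#' @export
assemble_verdict <- function(gene, mr = NULL, adjusted_p = NA_real_,
                             coloc_class = NA_character_,
                             near_known_locus = NA,
                             pleiotropy_flag = NA_character_,
                             modality = NA_character_,
                             druggability_group = NA_character_,
                             fdr_level = 0.05) {
  mr_fdr_pass <- !is.na(adjusted_p) & adjusted_p < fdr_level
  candidate <- mr_fdr_pass & !is.na(coloc_class) &
    coloc_class %in% c("suggestive", "strong")
  data.frame(gene = gene,
             n_snps = if (!is.null(mr)) mr$n_snps else NA_integer_,
             theta = if (!is.null(mr)) mr$theta else NA_real_,
             or_point = if (!is.null(mr)) mr$or_point else NA_real_,
             pvalue = if (!is.null(mr)) mr$pvalue else NA_real_,
             adjusted_p = adjusted_p, mr_fdr_pass = mr_fdr_pass,
             coloc_class = coloc_class,
             near_known_locus = near_known_locus,
             pleiotropy_flag = pleiotropy_flag,
             modality = modality,
             druggability_group = druggability_group,
             candidate = candidate, stringsAsFactors = FALSE)
}
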