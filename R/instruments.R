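# Cis-pQTL instrument selection and exposure-outcome pairing.

#' Define a protein-coding gene region
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome (character).
#' @param start,end 1-based inclusive gene boundaries (GRCh37).
#' @return A `gene_region` object.
#' @export
gene_region <- function(gene, chrom, start, end) {
  stopifnot(start <= end, start >= 1)
  structure(list(gene = gene, chrom = as.character(chrom),
                 start = start, end = end),
            class = "gene_region")
}

#' Select cis-pQTL instruments for a gene
#'
#' Candidate instruments are pQTL associations on the gene's chromosome
#' within `[start - window, end + window]` with `pvalue < p_max`. The
#' candidates are thinned to an approximately independent set by greedy
#' LD clumping in ascending p-value order: a candidate is discarded when
#' its `r^2` with a retained instrument is `>= r2_independent`; without an
#' LD matrix a distance rule (`<= distance_independent` bp) is the
#' fallback.
#'
#' @param pqtl [study_sumstats()] of pQTL associations for one protein.
#' @param region [gene_region()] of the encoding gene.
#' @param window Cis window in bp around the gene boundaries (default 1 Mb).
#' @param p_max Instrument p-value threshold (default 5e-8).
#' @param ld Optional LD object (list with `variant_ids`, `r`).
#' @param r2_independent Clumping threshold (default 0.1).
#' @param distance_independent Distance fallback in bp (default 500 kb).
#' @return An `instrument_set`: list with `gene`, `protein`, `data` (one
#'   row per instrument: `variant_id, chrom, pos, effect_allele,
#'   other_allele, eaf, beta_exposure, se_exposure, pvalue_exposure`,
#'   ordered by ascending p), and `ld` (subset LD or NULL). Zero
#'   candidates give an empty set with attribute `"reason"`.
#' @export
select_cis_instruments <- function(pqtl, region, window = 1e6,
                                   p_max = 5e-8, ld = NULL,
                                   r2_independent = 0.1,
                                   distance_independent = 5e5) {
  stopifnot(inherits(pqtl, "study_sumstats"), inherits(region, "gene_region"),
            window > 0)
  r <- pqtl$records
  lo <- max(1, region$start - window)
  hi <- region$end + window
  cand <- r[r$chrom == region$chrom & !is.na(r$pos) &
              r$pos >= lo & r$pos <= hi & r$pvalue < p_max, , drop = FALSE]
  cand <- cand[order(cand$pvalue, cand$pos), , drop = FALSE]

  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    independent <- TRUE
    for (j in kept) {
      if (!is.null(ld)) {
        ii <- match(cand$variant_id[i], ld$variant_ids)
        jj <- match(cand$variant_id[j], ld$variant_ids)
        if (!is.na(ii) && !is.na(jj) &&
            ld$r[ii, jj]^2 >= r2_independent) {
          independent <- FALSE; break
        }
      } else if (abs(cand$pos[i] - cand$pos[j]) <= distance_independent) {
        independent <- FALSE; break
      }
    }
    if (independent) kept <- c(kept, i)
  }
  cand <- cand[kept, , drop = FALSE]

  dat <- data.frame(variant_id = cand$variant_id, chrom = cand$chrom,
                    pos = cand$pos, effect_allele = cand$effect_allele,
                    other_allele = cand$other_allele, eaf = cand$eaf,
                    beta_exposure = cand$beta, se_exposure = cand$se,
                    pvalue_exposure = cand$pvalue, stringsAsFactors = FALSE)
  rownames(dat) <- NULL
  sub_ld <- NULL
  if (!is.null(ld) && nrow(dat)) {
    idx <- match(dat$variant_id, ld$variant_ids)
    if (!anyNA(idx))
      sub_ld <- list(variant_ids = dat$variant_id,
                     r = ld$r[idx, idx, drop = FALSE])
  }
  out <- structure(list(gene = region$gene, protein = pqtl$trait_name,
                        data = dat, ld = sub_ld),
                   class = "instrument_set")
  if (nrow(dat) == 0L) {
    message("gene ", region$gene, ": no cis instruments (excluded from MR)")
    attr(out, "reason") <- "no_cis_instruments"
  }
  out
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set> ", x$gene, ": ", nrow(x$data), " instrument(s)\n",
      sep = "")
  invisible(x)
}

#' Attach outcome associations to an instrument set
#'
#' Joins outcome effects to the exposure instruments after allele
#' harmonization (outcome betas are negated for swapped alleles; the
#' exposure orientation is preserved). Instruments absent from the
#' outcome are dropped and logged; no proxy lookup is attempted.
#'
#' @param inst An `instrument_set` (exposure side only).
#' @param outcome [study_sumstats()] for the outcome trait.
#' @param drop_ambiguous_maf Passed to [harmonize_pair()].
#' @return The `instrument_set` with `data` gaining
#'   `beta_outcome, se_outcome, pvalue_outcome`. An all-missing join gives
#'   an empty set with attribute `"reason"`.
#' @export
attach_outcome <- function(inst, outcome, drop_ambiguous_maf = 0.08) {
  stopifnot(inherits(inst, "instrument_set"),
            inherits(outcome, "study_sumstats"))
  d <- inst$data
  if (nrow(d) == 0L) return(inst)
  expo <- study_sumstats(
    data.frame(variant_id = d$variant_id, chrom = d$chrom, pos = d$pos,
               effect_allele = d$effect_allele,
               other_allele = d$other_allele, eaf = d$eaf,
               beta = d$beta_exposure, se = d$se_exposure,
               pvalue = d$pvalue_exposure, n = NA_real_,
               stringsAsFactors = FALSE),
    trait_name = inst$protein, validate = FALSE)
  h <- harmonize_pair(expo, outcome, drop_ambiguous_maf = drop_ambiguous_maf)
  n_lost <- nrow(d) - nrow(h)
  if (n_lost > 0)
    message("gene ", inst$gene, ": ", n_lost,
            " instrument(s) not recovered in outcome")
  idx <- match(h$variant_id, d$variant_id)
  dat <- d[idx, , drop = FALSE]
  dat$beta_outcome <- h$beta_b
  dat$se_outcome <- h$se_b
  dat$pvalue_outcome <- h$pvalue_b
  rownames(dat) <- NULL
  inst$data <- dat
  if (!is.null(inst$ld) && nrow(dat)) {
    jj <- match(dat$variant_id, inst$ld$variant_ids)
    inst$ld <- list(variant_ids = dat$variant_id,
                    r = inst$ld$r[jj, jj, drop = FALSE])
  }
  if (nrow(dat) == 0L) {
    message("gene ", inst$gene, ": all instruments missing from outcome")
    attr(inst, "reason") <- "no_outcome_overlap"
  }
  inst
}
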