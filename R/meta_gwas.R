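# Fixed-effects IVW meta-analysis of two harmonized GWAS, MAF filtering,
# significance calling, greedy clumping and novelty flagging.

#' Remove rare variants by minor allele frequency
#'
#' Drops records whose minor allele frequency `min(eaf, 1 - eaf)` is
#' strictly below `min_maf`. Records with missing `eaf` are retained and
#' counted in a message.
#'
#' @param s A [study_sumstats()] object.
#' @param min_maf Minimum minor allele frequency; default 0.005 (0.5%).
#' @return The filtered `study_sumstats` object.
#' @export
maf_filter <- function(s, min_maf = 0.005) {
  stopifnot(inherits(s, "study_sumstats"))
  maf <- pmin(s$records$eaf, 1 - s$records$eaf)
  n_missing <- sum(is.na(maf))
  if (n_missing > 0)
    message(n_missing, " record(s) with missing eaf retained by maf_filter")
  keep <- is.na(maf) | maf >= min_maf
  s$records <- s$records[keep, , drop = FALSE]
  rownames(s$records) <- NULL
  s
}

#' Fixed-effects inverse-variance-weighted meta-analysis of two studies
#'
#' Pools per-variant effects with weights `1/se^2`:
#' `beta = (b_a/se_a^2 + b_b/se_b^2) / (1/se_a^2 + 1/se_b^2)` and
#' `se = (1/se_a^2 + 1/se_b^2)^(-1/2)`; the p-value is the two-sided
#' normal tail of `beta/se`.
#'
#' @param beta_a,se_a,beta_b,se_b Numeric vectors of per-variant effects
#'   and standard errors, already harmonized to a shared effect allele.
#' @param variant_id Optional ids used in error messages.
#' @return data.frame with columns `beta`, `se`, `z`, `pvalue`,
#'   `k_studies` (= 2).
#' @export
ivw_meta <- function(beta_a, se_a, beta_b, se_b, variant_id = NULL) {
  bad <- which(se_a <= 0 | se_b <= 0 | is.na(se_a) | is.na(se_b))
  if (length(bad)) {
    id <- if (!is.null(variant_id)) variant_id[bad[1]] else bad[1]
    stop("non-positive standard error at variant ", id)
  }
  w_a <- 1 / se_a^2
  w_b <- 1 / se_b^2
  beta <- (beta_a * w_a + beta_b * w_b) / (w_a + w_b)
  se <- 1 / sqrt(w_a + w_b)
  z <- beta / se
  data.frame(beta = beta, se = se, z = z, pvalue = z_pvalue(beta, se),
             k_studies = 2L)
}

#' Meta-analyze two harmonized studies into a pooled study
#'
#' Convenience wrapper: harmonizes `a` and `b`, pools shared variants with
#' [ivw_meta()], and returns the pooled associations as a new
#' `study_sumstats` in `a`'s allele orientation.
#'
#' @inheritParams harmonize_pair
#' @param trait_name Name for the pooled study.
#' @return A [study_sumstats()] object of pooled associations.
#' @export
meta_analyze <- function(a, b, drop_ambiguous_maf = 0.08,
                         trait_name = paste0(a$trait_name, "+", b$trait_name)) {
  h <- harmonize_pair(a, b, drop_ambiguous_maf = drop_ambiguous_maf)
  m <- ivw_meta(h$beta_a, h$se_a, h$beta_b, h$se_b, h$variant_id)
  recs <- data.frame(variant_id = h$variant_id, chrom = h$chrom, pos = h$pos,
                     effect_allele = h$effect_allele,
                     other_allele = h$other_allele,
                     eaf = ifelse(is.na(h$eaf_a), h$eaf_b,
                                  ifelse(is.na(h$eaf_b), h$eaf_a,
                                         (h$eaf_a + h$eaf_b) / 2)),
                     beta = m$beta, se = m$se, pvalue = m$pvalue,
                     n = ifelse(is.na(h$n_a) | is.na(h$n_b), NA_real_,
                                h$n_a + h$n_b),
                     stringsAsFactors = FALSE)
  n_cases <- a$n_cases + b$n_cases
  n_controls <- a$n_controls + b$n_controls
  if (a$trait_type == "case_control" && b$trait_type == "case_control")
    study_sumstats(recs, trait_name, "case_control",
                   n_cases = n_cases, n_controls = n_controls,
                   validate = FALSE)
  else
    study_sumstats(recs, trait_name, "quantitative", validate = FALSE)
}

#' Call lead variants by greedy p-ordered clumping and flag novelty
#'
#' Candidates passing `p_threshold` are visited in ascending p-value order
#' (ties broken by ascending position); a candidate is absorbed into an
#' already-selected lead when its LD with that lead is `r^2 >= r2_max`
#' (when an LD matrix is supplied) or, as a distance fallback, when it
#' lies within `novelty_window` of the lead on the same chromosome. A lead
#' is novel iff its distance to every known lead exceeds `novelty_window`.
#'
#' @param meta data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `pvalue` (extra columns are carried through).
#' @param ld Optional [make_ld()]-style object: list with `variant_ids`
#'   and correlation matrix `r` covering (at least) the candidates.
#' @param known_leads data.frame of previously reported leads with
#'   columns `chrom` and `pos`; may be empty.
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param r2_max Leads must be mutually separated at `r^2 <` this value
#'   (default 0.6).
#' @param novelty_window Distance in bp (default 500 kb) used both for the
#'   distance-clumping fallback and the novelty rule.
#' @return data.frame of leads with the input columns plus `is_novel` and
#'   `nearest_known_distance` (Inf when no known lead shares the
#'   chromosome).
#' @export
call_leads <- function(meta, ld = NULL,
                       known_leads = data.frame(chrom = character(),
                                                pos = integer()),
                       p_threshold = 5e-8, r2_max = 0.6,
                       novelty_window = 5e5) {
  cand <- meta[meta$pvalue < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$pvalue, cand$pos), , drop = FALSE]
  lead_idx <- integer(0)
  for (i in seq_len(nrow(cand))) {
    absorbed <- FALSE
    for (j in lead_idx) {
      same_chr <- cand$chrom[i] == cand$chrom[j]
      if (!is.null(ld)) {
        ii <- match(cand$variant_id[i], ld$variant_ids)
        jj <- match(cand$variant_id[j], ld$variant_ids)
        if (!is.na(ii) && !is.na(jj) && ld$r[ii, jj]^2 >= r2_max) {
          absorbed <- TRUE; break
        }
      } else if (same_chr &&
                 abs(cand$pos[i] - cand$pos[j]) <= novelty_window) {
        absorbed <- TRUE; break
      }
    }
    if (!absorbed) lead_idx <- c(lead_idx, i)
  }
  leads <- cand[lead_idx, , drop = FALSE]
  nearest <- vapply(seq_len(nrow(leads)), function(i) {
    same <- known_leads$chrom == leads$chrom[i]
    if (!any(same)) return(Inf)
    min(abs(known_leads$pos[same] - leads$pos[i]))
  }, numeric(1))
  leads$is_novel <- nearest > novelty_window
  leads$nearest_known_distance <- nearest
  rownames(leads) <- NULL
  leads
}
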