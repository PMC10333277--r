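# Configuration-driven orchestration: instrument selection -> MR -> FDR
# -> colocalization -> triage over many genes, with a per-gene exclusion
# trail and a deterministic, byte-stable report.

#' Pipeline configuration
#'
#' Every threshold of the screen is a named key with the screen's
#' canonical default, so any deviation is explicit in the config.
#'
#' @param instrument_p Cis-instrument p-value threshold (default 5e-8).
#' @param cis_window Cis window in bp around gene boundaries (default 1 Mb).
#' @param r2_independent LD-clumping threshold for instrument
#'   independence (default 0.1).
#' @param fdr FDR level for MR significance (default 0.05).
#' @param m_total Total tests for the BH correction; `NULL` uses the
#'   number of genes that reached MR.
#' @param priors [coloc_priors()] for colocalization.
#' @param pph4_suggestive,pph4_strong Colocalization class thresholds
#'   (defaults 0.5, 0.8).
#' @param risk_factor_p MR p-value threshold for risk-factor follow-up
#'   (default 1e-4).
#' @param drop_ambiguous_maf Palindromic ambiguity window half-width
#'   (default 0.08).
#' @param seed Integer seed recorded with the run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(instrument_p = 5e-8, cis_window = 1e6,
                            r2_independent = 0.1, fdr = 0.05,
                            m_total = NULL, priors = coloc_priors(),
                            pph4_suggestive = 0.5, pph4_strong = 0.8,
                            risk_factor_p = 1e-4, drop_ambiguous_maf = 0.08,
                            seed = 1L) {
  stopifnot(instrument_p > 0, cis_window > 0, fdr > 0,
            pph4_suggestive > 0, pph4_strong > 0, risk_factor_p > 0)
  structure(list(instrument_p = instrument_p, cis_window = cis_window,
                 r2_independent = r2_independent, fdr = fdr,
                 m_total = m_total, priors = priors,
                 pph4_suggestive = pph4_suggestive,
                 pph4_strong = pph4_strong, risk_factor_p = risk_factor_p,
                 drop_ambiguous_maf = drop_ambiguous_maf,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the cis-MR + colocalization screen over many genes
#'
#' For each gene: selects cis instruments from its pQTL study, attaches
#' outcome effects, estimates the causal effect (Wald ratio / IVW with Q
#' and Egger diagnostics), then BH-adjusts MR p-values across genes, runs
#' approximate-Bayes-factor colocalization over the shared cis-region
#' variants, classifies the evidence, and assembles per-gene verdicts.
#' Genes excluded at any stage (no instruments, no outcome overlap) are
#' reported with the reason; per-gene failures never abort the run. The
#' run is deterministic given the config and inputs.
#'
#' @param outcome [study_sumstats()] for the outcome trait.
#' @param pqtl_list Named list of [study_sumstats()], one per gene, with
#'   pQTL associations for that gene's protein.
#' @param genes data.frame with `gene`, `chrom`, `start`, `end`.
#' @param config A [pipeline_config()].
#' @param ld_list Optional named list of LD objects per gene.
#' @param known_loci Optional data.frame (`chrom`, `pos`) of known
#'   outcome risk loci for the proximity column.
#' @param druggability Optional data.frame (`gene`, `bucket`,
#'   `modality_class`).
#' @return list with `verdicts` (one row per gene with instruments),
#'   `mr`, `coloc`, `exclusions` (`gene`, `reason`) and `log` (filter
#'   counts). `|verdicts| + |exclusions|` equals the number of input
#'   genes.
#' @export
run_pipeline <- function(outcome, pqtl_list, genes,
                         config = pipeline_config(), ld_list = NULL,
                         known_loci = NULL, druggability = NULL) {
  stopifnot(inherits(outcome, "study_sumstats"),
            inherits(config, "pipeline_config"))
  exclusions <- data.frame(gene = character(), reason = character(),
                           stringsAsFactors = FALSE)
  mr_rows <- list()
  coloc_rows <- list()
  insts <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene[i]
    res <- tryCatch({
      pq <- pqtl_list[[g]]
      if (is.null(pq)) stop("no pQTL study supplied")
      region <- gene_region(g, genes$chrom[i], genes$start[i], genes$end[i])
      inst <- select_cis_instruments(pq, region,
                                     window = config$cis_window,
                                     p_max = config$instrument_p,
                                     ld = ld_list[[g]],
                                     r2_independent = config$r2_independent)
      if (nrow(inst$data) == 0L) stop("no_cis_instruments")
      inst <- attach_outcome(inst, outcome,
                             drop_ambiguous_maf = config$drop_ambiguous_maf)
      if (nrow(inst$data) == 0L) stop("no_outcome_overlap")
      list(inst = inst, mr = mr_estimate(inst))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      exclusions <- rbind(exclusions,
                          data.frame(gene = g, reason = res,
                                     stringsAsFactors = FALSE))
      next
    }
    insts[[g]] <- res$inst
    mr_rows[[g]] <- res$mr

    # Colocalization over every cis-region variant shared with the
    # outcome, using marginal statistics.
    cl <- tryCatch({
      pq <- pqtl_list[[g]]
      region_rec <- pq$records[pq$records$chrom == genes$chrom[i] &
                                 pq$records$pos >= genes$start[i] -
                                   config$cis_window &
                                 pq$records$pos <= genes$end[i] +
                                   config$cis_window, , drop = FALSE]
      pq_region <- pq
      pq_region$records <- region_rec
      h <- harmonize_pair(pq_region, outcome,
                          drop_ambiguous_maf = config$drop_ambiguous_maf)
      if (nrow(h) == 0L) stop("no shared region variants")
      pri <- config$priors
      pri$w2 <- prior_effect_variance(outcome$trait_type)
      pri$w1 <- prior_effect_variance(pq$trait_type)
      res_cl <- coloc_abf(h$beta_a, h$se_a, h$beta_b, h$se_b, priors = pri)
      data.frame(gene = g, n_snps_region = res_cl$n_snps,
                 t(res_cl$pp),
                 coloc_class = classify_coloc(res_cl,
                                              config$pph4_suggestive,
                                              config$pph4_strong),
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(gene = g, n_snps_region = NA_integer_, pp_h0 = NA_real_,
                 pp_h1 = NA_real_, pp_h2 = NA_real_, pp_h3 = NA_real_,
                 pp_h4 = NA_real_, coloc_class = NA_character_,
                 stringsAsFactors = FALSE))
    coloc_rows[[g]] <- cl
  }

  mr <- do.call(rbind, mr_rows)
  coloc <- do.call(rbind, coloc_rows)
  verdicts <- NULL
  if (!is.null(mr) && nrow(mr) > 0) {
    m_total <- config$m_total %||% nrow(mr)
    adj <- bh_adjust(mr$pvalue, m_total = m_total)
    mr$adjusted_p <- adj$adjusted
    near <- if (!is.null(known_loci))
      step2_known_locus_proximity(genes[genes$gene %in% mr$gene, ,
                                        drop = FALSE], known_loci)
    else NULL
    verdicts <- do.call(rbind, lapply(seq_len(nrow(mr)), function(j) {
      g <- mr$gene[j]
      drug <- NA_character_
      if (!is.null(druggability) && g %in% druggability$gene) {
        dr <- druggability[druggability$gene == g, , drop = FALSE][1, ]
        drug <- regroup_buckets(dr$bucket, dr$modality_class)
      }
      assemble_verdict(g, mr = mr[j, , drop = FALSE],
                       adjusted_p = mr$adjusted_p[j],
                       coloc_class = coloc$coloc_class[coloc$gene == g],
                       near_known_locus = if (!is.null(near)) near[[g]] else NA,
                       modality = infer_modality(mr$or_point[j]),
                       druggability_group = drug,
                       fdr_level = config$fdr)
    }))
    rownames(verdicts) <- NULL
  } else {
    verdicts <- assemble_verdict("placeholder")[0, , drop = FALSE]
  }
  rownames(exclusions) <- NULL
  list(verdicts = verdicts, mr = mr, coloc = coloc,
       exclusions = exclusions,
       log = list(n_genes = nrow(genes),
                  n_with_instruments = length(insts),
                  n_excluded = nrow(exclusions),
                  m_total = if (!is.null(mr)) config$m_total %||% nrow(mr)
                            else NA_integer_,
                  seed = config$seed))
}

#' Write the verdict report
#'
#' Emits a tab-delimited table and a JSON sidecar with the run log.
#'
#' @param result Output of [run_pipeline()].
#' @param path Base path; `<path>.tsv` and `<path>.json` are written.
#' @return Invisibly, the two file paths.
#' @export
write_verdicts <- function(result, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(result$verdicts, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(verdicts = result$verdicts,
                            exclusions = result$exclusions,
                            log = result$log),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, json))
}
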