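# Simulation of paired GWAS/pQTL summary statistics with known ground
# truth. Rather than simulating individual-level genotypes, z-scores are
# drawn directly from the standard summary-statistic model
#   z | lambda ~ N(R lambda, R)
# where R is the LD correlation matrix and lambda carries the
# non-centrality of the causal variant(s). Reported effects are
# beta = z / sqrt(n) with se = 1 / sqrt(n), sufficient for every
# downstream consumer (harmonization, MR, colocalization).

#' First-order autoregressive LD matrix
#'
#' `r[j, k] = rho^|j - k|`, symmetric positive-definite for `|rho| < 1`.
#'
#' @param n_snps Number of variants (>= 1).
#' @param rho Adjacent-variant correlation, `|rho| < 1`.
#' @return list with `variant_ids` and the correlation matrix `r`.
#' @export
make_ld <- function(n_snps, rho) {
  stopifnot(n_snps >= 1)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  idx <- seq_len(n_snps)
  r <- rho^abs(outer(idx, idx, "-"))
  list(variant_ids = paste0("rs", 1000L + idx), r = r)
}

# Draw one multivariate-normal z vector with mean R lambda and
# covariance R, using the upper Cholesky factor of R.
draw_z <- function(chol_r, r, lambda) {
  mu <- as.vector(r %*% lambda)
  mu + as.vector(crossprod(chol_r, stats::rnorm(nrow(r))))
}

# Allele pairs used by the simulator; palindromic pairs are injected
# only on request (harmonization edge-case tests).
.allele_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                        ncol = 2, byrow = TRUE)
.palindromic_pairs <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)

#' Simulate a pair of regional association studies under a causal scenario
#'
#' Generates summary statistics for two traits over one LD region under
#' one of the colocalization configurations: `H0` (neither trait has a
#' causal variant), `H1`/`H2` (one trait only), `H3` (distinct causal
#' variants), `H4` (one shared causal variant). Causal positions default
#' to the middle of the region (shared) and to the 1/4 and 3/4 positions
#' (distinct), keeping the LD between distinct causal variants low.
#'
#' @param n_snps Number of variants.
#' @param ld LD object from [make_ld()] (defaults to AR(1) with
#'   `rho = 0.9`).
#' @param scenario One of `"H0" ... "H4"`.
#' @param effect_z Non-centrality (expected |z|) at the causal variant.
#' @param n1,n2 Sample sizes of the two studies.
#' @param seed Integer seed; the call consumes a single seeded stream and
#'   is bit-reproducible.
#' @param causal1,causal2 Optional causal indices overriding the
#'   defaults.
#' @param palindromic_frac Fraction of variants given palindromic (A/T or
#'   C/G) alleles, for harmonization edge-case testing (default 0).
#' @param chrom,pos_start,pos_step Genomic placement of the region
#'   (variants are evenly spaced), so several simulated regions can be
#'   composed into one genome-wide study.
#' @return list with `trait1`, `trait2` ([study_sumstats()]), `truth`
#'   (scenario, causal indices, `effect_z`, seed) and `ld`.
#' @export
simulate_region <- function(n_snps = 50, ld = make_ld(n_snps, 0.9),
                            scenario = c("H4", "H0", "H1", "H2", "H3"),
                            effect_z = 8, n1 = 10000, n2 = 50000,
                            seed = 1, causal1 = NULL, causal2 = NULL,
                            palindromic_frac = 0, chrom = "1",
                            pos_start = 10000000L, pos_step = 5000L) {
  scenario <- match.arg(scenario)
  stopifnot(effect_z >= 0, nrow(ld$r) == n_snps)
  set.seed(seed)
  ch <- tryCatch(chol(ld$r),
                 error = function(e) stop("singular LD matrix; jitter the ",
                                          "diagonal or lower |rho|"))
  mid <- max(1L, round(n_snps / 2))
  q1 <- max(1L, round(n_snps / 4))
  q3 <- min(n_snps, round(3 * n_snps / 4))
  causal <- switch(scenario,
                   H0 = list(NULL, NULL),
                   H1 = list(causal1 %||% mid, NULL),
                   H2 = list(NULL, causal2 %||% mid),
                   H3 = list(causal1 %||% q1, causal2 %||% q3),
                   H4 = {
                     c1 <- causal1 %||% mid
                     list(c1, causal2 %||% c1)
                   })
  if (scenario == "H4" && !identical(causal[[1]], causal[[2]]))
    stop("H4 requires a shared causal position")
  if (scenario == "H3" && identical(causal[[1]], causal[[2]]))
    stop("H3 requires distinct causal positions")
  lam <- function(idx) {
    l <- numeric(n_snps)
    if (!is.null(idx)) l[idx] <- effect_z
    l
  }
  z1 <- draw_z(ch, ld$r, lam(causal[[1]]))
  z2 <- draw_z(ch, ld$r, lam(causal[[2]]))
  eaf <- stats::runif(n_snps, 0.05, 0.95)
  pal <- stats::runif(n_snps) < palindromic_frac
  pair_idx <- sample.int(nrow(.allele_pairs), n_snps, replace = TRUE)
  pal_idx <- sample.int(nrow(.palindromic_pairs), n_snps, replace = TRUE)
  ea <- ifelse(pal, .palindromic_pairs[pal_idx, 1], .allele_pairs[pair_idx, 1])
  oa <- ifelse(pal, .palindromic_pairs[pal_idx, 2], .allele_pairs[pair_idx, 2])
  pos <- as.integer(pos_start) + (seq_len(n_snps) - 1L) * as.integer(pos_step)
  mk <- function(z, n, trait) {
    study_sumstats(
      data.frame(variant_id = ld$variant_ids, chrom = chrom, pos = pos,
                 effect_allele = ea, other_allele = oa, eaf = eaf,
                 beta = z / sqrt(n), se = 1 / sqrt(n),
                 pvalue = 2 * stats::pnorm(-abs(z)), n = n,
                 stringsAsFactors = FALSE),
      trait_name = trait, validate = FALSE)
  }
  truth <- list(scenario = scenario, causal1 = causal[[1]],
                causal2 = causal[[2]], effect_z = effect_z, seed = seed)
  list(trait1 = mk(z1, n1, "sim_trait1"), trait2 = mk(z2, n2, "sim_trait2"),
       truth = truth, ld = ld)
}

#' Simulate a two-sample MR instrument set with known causal effect
#'
#' Exposure effects are drawn across instruments as
#' `bx ~ N(bx_mean, bx_sd)`; outcome effects follow
#' `by = theta * bx + pleiotropy_alpha + e`, `e ~ N(0, 1/n_out)`.
#' Instruments are independent (identity LD). Reported standard errors
#' are `1/sqrt(n_exp)` and `1/sqrt(n_out)`.
#'
#' @param k_instruments Number of instruments (>= 1).
#' @param bx_mean,bx_sd Location and spread of the exposure effects
#'   (defaults 0.25 and 0.08 give uniformly strong instruments at the
#'   default `n_exp`).
#' @param theta True causal effect of exposure on outcome.
#' @param pleiotropy_alpha Direct (directional-pleiotropy) effect of each
#'   instrument on the outcome, bypassing the exposure.
#' @param n_exp,n_out Exposure and outcome sample sizes (defaults 10708
#'   and 50000).
#' @param seed Integer seed.
#' @param gene Label for the simulated gene.
#' @return list with `inst` (an `instrument_set` with outcome columns
#'   attached) and `truth`.
#' @export
simulate_mr <- function(k_instruments, theta, bx_mean = 0.25, bx_sd = 0.08,
                        pleiotropy_alpha = 0, n_exp = 10708, n_out = 50000,
                        seed = 1, gene = "SIMGENE") {
  stopifnot(k_instruments >= 1)
  set.seed(seed)
  bx <- stats::rnorm(k_instruments, bx_mean, bx_sd)
  sx <- rep(1 / sqrt(n_exp), k_instruments)
  sy <- rep(1 / sqrt(n_out), k_instruments)
  by <- theta * bx + pleiotropy_alpha + stats::rnorm(k_instruments, 0, sy)
  eaf <- stats::runif(k_instruments, 0.05, 0.95)
  pair_idx <- sample.int(nrow(.allele_pairs), k_instruments, replace = TRUE)
  dat <- data.frame(variant_id = paste0("rs", 90000L + seq_len(k_instruments)),
                    chrom = "2",
                    pos = 5000000L + (seq_len(k_instruments) - 1L) * 600000L,
                    effect_allele = .allele_pairs[pair_idx, 1],
                    other_allele = .allele_pairs[pair_idx, 2],
                    eaf = eaf, beta_exposure = bx, se_exposure = sx,
                    pvalue_exposure = 2 * stats::pnorm(-abs(bx / sx)),
                    beta_outcome = by, se_outcome = sy,
                    pvalue_outcome = 2 * stats::pnorm(-abs(by / sy)),
                    stringsAsFactors = FALSE)
  inst <- structure(list(gene = gene, protein = gene, data = dat, ld = NULL),
                    class = "instrument_set")
  truth <- list(scenario = NA_character_, true_theta = theta,
                pleiotropy_alpha = pleiotropy_alpha, seed = seed)
  list(inst = inst, truth = truth)
}
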