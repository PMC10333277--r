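# Two-sample MR estimators and diagnostics: Wald ratio, fixed-effects
# IVW, Cochran's Q, MR-Egger regression, Benjamini-Hochberg FDR, and the
# 2x2 odds-ratio utility.
#
# Conventions: theta is the causal effect of a one-unit increase in the
# exposure on the outcome (log-odds for binary outcomes); odds ratios and
# 95% intervals use exp(theta +/- 1.96 se).

#' Wald ratio estimate from a single instrument
#'
#' `theta = by/bx`; the default standard error is the first-order delta
#' method `sy/|bx|`, which ignores the exposure-side sampling error. The
#' second-order form `sqrt(sy^2/bx^2 + by^2 sx^2 / bx^4)` is available
#' via `second_order = TRUE`.
#'
#' @param bx,sx Exposure effect and standard error (`sx` only used by the
#'   second-order SE).
#' @param by,sy Outcome effect and standard error.
#' @param second_order Use the second-order delta-method SE?
#' @return list with `theta`, `se`, `pvalue`.
#' @export
wald_ratio <- function(bx, sx, by, sy, second_order = FALSE) {
  if (any(bx == 0)) stop("wald_ratio undefined for bx = 0")
  theta <- by / bx
  se <- if (second_order) sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
        else sy / abs(bx)
  list(theta = theta, se = se, pvalue = z_pvalue(theta, se))
}

# Fixed-effects IVW estimate from per-instrument effects. Equivalent to
# weighted least squares of by on bx through the origin with weights
# 1/sy^2.
ivw_estimate <- function(bx, by, sy) {
  w <- 1 / sy^2
  denom <- sum(bx^2 * w)
  theta <- sum(bx * by * w) / denom
  se <- 1 / sqrt(denom)
  list(theta = theta, se = se, pvalue = z_pvalue(theta, se))
}

#' Cochran's Q heterogeneity test across instrument-level estimates
#'
#' `Q = sum_i w_i (by_i/bx_i - theta)^2` with `w_i = bx_i^2 / sy_i^2`,
#' referred to a chi-square distribution on `n - 1` degrees of freedom.
#'
#' @param bx,by,sy Per-instrument effects; at least two instruments.
#' @param theta The pooled IVW estimate; computed internally if omitted.
#' @return list with `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(bx, by, sy, theta = NULL) {
  k <- length(bx)
  if (k < 2) stop("heterogeneity requires at least two instruments")
  if (is.null(theta)) theta <- ivw_estimate(bx, by, sy)$theta
  w <- bx^2 / sy^2
  q <- sum(w * (by / bx - theta)^2)
  list(q_stat = q, q_df = k - 1L,
       q_pvalue = stats::pchisq(q, df = k - 1L, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted linear regression of `by` on `bx` with a free intercept and
#' weights `1/sy^2`, after orienting every instrument to `bx >= 0` (rows
#' with negative exposure effect have both signs flipped). The intercept
#' estimates the average directional (horizontal) pleiotropic effect.
#' Standard errors are the usual WLS ones (residual-variance scaled);
#' p-values use the t distribution on `n - 2` degrees of freedom.
#'
#' @param bx,by,sy Per-instrument effects; at least three instruments.
#' @return list with `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `intercept_low95`, `intercept_high95`, `intercept_p`.
#' @export
egger_regression <- function(bx, by, sy) {
  k <- length(bx)
  if (k < 3) stop("MR-Egger requires at least three instruments")
  flip <- sign(bx)
  flip[flip == 0] <- 1
  x <- bx * flip
  y <- by * flip
  w <- 1 / sy^2
  # weighted normal equations for [intercept, slope]
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  intercept <- (swxx * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  resid <- y - intercept - slope * x
  sigma2 <- sum(w * resid^2) / (k - 2)
  intercept_se <- sqrt(sigma2 * swxx / det)
  slope_se <- sqrt(sigma2 * sw / det)
  tcrit <- 1.96
  list(slope = slope, slope_se = slope_se,
       intercept = intercept, intercept_se = intercept_se,
       intercept_low95 = intercept - tcrit * intercept_se,
       intercept_high95 = intercept + tcrit * intercept_se,
       intercept_p = 2 * stats::pt(-abs(intercept / intercept_se),
                                   df = k - 2))
}

#' Causal estimate with diagnostics for one instrument set
#'
#' Routes single-instrument sets to the Wald ratio and multi-instrument
#' sets to fixed-effects IVW; attaches Cochran's Q (two or more
#' instruments) and the MR-Egger intercept (three or more). Odds ratios
#' are `exp(theta)` with `exp(theta +/- 1.96 se)` intervals.
#'
#' @param inst An `instrument_set` with outcome columns attached
#'   ([attach_outcome()]).
#' @return One-row data.frame (`mr_result`): `gene, protein, n_snps,
#'   method, theta, se, or_point, or_low95, or_high95, pvalue, q_stat,
#'   q_df, q_pvalue, egger_intercept, egger_intercept_low95,
#'   egger_intercept_high95, egger_intercept_p` (diagnostics `NA` where
#'   not computed).
#' @export
mr_estimate <- function(inst) {
  stopifnot(inherits(inst, "instrument_set"))
  d <- inst$data
  if (nrow(d) == 0L) stop("empty instrument set for gene ", inst$gene)
  if (!"beta_outcome" %in% names(d))
    stop("outcome not attached; call attach_outcome() first")
  k <- nrow(d)
  if (k == 1L) {
    est <- wald_ratio(d$beta_exposure, d$se_exposure,
                      d$beta_outcome, d$se_outcome)
    method <- "wald_ratio"
  } else {
    est <- ivw_estimate(d$beta_exposure, d$beta_outcome, d$se_outcome)
    method <- "ivw_fe"
  }
  q <- if (k >= 2) cochran_q(d$beta_exposure, d$beta_outcome,
                             d$se_outcome, theta = est$theta)
       else list(q_stat = NA_real_, q_df = NA_integer_, q_pvalue = NA_real_)
  eg <- if (k >= 3) egger_regression(d$beta_exposure, d$beta_outcome,
                                     d$se_outcome)
        else list(intercept = NA_real_, intercept_low95 = NA_real_,
                  intercept_high95 = NA_real_, intercept_p = NA_real_)
  data.frame(gene = inst$gene, protein = inst$protein, n_snps = k,
             method = method, theta = est$theta, se = est$se,
             or_point = exp(est$theta),
             or_low95 = exp(est$theta - 1.96 * est$se),
             or_high95 = exp(est$theta + 1.96 * est$se),
             pvalue = est$pvalue,
             q_stat = q$q_stat, q_df = q$q_df, q_pvalue = q$q_pvalue,
             egger_intercept = eg$intercept,
             egger_intercept_low95 = eg$intercept_low95,
             egger_intercept_high95 = eg$intercept_high95,
             egger_intercept_p = eg$intercept_p,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values against a total test count
#'
#' Step-up BH with monotonization:
#' `adj_(i) = min(1, min_{j >= i} (m_total/j) p_(j))` over the observed
#' p-values sorted ascending with ranks `j`, where `m_total` may exceed
#' the number of observed p-values (tests whose p-values are not carried
#' forward still count toward the correction). Results are returned in
#' input order.
#'
#' @param raw_p Numeric vector of raw p-values in (0, 1].
#' @param m_total Total number of tests performed; must be at least
#'   `length(raw_p)` (default: the length).
#' @return list with `raw_p`, `m_total`, `adjusted` (same order as input).
#' @export
bh_adjust <- function(raw_p, m_total = length(raw_p)) {
  if (m_total < length(raw_p))
    stop("m_total must be at least length(raw_p)")
  stopifnot(all(raw_p > 0 & raw_p <= 1))
  k <- length(raw_p)
  o <- order(raw_p)
  p_sorted <- raw_p[o]
  adj_sorted <- rev(cummin(rev(pmin(1, m_total / seq_len(k) * p_sorted))))
  adjusted <- numeric(k)
  adjusted[o] <- adj_sorted
  list(raw_p = raw_p, m_total = m_total, adjusted = adjusted)
}

#' Odds ratio from a 2x2 contingency table with Woolf confidence interval
#'
#' `OR = (a d)/(b c)` with
#' `CI = exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Zero cells are an error; no continuity correction is applied (add 0.5
#' to each cell explicitly if needed).
#'
#' @param cases_exposed,controls_exposed,cases_unexposed,controls_unexposed
#'   Positive cell counts.
#' @return list with `or`, `low95`, `high95`.
#' @export
or_2x2 <- function(cases_exposed, controls_exposed,
                   cases_unexposed, controls_unexposed) {
  cells <- unname(c(cases_exposed, controls_exposed,
                    cases_unexposed, controls_unexposed))
  if (any(cells <= 0)) stop("all cells must be positive (no zero cells)")
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se_log <- sqrt(sum(1 / cells))
  list(or = or,
       low95 = exp(log(or) - 1.96 * se_log),
       high95 = exp(log(or) + 1.96 * se_log))
}
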