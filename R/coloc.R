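# Bayesian colocalization of two association signals via per-variant
# Wakefield-style approximate Bayes factors and enumeration of the five
# single-causal-variant configuration hypotheses:
#   H0 no association, H1 trait-1 only, H2 trait-2 only,
#   H3 two distinct causal variants, H4 one shared causal variant.
# All accumulation is in log space (log-sum-exp); the H3 subtraction term
# uses log-diff-exp with a non-negativity clamp so that 50+ variants with
# |z| ~ 10 cannot overflow or cancel below zero.

#' Colocalization priors
#'
#' @param p1,p2 Prior probability that a given variant is causal for
#'   trait 1 / trait 2 (default 1e-4 each).
#' @param p12 Prior probability that a given variant is causal for both
#'   traits (default 1e-5); must satisfy `0 < p12 <= min(p1, p2) < 1`.
#' @param w1,w2 Prior effect variances (squared prior SD of the true
#'   effect) per trait. Defaults to `0.2^2`, the convention for
#'   quantitative traits; use `prior_effect_variance("case_control")`
#'   (`0.15^2`) for binary traits.
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w1 = 0.2^2, w2 = 0.2^2) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), min(p1, p2) < 1, w1 > 0, w2 > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, w1 = w1, w2 = w2),
            class = "coloc_priors")
}

#' Default prior effect variance by trait type
#'
#' Squared prior standard deviation of the true effect size: 0.2 for
#' quantitative traits, 0.15 (on the log-odds scale) for case-control.
#'
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @return Prior variance (scalar).
#' @export
prior_effect_variance <- function(trait_type = c("quantitative",
                                                 "case_control")) {
  switch(match.arg(trait_type), quantitative = 0.2^2, case_control = 0.15^2)
}

#' Log approximate Bayes factor for a single association
#'
#' With `V = se^2`, `z = beta/se`, and shrinkage `r = w/(V + w)`:
#' `log ABF = 0.5 (log(1 - r) + r z^2)`.
#'
#' @param beta,se Estimated effect and its standard error (`se > 0`).
#' @param w Prior effect variance (`w >= 0`; `w = 0` gives log ABF = 0).
#' @return Vector of log approximate Bayes factors (alternative vs null).
#' @export
log_abf <- function(beta, se, w) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(w < 0)) stop("prior variance w must be non-negative")
  V <- se^2
  r <- w / (V + w)
  0.5 * (log1p(-r) + r * (beta / se)^2)
}

#' Colocalization posteriors from paired summary statistics
#'
#' Computes per-variant log ABFs for both traits over an identical,
#' harmonized variant list and enumerates the configuration hypotheses.
#' With `L1_j`, `L2_j` the per-variant ABFs, the unnormalized hypothesis
#' weights are `H0: 1`, `H1: p1 S1`, `H2: p2 S2`,
#' `H3: p1 p2 (S1 S2 - S12)`, `H4: p12 S12`, where `S1 = sum L1_j`,
#' `S2 = sum L2_j`, `S12 = sum L1_j L2_j`.
#'
#' @param beta1,se1 Effects and standard errors for trait 1.
#' @param beta2,se2 Effects and standard errors for trait 2, over the
#'   same variants in the same order.
#' @param priors A [coloc_priors()] object.
#' @return A `coloc_result`: list with `pp` (named vector
#'   `pp_h0 ... pp_h4` summing to 1), `n_snps`, `priors`.
#' @export
coloc_abf <- function(beta1, se1, beta2, se2, priors = coloc_priors()) {
  n <- length(beta1)
  if (length(se1) != n || length(beta2) != n || length(se2) != n)
    stop("mismatched variant lists: all inputs must have equal length")
  if (n < 1) stop("at least one variant is required")
  l1 <- log_abf(beta1, se1, priors$w1)
  l2 <- log_abf(beta2, se2, priors$w2)
  ls1 <- logsumexp(l1)
  ls2 <- logsumexp(l2)
  ls12 <- logsumexp(l1 + l2)
  lw <- c(h0 = 0,
          h1 = log(priors$p1) + ls1,
          h2 = log(priors$p2) + ls2,
          h3 = if (n > 1)
            log(priors$p1) + log(priors$p2) + logdiffexp(ls1 + ls2, ls12)
          else -Inf,
          h4 = log(priors$p12) + ls12)
  denom <- logsumexp(lw)
  pp <- exp(lw - denom)
  names(pp) <- paste0("pp_", names(lw))
  structure(list(pp = pp, n_snps = n, priors = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result> n_snps =", x$n_snps, "\n")
  print(round(x$pp, 4))
  invisible(x)
}

#' Classify colocalization evidence from PP.H4
#'
#' Strict thresholds: `pp_h4 > strong` is `"strong"`, otherwise
#' `pp_h4 > suggestive` is `"suggestive"`, otherwise `"none"`.
#'
#' @param res A `coloc_result` (or a bare PP.H4 value).
#' @param suggestive,strong Thresholds (defaults 0.5 and 0.8).
#' @return `"none"`, `"suggestive"` or `"strong"`.
#' @export
classify_coloc <- function(res, suggestive = 0.5, strong = 0.8) {
  pp_h4 <- if (inherits(res, "coloc_result")) unname(res$pp["pp_h4"]) else res
  ifelse(pp_h4 > strong, "strong",
         ifelse(pp_h4 > suggestive, "suggestive", "none"))
}
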