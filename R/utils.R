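# Internal numeric helpers shared across modules.

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; clamped at -Inf when cancellation
# drives the difference non-positive.
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  if (!is.finite(b)) return(a)
  a + log1p(-exp(b - a))
}

# Two-sided normal p-value from an estimate and its standard error.
z_pvalue <- function(est, se) 2 * stats::pnorm(-abs(est / se))

`%||%` <- function(a, b) if (is.null(a)) b else a
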