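---
title: "Cis-MR and colocalization for drug-target discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cis-MR and colocalization for drug-target discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoMR)
```

## The problem and the approach

Most approved drugs act on proteins, and a protein whose genetically
predicted plasma level associates with disease risk is a natural
candidate target. Two-sample Mendelian randomization (MR) formalizes
this: variants that perturb a protein's abundance serve as instrumental
variables, and the ratio of their outcome effects to their protein
effects estimates the causal effect of the protein on disease, free (in
expectation) of classical confounding and reverse causation.

`proteoMR` implements the full analytical chain of a proteome-wide
cis-MR screen for a binary outcome such as heart failure:

1. **Harmonization** of exposure (pQTL) and outcome (GWAS) summary
   statistics to a shared effect-allele orientation.
2. **GWAS meta-analysis** utilities (fixed-effects IVW pooling, MAF
   filtering, greedy clumping, novelty flagging) for building the
   outcome dataset.
3. **Cis-instrument selection**: variants within ±1 Mb of the encoding
   gene at p < 5×10⁻⁸, thinned to an approximately independent set.
4. **MR estimation**: Wald ratio (single instrument) or fixed-effects
   IVW (two or more), with Cochran's Q and the MR-Egger intercept as
   instrument diagnostics, and Benjamini–Hochberg FDR control across
   the proteome.
5. **Colocalization** by Wakefield approximate Bayes factors, to ensure
   an MR hit reflects a shared causal variant (H4) rather than
   confounding by linkage disequilibrium (H3).
6. **Triage**: a four-step horizontal-pleiotropy assessment,
   risk-factor directionality checks, agonist/inhibitor inference from
   the odds-ratio direction, and druggability regrouping.

The restriction to *cis* instruments is itself a pleiotropy defence: a
variant inside or adjacent to the encoding gene is far more likely to
affect the outcome through that gene's product than a trans signal is.

## Models and estimators

### Harmonization rules

Two studies are joined on `variant_id`. When study B reports the
opposite allele orientation, its beta is negated and its allele
frequency reflected. Strand flips are resolved by complementing;
alleles that are neither equal, swapped, nor complement-resolvable drop
the variant. Palindromic variants (A/T, C/G) cannot be resolved by
allele matching at all, so they are resolved by allele-frequency
concordance and dropped whenever either study's frequency lies within
0.08 of 0.5 (i.e. eaf in (0.42, 0.58)) or is missing. The window is a
deliberately conservative default and is configurable
(`drop_ambiguous_maf`); frequency concordance near 0.5 is essentially
uninformative about strand, and the screen loses little by discarding
these variants. Harmonization is idempotent and invariant to
pre-flipping either study, properties the test suite checks directly.

### MR estimators

For a single instrument the Wald ratio is `theta = by/bx` with
first-order delta-method standard error `sy/|bx|`; the second-order
form (adding the exposure-error term) is available behind a flag but is
not the default, matching the convention of standard two-sample MR
software. For k ≥ 2 instruments the fixed-effects IVW estimate

\[
\hat\theta = \frac{\sum_i b_{x,i} b_{y,i}/s_{y,i}^2}
                  {\sum_i b_{x,i}^2/s_{y,i}^2},\qquad
\mathrm{se} = \Big(\sum_i b_{x,i}^2/s_{y,i}^2\Big)^{-1/2}
\]

is identical to weighted least squares of `by` on `bx` through the
origin. Fixed-effects (not multiplicative random-effects) weighting is
used throughout; cis instrument sets here are small (1–14 variants) and
heterogeneity is reported, not absorbed. Cochran's Q compares
per-instrument ratios to the pooled estimate on k−1 degrees of freedom;
the MR-Egger intercept—fitted by weighted regression with a free
intercept after orienting all instruments to positive exposure
effects—estimates average directional pleiotropy and requires k ≥ 3.
Sign orientation before the Egger fit is standard practice (the model
is not invariant to per-row sign flips) and is applied always.

95% intervals use z = 1.96 exactly. Odds ratios are derived from
log-odds effects only at reporting time.

### FDR control

BH adjustment is computed against the full number of tests in the
screen (`m_total`, 1557 in the bundled worked example), not just the
rows carried forward into a report:
`adj_(i) = min(1, min_{j≥i} (m_total/j) p_(j))`. This matters when
reproducing published tables that print only the significant rows.

### Colocalization

Each variant's evidence is a Wakefield approximate Bayes factor. With
`V = se²`, `z = beta/se` and prior effect variance `w`,

\[
\log \mathrm{ABF} = \tfrac12\left[\log(1-r) + r z^2\right],
\qquad r = \frac{w}{V+w}.
\]

Under the single-causal-variant assumption per trait, summing ABFs over
variants (and over ordered pairs of distinct variants for H3) gives the
unnormalized posterior weights for the five hypotheses, with priors
p1 = p2 = 1×10⁻⁴ and p12 = 1×10⁻⁵ (the conventional defaults). The
prior effect SD defaults to 0.2 for quantitative traits and 0.15 on the
log-odds scale for case-control traits; both are configurable. PP.H4 >
0.5 is treated as suggestive and PP.H4 > 0.8 as strong evidence of a
shared causal variant (strict inequalities).

All accumulation is in log space via log-sum-exp. The H3 term
`S1·S2 − S12` is computed as a log-difference with a non-negativity
clamp: with 50+ variants at |z| ≈ 10 the naive products overflow double
precision, and near-total cancellation can otherwise produce a small
negative weight. A single-variant region is legal and gets H3 weight
exactly zero (no two-distinct-variant configuration exists).
Correctness is established against a brute-force enumeration over all
single-causal configurations on small instances, which the acceptance
checks run on 200 random cases at 1×10⁻¹⁰ tolerance.

### Pleiotropy triage

The four-step assessment asks, for each MR hit: (1) which *other*
proteins or transcripts its instruments associate with at p < 5×10⁻⁸;
(2) whether the implicated genes sit near known outcome risk loci
(±1 Mb); (3) whether those secondary traits themselves causally
associate with the outcome, each instrumented by its own lead cis
variant (pQTL preferred over eQTL) at a Bonferroni threshold
0.05/n; and (4) whether outcome-significant secondary genes share a
pathway with the primary gene. A shared pathway indicates vertical
(downstream, harmless) pleiotropy; disjoint annotated pathways indicate
horizontal pleiotropy; missing annotation leaves the question open.
When a gene accumulates mixed evidence the flag takes the most
conservative label present (horizontal > unknown > vertical): a single
genuine horizontal path invalidates the MR interpretation regardless of
how many vertical paths coexist.

Risk-factor directionality uses a *declared* harmful/protective
polarity per factor rather than inferring it, because polarity is
contestable (HDL-C and diastolic blood pressure are documented sources
of discordance). Modality inference reads the odds ratio direction:
OR > 1 suggests an inhibitor, OR < 1 an agonist. Druggability buckets
1–9 regroup as: 1 → licensed; 2–3 → clinical; 4–5 → preclinical (small
molecules) or predicted (antibodies); 6–8 → predicted (small
molecules); everything else → non-druggable.

## The synthetic-data generator

Restricted accessions stand behind the real inputs of such screens, so
the package carries a simulator that reproduces their statistical
structure. It draws association z-scores directly from the standard
summary-statistic model `z | λ ~ N(Rλ, R)`, where `R` is an AR(1) LD
matrix (`r_jk = ρ^|j−k|`, default ρ = 0.9) and `λ` places the
non-centrality (default expected |z| of 8–10, typical of a strong
cis-pQTL) at the causal variant(s). Reported effects are `z/√n` with
standard errors `1/√n`. Causal configurations cover all five
colocalization hypotheses; H4 shares one position, H3 separates two
positions to the region's quarter points so their LD is ρ^(n/2) ≈ 0.07
at the defaults, and an LD-confounded variant of H3 (closer causal
variants, r ≈ 0.6) is used to demonstrate that a nominally significant
MR signal without colocalization is rejected.

`simulate_mr` draws exposure effects across instruments as
`bx ~ N(0.25, 0.08)`—uniformly strong instruments relative to the
exposure standard error `1/√10708`, the size of a typical
proteogenomic discovery cohort—and outcome effects as
`by = θ·bx + α + e` with `e ~ N(0, 1/n_out)`, `n_out = 50000` by
default. The generative model places sampling noise on the outcome side
only, so the no-measurement-error condition assumed by the first-order
Wald/IVW standard errors holds exactly and the estimators' calibration
(CI coverage, Q test size, Egger intercept recovery) can be tested
against their nominal values rather than against approximations.

What the simulator does *not* emulate: realistic human LD panels,
allele-frequency-dependent effect sizes, liability-scale case-control
sampling, sample overlap between exposure and outcome studies, and
weak-instrument bias regimes. Tests passing on these simulations
demonstrate the correctness and calibration of the estimators under
their stated assumptions, not robustness to every pathology of real
cohort data.

## Numerical and design choices

- Variants are matched by identifier, not position; positional matching
  would require build-aware liftover, which is out of scope.
- Instrument independence is approximated by greedy LD clumping at
  r² < 0.1 (distance fallback 500 kb without an LD matrix), replacing
  the approximate conditional analysis used by proteogenomic discovery
  studies; conditional statistics are accepted as input but never
  derived.
- The cis window anchors on gene boundaries (start/end), not the TSS
  alone; both choices appear in the literature and the window is a
  parameter.
- Greedy p-ordered clumping breaks p ties by ascending position, making
  reports byte-stable.
- Lead-variant novelty means > 500 kb from every known lead.
- `call_leads` uses r² when an LD matrix is supplied and pure distance
  otherwise; the distance rule is an approximation of the r² rule and
  is documented as such.
- Problem sizes in tests and the acceptance script (200 enumeration
  instances, 100 seeds per coloc scenario, 500 seeds for recovery, 2000
  for test size) were chosen so that Monte-Carlo error is well inside
  each assertion's band while the whole suite stays quick to run.

## Known limitations

- Only the first-order Wald SE is the default; with very weak
  instruments it understates uncertainty (the second-order form is
  available).
- No proxy-variant substitution: instruments absent from the outcome
  study are dropped.
- No Steiger filtering, weighted-median/mode estimators, or
  multivariable MR; the screen's defence against invalid instruments is
  the cis restriction, the diagnostics, and the triage steps.
- Colocalization assumes at most one causal variant per trait per
  region; multi-signal regions should be conditioned upstream.

## A worked example

The bundled fixture reproduces a published 16-gene screen end to end:

```{r}
demo <- demo_published_example()
```

And a fully synthetic screen with known truth:

```{r}
g1 <- simulate_region(50, scenario = "H4", effect_z = 10, seed = 1)
h <- harmonize_pair(g1$trait1, g1$trait2)
coloc_abf(h$beta_a, h$se_a, h$beta_b, h$se_b)
```
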