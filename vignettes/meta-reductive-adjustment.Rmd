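---
title: "Removing a cohort from IVW meta-analysis summary statistics: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing a cohort from IVW meta-analysis summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metareduce)
```

## The model

A fixed-effect inverse-variance-weighted (IVW) meta-analysis of $n$
independent cohorts pools per-marker effect estimates $\beta_i$ with
standard errors $se_i$ as

$$B = \frac{\sum_i \beta_i w_i}{\sum_i w_i}, \qquad
  SE^2 = \frac{1}{\sum_i w_i}, \qquad w_i = \frac{1}{se_i^2}.$$

Suppose cohort $n$ — the one you want to reuse as a polygenic-score training
or target sample — contributed to this meta-analysis, and you hold only the
published $(B, SE)$ and your own $(\beta_n, se_n)$ per marker. Because
$SE^2 \sum_i w_i = 1$, the removed cohort's share of the total weight is
exactly $SE^2 w_n$, so the weight of the remaining cohorts is
$(1 - SE^2 w_n)/SE^2$. Writing $d = 1 - SE^2 w_n$, subtracting cohort $n$'s
contribution from the weighted sum gives

$$B_{adj} = B + \frac{SE^2\,w_n\,(B - \beta_n)}{d}
          = \frac{B - SE^2\,\beta_n w_n}{d}, \qquad
  SE^2_{adj} = \frac{SE^2}{d}.$$

These are not approximations: they are the identical quantities an IVW
re-analysis of the other $n-1$ cohorts would produce, which is what the
validation harness verifies marker by marker against a brute-force
leave-one-out recomputation.

**Assumptions.** The published meta-analysis must be fixed-effect IVW (not
random-effects, not sample-size/z-score weighted, not genomic-control
scaled), the cohorts must be independent (no shared individuals), and both
tables must report effects on the same allele per marker — that last
condition is what the harmonization step enforces. The adjustment is
agnostic to trait type; only $(\beta, se)$ pairs enter.

## Parameters that matter

* **`eps`** (default `1e-12`), the degeneracy threshold on $d$. When the
  removed cohort carries essentially all the weight, $d \to 0$ and both
  adjusted quantities diverge: there is no information left to report. Such
  markers get `status = "dominant_cohort"` and `NA` values rather than a
  number amplified from round-off. `1e-12` sits a few orders above double
  round-off on $d$ yet far below any $d$ arising when at least one other
  cohort genuinely contributes.
* **`palindromic`** (default `"drop_if_flip"`). A/T and C/G markers are their
  own strand complements, so a strand flip is indistinguishable from an
  allele swap without frequency information (which summary tables often
  lack, and which this package deliberately does not use). The default keeps
  palindromic markers whose alleles match as written and excludes the rest;
  `"drop"` and `"keep"` are available for stricter or laxer pipelines.
* **Dialects.** Column mappings for METAL-style and PLINK-style files ship
  built in; anything else is a small YAML file. `marker_id`, `beta`, `se`
  are mandatory; alleles, p-value, and sample size optional.

Inconsistent inputs — a cohort claiming more weight than the whole
meta-analysis, $w_n SE^2 > 1$ — are mathematically impossible for correct
full-precision tables but occur with rounded published values. They are
flagged `inconsistent_inputs` and excluded; clamping $d$ to a positive value
would fabricate precision.

## Numerical choices

Of the two algebraically identical arrangements for $B_{adj}$, the package
computes the correction-term form $B + SE^2 w_n (B - \beta_n)/d$. At the
fixed point $\beta_n = B$ the correction term is exactly zero in floating
point, so a cohort sitting precisely at the pooled effect provably moves
nothing; the subtractive arrangement misses this by a few ulp when $d$ is
small. Summation in the IVW engine follows input order (at most dozens of
cohorts, compensated summation would be over-engineering), and cohort order
is a no-op up to $10^{-14}$ relative round-off.

One measurement convention: invariant checks that compare effect sizes
"relatively" divide by $\max(|B|, SE)$ rather than $|B|$ alone. A pooled
effect is a difference of same-sized terms and can land arbitrarily close to
zero, where relative-to-$|B|$ error is unbounded for any double-precision
computation even though the absolute error is $\sim 10^{-18}$; $SE$ is the
estimate's own scale and the natural floor. Variance-like quantities
($SE^2$), being bounded away from zero, are compared strictly relatively.
The validation report's `max_rel` columns keep the plain
$|\Delta|/\max(|B_{LOO}|, 10^{-30})$ definition so that what is printed is
the worst case a user would compute themselves.

## What the simulator emulates — and what it does not

`simulate_cohorts()` generates $K$ pre-aligned cohort tables around shared
true effects: marker allele frequency $p_j \sim U(0.01, 0.5)$; a marker is
causal with probability `causal_fraction`, in which case
$\beta_{true} \sim N(0, \tau^2)$, else exactly zero; cohort $i$ observes
$\hat\beta_{ij} \sim N(\beta_{true,j}, se_{ij}^2)$ with the
quantitative-trait, unit-variance approximation
$se_{ij} = 1/\sqrt{2 p_j (1-p_j) n_i}$. The defaults — four cohorts of
20,000 / 8,000 / 45,000 / 6,000 individuals and 100,000 markers — mirror a
realistic validation design of several unequal-sized studies meta-analyzed
together; 1% causal markers with $\tau = 0.02$ gives a sparse polygenic
architecture with per-marker effects of the size seen in complex-trait
GWAS. One global seed drives the run, with per-cohort substreams derived
deterministically from it, so identical configurations are bit-identical.

The simulator deliberately omits LD between markers, case-control log-odds
sampling variance, population stratification, and overlapping individuals
between cohorts. None of these affect what the tests establish — that the
adjustment is algebraically exact given fixed-effect IVW inputs — but they
do mean passing tests say nothing about whether fixed-effect IVW was the
right model for a particular real meta-analysis, nor about markers whose
real tables violate the shared-effect-allele assumption in ways
harmonization cannot detect (e.g. mislabelled strands on palindromic
markers).

## Design choices on open points

* **Markers absent from the cohort of interest** pass through with the meta
  values verbatim (`passthrough_not_in_cohort`): a cohort that never
  measured a marker contributed zero weight, so removal changes nothing, and
  dropping the marker would shrink PRS panels needlessly.
* **Duplicate marker ids on read** keep the first occurrence with a counted
  warning — deterministic and order-stable.
* **Mismatched alleles that no swap or strand flip resolves** are excluded,
  never guessed: a sign-misaligned adjustment silently corrupts every
  downstream score.
* **Matching is by marker id alone**, not chromosome/position — the minimal
  assumption for marker-keyed tables; liftover and rsID resolution are out
  of scope.
* **p-values are always recomputed** from $z = B_{adj}/SE_{adj}$ against the
  standard normal; carried-over input p-values describe the unadjusted
  estimate.
* **Heterogeneity statistics** (Q, I²) are omitted: the adjustment neither
  needs nor informs them.

## Problem sizes in the shipped checks

The validation harness runs the full K = 4, M = 100,000 design (seconds on
one CPU; everything is vectorized), alongside K ∈ {2..6} sweeps at M = 1,000,
a 10,000-draw property sweep of the fixed-point/monotonicity/round-trip
invariants, and calibration checks of the simulator at M × K = 40,000 draws.
A precision-truncation mode (`run_validation(..., round_digits = 4)`) rounds
the meta and cohort tables to 4 decimals before adjustment while keeping the
oracle at full precision, quantifying what published-file rounding costs:
correlations drop measurably below 1 but stay above 0.999, and tighten again
as retained precision grows.

## Known limitations

Removing several cohorts requires iterating the single-cohort adjustment
(tested as a property); there is no dedicated multi-cohort formula, and no
covariance-aware removal of *partially* overlapping cohorts — if your cohort
shares individuals with a remaining study, the independence assumption is
already broken. Random-effects meta-analyses cannot be reduced this way: the
weights are not recoverable from $(B, SE)$ alone.
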