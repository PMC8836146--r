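---
title: "Methods: testing the Menzerath-Altmann law on protein secondary structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing the Menzerath-Altmann law on protein secondary structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

In quantitative linguistics, Menzerath's Law is the tendency for larger
constructs to be built from smaller constituents: longer words have, on
average, shorter syllables. The Menzerath-Altmann law (MAL) is its
quantitative refinement — a specific parametric formula for how constituent
size decays with construct size. `malss` treats a protein as the construct
and its secondary-structure segments (alpha-helices, H, and beta-strands, E,
measured in amino acids) as the constituents, and asks two questions in
order:

1. **Menzerath's Law (qualitative).** Is the average segment length `y`
   negatively associated with the segment count `x` across proteins?
2. **Menzerath-Altmann law (quantitative).** If so, which parametric curve
   best describes the binned trend `y_bar(x)`?

A third stage asks which individual proteins escape the fitted trend, and
whether those escapees share subcellular locations more often than chance.

## Data admission

Secondary-structure annotation is only trustworthy where the structure was
actually observed, so a protein enters the analysis only when a single
continuous interval covering at least 95% of its sequence was observed;
unobserved residues are tolerated only at the termini. The threshold is the
exact ceiling `min_required_observed(L) = ceil(0.95 L)`, computed in integer
arithmetic (`ceil(19L/20)`) so that floating-point representation of 0.95
can never shift a boundary case: a 14-residue sequence must be fully
observed, a 33-residue sequence needs 32, a 75-residue one needs 72.
Coverage is modelled as one interval; records with internal gaps are not
"continuous" and must be rejected upstream. Only H and E segments count as
secondary structures; turn/coil annotations in the input are dropped with a
logged count, and proteins left with zero segments are excluded (also
counted). The minimum accepted segment length is 1 amino acid — no
biophysical minimum is imposed.

## Binning and the correlation battery

Bins collect all proteins sharing one `x`. The bin mean `y_bar` is the
*pooled* average over every segment of every member — total residues in
segments divided by total segments — not the mean of per-protein means; the
two differ whenever member proteins differ in segment count contributions.
The fitting weight is `w = n * x`, the number of segments pooled into the
bin, proportional to the inverse sampling variance of `y_bar`.

Stage one computes five statistics: Pearson's r, Spearman's rho (midranks
for ties) and the correlation ratio eta on the per-protein pairs, and
Pearson and Spearman again on the binned pairs. Eta is the square root of
the between-group over total sum of squares from the one-way ANOVA
decomposition with the distinct `x` values as groups; it measures strength
without assuming linearity or monotonicity, and satisfies `eta^2 >= r^2` by
construction. Menzerath's Law is "not rejected" when both Pearson
coefficients are negative with p below 0.001, the reporting convention we
adopt throughout.

Interval choices the literature leaves open, fixed here once: the Pearson CI
is the Fisher z-transform; the Spearman CI uses the z-transform with
variance `1.06/(n - 3)` (the standard large-sample approximation); the
Spearman p-value is exact for n up to 50 and t-approximate beyond; the eta
CI is a seeded nonparametric bootstrap over proteins (2000 resamples,
percentile interval), since no standard closed form exists.

## The five formulas and their fitting

```
(1)  y = a * x^b * exp(c x)
(2)  y = a * x^b
(3)  y = a / x
(4)  y = d + a / x
(5)  y = sqrt(d + a / x)
```

Model 3 is model 2 with `b = -1`, and model 4 generalises it with an
additive floor `d`, interpretable as a minimal segment length. Model 5 is an
empirical form: it decays from `sqrt(d + a)` at `x = 1` to the asymptote
`sqrt(d)`, and with its published reference parameters (a = 207.738,
d = 46.938) it tracks the same 16-to-7 amino-acid decay as model 4 while
bending differently at small `x`. Because that form is easy to corrupt
silently, the registry ships a consistency gate (`check_formula5_gate()`):
reference-parameter predictions over `x` in 1..142 must decrease strictly,
stay in the plausible binned range, and approach the ~7 AA asymptote; any
candidate registry change failing the gate is rejected.

Parameters are estimated by minimising `sum_j w_j (y_bar_j - yhat_j)^2` with
a Gauss-Newton iteration using analytic Jacobians; Levenberg-Marquardt
damping is enabled purely as a safeguard (it vanishes near the optimum, so
the stationary point is the Gauss-Newton one). We deliberately do not
log-linearise before fitting — models 4 and 5 cannot be linearised that way,
and fitting all models on one scale keeps their comparison honest.
Numerical choices: starting values come from model-specific heuristics
(log-log regression for models 1-2, the weighted closed form for model 3,
linearised regressions on `1/x` for models 4-5) plus 10 seeded random
restarts, best objective wins; convergence is a relative objective change
below 1e-10 or 200 iterations; inadmissible parameter points (non-finite
predictions, e.g. a negative argument under model 5's square root) get an
infinite objective so the damping loop steps around them; a rank-deficient
Jacobian at the optimum is an error rather than a silent pseudo-inverse.

Fit quality uses two indices. The residual standard error is
`s = sqrt(sum_j w_j (y_bar_j - yhat_j)^2 / (k - p))` for `k` bins and `p`
free parameters. The AIC is `2p - 2 ln L` under a Gaussian likelihood with
per-bin variance `sigma^2 / w_j` and `sigma^2` profiled at its MLE; `p`
counts mean-function parameters only. Absolute AIC values depend on
likelihood constants, so only within-dataset orderings are meaningful, and
`compare_models()` refuses to rank fits that mix weightings or bins.
Standard errors are `s^2 (J' W J)^{-1}` diagonals; the Wald statistic
`(b + 1)/SE(b)` from the model-2 fit tests whether the pure reciprocal
(model 3) is adequate.

## Outliers and enrichment

Individual proteins are judged against the binned fit through internally
studentized residuals: `e_i / (sigma_hat * sqrt(1 - h_i))`, where `e_i` is
the protein's raw residual from the curve, `sigma_hat` the global
dispersion of per-protein residuals (`sqrt(sum e_i^2 / (n - p))`), and
`h_i` the leverage of the protein's bin under the weighted fit (the
tangent-plane hat value at the protein's `x`). This is an interpretation
rather than a formula fixed by precedent: studentizing individuals against
a bin-level fit requires choosing both the residual scale (we use a single
global scale, honouring the aim of comparing proteins regardless of weight
and position on the x-axis) and the leverage (we use the bin's). On the
degenerate case where each protein is its own unit-weight bin and the model
is linear in its parameters, the construction reduces exactly to the
textbook internally studentized residuals of OLS — the test suite pins that
equivalence. Thresholds are deliberately asymmetric: above-model outliers
at +3 studentized deviations, below-model at -2, because strong
above-model cases dominate the residual scale and a symmetric -3 cut
finds nothing below.

Enrichment of location labels among the above-model outliers uses the exact
hypergeometric upper tail `P(X >= x)` for `x` labelled outliers among `n`,
given `M` labelled proteins in a dataset of `N`, accumulated in log space
from `lchoose` terms. With `c` distinct categories the family-wise level
alpha = 0.05 is Bonferroni-corrected to `alpha / c`; for 211 categories
that is 0.0002369668. The test is one-sided (over-representation), matching
the upper tail; under-representation is reported descriptively in the
`direction` column. Proteins with several labels count once per label.
Because published category frequencies can be quoted against either the
whole dataset or only its annotated subset, the result table reports both
percentages.

## What the synthetic generator emulates — and what it does not

The generator exists so every stage is testable without downloads. Its
defaults are the study conditions the pipeline is meant to emulate:
secondary-structure counts on 1..142 from a zipf-like distribution with
exponent 1.6 (low counts dominate, median below 5, as in the observed
scatter of such datasets); conditional mean segment lengths from model 4
with a = 11, d = 7 — near the published weighted fit, giving bin means
decaying from about 18 to 7 amino acids, close to though not identical with
the observed 4.4-15.6 span; integer segment lengths drawn as
`1 + Poisson(mean - 1)` so the amino-acid count is integral and at least 1
(a rounded lognormal is available as an alternative); 211 flat location
categories with a 60% annotation rate; optional planted outliers
(mean-length inflation) and a planted enriched category with separate
background and outlier rates. Sequence lengths are the total segment length
plus a 25% coil allowance, so the record invariants always hold.

No per-bin variance model is published for real data, so the generator's
noise law is a convention, recorded in `truth_report()` to keep recovery
experiments self-consistent. The generator does not emulate 3D structure,
residue content, correlated segment lengths within a protein, the UniProt
annotation hierarchy, or homology structure; consequently, passing tests
show the *pipeline* is correct under the assumed statistical shape, not
that real proteomes obey the law — that question needs the real data.

## Problem sizes and verification

The test suite verifies each estimator against an independent oracle: the
closed-form weighted normal equation for model 3 (agreement to 1e-8), an
iteratively refined exhaustive grid search for model 2 (to 1e-3), the
reference `nls`/`minpack.lm` implementations for the full fitter,
exhaustive subset enumeration for the hypergeometric tail (every instance
with N up to 12), and OLS `rstandard()` for studentization. Simulation
checks run at the scale a single CPU handles in minutes, chosen as the
package's own study sizes: parameter recovery uses 100 bins and 200
replicates per generating model (coverage of the 3-SE interval at or above
90%), AIC selection of the shifted reciprocal over the pure reciprocal uses
200 replicates (at or above 95%), the correlation battery runs on 5000
synthetic proteins, and the planted-enrichment power and null-calibration
studies use 200 replicates of a 5000-protein dataset with 100 outliers.
The workflow scripts under `analysis/` run the same stages end to end on a
5000-protein simulation and write their tables under `results/`.

## Known limitations

Bootstrap eta intervals are percentile intervals and can undercover for
very unbalanced groupings. The studentization leverage is a bin-level
interpretation; alternatives (per-bin residual scales, zero leverage) would
shift borderline outliers. Absolute AIC values are not comparable across
weightings or datasets by design. The generator's independence assumptions
(segment lengths i.i.d. given x) make planted-outlier recovery easier than
it would be on real, homology-structured data.
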