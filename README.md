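# malss

Do protein secondary structures follow the Menzerath–Altmann law — the
more secondary structures a protein has, the shorter they are on average?
`malss` implements the full statistical pipeline for asking that question
of per-protein secondary-structure annotations: data admission by a 95%
continuous-coverage rule, pooled binning by segment count, a correlation
battery for the qualitative law, weighted nonlinear fitting and comparison
of five candidate formulas, studentized-residual outlier detection, and
exact hypergeometric enrichment of outlier annotations. A synthetic-data
generator with planted ground truth makes every stage testable end to end
without any external downloads.

It is written for structural bioinformaticians and quantitative linguists
who want a reproducible, oracle-tested implementation of the method, either
as a library or as the numbered workflow under `analysis/`.

## The model

For a protein with `x` secondary-structure segments (helix H, strand E) of
mean length `y` amino acids, proteins sharing an `x` are pooled into a bin
with mean `ȳ(x)` and weight `w = n·x`. Five formulas for `ȳ(x)` are fitted
by weighted nonlinear least squares (Gauss–Newton, analytic Jacobians):

| id | formula | parameters |
|----|------------------------|------------|
| 1 | `ȳ = a·x^b·exp(c·x)` | a, b, c |
| 2 | `ȳ = a·x^b` | a, b |
| 3 | `ȳ = a/x` | a |
| 4 | `ȳ = d + a/x` | a, d |
| 5 | `ȳ = √(d + a/x)` | a, d |

Fits are compared by the residual standard error
`s = √( Σⱼ wⱼ(ȳⱼ − ŷⱼ)² / (k − p) )` and by AIC (`2p − 2 ln L`, Gaussian
likelihood with per-bin variance `σ²/wⱼ`). Proteins with internally
studentized residuals above +3 (or below −2) are outliers; their
subcellular-location labels are tested for over-representation with the
exact hypergeometric upper tail under Bonferroni correction (`α/c` over the
`c` categories).

## Worked example

```r
library(malss)

# admission rule: minimum continuously observed residues
min_required_observed(c(14, 33, 75))
#> [1] 14 32 72

# a protein with segments of 29, 15 and 20 AA has x = 3, y = 21.33
mean_ss_length(c(29, 15, 20))
#> [1] 21.33333

# simulate a dataset with known truth and run the pipeline
cfg <- synthetic_config(n_proteins = 1200, outlier_fraction = 0.01,
                        outlier_inflation = 3,
                        enriched_category = list(name = "membrane",
                                                 background_rate = 0.05,
                                                 outlier_rate = 0.6),
                        seed = 42)
man <- run_pipeline(run_config(generate_dataset(cfg), models = c(2, 3, 4),
                               seed = 42, out_dir = "run42"))
render_report(man)
```

The report prints:

```
Correlation battery (Menzerath's Law):
  pearson_r     per_protein -0.381  [-0.428, -0.331]  p = 1.07e-42
  spearman_rho  per_protein -0.837  [-0.853, -0.818]  p = 1.36e-315
  eta           per_protein  0.715  [ 0.675,  0.766]  p = 3e-131
  pearson_r     binned      -0.434  [-0.607, -0.222]  p = 0.000175
  spearman_rho  binned      -0.642  [-0.765, -0.474]  p = 2.14e-09
  ML not rejected: TRUE

Model comparison (best first by AIC):
  model 4: s = 6.439, AIC = 137.1 (rank_s 1, rank_aic 1)
  model 2: s = 14.38, AIC = 249.6 (rank_s 2, rank_aic 2)
  model 3: s = 68.72, AIC = 467.6 (rank_s 3, rank_aic 3)

Outliers vs model 4: 72 above (> +3 st.res.), 140 below (< -2)
```

Both correlation coefficients are negative far below p = 0.001, so the
qualitative law is not rejected, and the generating model 4 outranks its
pure-reciprocal sub-model 3 on both `s` and AIC. At this small size the
planted membrane enrichment is visible but not Bonferroni-significant; the
full-scale version of the run (5000 proteins) in `analysis/01_simulate.R` …
`05_outliers_enrichment.R` recovers all 47 admitted planted outliers and
detects the membrane category at p = 1.8e−12 against a Bonferroni
threshold of 2.4e−4. The analysis scripts write their tables under
`results/`.

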