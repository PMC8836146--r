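#!/usr/bin/env Rscript
# Stage 4: fit the five Menzerath-Altmann formulas to the bins.
#
# Weighted (w = n * x) and unweighted nonlinear least squares, compared by
# residual standard error and AIC; plus the Wald test of b = -1 in the
# power law, which asks whether the pure reciprocal is adequate.

suppressPackageStartupMessages(library(malss))

bins <- tibble::as_tibble(read.delim("results/bins.tsv"))

for (tag in c("weighted", "unweighted")) {
  fits <- lapply(1:5, fit_nwls, bins = bins, weighted = (tag == "weighted"), seed = 1)
  write_fits(fits, sprintf("results/fits_%s.json", tag))
  cmp <- compare_models(fits)
  cat(sprintf("\n%s fits (best first by AIC):\n", tag))
  print(as.data.frame(cmp), digits = 4)
  if (tag == "weighted") {
    tb <- test_b_equals_minus1(fits[[2]])
    cat(sprintf("power-law exponent b = %.3f (SE %.3f); Wald z vs b = -1: %.1f, p = %.3g\n",
                tb$b, tb$se, tb$z, tb$p_value))
    write.table(as.data.frame(cmp), "results/model_comparison.tsv",
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
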