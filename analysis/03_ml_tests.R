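#!/usr/bin/env Rscript
# Stage 3: Menzerath's-Law correlation battery.
#
# Pearson, Spearman and the correlation ratio eta on per-protein (x, y),
# plus Pearson and Spearman on the binned (x, y_bar). The law's qualitative
# form ("the more secondary structures, the shorter they are") is not
# rejected when both Pearson coefficients are negative at p < 0.001.

suppressPackageStartupMessages(library(malss))

admitted <- read_protein_table("results/proteins_admitted.tsv")
battery <- ml_test_battery(admitted, n_boot = 2000, seed = 1)
write_ml_report(battery, "results/ml_report.json")

print(as.data.frame(battery), digits = 3)
cat(sprintf("Menzerath's Law not rejected: %s\n",
            isTRUE(attr(battery, "ml_not_rejected"))))
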