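#!/usr/bin/env Rscript
# Stage 2: admission filter and binning.
#
# Applies the 95% continuous-coverage rule to the simulated records, then
# pools the admitted proteins into bins by secondary-structure count.

suppressPackageStartupMessages(library(malss))

proteins <- read_protein_table("results/proteins.tsv")
coverage <- read_coverage_table("results/coverage.tsv")
admitted <- filter_by_coverage(proteins, coverage)
cat(sprintf("funnel: %d proteins in -> %d admitted (%d fail the 95%% rule)\n",
            attr(admitted, "n_input"), attr(admitted, "n_admitted"),
            attr(admitted, "n_input") - attr(admitted, "n_admitted")))

write_protein_table(admitted, "results/proteins_admitted.tsv")
bins <- make_bins(admitted)
write_bins(bins, "results/bins.tsv")
cat(sprintf("%d bins; pooled means span [%.1f, %.1f] AA over x in [%d, %d]\n",
            nrow(bins), min(bins$y_bar), max(bins$y_bar),
            min(bins$x), max(bins$x)))
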