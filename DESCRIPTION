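Package: malss
Title: Menzerath-Altmann Law Analysis of Protein Secondary Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether protein secondary structures (alpha-helices and
    beta-strands, measured in amino acids) obey the Menzerath-Altmann law:
    the more secondary structures a protein contains, the shorter they are
    on average. Provides a coverage-based admission filter for structure
    records, pooled binning by secondary-structure count, a correlation
    battery (Pearson, Spearman, correlation ratio eta), weighted nonlinear
    least-squares fitting of five Menzerath-Altmann formulas by
    Gauss-Newton with model comparison via residual standard error and AIC,
    studentized-residual outlier detection, exact hypergeometric enrichment
    of outlier annotations with Bonferroni correction, and a synthetic-data
    generator for end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm
Config/testthat/edition: 3
RoxygenNote: 7.3.3
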