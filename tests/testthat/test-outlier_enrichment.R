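test_that("studentized residuals reproduce the textbook OLS formula", {
  set.seed(1)
  xs <- 1:6
  segs <- lapply(xs, function(x) pmax(1L, as.integer(round(rnorm(x, 7 + 11 / x, 2)))))
  pr <- protein_records(paste0("P", xs), rep(1000L, 6), segments = segs)
  fit <- fit_nwls(4, make_bins(pr), weighted = FALSE)
  rep <- studentized_residuals(fit, pr)
  # each protein is its own unit-weight bin, so the weighted-fit leverages
  # and global sigma reduce to the hat matrix of the OLS regression on 1/x
  ref <- stats::rstandard(stats::lm(pr$y ~ I(1 / pr$x)))
  expect_equal(rep$stud_resid, unname(ref), tolerance = 1e-10)
  expect_equal(rep$leverage, unname(stats::hatvalues(stats::lm(pr$y ~ I(1 / pr$x)))),
               tolerance = 1e-10)
})

test_that("a protein exactly on the curve has zero studentized residual", {
  bins <- simulate_bins(4, c(a = 11, d = 7), n_bins = 30, sigma = 4, seed = 2)
  fit <- fit_nwls(4, bins)
  xs <- c(5L, 1L, 2L, 8L, 20L, 40L)
  pr <- protein_records(paste0("P", seq_along(xs)), rep(2000L, length(xs)),
                        segments = lapply(xs, function(x) rep(9L, x)))
  set.seed(3)
  pr$y <- eval_model(4, fit$estimates, xs) + c(0, rnorm(length(xs) - 1, sd = 0.5))
  rep <- studentized_residuals(fit, pr)
  expect_equal(rep$stud_resid[1], 0, tolerance = 1e-10)
  expect_equal(rep$flag[1], "none")
})

test_that("planted 3x-inflated proteins are flagged above the model", {
  hits <- vapply(1:30, function(s) {
    cfg <- synthetic_config(n_proteins = 1200, outlier_fraction = 0.01,
                            outlier_inflation = 3, seed = 400 + s)
    ds <- generate_dataset(cfg)
    fit <- fit_nwls(4, make_bins(ds), restarts = 2)
    rep <- studentized_residuals(fit, ds)
    planted <- ds$planted_outlier
    mean(rep$flag[planted] == "above")
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("outlier partition applies asymmetric thresholds deterministically", {
  rep <- tibble::tibble(
    accession = c("A", "B", "C", "D"), x = 1:4, y = 1:4, y_hat = 1:4,
    resid = 0, leverage = 0, stud_resid = c(3.5, 2.9, -1.9, -2.5),
    flag = c("above", "none", "none", "below")
  )
  out <- detect_outliers(rep, upper = 3, lower = -2)
  expect_equal(out$above$accession, "A")
  expect_equal(out$below$accession, "D")
  symm <- detect_outliers(rep, upper = 3, lower = -3)
  expect_equal(symm$above$accession, "A")
  expect_equal(nrow(symm$below), 0L)
  empty <- detect_outliers(rep[0, ])
  expect_equal(nrow(empty$above), 0L)
  expect_equal(nrow(empty$below), 0L)
  # raising the upper threshold never enlarges the above set
  for (u in c(2, 2.5, 3, 3.6)) {
    a1 <- detect_outliers(rep, upper = u)$above$accession
    a2 <- detect_outliers(rep, upper = u + 0.5)$above$accession
    expect_true(all(a2 %in% a1))
  }
})

test_that("hypergeometric tail is exact against full enumeration and phyper", {
  expect_equal(hypergeom_tail(2, 3, 4, 10), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_tail(0, 3, 4, 10), 1)
  expect_equal(hypergeom_tail(4, 3, 4, 10), 0)  # x > n infeasible

  for (N in c(5, 8, 12)) {
    for (M in 0:N) {
      for (n in 0:N) {
        for (x in 0:min(n, M)) {
          expect_equal(hypergeom_tail(x, n, M, N),
                       hyper_tail_enum(x, n, M, N), tolerance = 1e-10)
        }
      }
    }
  }

  # large-count agreement with the distribution implementation in stats
  expect_equal(hypergeom_tail(23, 100, 168, 4728),
               phyper(22, 168, 4728 - 168, 100, lower.tail = FALSE),
               tolerance = 1e-12)
  # non-increasing in x
  p <- vapply(0:30, hypergeom_tail, numeric(1), n = 100, M = 168, N = 4728)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(hypergeom_tail(1, 5, 3, 2), "n <= N")
})

test_that("Bonferroni correction divides the level by the category count", {
  expect_equal(bonferroni(0.05, 211), 0.05 / 211)
  expect_equal(round(bonferroni(0.05, 211), 10), 0.0002369668)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(1.0, 4), 0.25)
  expect_error(bonferroni(0, 5), "alpha")
  expect_error(bonferroni(0.05, 0), "positive integer")
})

test_that("category enrichment counts, corrects and orders as specified", {
  ds <- tibble::tibble(
    accession = sprintf("D%02d", 1:20),
    locations = c(rep(list("membrane"), 6), rep(list("cytoplasm"), 10),
                  rep(list(c("membrane", "nucleus")), 2), rep(list(character(0)), 2))
  )
  out5 <- ds[c(1:4, 7), ]  # 4 membrane of 5 outliers vs 8 of 20 overall
  enr <- enrich_categories(out5, ds, alpha = 0.05)
  expect_equal(nrow(enr), 3L)  # three distinct categories -> c = 3
  expect_equal(enr$alpha_corrected[1], 0.05 / 3)
  mem <- enr[enr$category == "membrane", ]
  expect_equal(mem$M, 8L)
  expect_equal(mem$x, 4L)
  expect_equal(mem$p_value, hypergeom_tail(4, 5, 8, 20))
  expect_equal(mem$direction, "over")
  # absent category: x = 0 gives p = 1, never significant
  nuc <- enr[enr$category == "nucleus", ]
  expect_equal(nuc$x, 0L)
  expect_equal(nuc$p_value, 1)
  expect_false(nuc$significant)
  expect_true(!is.unsorted(enr$p_value))
  # annotated-subset percentage uses only labelled proteins (18 of 20)
  expect_equal(mem$M_pct_dataset, 100 * 8 / 20)
  expect_equal(mem$M_pct_annotated, 100 * 8 / 18)

  expect_warning(e0 <- enrich_categories(ds[0, ], ds), "empty outlier set")
  expect_equal(nrow(e0), 0L)
  expect_error(enrich_categories(tibble::tibble(accession = "ZZ", locations = list("a")), ds),
               "subset")
})
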