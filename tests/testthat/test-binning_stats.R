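test_that("bins pool segments, not protein means, and conserve residues", {
  pr1 <- protein_records("P1", 100L, list(c(29L, 15L, 20L)))
  b1 <- make_bins(pr1)
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$x, 3L)
  expect_equal(b1$n, 1L)
  expect_equal(b1$y_bar, 64 / 3)

  # pooled mean (24 residues / 4 segments), not mean of means (6 vs (10+2)/2)
  pr2 <- protein_records(c("A", "B"), c(60L, 30L),
                         list(c(10L, 10L), c(2L, 2L)))
  b2 <- make_bins(pr2)
  expect_equal(b2$x, 2L)
  expect_equal(b2$n, 2L)
  expect_equal(b2$total_segments, 4L)
  expect_equal(b2$total_residues, 24)
  expect_equal(b2$y_bar, 6)
  expect_equal(b2$weight, 4)

  cfg <- synthetic_config(n_proteins = 300, seed = 5)
  ds <- generate_dataset(cfg)
  bins <- make_bins(ds)
  expect_true(!is.unsorted(bins$x, strictly = TRUE))
  expect_equal(sum(bins$total_residues),
               sum(vapply(ds$seg_lengths, sum, numeric(1))))
  # weight = n * x equals the number of segments pooled into each bin
  expect_equal(bins$weight, as.numeric(bins$total_segments))
  expect_error(make_bins(ds[0, ]), "non-empty")
})

test_that("Pearson test handles exact linearity and matches a permutation null", {
  x <- c(1, 2, 3, 4, 5)
  r_perfect <- pearson_test(x, 2 * x)
  expect_equal(r_perfect$estimate, 1)
  r_inv <- pearson_test(x, -x)
  expect_equal(r_inv$estimate, -1)
  expect_lt(r_inv$p_value, 1e-6)

  set.seed(20)
  xr <- rnorm(1000)
  yr <- sample(xr)  # independent permutation
  r0 <- pearson_test(xr, yr)
  expect_lt(abs(r0$estimate), 0.1)
  expect_gt(r0$p_value, 0.05)
  # permutation oracle: observed r is unremarkable under reshuffling
  perm <- replicate(500, cor(xr, sample(yr)))
  expect_gt(mean(abs(perm) >= abs(r0$estimate)), 0.01)

  expect_error(pearson_test(x, rep(2, 5)), "zero variance")
})

test_that("Spearman test is rank-based and tie-aware", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_test(x, exp(-x))$estimate, -1)
  sq <- spearman_test(x, x^2)
  expect_equal(sq$estimate, 1)
  expect_lt(pearson_test(x, exp(x))$estimate, 1)

  # midrank formula evaluated directly as the oracle for tied data
  xt <- c(1, 1, 2); yt <- c(3, 3, 1)
  brute <- cor(rank(xt), rank(yt))
  expect_equal(spearman_test(xt, yt)$estimate, brute, tolerance = 1e-12)

  # invariance under strictly monotone transforms of y
  set.seed(21)
  xs <- rnorm(40); ys <- rnorm(40)
  s0 <- spearman_test(xs, ys)$estimate
  expect_equal(spearman_test(xs, exp(ys))$estimate, s0)
  expect_equal(spearman_test(xs, ys^3)$estimate, s0)
})

test_that("correlation ratio matches the hand-computed sums of squares", {
  # groups {1:(2,4), 2:(6,8)}: SSB = 16, SST = 20 -> eta = sqrt(0.8)
  vals <- c(2, 4, 6, 8)
  grp <- c(1, 1, 2, 2)
  eta <- correlation_ratio(vals, grp, n_boot = 200, seed = 1)
  expect_equal(eta$estimate, sqrt(0.8), tolerance = 1e-12)

  # p-value agrees with the one-way ANOVA F test
  av <- summary(stats::aov(vals ~ factor(grp)))[[1]]
  expect_equal(eta$p_value, av[["Pr(>F)"]][1], tolerance = 1e-10)

  expect_equal(correlation_ratio(c(1, 3, 1, 3), c(1, 1, 2, 2),
                                 n_boot = 50, seed = 1)$estimate, 0)
  expect_equal(correlation_ratio(c(2, 2, 5, 5), c(1, 1, 2, 2),
                                 n_boot = 50, seed = 1)$estimate, 1)
  expect_error(correlation_ratio(rep(3, 6), rep(1:2, 3), n_boot = 10),
               "zero total variance")
})

test_that("battery returns the five statistics with coherent CIs and verdict", {
  cfg <- synthetic_config(n_proteins = 1500, seed = 9)
  ds <- generate_dataset(cfg)
  bat <- ml_test_battery(ds, n_boot = 300, seed = 2)
  expect_equal(nrow(bat), 5L)
  expect_setequal(unique(bat$statistic), c("pearson_r", "spearman_rho", "eta"))
  expect_equal(sum(bat$data == "binned"), 2L)
  expect_true(all(bat$ci_low <= bat$estimate + 1e-12))
  expect_true(all(bat$ci_high >= bat$estimate - 1e-12))
  expect_true(all(abs(bat$estimate[bat$statistic != "eta"]) <= 1))
  eta_row <- bat[bat$statistic == "eta", ]
  expect_gte(eta_row$estimate, 0)
  expect_lte(eta_row$estimate, 1)
  expect_true(isTRUE(attr(bat, "ml_not_rejected")))

  flat <- protein_records(paste0("Q", 1:6), rep(100L, 6),
                          segments = rep(list(c(5L, 5L)), 6))
  flat$x <- 1:6  # distinct x, constant y
  expect_error(ml_test_battery(flat), "zero variance")
})

test_that("eta squared dominates squared Pearson r when grouping by x", {
  set.seed(33)
  for (i in 1:10) {
    x <- sample(1:8, 120, replace = TRUE)
    y <- 10 / x + rnorm(120, sd = 0.8)
    eta <- correlation_ratio(y, x, n_boot = 10, seed = i)$estimate
    r <- pearson_test(as.numeric(x), y)$estimate
    expect_gte(eta^2, r^2 - 1e-12)
  }
})
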