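test_that("model registry evaluates the five formulas and their nestings", {
  expect_equal(eval_model(2, c(a = 1, b = 0), c(1, 7, 50)), rep(1, 3))
  x <- 1:142
  expect_equal(eval_model(2, c(a = 5.3, b = -1), x),
               eval_model(3, c(a = 5.3), x), tolerance = 1e-14)
  # published model-4 parameters: 6.99 + 11.008 / x
  expect_equal(eval_model(4, c(a = 11.008, d = 6.99), 1), 17.998, tolerance = 1e-12)
  expect_equal(eval_model(4, c(a = 11.008, d = 6.99), 1e6), 6.99, tolerance = 1e-4)
  # model 1 with c = 0 collapses to model 2
  expect_equal(eval_model(1, c(a = 9, b = -0.3, c = 0), x),
               eval_model(2, c(a = 9, b = -0.3), x))
  expect_error(eval_model(2, c(a = 1), 3), "params")
  expect_error(eval_model(2, c(a = 1, b = 1), 0), ">= 1")
})

test_that("the empirical formula passes its consistency gate", {
  expect_true(check_formula5_gate())
  y <- eval_model(5, c(a = 207.738, d = 46.938), 1:142)
  expect_true(all(diff(y) < 0))
  expect_lt(abs(y[142] - sqrt(46.938)), 0.15)
})

test_that("analytic Jacobians match central finite differences", {
  set.seed(4)
  x <- c(1, 2, 5, 17, 60, 142)
  params <- list(
    c(a = 12.3, b = -0.18, c = 0.003),
    c(a = 10.7, b = -0.11),
    c(a = 75.2),
    c(a = 11.0, d = 6.99),
    c(a = 207.7, d = 46.9)
  )
  for (m in 1:5) {
    model <- mal_model(m)
    p <- params[[m]]
    J <- model$jacobian(as.list(p), x)
    for (j in seq_along(p)) {
      h <- 1e-6 * max(abs(p[j]), 1)
      pp <- p; pp[j] <- pp[j] + h
      pm <- p; pm[j] <- pm[j] - h
      num <- (model$predict(as.list(pp), x) - model$predict(as.list(pm), x)) / (2 * h)
      expect_equal(unname(J[, j]), num, tolerance = 1e-6)
    }
  }
})

test_that("noiseless data are recovered exactly and the closed form matches", {
  bins <- simulate_bins(4, c(a = 11, d = 7), n_bins = 40, sigma = 0)
  fit <- fit_nwls(4, bins, restarts = 3)
  expect_lt(abs(fit$estimates[["a"]] - 11), 1e-6)
  expect_lt(abs(fit$estimates[["d"]] - 7), 1e-6)
  expect_lt(fit$s, 1e-8)
  expect_true(fit$converged)

  # model 3: weighted normal-equation closed form, any bins
  nb <- simulate_bins(3, c(a = 60), n_bins = 50, sigma = 6, seed = 2)
  f3 <- fit_nwls(3, nb)
  a_star <- sum(nb$weight * nb$y_bar / nb$x) / sum(nb$weight / nb$x^2)
  expect_lt(abs(f3$estimates[["a"]] - a_star), 1e-8)
})

test_that("Gauss-Newton fit agrees with the exhaustive grid search for the power law", {
  bins <- simulate_bins(2, c(a = 10.7, b = -0.11), n_bins = 20, sigma = 4, seed = 3)
  fit <- fit_nwls(2, bins)
  oracle <- grid_fit_model2(bins)
  expect_lt(abs(fit$estimates[["a"]] - oracle[["a"]]), 1e-3)
  expect_lt(abs(fit$estimates[["b"]] - oracle[["b"]]), 1e-3)
})

test_that("fit matches the reference nls implementation, weighted and not", {
  skip_if_not_installed("minpack.lm")
  bins <- simulate_bins(1, c(a = 12.3, b = -0.18, c = 0.003),
                        n_bins = 80, sigma = 8, seed = 6)
  for (weighted in c(TRUE, FALSE)) {
    w <- if (weighted) bins$weight else rep(1, nrow(bins))
    ours <- fit_nwls(1, bins, weighted = weighted)
    ref <- minpack.lm::nlsLM(y_bar ~ a * x^b * exp(cc * x), data = bins,
                             weights = w,
                             start = list(a = 10, b = -0.1, cc = 0))
    expect_equal(unname(ours$estimates),
                 unname(coef(ref)), tolerance = 1e-5)
    expect_equal(unname(ours$std_errors),
                 unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
    expect_equal(ours$s, summary(ref)$sigma, tolerance = 1e-6)
  }
})

test_that("residual standard error follows its defining formula", {
  expect_equal(residual_standard_error(c(1, -1), n_params = 1), sqrt(2))
  expect_equal(residual_standard_error(c(1, -1), weights = c(0.5, 0.5), n_params = 1),
               sqrt(2) / sqrt(2))
  expect_error(residual_standard_error(c(1, -1), n_params = 2), "degrees of freedom")

  bins <- simulate_bins(4, c(a = 11, d = 7), n_bins = 30, sigma = 5, seed = 8)
  fit <- fit_nwls(4, bins)
  expect_equal(residual_standard_error(fit),
               sqrt(fit$objective / (fit$k - fit$p)))
  expect_equal(fit$s, residual_standard_error(fit))
})

test_that("AIC penalises a useless extra parameter by about 2", {
  bins <- simulate_bins(3, c(a = 60), n_bins = 100, sigma = 2, seed = 10)
  f3 <- fit_nwls(3, bins)
  f4 <- fit_nwls(4, bins)  # d is superfluous on model-3 data
  expect_lte(f4$objective, f3$objective + 1e-9)
  diff <- mal_aic(f4) - mal_aic(f3)
  expect_gt(diff, -0.5)
  expect_lt(diff, 4)
})

test_that("Wald test of b = -1 follows its arithmetic and calibrates under the null", {
  bins <- simulate_bins(2, c(a = 10, b = -0.5), n_bins = 40, sigma = 3, seed = 12)
  fit <- fit_nwls(2, bins)
  fit$estimates[["b"]] <- -1  # exact null value
  expect_equal(test_b_equals_minus1(fit)$z, 0)
  expect_equal(test_b_equals_minus1(fit)$p_value, 1)

  # published power-law row: b = -0.108 (0.007) decisively rejects b = -1
  fit$estimates[["b"]] <- -0.108
  fit$std_errors[["b"]] <- 0.007
  tb <- test_b_equals_minus1(fit)
  expect_gt(abs(tb$z), 120)
  expect_lt(tb$p_value, 1e-100)

  # type-I error on model-3 data (true b = -1): rejects in about 5% of runs
  rejections <- vapply(1:60, function(s) {
    b <- simulate_bins(3, c(a = 70), n_bins = 60, sigma = 5, seed = 100 + s)
    test_b_equals_minus1(fit_nwls(2, b, restarts = 2))$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.15)
})

test_that("model comparison ranks by s and AIC and rejects mixed weighting", {
  bins <- simulate_bins(4, c(a = 11, d = 7), n_bins = 60, sigma = 8, seed = 14)
  fits <- lapply(1:5, fit_nwls, bins = bins)
  cmp <- compare_models(fits)
  expect_equal(cmp$model_id[order(cmp$rank_s)], cmp$model_id[order(cmp$s)])
  expect_equal(cmp$model_id[order(cmp$rank_aic)], cmp$model_id[order(cmp$aic)])
  # model-4 truth: its generalisation beats the pure reciprocal
  expect_lt(cmp$s[cmp$model_id == 4], cmp$s[cmp$model_id == 3])

  fits[[2]] <- fit_nwls(2, bins, weighted = FALSE)
  expect_error(compare_models(fits), "mix")

  # nestedness at the optimum: extra freedom cannot worsen the objective
  f2 <- fit_nwls(2, bins); f3 <- fit_nwls(3, bins); f4 <- fit_nwls(4, bins)
  expect_lte(f2$objective, f3$objective + 1e-9)
  expect_lte(f4$objective, f3$objective + 1e-9)

  # identical fits tie
  cmp2 <- compare_models(list(f3, f3))
  expect_equal(cmp2$rank_s, c(1L, 1L))
})

test_that("weights are immaterial when all bins share the same weight", {
  bins <- simulate_bins(2, c(a = 12, b = -0.2), n_bins = 30, sigma = 3, seed = 16)
  bins$weight <- rep(50, nrow(bins))
  fw <- fit_nwls(2, bins, weighted = TRUE)
  fu <- fit_nwls(2, bins, weighted = FALSE)
  expect_equal(fw$estimates, fu$estimates, tolerance = 1e-8)
})

test_that("standard errors shrink roughly as 1/sqrt(replication)", {
  base <- simulate_bins(4, c(a = 11, d = 7), n_bins = 50, sigma = 6, seed = 18)
  se_at <- function(mult) {
    b <- base
    b$weight <- b$weight * mult
    set.seed(19)
    b$y_bar <- eval_model(4, c(a = 11, d = 7), b$x) +
      rnorm(nrow(b), sd = 6 / sqrt(b$weight))
    fit_nwls(4, b)$std_errors[["a"]]
  }
  ratio <- se_at(1) / se_at(16)
  expect_gt(ratio, 2)   # ideal factor 4
  expect_lt(ratio, 8)
})
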