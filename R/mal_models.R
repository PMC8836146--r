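#' The Menzerath-Altmann model registry
#'
#' Five parametric forms relate a protein's secondary-structure count `x`
#' to the expected average segment length `y_bar` (amino acids):
#' \describe{
#'   \item{1}{`y = a * x^b * exp(c*x)` — the full classical form}
#'   \item{2}{`y = a * x^b` — the power law}
#'   \item{3}{`y = a / x` — the power law with `b` fixed at -1}
#'   \item{4}{`y = d + a / x` — model 3 shifted by a minimal segment length `d`}
#'   \item{5}{`y = sqrt(d + a / x)` — an empirical form that decays to the
#'     asymptote `sqrt(d)`; see [check_formula5_gate()]}
#' }
#' Model 3 is nested in model 2 (`b = -1`) and in model 4 (`d = 0`).
#'
#' @param model_id Integer 1..5.
#' @return A `mal_model` object: `id`, `param_names`, `formula` (display
#'   string), `predict(params, x)`, `jacobian(params, x)` (matrix with one
#'   column per parameter), and `init(x, y, w)` returning heuristic starting
#'   values.
#' @export
mal_model <- function(model_id) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:5) stop("`model_id` must be in 1..5", call. = FALSE)
  loglog_init <- function(x, y, w) {
    fit <- stats::lm.wfit(cbind(1, log(x)), log(pmax(y, 1e-9)), w)
    c(a = exp(fit$coefficients[[1]]), b = fit$coefficients[[2]])
  }
  specs <- list(
    list(
      id = 1L, param_names = c("a", "b", "c"), formula = "y = a * x^b * exp(c*x)",
      predict = function(p, x) p[["a"]] * x^p[["b"]] * exp(p[["c"]] * x),
      jacobian = function(p, x) {
        f <- p[["a"]] * x^p[["b"]] * exp(p[["c"]] * x)
        cbind(a = f / p[["a"]], b = f * log(x), c = f * x)
      },
      init = function(x, y, w) c(loglog_init(x, y, w), c = 0)
    ),
    list(
      id = 2L, param_names = c("a", "b"), formula = "y = a * x^b",
      predict = function(p, x) p[["a"]] * x^p[["b"]],
      jacobian = function(p, x) {
        f <- p[["a"]] * x^p[["b"]]
        cbind(a = x^p[["b"]], b = f * log(x))
      },
      init = loglog_init
    ),
    list(
      id = 3L, param_names = "a", formula = "y = a / x",
      predict = function(p, x) p[["a"]] / x,
      jacobian = function(p, x) cbind(a = 1 / x),
      init = function(x, y, w) c(a = sum(w * y / x) / sum(w / x^2))
    ),
    list(
      id = 4L, param_names = c("a", "d"), formula = "y = d + a / x",
      predict = function(p, x) p[["d"]] + p[["a"]] / x,
      jacobian = function(p, x) cbind(a = 1 / x, d = rep(1, length(x))),
      init = function(x, y, w) {
        fit <- stats::lm.wfit(cbind(1, 1 / x), y, w)
        c(a = fit$coefficients[[2]], d = fit$coefficients[[1]])
      }
    ),
    list(
      id = 5L, param_names = c("a", "d"), formula = "y = sqrt(d + a / x)",
      predict = function(p, x) sqrt(p[["d"]] + p[["a"]] / x),
      jacobian = function(p, x) {
        f <- sqrt(p[["d"]] + p[["a"]] / x)
        cbind(a = 1 / (2 * f * x), d = 1 / (2 * f))
      },
      init = function(x, y, w) {
        fit <- stats::lm.wfit(cbind(1, 1 / x), y^2, w)
        c(a = fit$coefficients[[2]], d = max(fit$coefficients[[1]], 1e-3))
      }
    )
  )
  out <- specs[[model_id]]
  class(out) <- "mal_model"
  out
}

#' Evaluate a MAL model
#'
#' @param model A `mal_model` object or an id in 1..5.
#' @param params Named numeric vector covering the model's `param_names`.
#' @param x Positive numeric vector of secondary-structure counts.
#' @return Predicted average segment lengths.
#' @examples
#' eval_model(4, c(a = 11.008, d = 6.99), 1) # 17.998
#' @export
eval_model <- function(model, params, x) {
  if (!inherits(model, "mal_model")) model <- mal_model(model)
  if (!all(model$param_names %in% names(params))) {
    stop("`params` must name ", paste(model$param_names, collapse = ", "), call. = FALSE)
  }
  if (any(x < 1)) stop("`x` must be >= 1", call. = FALSE)
  y <- model$predict(as.list(params), x)
  if (any(!is.finite(y))) stop("model prediction is not finite", call. = FALSE)
  y
}

#' Consistency gate for the empirical formula (model 5)
#'
#' Model 5's closed form decays from `sqrt(d + a)` at `x = 1` to the
#' asymptote `sqrt(d)`. With the published reference parameters
#' (a = 207.738, d = 46.938) its predictions over `x` in 1..142 must be
#' strictly decreasing, span approximately the observed binned range of mean
#' segment lengths (about 4.4 to 15.6 amino acids, allowing the same modest
#' overshoot at `x = 1` that model 4 shows), and approach model 4's minimal
#' segment length of about 7 amino acids at large `x`. The gate guards the
#' registry against regressions in the functional form.
#'
#' @return `TRUE` invisibly; errors if the gate fails.
#' @export
check_formula5_gate <- function() {
  p <- c(a = 207.738, d = 46.938)
  x <- 1:142
  y <- eval_model(5, p, x)
  if (any(diff(y) >= 0)) stop("formula-5 gate: predictions not strictly decreasing")
  if (y[1] < 4.4 || y[1] > 15.6 * 1.15) {
    stop("formula-5 gate: prediction at x = 1 outside the plausible binned range")
  }
  if (min(y) < 4.4 * 0.85) stop("formula-5 gate: predictions fall below the binned range")
  if (abs(y[142] - 6.99) > 0.5) {
    stop("formula-5 gate: large-x predictions do not approach the ~7 AA asymptote")
  }
  invisible(TRUE)
}

# Internal: weighted residual sum of squares; Inf for inadmissible params.
nwls_objective <- function(model, theta, x, y, w) {
  f <- tryCatch(model$predict(as.list(theta), x), error = function(e) NULL)
  if (is.null(f) || any(!is.finite(f))) return(Inf)
  sum(w * (y - f)^2)
}

# Internal: one Gauss-Newton run with Levenberg-Marquardt damping as a
# safeguard (same stationary point; damping -> 0 near the optimum).
gauss_newton <- function(model, theta, x, y, w, max_iter, tol) {
  S <- nwls_objective(model, theta, x, y, w)
  if (!is.finite(S)) return(list(theta = theta, S = Inf, converged = FALSE, iter = 0L))
  lambda <- 1e-8
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    f <- model$predict(as.list(theta), x)
    J <- model$jacobian(as.list(theta), x)
    r <- y - f
    JtWJ <- crossprod(J, w * J)
    JtWr <- crossprod(J, w * r)
    accepted <- FALSE
    for (try in 1:40) {
      A <- JtWJ + lambda * diag(pmax(diag(JtWJ), 1e-12), nrow(JtWJ))
      delta <- tryCatch(solve(A, JtWr), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- theta + as.numeric(delta)
        names(cand) <- names(theta)
        Sc <- nwls_objective(model, cand, x, y, w)
        if (is.finite(Sc) && Sc <= S) {
          rel <- (S - Sc) / (Sc + 1e-300)
          theta <- cand
          S <- Sc
          lambda <- max(lambda / 8, 1e-12)
          accepted <- TRUE
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 8
      if (lambda > 1e12) break
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    if (converged) break
  }
  list(theta = theta, S = S, converged = converged, iter = iter)
}

#' Fit a MAL model to bins by (weighted) nonlinear least squares
#'
#' Minimises the weighted residual sum of squares
#' \eqn{\sum_j w_j (\bar y_j - \hat y_j)^2} over the model parameters with a
#' Gauss-Newton iteration (Levenberg-Marquardt damping as a safeguard),
#' using analytic Jacobians. Weights are the bin weights `w = n * x`; pass
#' `weighted = FALSE` for unit weights. Starting values come from
#' model-specific heuristics (log-log or linearised regressions) plus seeded
#' random restarts; the best objective wins. Log-linearising the model
#' before fitting is deliberately not done.
#'
#' Standard errors are the square roots of the diagonal of
#' \eqn{s^2 (J^T W J)^{-1}} at the optimum, with `s` the residual standard
#' error (see [residual_standard_error()]).
#'
#' @param model A `mal_model` or id 1..5.
#' @param bins A bin tibble from [make_bins()] (needs `x`, `y_bar`, `weight`).
#' @param weighted Use bin weights `n * x` (default) or unit weights.
#' @param init Optional named starting values; replaces the heuristic start.
#' @param restarts Number of seeded random restarts around the start (default 10).
#' @param seed Integer seed for the restarts.
#' @param max_iter Iteration cap per start (default 200).
#' @param tol Relative objective-change convergence tolerance (default 1e-10).
#' @return A `mal_fit` object: estimates, std_errors, covariance, k (bins),
#'   p (free parameters), s, aic, log_lik, weighted, converged, n_iterations,
#'   and a per-bin residual table.
#' @export
fit_nwls <- function(model, bins, weighted = TRUE, init = NULL,
                     restarts = 10L, seed = 1L, max_iter = 200L, tol = 1e-10) {
  if (!inherits(model, "mal_model")) model <- mal_model(model)
  x <- as.numeric(bins$x)
  y <- as.numeric(bins$y_bar)
  if (any(y <= 0)) stop("all bin means must be positive", call. = FALSE)
  k <- length(x)
  p <- length(model$param_names)
  if (k < p + 1) stop("need at least p + 1 = ", p + 1, " bins", call. = FALSE)
  w <- if (weighted) as.numeric(bins$weight) else rep(1, k)

  start <- if (!is.null(init)) {
    if (!all(model$param_names %in% names(init))) {
      stop("`init` must name ", paste(model$param_names, collapse = ", "), call. = FALSE)
    }
    init[model$param_names]
  } else {
    st <- model$init(x, y, w)
    stats::setNames(as.numeric(st), model$param_names)
  }
  starts <- list(start)
  if (restarts > 0) {
    starts <- c(starts, withr_seed(seed, {
      lapply(seq_len(restarts), function(i) {
        start + stats::rnorm(p) * (abs(start) * 0.3 + 0.05)
      })
    }))
  }

  best <- NULL
  for (st in starts) {
    run <- gauss_newton(model, st, x, y, w, max_iter, tol)
    if (is.null(best) || run$S < best$S) best <- run
  }
  if (!is.finite(best$S)) stop("no admissible starting point found", call. = FALSE)

  theta <- best$theta
  f <- model$predict(as.list(theta), x)
  J <- model$jacobian(as.list(theta), x)
  JtWJ <- crossprod(J, w * J)
  qrj <- qr(JtWJ)
  if (qrj$rank < p) stop("rank-deficient Jacobian at the optimum", call. = FALSE)
  cov_unscaled <- solve(JtWJ)
  resid <- y - f
  s <- sqrt(best$S / (k - p))
  covariance <- s^2 * cov_unscaled
  se <- sqrt(diag(covariance))
  names(se) <- model$param_names
  dimnames(covariance) <- list(model$param_names, model$param_names)

  # Gaussian likelihood with per-bin variance sigma^2 / w_j, sigma^2 at its MLE
  sigma2 <- best$S / k
  log_lik <- -k / 2 * log(2 * pi * sigma2) + sum(log(w)) / 2 - k / 2
  aic <- 2 * p - 2 * log_lik

  out <- list(
    model_id = model$id,
    model = model,
    param_names = model$param_names,
    estimates = theta,
    std_errors = se,
    covariance = covariance,
    cov_unscaled = cov_unscaled,
    k = k, p = p,
    objective = best$S,
    s = s,
    log_lik = log_lik,
    aic = aic,
    weighted = weighted,
    converged = best$converged,
    n_iterations = best$iter,
    residuals = tibble::tibble(
      x = bins$x, y_bar = y, fitted = f, weight = w,
      resid = resid, wresid = sqrt(w) * resid
    )
  )
  class(out) <- "mal_fit"
  out
}

#' @export
print.mal_fit <- function(x, ...) {
  cat(sprintf("MAL model %d: %s  [%s]\n", x$model_id, x$model$formula,
              if (x$weighted) "weighted" else "unweighted"))
  est <- sprintf("%s = %.4g (+/- %.4g)", x$param_names, x$estimates, x$std_errors)
  cat(" ", paste(est, collapse = ", "), "\n")
  cat(sprintf("  k = %d bins, s = %.4g, AIC = %.4g, converged = %s (%d iter.)\n",
              x$k, x$s, x$aic, x$converged, x$n_iterations))
  invisible(x)
}

#' Residual standard error of a fit
#'
#' \eqn{s = \sqrt{\sum_j w_j(\bar y_j - \hat y_j)^2 / (k - p)}} over the `k`
#' fitted bins with `p` free parameters.
#'
#' @param fit A `mal_fit`, or a numeric vector of raw residuals.
#' @param weights Weights (vector form only; default unit).
#' @param n_params Number of free parameters (vector form only).
#' @return The residual standard error.
#' @export
residual_standard_error <- function(fit, weights = NULL, n_params = NULL) {
  if (inherits(fit, "mal_fit")) {
    r <- fit$residuals
    k <- nrow(r)
    if (k <= fit$p) stop("k <= p: no residual degrees of freedom", call. = FALSE)
    return(sqrt(sum(r$weight * r$resid^2) / (k - fit$p)))
  }
  r <- as.numeric(fit)
  if (is.null(weights)) weights <- rep(1, length(r))
  if (is.null(n_params)) stop("`n_params` is required for the vector form", call. = FALSE)
  k <- length(r)
  if (k <= n_params) stop("k <= p: no residual degrees of freedom", call. = FALSE)
  sqrt(sum(weights * r^2) / (k - n_params))
}

#' AIC of a MAL fit
#'
#' Computed as `2p - 2 log L` under a Gaussian likelihood whose per-bin
#' variance is `sigma^2 / w_j` with `sigma^2` profiled at its maximum
#' likelihood value; `p` counts the mean-function parameters. Absolute
#' values depend on the likelihood constants, so only differences between
#' models fitted to the same bins with the same weighting are meaningful.
#'
#' @param fit A converged `mal_fit`.
#' @return The AIC (lower is better).
#' @export
mal_aic <- function(fit) {
  if (!inherits(fit, "mal_fit")) stop("`fit` must be a mal_fit", call. = FALSE)
  if (!fit$converged) stop("fit did not converge; AIC not meaningful", call. = FALSE)
  fit$aic
}

#' Wald test of b = -1 in the power-law model
#'
#' If the exponent of model 2 (`y = a x^b`) does not differ significantly
#' from -1, the data are compatible with the pure reciprocal model 3.
#'
#' @param fit A `mal_fit` of model 2.
#' @return A one-row tibble: `b`, `se`, `z` = (b + 1)/se, two-sided
#'   `p_value`.
#' @export
test_b_equals_minus1 <- function(fit) {
  if (!inherits(fit, "mal_fit") || fit$model_id != 2L) {
    stop("`fit` must be a mal_fit of model 2", call. = FALSE)
  }
  b <- fit$estimates[["b"]]
  se <- fit$std_errors[["b"]]
  if (!is.finite(se) || se <= 0) stop("missing standard error for b", call. = FALSE)
  z <- (b + 1) / se
  tibble::tibble(b = b, se = se, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Rank fitted models by residual standard error and AIC
#'
#' @param fits List of `mal_fit` objects over the same bins and weighting.
#' @return A tibble with one row per model: `model_id`, `s`, `aic`,
#'   `rank_s`, `rank_aic` (1 = best, i.e. lowest), sorted best-first by AIC.
#'   Ties share the minimum rank.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) stop("need at least two fits to compare", call. = FALSE)
  if (!all(vapply(fits, inherits, logical(1), "mal_fit"))) {
    stop("all elements must be mal_fit objects", call. = FALSE)
  }
  wt <- vapply(fits, function(f) f$weighted, logical(1))
  if (length(unique(wt)) != 1) {
    stop("invalid comparison: fits mix weighted and unweighted estimation", call. = FALSE)
  }
  xs <- lapply(fits, function(f) f$residuals$x)
  if (!all(vapply(xs, identical, logical(1), xs[[1]]))) {
    stop("invalid comparison: fits use different bins", call. = FALSE)
  }
  out <- tibble::tibble(
    model_id = vapply(fits, function(f) f$model_id, integer(1)),
    s = vapply(fits, function(f) f$s, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1))
  )
  out$rank_s <- rank(out$s, ties.method = "min")
  out$rank_aic <- rank(out$aic, ties.method = "min")
  out[order(out$aic), ]
}

#' Write fit results to JSON
#'
#' @param fits List of `mal_fit` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  payload <- lapply(fits, function(f) {
    list(model_id = f$model_id, formula = f$model$formula,
         estimates = as.list(f$estimates), std_errors = as.list(f$std_errors),
         covariance = unname(apply(f$covariance, 1, as.list)),
         k = f$k, p = f$p, s = f$s, aic = f$aic,
         weighted = f$weighted, converged = f$converged,
         n_iterations = f$n_iterations)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
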