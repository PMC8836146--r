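#' Bin proteins by secondary-structure count
#'
#' All proteins sharing the same segment count `x` form one bin. The bin's
#' average segment length `y_bar` is the pooled mean over every segment of
#' every member protein (total residues in segments / total segments), not
#' the mean of the per-protein means. The fitting weight is `w = n * x`,
#' which for bins of same-`x` proteins equals the number of segments pooled
#' into `y_bar` and is therefore proportional to the inverse sampling
#' variance of `y_bar`.
#'
#' @param proteins A `malss_proteins` tibble (see [protein_records()]).
#' @return A tibble with one row per distinct `x`, ascending: columns `x`,
#'   `n`, `total_segments`, `total_residues`, `y_bar`, `weight`.
#' @export
make_bins <- function(proteins) {
  if (!is.data.frame(proteins) || nrow(proteins) == 0) {
    stop("`proteins` must be a non-empty protein table", call. = FALSE)
  }
  if (any(proteins$x < 1)) stop("all proteins must have x >= 1", call. = FALSE)
  res <- vapply(proteins$seg_lengths, sum, numeric(1))
  g <- factor(proteins$x)  # levels sort numerically for integer x
  sp <- split(res, g)
  x <- as.integer(names(sp))
  n <- vapply(sp, length, integer(1))
  out <- tibble::tibble(
    x = x,
    n = as.integer(n),
    total_segments = as.integer(n * x),
    total_residues = unname(vapply(sp, sum, numeric(1)))
  )
  out$y_bar <- out$total_residues / out$total_segments
  out$weight <- as.numeric(out$total_segments)
  out
}

# Internal: one-row correlation-result tibble.
corr_result <- function(statistic, estimate, ci, p_value, n_points) {
  tibble::tibble(
    statistic = statistic,
    estimate = estimate,
    ci_low = ci[1],
    ci_high = ci[2],
    p_value = p_value,
    n_points = as.integer(n_points)
  )
}

check_corr_input <- function(x, y, min_n = 3) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < min_n) stop("need at least ", min_n, " paired observations", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation, 95% CI by the Fisher z-transform, and a
#' two-sided p-value from the t distribution with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, non-zero variance).
#' @param conf Confidence level, default 0.95.
#' @return A one-row correlation tibble (`statistic = "pearson_r"`).
#' @export
pearson_test <- function(x, y, conf = 0.95) {
  check_corr_input(x, y)
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf)
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA_real_, NA_real_)
  corr_result("pearson_r", unname(ct$estimate), ci, ct$p.value, length(x))
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Rank correlation using midranks for ties. The p-value uses the exact null
#' distribution for n <= 50 without ties and the t approximation otherwise.
#' The 95% CI uses the Fisher z-transform with variance 1.06/(n - 3), the
#' standard large-sample approximation for Spearman's rho.
#'
#' @inheritParams pearson_test
#' @return A one-row correlation tibble (`statistic = "spearman_rho"`).
#' @export
spearman_test <- function(x, y, conf = 0.95) {
  check_corr_input(x, y)
  n <- length(x)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = (n <= 50))
  )
  rho <- unname(ct$estimate)
  if (n > 3 && abs(rho) < 1) {
    z <- atanh(rho)
    hw <- stats::qnorm(1 - (1 - conf) / 2) * sqrt(1.06 / (n - 3))
    ci <- tanh(c(z - hw, z + hw))
  } else {
    ci <- c(rho, rho)  # n <= 3 or |rho| = 1: no usable z-approximation
  }
  corr_result("spearman_rho", rho, ci, ct$p.value, n)
}

#' Correlation ratio eta
#'
#' The correlation ratio measures the strength (not direction) of the
#' dependence of `values` on the grouping: eta^2 is the between-group sum of
#' squares over the total sum of squares from the one-way ANOVA
#' decomposition, and eta its square root, in [0, 1]. The p-value is from
#' the one-way ANOVA F test on the same decomposition. Because no standard
#' closed-form CI exists for eta, the 95% CI is a seeded nonparametric
#' bootstrap (percentile interval) over observations.
#'
#' @param values Numeric response vector (here: per-protein mean segment
#'   lengths).
#' @param groups Grouping vector of the same length (here: segment counts).
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level.
#' @return A one-row correlation tibble (`statistic = "eta"`).
#' @export
correlation_ratio <- function(values, groups, n_boot = 2000, seed = 1L, conf = 0.95) {
  if (length(values) != length(groups)) stop("lengths differ", call. = FALSE)
  g <- as.factor(groups)
  if (nlevels(droplevels(g)) < 2) stop("need at least 2 groups", call. = FALSE)
  if (stats::var(values) == 0) stop("degenerate input: zero total variance", call. = FALSE)

  eta_of <- function(y, g) {
    gm <- mean(y)
    mns <- tapply(y, g, mean)
    ns <- tapply(y, g, length)
    ssb <- sum(ns * (mns - gm)^2)
    sst <- sum((y - gm)^2)
    sqrt(ssb / sst)
  }
  g <- droplevels(g)
  n <- length(values)
  k <- nlevels(g)
  eta <- eta_of(values, g)
  ssb <- eta^2
  # F test on the same decomposition
  f_stat <- (ssb / (k - 1)) / ((1 - ssb) / (n - k))
  p <- stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE)

  ci <- withr_seed(seed, {
    boots <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      gb <- droplevels(g[idx])
      yb <- values[idx]
      if (nlevels(gb) < 2 || stats::var(yb) == 0) NA_real_ else eta_of(yb, gb)
    })
    stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE, names = FALSE)
  })
  corr_result("eta", eta, ci, p, n)
}

# Internal: evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Menzerath's-Law correlation battery
#'
#' Runs the five tests used to decide whether "the more secondary structures,
#' the shorter they are" holds: Pearson, Spearman and the correlation ratio
#' eta on per-protein (x, y) pairs, plus Pearson and Spearman on the binned
#' (x, y_bar) pairs. Menzerath's Law is declared "not rejected" when both
#' Pearson coefficients (per-protein and binned) are negative with p < 0.001.
#'
#' @param proteins A `malss_proteins` tibble with >= 3 proteins over >= 3
#'   distinct segment counts.
#' @param n_boot,seed Passed to [correlation_ratio()] for the eta CI.
#' @return A five-row correlation tibble with an additional `data` column
#'   ("per_protein" or "binned"); the logical attribute `ml_not_rejected`
#'   carries the verdict.
#' @export
ml_test_battery <- function(proteins, n_boot = 2000, seed = 1L) {
  if (nrow(proteins) < 3 || length(unique(proteins$x)) < 3) {
    stop("need at least 3 proteins over at least 3 distinct x values", call. = FALSE)
  }
  x <- as.numeric(proteins$x)
  y <- proteins$y
  bins <- make_bins(proteins)
  per <- dplyr::bind_rows(
    pearson_test(x, y),
    spearman_test(x, y),
    correlation_ratio(y, x, n_boot = n_boot, seed = seed)
  )
  per$data <- "per_protein"
  if (nrow(bins) < 3) stop("need at least 3 bins", call. = FALSE)
  bnd <- dplyr::bind_rows(
    pearson_test(as.numeric(bins$x), bins$y_bar),
    spearman_test(as.numeric(bins$x), bins$y_bar)
  )
  bnd$data <- "binned"
  out <- dplyr::bind_rows(per, bnd)
  r1 <- out[out$statistic == "pearson_r" & out$data == "per_protein", ]
  r2 <- out[out$statistic == "pearson_r" & out$data == "binned", ]
  attr(out, "ml_not_rejected") <-
    r1$estimate < 0 && r1$p_value < 0.001 && r2$estimate < 0 && r2$p_value < 0.001
  out
}

#' Write bins / correlation reports
#'
#' @param bins A bin tibble from [make_bins()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  utils::write.table(bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bins
#' @param battery A correlation tibble from [ml_test_battery()].
#' @export
write_ml_report <- function(battery, path) {
  jsonlite::write_json(
    list(ml_not_rejected = isTRUE(attr(battery, "ml_not_rejected")),
         results = battery),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
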