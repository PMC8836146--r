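#' Internally studentized residuals of proteins around a fitted MAL curve
#'
#' Each protein's raw residual is its mean segment length minus the model
#' prediction at its segment count, `e_i = y_i - yhat(x_i)`. The studentized
#' value divides by an estimate of the residual's standard deviation,
#' `e_i / (sigma_hat * sqrt(1 - h_i))`, so that proteins can be compared on
#' one scale regardless of their weight and position on the x axis:
#' `sigma_hat` is the global dispersion of per-protein residuals around the
#' curve, `sqrt(sum e_i^2 / (n - p))`, and `h_i` the leverage of the
#' protein's bin under the weighted fit (the tangent-plane hat value
#' `w_j J_j (J'WJ)^{-1} J_j'` evaluated at the protein's x). Proteins whose
#' x was not a fitted bin get zero leverage. A leverage of 1 or more makes
#' the studentized value undefined; such records get `NA` with a warning.
#'
#' Flags: `above` when the studentized residual exceeds `upper` (default +3),
#' `below` when it falls under `lower` (default -2, the deliberately
#' asymmetric threshold for proteins under the curve), otherwise `none`.
#'
#' @param fit A converged `mal_fit`.
#' @param proteins A `malss_proteins` tibble.
#' @param upper,lower Studentization thresholds.
#' @return An outlier-report tibble: `accession`, `x`, `y`, `y_hat`, `resid`,
#'   `leverage`, `stud_resid`, `flag`; attributes `sigma_hat`, `upper`,
#'   `lower`.
#' @export
studentized_residuals <- function(fit, proteins, upper = 3, lower = -2) {
  if (!inherits(fit, "mal_fit")) stop("`fit` must be a mal_fit", call. = FALSE)
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  x <- as.numeric(proteins$x)
  y <- proteins$y
  yhat <- eval_model(fit$model, fit$estimates, x)
  e <- y - yhat
  n <- length(e)
  if (n <= fit$p) stop("need more proteins than model parameters", call. = FALSE)
  sigma_hat <- sqrt(sum(e^2) / (n - fit$p))

  # bin-level leverage at each protein's x
  bin_w <- stats::setNames(fit$residuals$weight, fit$residuals$x)
  w_i <- unname(bin_w[as.character(proteins$x)])
  w_i[is.na(w_i)] <- 0
  J <- fit$model$jacobian(as.list(fit$estimates), x)
  h <- unname(w_i * rowSums((J %*% fit$cov_unscaled) * J))
  bad <- h >= 1
  if (any(bad)) {
    warning(sum(bad), " record(s) with leverage >= 1; studentized residual set to NA")
  }
  stud <- ifelse(bad, NA_real_, e / (sigma_hat * sqrt(pmax(1 - h, 0))))
  flag <- rep("none", n)
  flag[!is.na(stud) & stud > upper] <- "above"
  flag[!is.na(stud) & stud < lower] <- "below"
  out <- tibble::tibble(
    accession = proteins$accession, x = proteins$x, y = y,
    y_hat = yhat, resid = e, leverage = as.numeric(h),
    stud_resid = stud, flag = flag
  )
  attr(out, "sigma_hat") <- sigma_hat
  attr(out, "upper") <- upper
  attr(out, "lower") <- lower
  out
}

#' Partition an outlier report into above- and below-model outliers
#'
#' @param report Output of [studentized_residuals()].
#' @param upper,lower Thresholds (default +3 / -2); may differ from the
#'   flags stored in the report, which are recomputed here.
#' @return `list(above = , below = )`, each a tibble ordered by decreasing
#'   absolute studentized residual.
#' @export
detect_outliers <- function(report, upper = 3, lower = -2) {
  st <- report$stud_resid
  above <- report[!is.na(st) & st > upper, , drop = FALSE]
  below <- report[!is.na(st) & st < lower, , drop = FALSE]
  above <- above[order(-abs(above$stud_resid)), , drop = FALSE]
  below <- below[order(-abs(below$stud_resid)), , drop = FALSE]
  list(above = above, below = below)
}

#' Exact upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge x)} when drawing `n` items without replacement from `N`
#' items of which `M` carry the feature: the probability that at least `x`
#' of the drawn items carry it. Terms are accumulated in log space from
#' `lchoose` for numerical safety; `x <= 0` gives 1 and infeasible
#' `x > min(n, M)` gives 0.
#'
#' @param x Observed feature count among the drawn items.
#' @param n Number of drawn items (here: outliers).
#' @param M Feature count in the population.
#' @param N Population size.
#' @return The exact tail probability in [0, 1].
#' @examples
#' hypergeom_tail(2, 3, 4, 10) # 1/3
#' @export
hypergeom_tail <- function(x, n, M, N) {
  vals <- c(x = x, n = n, M = M, N = N)
  if (anyNA(vals) || any(vals != floor(vals)) || any(vals < 0)) {
    stop("all counts must be non-negative integers", call. = FALSE)
  }
  if (n > N || M > N) stop("need n <= N and M <= N", call. = FALSE)
  if (x <= 0) return(1)
  hi <- min(n, M)
  if (x > hi) return(0)
  k <- x:hi
  logs <- lchoose(M, k) + lchoose(N - M, n - k) - lchoose(N, n)
  m <- max(logs)
  p <- exp(m) * sum(exp(logs - m))
  min(max(p, 0), 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level in (0, 1].
#' @param c Number of tested categories (>= 1).
#' @return `alpha / c`.
#' @examples
#' bonferroni(0.05, 211) # 0.0002369668...
#' @export
bonferroni <- function(alpha, c) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(c) || length(c) != 1 || is.na(c) || c < 1 || c != floor(c)) {
    stop("`c` must be a positive integer", call. = FALSE)
  }
  alpha / c
}

#' Hypergeometric enrichment of annotation categories among outliers
#'
#' For every distinct subcellular-location label in the dataset, tests
#' whether the label occurs among the outliers more often than expected if
#' the outliers were a random sample of the dataset, by the exact
#' hypergeometric upper tail. The family of tests is Bonferroni-corrected
#' by the number of distinct categories. The test is one-sided
#' (over-representation); the `direction` column reports descriptively
#' whether the outlier rate exceeds the dataset rate. Proteins with several
#' labels count once per label.
#'
#' @param outliers Protein tibble of outliers (a subset of `dataset`).
#' @param dataset Full protein tibble with `locations` list-column.
#' @param alpha Family-wise significance level (default 0.05).
#' @return A tibble sorted by ascending p: `category`, `N` (dataset size),
#'   `M` (dataset count with the label), `M_pct_dataset`, `M_pct_annotated`
#'   (percentage among proteins carrying at least one label), `n` (outlier
#'   count), `x` (outliers with the label), `p_value`, `alpha_corrected`,
#'   `significant`, `direction`.
#' @export
enrich_categories <- function(outliers, dataset, alpha = 0.05) {
  if (!all(outliers$accession %in% dataset$accession)) {
    stop("`outliers` must be a subset of `dataset`", call. = FALSE)
  }
  N <- nrow(dataset)
  n <- nrow(outliers)
  cats <- sort(unique(unlist(dataset$locations)))
  if (n == 0) {
    warning("empty outlier set; no enrichment computed")
    return(tibble::tibble(
      category = character(0), N = integer(0), M = integer(0),
      M_pct_dataset = numeric(0), M_pct_annotated = numeric(0),
      n = integer(0), x = integer(0), p_value = numeric(0),
      alpha_corrected = numeric(0), significant = logical(0),
      direction = character(0)
    ))
  }
  if (length(cats) == 0) stop("dataset carries no location labels", call. = FALSE)
  n_annot <- sum(vapply(dataset$locations, length, integer(1)) > 0)
  # a protein counts once per label even if a label is repeated on it
  tab <- function(tbl) {
    labs <- unlist(lapply(tbl$locations, unique), use.names = FALSE)
    table(factor(labs, levels = cats))
  }
  M <- as.numeric(tab(dataset))
  x <- as.numeric(tab(outliers))
  alpha_c <- bonferroni(alpha, length(cats))
  p <- mapply(hypergeom_tail, x = x, n = n, M = M, N = N)
  out <- tibble::tibble(
    category = cats,
    N = as.integer(N),
    M = as.integer(M),
    M_pct_dataset = 100 * M / N,
    M_pct_annotated = if (n_annot > 0) 100 * M / n_annot else NA_real_,
    n = as.integer(n),
    x = as.integer(x),
    p_value = as.numeric(p),
    alpha_corrected = alpha_c,
    significant = as.numeric(p) < alpha_c,
    direction = ifelse(x / n >= M / N, "over", "under")
  )
  out[order(out$p_value), ]
}

#' Write outlier / enrichment tables
#'
#' @param report Outlier report from [studentized_residuals()].
#' @param path Output file (TSV).
#' @return `path`, invisibly.
#' @export
write_outliers <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outliers
#' @param enrichment Enrichment tibble from [enrich_categories()].
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
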