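#' Configuration for the synthetic protein-structure generator
#'
#' The generator emulates the statistical structure of a non-redundant,
#' coverage-filtered structural dataset: per-protein secondary-structure
#' counts `x` with a right-skewed distribution on 1..142, segment lengths
#' whose conditional mean follows one of the Menzerath-Altmann formulas,
#' integer-valued segment noise, flat subcellular-location labels over 211
#' categories, and optionally planted outliers and a planted enriched
#' category.
#'
#' Defaults follow the study conditions the pipeline is meant to emulate:
#' `x_max = 142` and `n_categories = 211` match the observed dataset; the
#' generating model defaults to the shifted reciprocal `y = d + a/x` with
#' `a = 11, d = 7` (near the published weighted fit), so synthetic bin means
#' decay from about 18 towards 7 amino acids; the `x` distribution is
#' zipf-like with exponent 1.6 so low counts dominate, as in the observed
#' scatter; segments are `1 + Poisson(mean - 1)` so lengths are integers
#' of at least one amino acid.
#'
#' @param n_proteins Number of proteins to generate.
#' @param x_max Maximum secondary-structure count (support is 1..x_max).
#' @param x_exponent Zipf exponent of `P(x) proportional to x^-exponent`.
#' @param generating_model Model id 1..5 for the conditional mean.
#' @param generating_params Named parameters for the generating model.
#' @param noise `"poisson"` (shifted Poisson, default), `"lognormal"`
#'   (rounded, clamped at 1) or `"none"` (lengths rounded to the mean).
#' @param noise_sdlog `sdlog` for the lognormal option.
#' @param outlier_fraction Fraction of proteins whose segment-length mean is
#'   inflated.
#' @param outlier_inflation Multiplier applied to the mean for planted
#'   outliers.
#' @param n_categories Number of distinct location labels.
#' @param annotation_rate Probability that a protein carries a background
#'   location label.
#' @param enriched_category Optional `list(name =, background_rate =,
#'   outlier_rate =)`: the label is attached to planted outliers with
#'   `outlier_rate` and to other proteins with `background_rate`.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A validated `malss_config` list.
#' @export
synthetic_config <- function(n_proteins = 5000,
                             x_max = 142,
                             x_exponent = 1.6,
                             generating_model = 4,
                             generating_params = c(a = 11, d = 7),
                             noise = c("poisson", "lognormal", "none"),
                             noise_sdlog = 0.3,
                             outlier_fraction = 0,
                             outlier_inflation = 3,
                             n_categories = 211,
                             annotation_rate = 0.6,
                             enriched_category = NULL,
                             seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(n_proteins >= 1, x_max >= 1,
            outlier_fraction >= 0, outlier_fraction < 1,
            outlier_inflation > 0, n_categories >= 1,
            annotation_rate >= 0, annotation_rate <= 1)
  model <- mal_model(generating_model)
  mu <- eval_model(model, generating_params, seq_len(x_max))
  if (any(mu < 1)) {
    stop("invalid config: generating model predicts mean segment length < 1 AA",
         call. = FALSE)
  }
  if (!is.null(enriched_category)) {
    stopifnot(is.list(enriched_category),
              all(c("name", "background_rate", "outlier_rate") %in% names(enriched_category)),
              enriched_category$background_rate >= 0, enriched_category$background_rate <= 1,
              enriched_category$outlier_rate >= 0, enriched_category$outlier_rate <= 1)
  }
  out <- list(
    n_proteins = as.integer(n_proteins), x_max = as.integer(x_max),
    x_exponent = x_exponent, generating_model = model$id,
    generating_params = generating_params, noise = noise,
    noise_sdlog = noise_sdlog, outlier_fraction = outlier_fraction,
    outlier_inflation = outlier_inflation, n_categories = as.integer(n_categories),
    annotation_rate = annotation_rate, enriched_category = enriched_category,
    seed = as.integer(seed)
  )
  class(out) <- "malss_config"
  out
}

# Internal: draw integer segment lengths (>= 1) with the requested mean.
draw_lengths <- function(n, mean, noise, sdlog) {
  switch(noise,
    poisson = 1L + stats::rpois(n, max(mean - 1, 0)),
    lognormal = pmax(1L, as.integer(round(
      stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
    ))),
    none = rep(as.integer(round(mean)), n)
  )
}

#' Generate a synthetic protein dataset
#'
#' Draws, for each protein: a segment count `x` from the truncated zipf-like
#' distribution; `x` integer segment lengths around the generating model's
#' mean at `x` (multiplied by `outlier_inflation` for the planted-outlier
#' subset); random helix/strand kinds; and location labels. The sequence
#' length is the total segment length plus a coil allowance, so the segment
#' lengths always fit into the sequence. Fully reproducible from
#' `config$seed` (the caller's RNG stream is left untouched).
#'
#' @param config A `malss_config` from [synthetic_config()].
#' @return A `malss_proteins` tibble with an extra logical column
#'   `planted_outlier`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "malss_config")) stop("`config` must be a malss_config", call. = FALSE)
  withr_seed(config$seed, {
    n <- config$n_proteins
    probs <- seq_len(config$x_max)^(-config$x_exponent)
    x <- sample.int(config$x_max, n, replace = TRUE, prob = probs)
    mu <- eval_model(config$generating_model, config$generating_params, x)
    planted <- rep(FALSE, n)
    n_out <- round(config$outlier_fraction * n)
    if (n_out > 0) planted[sample.int(n, n_out)] <- TRUE
    mu[planted] <- mu[planted] * config$outlier_inflation

    seg_lengths <- vector("list", n)
    seg_kinds <- vector("list", n)
    for (i in seq_len(n)) {
      seg_lengths[[i]] <- draw_lengths(x[i], mu[i], config$noise, config$noise_sdlog)
      seg_kinds[[i]] <- sample(c("H", "E"), x[i], replace = TRUE, prob = c(0.65, 0.35))
    }

    cat_names <- sprintf("loc%03d", seq_len(config$n_categories))
    locations <- vector("list", n)
    has_bg <- stats::runif(n) < config$annotation_rate
    bg <- sample(cat_names, n, replace = TRUE)
    for (i in seq_len(n)) {
      locs <- if (has_bg[i]) bg[i] else character(0)
      locations[[i]] <- locs
    }
    if (!is.null(config$enriched_category)) {
      ec <- config$enriched_category
      rate <- ifelse(planted, ec$outlier_rate, ec$background_rate)
      gets <- stats::runif(n) < rate
      for (i in which(gets)) {
        locations[[i]] <- unique(c(locations[[i]], ec$name))
      }
    }

    totals <- vapply(seg_lengths, sum, numeric(1))
    coil <- as.integer(ceiling(totals * 0.25)) + x  # inter-segment coil allowance
    out <- build_protein_tbl(
      accession = sprintf("SYN%05d", seq_len(n)),
      seq_length = as.integer(totals) + coil,
      locations = locations,
      seg_lengths = lapply(seg_lengths, as.integer),
      seg_kinds = seg_kinds
    )
    out$planted_outlier <- planted
    out
  })
}

#' Generate coverage records with known pass/fail labels
#'
#' Produces a mixture of records that pass and fail the 95% continuous
#' coverage rule. The first six records are the boundary cases for sequence
#' lengths 14, 33 and 75: observed exactly at the admission threshold
#' (pass) and one residue short of it (fail). The rest are random lengths
#' with intervals placed at or around the threshold. The construction
#' records its intended verdict in `expected_pass` for oracle bookkeeping.
#'
#' @param n Total number of records (>= 6).
#' @param seed Integer seed.
#' @return A coverage tibble with the extra `expected_pass` column.
#' @export
generate_coverage_records <- function(n, seed = 1L) {
  stopifnot(n >= 6)
  withr_seed(seed, {
    need <- function(L) as.integer((19 * L + 19) %/% 20)  # ceil(0.95 L), exact
    Ls <- c(14L, 14L, 33L, 33L, 75L, 75L)
    pass <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
    extra <- n - 6L
    if (extra > 0) {
      Ls <- c(Ls, sample(10:2000, extra, replace = TRUE))
      pass <- c(pass, stats::runif(extra) < 0.5)
    }
    obs <- ifelse(pass, need(Ls), need(Ls) - 1L)
    # a failing record needs at least one observed residue
    ok <- obs >= 1
    pass[!ok] <- TRUE
    obs[!ok] <- need(Ls[!ok])
    start <- vapply(seq_along(Ls), function(i) {
      sample.int(Ls[i] - obs[i] + 1L, 1L)
    }, integer(1))
    tibble::tibble(
      accession = sprintf("COV%05d", seq_along(Ls)),
      seq_length = as.integer(Ls),
      observed_start = as.integer(start),
      observed_end = as.integer(start + obs - 1L),
      expected_pass = pass
    )
  })
}

#' Generating truth for a synthetic configuration
#'
#' Recreates the dataset deterministically from the config and reports the
#' ground truth that recovery experiments need: the generating model and
#' parameters, the accessions of planted outliers, and the enriched
#' category (if any).
#'
#' @param config A `malss_config`.
#' @return A list: `generating_model`, `generating_params`,
#'   `planted_outliers` (character), `enriched_category`, `seed`.
#' @export
truth_report <- function(config) {
  ds <- generate_dataset(config)
  list(
    generating_model = config$generating_model,
    generating_params = config$generating_params,
    planted_outliers = ds$accession[ds$planted_outlier],
    enriched_category = config$enriched_category,
    seed = config$seed
  )
}
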