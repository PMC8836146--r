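#' Configuration for a full pipeline run
#'
#' @param proteins A `malss_proteins` tibble, or a path to a protein table
#'   readable by [read_protein_table()].
#' @param coverage Optional coverage tibble or path; when given, the 95%
#'   continuous-coverage filter is applied before analysis.
#' @param models Model ids to fit (default 1:5).
#' @param weighted Fit with bin weights `n * x` (default) or unit weights.
#' @param upper,lower Studentized-residual outlier thresholds (+3 / -2).
#' @param alpha Family-wise level for the enrichment tests.
#' @param restarts,n_boot Fitting restarts and eta-CI bootstrap resamples.
#' @param seed Integer seed used for every stochastic step.
#' @param out_dir Output directory (created if absent).
#' @return A validated `malss_run_config` list.
#' @export
run_config <- function(proteins, coverage = NULL, models = 1:5, weighted = TRUE,
                       upper = 3, lower = -2, alpha = 0.05,
                       restarts = 10L, n_boot = 2000L, seed = 1L,
                       out_dir = tempfile("malss_run_")) {
  if (is.character(proteins) && !file.exists(proteins)) {
    stop("protein table not found: ", proteins, call. = FALSE)
  }
  if (is.character(coverage) && !file.exists(coverage)) {
    stop("coverage table not found: ", coverage, call. = FALSE)
  }
  stopifnot(all(models %in% 1:5), is.finite(upper), is.finite(lower),
            alpha > 0, alpha <= 1)
  out <- list(proteins = proteins, coverage = coverage,
              models = as.integer(models), weighted = weighted,
              upper = upper, lower = lower, alpha = alpha,
              restarts = as.integer(restarts), n_boot = as.integer(n_boot),
              seed = as.integer(seed), out_dir = out_dir)
  class(out) <- "malss_run_config"
  out
}

#' Run the full analysis pipeline
#'
#' Stages, in order: coverage filter (if a coverage table is given), binning,
#' the Menzerath's-Law correlation battery, weighted nonlinear fitting of the
#' requested models with comparison by residual standard error and AIC,
#' studentized-residual outlier detection against the best model by AIC, and
#' hypergeometric enrichment of location labels among the above-model
#' outliers. Writes `bins.tsv`, `ml_report.json`, `fits.json`,
#' `outliers.tsv`, `enrichment.tsv` and `manifest.json` into
#' `config$out_dir`. Identical inputs and seed give identical outputs.
#'
#' @param config A `malss_run_config` from [run_config()].
#' @return The run manifest (list, class `malss_manifest`), invisibly
#'   containing stage record counts, the model comparison, the verdict of
#'   the correlation battery, and md5 checksums of the outputs.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "malss_run_config")) {
    stop("`config` must come from run_config()", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- if (is.character(config$proteins)) {
    read_protein_table(config$proteins)
  } else config$proteins
  counts <- list(proteins_in = nrow(proteins))

  if (!is.null(config$coverage)) {
    coverage <- if (is.character(config$coverage)) {
      read_coverage_table(config$coverage)
    } else config$coverage
    proteins <- filter_by_coverage(proteins, coverage)
  }
  counts$proteins_admitted <- nrow(proteins)
  counts$proteins_excluded <- counts$proteins_in - counts$proteins_admitted

  bins <- make_bins(proteins)
  counts$bins <- nrow(bins)
  write_bins(bins, file.path(config$out_dir, "bins.tsv"))

  battery <- ml_test_battery(proteins, n_boot = config$n_boot, seed = config$seed)
  write_ml_report(battery, file.path(config$out_dir, "ml_report.json"))

  fits <- lapply(config$models, function(m) {
    fit_nwls(m, bins, weighted = config$weighted,
             restarts = config$restarts, seed = config$seed)
  })
  names(fits) <- paste0("model", config$models)
  comparison <- compare_models(fits)
  write_fits(fits, file.path(config$out_dir, "fits.json"))

  best_id <- comparison$model_id[which.min(comparison$aic)]
  best_fit <- fits[[paste0("model", best_id)]]
  report <- studentized_residuals(best_fit, proteins,
                                  upper = config$upper, lower = config$lower)
  write_outliers(report, file.path(config$out_dir, "outliers.tsv"))
  outliers <- detect_outliers(report, upper = config$upper, lower = config$lower)
  counts$outliers_above <- nrow(outliers$above)
  counts$outliers_below <- nrow(outliers$below)

  enrichment <- if (nrow(outliers$above) > 0 &&
                    any(vapply(proteins$locations, length, integer(1)) > 0)) {
    enrich_categories(proteins[proteins$accession %in% outliers$above$accession, ],
                      proteins, alpha = config$alpha)
  } else NULL
  if (!is.null(enrichment)) {
    write_enrichment(enrichment, file.path(config$out_dir, "enrichment.tsv"))
  }

  out_files <- c("bins.tsv", "ml_report.json", "fits.json", "outliers.tsv",
                 if (!is.null(enrichment)) "enrichment.tsv")
  checksums <- tools::md5sum(file.path(config$out_dir, out_files))
  names(checksums) <- out_files

  manifest <- list(
    package_version = as.character(utils::packageVersion("malss")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    weighted = config$weighted,
    models = config$models,
    thresholds = list(upper = config$upper, lower = config$lower, alpha = config$alpha),
    counts = counts,
    ml_not_rejected = isTRUE(attr(battery, "ml_not_rejected")),
    best_model = best_id,
    comparison = comparison,
    checksums = as.list(checksums),
    out_dir = config$out_dir
  )
  class(manifest) <- "malss_manifest"
  jsonlite::write_json(unclass(manifest), file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render a human-readable run summary
#'
#' Formats the manifest and the run's own tables (re-read from the output
#' directory) into a plain-text report: the record funnel, the five
#' correlation rows, the per-model fit summary, and the outlier and
#' enrichment headlines.
#'
#' @param manifest A `malss_manifest` from [run_pipeline()].
#' @return The report, invisibly, as a character vector of lines; also
#'   printed.
#' @export
render_report <- function(manifest) {
  stopifnot(inherits(manifest, "malss_manifest"))
  lines <- c(
    "Menzerath-Altmann analysis of protein secondary structures",
    strrep("=", 58),
    sprintf("seed %d | %s fits | models %s",
            manifest$seed, if (manifest$weighted) "weighted" else "unweighted",
            paste(manifest$models, collapse = ",")),
    "",
    sprintf("Record funnel: %d in -> %d admitted (%d excluded) -> %d bins",
            manifest$counts$proteins_in, manifest$counts$proteins_admitted,
            manifest$counts$proteins_excluded, manifest$counts$bins)
  )
  ml_path <- file.path(manifest$out_dir, "ml_report.json")
  if (file.exists(ml_path)) {
    ml <- jsonlite::fromJSON(ml_path)
    lines <- c(lines, "", "Correlation battery (Menzerath's Law):")
    res <- ml$results
    lines <- c(lines, sprintf("  %-13s %-11s % .3f  [% .3f, % .3f]  p = %.3g",
                              res$statistic, res$data, res$estimate,
                              res$ci_low, res$ci_high, res$p_value))
    lines <- c(lines, sprintf("  ML not rejected: %s", ml$ml_not_rejected))
  }
  cmp <- manifest$comparison
  lines <- c(lines, "", "Model comparison (best first by AIC):",
             sprintf("  model %d: s = %.4g, AIC = %.4g (rank_s %d, rank_aic %d)",
                     cmp$model_id, cmp$s, cmp$aic, cmp$rank_s, cmp$rank_aic))
  if (manifest$counts$outliers_above + manifest$counts$outliers_below > 0) {
    lines <- c(lines, "",
               sprintf("Outliers vs model %d: %d above (> +%g st.res.), %d below (< %g)",
                       manifest$best_model, manifest$counts$outliers_above,
                       manifest$thresholds$upper, manifest$counts$outliers_below,
                       manifest$thresholds$lower))
    enr_path <- file.path(manifest$out_dir, "enrichment.tsv")
    if (file.exists(enr_path)) {
      enr <- utils::read.delim(enr_path)
      sig <- enr[enr$significant, , drop = FALSE]
      lines <- c(lines, sprintf("Enrichment: %d of %d categories significant at alpha' = %.3g",
                                nrow(sig), nrow(enr), enr$alpha_corrected[1]))
      if (nrow(sig) > 0) {
        lines <- c(lines, sprintf("  %s: %d/%d outliers vs %d/%d dataset (p = %.3g)",
                                  sig$category, sig$x, sig$n, sig$M, sig$N, sig$p_value))
      }
    }
  } else {
    lines <- c(lines, "", "Outliers: none flagged; no enrichment computed")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
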