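#' Preprocessing configuration
#'
#' Bundles the method choice for every preprocessing stage. Stages run in the
#' fixed order impute -> QC-RSD filter -> normalize -> log10 -> scale; a
#' stage is skipped when its method is `"none"` (or `log10_transform =
#' FALSE`, `rsd_threshold_pct = NULL`).
#'
#' @param impute_method Imputation method, see [impute_missing()]. `"none"`
#'   skips imputation (the table must already be complete for later stages).
#' @param knn_k Neighbours for KNN imputation.
#' @param rsd_threshold_pct QC-RSD threshold in per cent, or `NULL` to skip
#'   filtering.
#' @param normalize_method See [normalize_intensities()].
#' @param log10_transform Apply [log_transform()]?
#' @param scale_method See [scale_features()].
#' @param drop_degenerate Passed to [scale_features()].
#' @return A `mtb_config` list.
#' @examples
#' preprocess_config() # the defaults: min5, RSD 30, PQN, log10, pareto
#' @export
preprocess_config <- function(impute_method = "min5", knn_k = 10,
                              rsd_threshold_pct = 30,
                              normalize_method = "pqn",
                              log10_transform = TRUE,
                              scale_method = "pareto",
                              drop_degenerate = FALSE) {
  impute_method <- match.arg(impute_method, c("min5", "one", "mean", "median", "knn", "none"))
  normalize_method <- match.arg(normalize_method,
                                c("pqn", "none", "internal_standard",
                                  "baseline_mean", "baseline_median", "quantile"))
  scale_method <- match.arg(scale_method,
                            c("pareto", "none", "center", "auto", "range", "vast", "level"))
  if (!is.null(rsd_threshold_pct)) {
    stopifnot(is.numeric(rsd_threshold_pct), rsd_threshold_pct >= 0)
  }
  stopifnot(is.numeric(knn_k), knn_k >= 1, is.logical(log10_transform))
  structure(list(
    impute_method = impute_method, knn_k = as.integer(knn_k),
    rsd_threshold_pct = rsd_threshold_pct,
    normalize_method = normalize_method,
    log10_transform = log10_transform,
    scale_method = scale_method,
    drop_degenerate = drop_degenerate
  ), class = "mtb_config")
}

#' @export
print.mtb_config <- function(x, ...) {
  cat("# Preprocess config\n")
  cat("  impute:    ", x$impute_method, if (x$impute_method == "knn") sprintf(" (k = %d)", x$knn_k), "\n", sep = "")
  cat("  rsd filter:", if (is.null(x$rsd_threshold_pct)) "off" else paste0(x$rsd_threshold_pct, "%"), "\n")
  cat("  normalize: ", x$normalize_method, "\n")
  cat("  log10:     ", x$log10_transform, "\n")
  cat("  scale:     ", x$scale_method, "\n")
  invisible(x)
}

#' Run the preprocessing chain
#'
#' Executes impute -> QC-RSD filter -> normalize -> log10 -> scale in that
#' fixed order, recording full provenance (stage, method, parameters, and
#' counts of cells imputed / features removed) so a report can document
#' exactly how the clean table was produced.
#'
#' @param table A raw [feature_table()].
#' @param meta A [sample_metadata()] tibble.
#' @param config A [preprocess_config()].
#' @return A `mtb_preprocessed` list: `table` (the clean [feature_table()]),
#'   `raw_table` (post-imputation, pre-normalization intensities, the scale
#'   on which fold changes are computed), `removed_features` (tibble from the
#'   RSD filter), `normalization_factors` (per-sample numeric vector) and
#'   `provenance` (tibble of stage, method, parameters, detail).
#' @export
run_preprocess <- function(table, meta, config = preprocess_config()) {
  stopifnot(inherits(config, "mtb_config"))
  rep <- validate_dataset(table, meta)
  if (length(rep$errors) > 0) {
    stop("dataset fails validation:\n  ", paste(rep$errors, collapse = "\n  "), call. = FALSE)
  }
  prov <- list()
  push <- function(stage, method, params, detail) {
    prov[[length(prov) + 1]] <<- tibble::tibble(
      stage = stage, method = method, parameters = params, detail = detail
    )
  }
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  n_missing <- sum(is.na(ft_matrix(table)))
  if (config$impute_method != "none") {
    table <- with_stage("impute",
      impute_missing(table, config$impute_method, k = config$knn_k))
    push("impute", config$impute_method,
         if (config$impute_method == "knn") sprintf("k=%d", config$knn_k) else "",
         sprintf("%d cells imputed", n_missing))
  }

  removed <- tibble::tibble(feature_id = character(), rsd_pct = numeric())
  if (!is.null(config$rsd_threshold_pct)) {
    res <- with_stage("rsd_filter",
      qc_rsd_filter(table, meta, config$rsd_threshold_pct))
    table <- res$table
    removed <- res$removed
    push("rsd_filter", "qc_rsd", sprintf("threshold=%g%%", config$rsd_threshold_pct),
         sprintf("%d features removed", nrow(removed)))
  }

  factors <- stats::setNames(rep(1, length(ft_samples(table))), ft_samples(table))
  if (config$normalize_method != "none") {
    res <- with_stage("normalize",
      normalize_intensities(table, meta, config$normalize_method))
    table <- res$table
    factors <- res$factors
    push("normalize", config$normalize_method, "",
         sprintf("factor range [%.3g, %.3g]", min(factors), max(factors)))
  }
  # positive-scale (normalized, untransformed) intensities: the scale on
  # which fold changes stay interpretable as concentration ratios
  raw_table <- table

  if (config$log10_transform) {
    table <- with_stage("log10", log_transform(table))
    push("log10", "log10", "", "")
  }

  if (config$scale_method != "none") {
    n_before <- nrow(table)
    table <- with_stage("scale",
      scale_features(table, config$scale_method, drop_degenerate = config$drop_degenerate))
    push("scale", config$scale_method, "",
         if (nrow(table) < n_before) sprintf("%d degenerate features dropped", n_before - nrow(table)) else "")
  }

  structure(list(
    table = table,
    raw_table = raw_table,
    removed_features = removed,
    normalization_factors = factors,
    provenance = if (length(prov)) dplyr::bind_rows(prov) else
      tibble::tibble(stage = character(), method = character(),
                     parameters = character(), detail = character()),
    config = config
  ), class = "mtb_preprocessed")
}

#' @export
print.mtb_preprocessed <- function(x, ...) {
  cat(sprintf("# Preprocessed dataset: %d features x %d samples\n",
              nrow(x$table), length(ft_samples(x$table))))
  p <- x$provenance
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %d. %-10s %s %s %s\n", i, p$stage[i], p$method[i], p$parameters[i], p$detail[i]))
  }
  invisible(x)
}

#' @rdname run_preprocess
#' @param x A `mtb_preprocessed` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mtb_preprocessed <- function(x, ...) x$provenance
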