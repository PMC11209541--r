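#' Relative standard deviation (per cent)
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation: the standard
#' measure of technical stability across pooled-QC injections.
#'
#' @param values Numeric vector of at least 2 finite values with non-zero mean.
#' @return RSD as a percentage.
#' @examples
#' compute_rsd(c(8, 10, 12)) # 20
#' @export
compute_rsd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("RSD needs at least 2 finite values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Filter unstable features by QC RSD
#'
#' Features whose relative standard deviation across pooled-QC injections
#' exceeds `threshold_pct` are technically unstable and removed. Missing QC
#' cells are excluded per feature provided at least 2 QC values remain.
#'
#' @param table A [feature_table()].
#' @param meta A [sample_metadata()] tibble with >= 2 QC samples.
#' @param threshold_pct RSD threshold in per cent (default 30, common QC
#'   practice).
#' @return A list with `table` (filtered [feature_table()], biological
#'   columns untouched) and `removed`, a tibble of `feature_id`, `rsd_pct`
#'   sorted by RSD descending.
#' @export
qc_rsd_filter <- function(table, meta, threshold_pct = 30) {
  qc <- intersect(ft_samples(table), qc_samples(meta))
  if (length(qc) < 2) stop("RSD filtering needs at least 2 QC samples", call. = FALSE)
  m <- ft_matrix(table)[, qc, drop = FALSE]
  rsd <- apply(m, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) {
      stop("feature with fewer than 2 observed QC values; impute first", call. = FALSE)
    }
    compute_rsd(v)
  })
  drop <- rsd > threshold_pct
  removed <- tibble::tibble(feature_id = table$feature_id[drop], rsd_pct = unname(rsd[drop]))
  removed <- dplyr::arrange(removed, dplyr::desc(.data$rsd_pct))
  list(table = ft_subset(table, features = !drop), removed = removed)
}

#' Normalize sample-to-sample variation
#'
#' Divides each sample column by a per-sample factor `s(j)`:
#'
#' * `internal_standard` — `s(j) = IS(j) / geometric mean(IS)`, where `IS` is
#'   the spiked internal-standard feature; the geometric-mean rescaling keeps
#'   the data at its original magnitude.
#' * `baseline_mean` / `baseline_median` — `s(j)` is the sample mean (median)
#'   divided by the grand mean of those statistics, so post-normalization
#'   sample means (medians) are equal.
#' * `pqn` — probabilistic quotient normalization: the reference spectrum is
#'   the per-feature median over QC samples (all samples when fewer than 2
#'   QCs exist) and `s(j)` is the median over features of `x(i,j) / r(i)`,
#'   the most-probable dilution factor of sample `j`.
#' * `quantile` — each sample's sorted values are replaced by the
#'   across-sample mean of order statistics; tied input values receive the
#'   mean of the reference values at the tied ranks. No per-sample factor
#'   exists; factors are reported as all 1.
#'
#' @param table A complete [feature_table()]; `pqn` and `internal_standard`
#'   additionally require strictly positive intensities.
#' @param meta A [sample_metadata()] tibble (used for QC identification and
#'   the internal-standard feature).
#' @param method One of `"none"`, `"internal_standard"`, `"baseline_mean"`,
#'   `"baseline_median"`, `"pqn"`, `"quantile"`.
#' @return A list with `table` (normalized [feature_table()]) and `factors`
#'   (named per-sample numeric vector).
#' @export
normalize_intensities <- function(table, meta,
                                  method = c("pqn", "none", "internal_standard",
                                             "baseline_mean", "baseline_median",
                                             "quantile")) {
  method <- match.arg(method)
  m <- ft_matrix(table)
  if (anyNA(m)) stop("normalize requires a complete (imputed) table", call. = FALSE)
  samples <- colnames(m)
  ones <- stats::setNames(rep(1, ncol(m)), samples)
  if (method == "none") return(list(table = table, factors = ones))

  if (method %in% c("pqn", "internal_standard")) {
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("%s normalization requires strictly positive values; first offender: feature '%s', sample '%s'",
                   method, rownames(m)[bad[1, 1]], samples[bad[1, 2]]), call. = FALSE)
    }
  }

  if (method == "quantile") {
    out <- quantile_normalize(m)
    return(list(table = ft_from_matrix(out), factors = ones))
  }

  s <- switch(method,
    internal_standard = {
      is_id <- attr(meta, "internal_standard_feature")
      if (is.null(is_id)) stop("internal_standard normalization needs an internal-standard feature in the metadata", call. = FALSE)
      if (!is_id %in% rownames(m)) stop("internal-standard feature not in table: ", is_id, call. = FALSE)
      is_row <- m[is_id, ]
      is_row / exp(mean(log(is_row)))
    },
    baseline_mean = {
      mu <- colMeans(m)
      mu / mean(mu)
    },
    baseline_median = {
      md <- apply(m, 2, stats::median)
      md / mean(md)
    },
    pqn = {
      qc <- intersect(samples, qc_samples(meta))
      ref_cols <- if (length(qc) >= 2) qc else samples
      r <- apply(m[, ref_cols, drop = FALSE], 1, stats::median)
      apply(m / r, 2, stats::median)
    }
  )
  s <- stats::setNames(as.numeric(s), samples)
  if (any(!is.finite(s) | s <= 0)) {
    stop("normalization produced non-positive factor(s) for sample(s): ",
         paste(samples[!is.finite(s) | s <= 0], collapse = ", "), call. = FALSE)
  }
  list(table = ft_from_matrix(sweep(m, 2, s, "/")), factors = s)
}

# mean-of-order-statistics quantile normalization, ties -> mean of the
# reference values at the tied rank positions
quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    rmin <- rank(v, ties.method = "min")
    rmax <- rank(v, ties.method = "max")
    out[, j] <- vapply(seq_along(v), function(i) mean(ref[rmin[i]:rmax[i]]), numeric(1))
  }
  out
}

#' Log10-transform intensities
#'
#' Addresses the heteroscedastic, right-skewed distribution of LC-MS
#' intensities. All values must be strictly positive (impute first).
#'
#' @param table A complete, strictly positive [feature_table()].
#' @return The transformed [feature_table()].
#' @export
log_transform <- function(table) {
  m <- ft_matrix(table)
  bad <- which(is.na(m) | m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("log10 requires strictly positive values; first offender: feature '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]), call. = FALSE)
  }
  ft_from_matrix(log10(m))
}

#' Scale features to comparable ranges
#'
#' Per-feature transforms with mean `m`, standard deviation `s` (n-1) and
#' range `r`:
#' center `x - m`; auto `(x - m)/s`; pareto `(x - m)/sqrt(s)`;
#' range `(x - m)/r`; vast `((x - m)/s) * (m/s)`; level `(x - m)/m`.
#'
#' @param table A complete [feature_table()].
#' @param method One of `"none"`, `"center"`, `"auto"`, `"pareto"`,
#'   `"range"`, `"vast"`, `"level"`.
#' @param drop_degenerate Drop features whose required statistic is
#'   degenerate (zero sd/range/mean) instead of raising an error.
#' @return The scaled [feature_table()] (possibly fewer rows when
#'   `drop_degenerate`).
#' @export
scale_features <- function(table, method = c("pareto", "none", "center", "auto",
                                             "range", "vast", "level"),
                           drop_degenerate = FALSE) {
  method <- match.arg(method)
  if (method == "none") return(table)
  m <- ft_matrix(table)
  if (anyNA(m)) stop("scaling requires a complete (imputed) table", call. = FALSE)
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  r <- apply(m, 1, function(v) max(v) - min(v))
  degenerate <- switch(method,
    center = rep(FALSE, nrow(m)),
    auto = s == 0, pareto = s == 0, vast = s == 0 | mu == 0,
    range = r == 0, level = mu == 0
  )
  if (any(degenerate)) {
    if (!drop_degenerate) {
      stop("degenerate feature(s) for ", method, " scaling: ",
           paste(rownames(m)[degenerate], collapse = ", "),
           " (set drop_degenerate = TRUE to drop them)", call. = FALSE)
    }
    m <- m[!degenerate, , drop = FALSE]
    mu <- mu[!degenerate]; s <- s[!degenerate]; r <- r[!degenerate]
  }
  cen <- m - mu
  out <- switch(method,
    center = cen,
    auto = cen / s,
    pareto = cen / sqrt(s),
    range = cen / r,
    vast = (cen / s) * (mu / s),
    level = cen / mu
  )
  ft_from_matrix(out)
}
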