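#' Impute missing intensities
#'
#' Missing values in peak-picked data arise both at random (MAR) and from
#' low-intensity features falling below the detection limit (MNAR). Five
#' strategies are offered:
#'
#' * `one` — constant 1 (a pseudo-count for clearly absent features),
#' * `min5` — one fifth of the per-feature minimum observed positive value
#'   (a detection-limit surrogate for MNAR holes),
#' * `mean` / `median` — per-feature mean/median of observed values,
#' * `knn` — feature-space k-nearest neighbours: for each feature with
#'   holes, the `k` nearest features by Euclidean distance over co-observed
#'   samples (distance rescaled by `sqrt(n_samples / n_co_observed)` so
#'   sparse overlaps are penalized) donate a `1/distance`-weighted mean of
#'   their values in the missing sample. When no neighbour observes that
#'   sample, the feature mean is used.
#'
#' Observed cells are never altered.
#'
#' @param table A [feature_table()].
#' @param method One of `"one"`, `"min5"`, `"mean"`, `"median"`, `"knn"`.
#' @param k Number of neighbours for `knn` (default 10).
#' @return A complete [feature_table()] (no missing cells).
#' @export
impute_missing <- function(table, method = c("min5", "one", "mean", "median", "knn"),
                           k = 10) {
  method <- match.arg(method)
  m <- ft_matrix(table)
  if (!anyNA(m)) return(table)
  n_obs <- rowSums(!is.na(m))
  if (any(n_obs == 0)) {
    stop("feature(s) with no observed value cannot be imputed: ",
         paste(rownames(m)[n_obs == 0], collapse = ", "), call. = FALSE)
  }
  filled <- switch(method,
    one = impute_constant(m, 1),
    min5 = impute_min5(m),
    mean = impute_rowstat(m, function(v) mean(v, na.rm = TRUE)),
    median = impute_rowstat(m, function(v) stats::median(v, na.rm = TRUE)),
    knn = impute_knn(m, k)
  )
  ft_from_matrix(filled)
}

impute_constant <- function(m, value) {
  m[is.na(m)] <- value
  m
}

impute_min5 <- function(m) {
  for (i in seq_len(nrow(m))) {
    holes <- is.na(m[i, ])
    if (!any(holes)) next
    pos <- m[i, !holes]
    pos <- pos[pos > 0]
    if (length(pos) == 0) {
      stop(sprintf("feature '%s' has no positive observed value for min5 imputation",
                   rownames(m)[i]), call. = FALSE)
    }
    m[i, holes] <- min(pos) / 5
  }
  m
}

impute_rowstat <- function(m, f) {
  for (i in seq_len(nrow(m))) {
    holes <- is.na(m[i, ])
    if (any(holes)) m[i, holes] <- f(m[i, ])
  }
  m
}

# feature-space KNN with missing-overlap distance rescaling
impute_knn <- function(m, k) {
  p <- nrow(m); n <- ncol(m)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (p < k + 1) stop(sprintf("knn needs at least k+1 = %d features, have %d", k + 1, p), call. = FALSE)
  obs <- !is.na(m)
  out <- m
  targets <- which(rowSums(obs) < n)
  for (i in targets) {
    d <- knn_distances(m, obs, i)
    ord <- order(d, seq_len(p))          # deterministic tie-break by index
    ord <- ord[is.finite(d[ord]) & ord != i]
    nb <- ord[seq_len(min(k, length(ord)))]
    for (j in which(!obs[i, ])) {
      donors <- nb[obs[nb, j]]
      if (length(donors) == 0) {
        out[i, j] <- mean(m[i, ], na.rm = TRUE)
        next
      }
      dd <- d[donors]
      if (any(dd == 0)) {
        out[i, j] <- mean(m[donors[dd == 0], j])
      } else {
        w <- 1 / dd
        out[i, j] <- sum(w * m[donors, j]) / sum(w)
      }
    }
  }
  out
}

knn_distances <- function(m, obs, i) {
  n <- ncol(m)
  co <- obs & matrix(obs[i, ], nrow = nrow(m), ncol = n, byrow = TRUE)
  n_co <- rowSums(co)
  diff2 <- (m - matrix(m[i, ], nrow = nrow(m), ncol = n, byrow = TRUE))^2
  diff2[!co] <- 0
  d <- sqrt(rowSums(diff2)) * sqrt(n / n_co)
  d[n_co == 0] <- Inf
  d
}
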