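#' Principal component analysis of samples
#'
#' Column-mean-centred singular value decomposition of the samples x
#' features view of a preprocessed table. No rescaling is applied here —
#' putting features on comparable scales is the job of [scale_features()],
#' so PCA reflects whatever scaling the preprocessing chose.
#'
#' @param table A complete [feature_table()] (or a samples x features
#'   numeric matrix).
#' @param meta Optional [sample_metadata()]; when supplied, group labels are
#'   attached to the scores for plotting.
#' @param n_components Number of components (default
#'   `min(n_samples - 1, n_features, 10)`).
#' @param factor_name Metadata factor used for score-plot groups.
#' @return A `mtb_pca` object with `scores` (tibble: sample, group,
#'   PC1...), `loadings` (tibble: feature_id, PC1...), `explained`
#'   (fraction of variance per component) and `n_components`.
#' @export
pca_ord <- function(table, meta = NULL, n_components = NULL, factor_name = NULL) {
  x <- if (inherits(table, "mtb_features")) t(ft_matrix(table)) else as.matrix(table)
  if (anyNA(x)) stop("PCA requires a complete matrix", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- min(max_comp, 10L)
  if (n_components > max_comp) {
    stop(sprintf("n_components must be <= min(n_samples - 1, n_features) = %d", max_comp), call. = FALSE)
  }
  if (all(apply(x, 2, stats::var) == 0)) stop("constant matrix has no principal components", call. = FALSE)
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2
  explained <- ev / sum(ev)
  idx <- seq_len(n_components)
  scores <- tibble::tibble(sample = rownames(x))
  if (!is.null(meta)) {
    factor_name <- resolve_factor(meta, factor_name)
    scores$group <- meta[[factor_name]][match(scores$sample, meta$sample)]
  }
  scores <- dplyr::bind_cols(scores, tibble::as_tibble(fit$x[, idx, drop = FALSE]))
  loadings <- dplyr::bind_cols(
    tibble::tibble(feature_id = colnames(x)),
    tibble::as_tibble(fit$rotation[, idx, drop = FALSE])
  )
  structure(list(
    scores = scores, loadings = loadings,
    explained = explained[idx], explained_all = explained,
    center = fit$center, n_components = n_components
  ), class = "mtb_pca")
}

#' @export
print.mtb_pca <- function(x, ...) {
  cat(sprintf("# PCA: %d components; explained: %s\n", x$n_components,
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' @rdname pca_ord
#' @param x A `mtb_pca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mtb_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "score")
}

#' @rdname pca_ord
#' @exportS3Method generics::glance
glance.mtb_pca <- function(x, ...) {
  tibble::tibble(
    n_components = x$n_components,
    var_pc1 = x$explained[1],
    var_pc2 = if (x$n_components >= 2) x$explained[2] else NA_real_,
    var_total = sum(x$explained)
  )
}

#' @rdname pca_ord
#' @param object A `mtb_pca` object.
#' @exportS3Method ggplot2::autoplot
autoplot.mtb_pca <- function(object, ...) {
  plot_scores(object$scores, object$explained, "PCA score plot")
}

plot_scores <- function(scores, explained, title) {
  stopifnot(all(c("PC1", "PC2") %in% names(scores) | c("C1", "C2") %in% names(scores)))
  c1 <- intersect(c("PC1", "C1"), names(scores))[1]
  c2 <- intersect(c("PC2", "C2"), names(scores))[1]
  lab1 <- sprintf("%s (%.1f%%)", c1, 100 * explained[1])
  lab2 <- sprintf("%s (%.1f%%)", c2, 100 * explained[2])
  p <- ggplot2::ggplot(scores, ggplot2::aes(.data[[c1]], .data[[c2]]))
  if ("group" %in% names(scores)) {
    p <- p + ggplot2::aes(colour = .data$group)
  }
  p + ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = lab1, y = lab2, title = title) +
    ggplot2::theme_bw()
}
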