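#' Pairwise correlation with significance
#'
#' Pearson or Spearman correlation between features (or samples), with
#' two-sided p-values from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and
#' Benjamini-Hochberg FDR over the upper triangle only (each unordered pair
#' is one hypothesis).
#'
#' @param table A complete [feature_table()] or numeric matrix
#'   (items x observations when a matrix is given).
#' @param axis Correlate `"features"` (default) or `"samples"`.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `mtb_corr` object: symmetric matrices `r`, `p`, `fdr` with
#'   unit/zero diagonals, plus `n_obs` and `method`. Constant items yield
#'   `NA` correlations with a warning.
#' @export
correlation_matrix <- function(table, axis = c("features", "samples"),
                               method = c("pearson", "spearman")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  if (inherits(table, "mtb_features")) {
    m <- ft_matrix(table)
    if (axis == "samples") m <- t(m)
  } else {
    m <- as.matrix(table)
  }
  if (anyNA(m)) stop("correlation requires a complete matrix", call. = FALSE)
  n <- ncol(m)
  if (n < 3) stop("correlation needs at least 3 observations per pair", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))
  constant <- apply(m, 1, stats::sd) == 0
  if (any(constant)) {
    warning("constant item(s), correlations recorded as NA: ",
            paste(rownames(m)[constant], collapse = ", "), call. = FALSE)
  }
  x <- t(m)
  if (method == "spearman") x <- apply(x, 2, rank)
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  rr <- pmin(pmax(r, -1), 1)
  tt <- rr * sqrt((n - 2) / (1 - rr^2))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[which(rr == 1 | rr == -1)] <- 0
  diag(p) <- 0
  fdr <- p
  up <- upper.tri(p)
  fdr[up] <- adjust_bh(p[up])
  fdr[lower.tri(fdr)] <- t(fdr)[lower.tri(fdr)]
  structure(list(r = r, p = p, fdr = fdr, n_obs = n, method = method, axis = axis),
            class = "mtb_corr")
}

#' @export
print.mtb_corr <- function(x, ...) {
  cat(sprintf("# %s correlation of %d %s (%d observations each)\n",
              x$method, nrow(x$r), x$axis, x$n_obs))
  invisible(x)
}

#' @rdname correlation_matrix
#' @param x A `mtb_corr` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mtb_corr <- function(x, ...) {
  ids <- rownames(x$r)
  up <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(
    item_a = ids[up[, 1]], item_b = ids[up[, 2]],
    r = x$r[up], p_value = x$p[up], fdr = x$fdr[up]
  )
}

#' Correlation-threshold network
#'
#' Builds an undirected network whose edges are the pairs passing both an
#' absolute-correlation and an FDR threshold (defaults `|r| >= 0.8`,
#' `FDR <= 0.05`). Isolated nodes are retained in the node list.
#'
#' @param corr A [correlation_matrix()] result.
#' @param r_threshold Minimum `|r|`, in `[0, 1]`.
#' @param fdr_threshold Maximum FDR, in `(0, 1]`.
#' @return A `mtb_network` object: `nodes` (tibble of `id` and `degree`),
#'   `edges` (tibble `from`, `to`, `r`, `p_value`, `fdr`), thresholds.
#' @export
correlation_network <- function(corr, r_threshold = 0.8, fdr_threshold = 0.05) {
  stopifnot(inherits(corr, "mtb_corr"))
  if (r_threshold < 0 || r_threshold > 1) stop("r_threshold must lie in [0, 1]", call. = FALSE)
  if (fdr_threshold <= 0 || fdr_threshold > 1) stop("fdr_threshold must lie in (0, 1]", call. = FALSE)
  edges <- tidy.mtb_corr(corr)
  edges <- dplyr::filter(edges, !is.na(.data$r),
                         abs(.data$r) >= r_threshold, .data$fdr <= fdr_threshold)
  edges <- dplyr::rename(edges, from = "item_a", to = "item_b")
  ids <- rownames(corr$r)
  degree <- stats::setNames(rep(0L, length(ids)), ids)
  if (nrow(edges) > 0) {
    tab <- table(c(edges$from, edges$to))
    degree[names(tab)] <- as.integer(tab)
  }
  structure(list(
    nodes = tibble::tibble(id = ids, degree = unname(degree)),
    edges = edges,
    r_threshold = r_threshold, fdr_threshold = fdr_threshold
  ), class = "mtb_network")
}

#' @export
print.mtb_network <- function(x, ...) {
  cat(sprintf("# Correlation network: %d nodes, %d edges (|r| >= %g, FDR <= %g)\n",
              nrow(x$nodes), nrow(x$edges), x$r_threshold, x$fdr_threshold))
  invisible(x)
}

#' @rdname correlation_network
#' @param x A `mtb_network` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mtb_network <- function(x, ...) x$edges

#' Convert a correlation network to an igraph graph
#' @param network A `mtb_network`.
#' @return An undirected `igraph` graph with `r`/`fdr` edge attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "mtb_network"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}

#' Write a network as GraphML
#' @param network A `mtb_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
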