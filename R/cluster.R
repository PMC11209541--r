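#' Hierarchical clustering of samples or features
#'
#' Agglomerative clustering with Euclidean or correlation (`1 - r`)
#' distance and single, complete, average (UPGMA) or Ward linkage
#' (Lance-Williams updates; Ward on Euclidean distances). Leaves are
#' ordered by a deterministic rule: at every merge the tighter subtree (the
#' one formed at the lower height, leaves counting as height 0) comes
#' first, ties broken by the smallest original index. The ordered items
#' give the row/column order for heatmap rendering.
#'
#' @param table A complete [feature_table()] or numeric matrix
#'   (items x variables when a matrix is given).
#' @param axis Cluster `"samples"` or `"features"` of a feature table.
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage `"ward"`, `"complete"`, `"average"` or `"single"`.
#' @return A `mtb_hclust` object: `merge` and `height` (hclust encoding),
#'   `labels`, `order` (deterministic leaf order, indices), `ordered_labels`,
#'   plus the settings. `as_newick()` serializes the dendrogram.
#' @export
hierarchical_clustering <- function(table, axis = c("samples", "features"),
                                    distance = c("euclidean", "correlation"),
                                    linkage = c("ward", "complete", "average", "single")) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (inherits(table, "mtb_features")) {
    m <- ft_matrix(table)
    if (axis == "samples") m <- t(m)
  } else {
    m <- as.matrix(table)
  }
  if (anyNA(m)) stop("clustering requires a complete matrix", call. = FALSE)
  if (nrow(m) < 2) stop("clustering needs at least 2 items", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("item", seq_len(nrow(m)))

  d <- if (distance == "euclidean") {
    stats::dist(m)
  } else {
    if (any(apply(m, 1, stats::sd) == 0)) {
      stop("correlation distance undefined for constant item(s): ",
           paste(rownames(m)[apply(m, 1, stats::sd) == 0], collapse = ", "), call. = FALSE)
    }
    stats::as.dist(1 - stats::cor(t(m)))
  }
  hc <- stats::hclust(d, method = switch(linkage,
    ward = "ward.D2", complete = "complete", average = "average", single = "single"))
  ord <- tightness_leaf_order(hc$merge, hc$height)
  structure(list(
    merge = hc$merge, height = hc$height, labels = rownames(m),
    order = ord, ordered_labels = rownames(m)[ord],
    axis = axis, distance = distance, linkage = linkage,
    hclust = hc
  ), class = "mtb_hclust")
}

# deterministic leaf order: tighter (lower-height) subtree first, ties by
# smallest original leaf index
tightness_leaf_order <- function(merge, height) {
  n <- nrow(merge) + 1L
  leaves <- function(node) {
    if (node < 0) return(-node)
    c(leaves(merge[node, 1]), leaves(merge[node, 2]))
  }
  node_height <- function(node) if (node < 0) 0 else height[node]
  order_node <- function(node) {
    if (node < 0) return(-node)
    l <- merge[node, 1]; r <- merge[node, 2]
    hl <- node_height(l); hr <- node_height(r)
    first_l <- min(leaves(l)); first_r <- min(leaves(r))
    swap <- hr < hl || (hr == hl && first_r < first_l)
    if (swap) c(order_node(r), order_node(l)) else c(order_node(l), order_node(r))
  }
  order_node(nrow(merge))
}

#' @export
print.mtb_hclust <- function(x, ...) {
  cat(sprintf("# Hierarchical clustering of %s: %d items, %s distance, %s linkage\n",
              x$axis, length(x$labels), x$distance, x$linkage))
  cat("  leaf order:", paste(utils::head(x$ordered_labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}

#' @rdname hierarchical_clustering
#' @param x A `mtb_hclust` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mtb_hclust <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$height),
    left = x$merge[, 1], right = x$merge[, 2],
    height = x$height
  )
}

#' Newick serialization of a dendrogram
#'
#' @param x A `mtb_hclust` result.
#' @return A single Newick string with branch lengths.
#' @export
as_newick <- function(x) {
  stopifnot(inherits(x, "mtb_hclust"))
  phy <- ape::as.phylo(x$hclust)
  ape::write.tree(phy)
}
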