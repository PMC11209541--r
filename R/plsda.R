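#' Partial least squares discriminant analysis
#'
#' Supervised ordination: PLS2 regression of the feature matrix against a
#' one-hot class matrix, fitted by NIPALS with deflation of both blocks per
#' component (convergence tolerance 1e-10, at most 500 iterations).
#' Companions follow standard chemometrics practice:
#'
#' * VIP — variable importance in projection,
#'   `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with unit-norm
#'   weight vectors, so the mean squared VIP over features is 1;
#' * R2Y — fraction of class-matrix variance explained by the fit;
#' * Q2 — `1 - PRESS/TSS` from stratified k-fold cross-validation
#'   (default 7 folds, fold assignment from `seed`); negative values mean
#'   the model predicts class membership worse than the class means.
#'
#' @param table A complete [feature_table()] (or samples x features matrix).
#' @param meta A [sample_metadata()] tibble; biological samples only are
#'   used.
#' @param factor_name Metadata factor supplying the class labels.
#' @param n_components Number of latent components (default 2).
#' @param cv_folds Cross-validation folds (default 7); `0` skips CV.
#' @param seed Seed for the fold assignment.
#' @return A `mtb_plsda` object: `scores` (tibble sample, group, C1...),
#'   `loadings` (feature_id, C1...), `weights`, `explained_x`,
#'   `explained_y` (per-component fractions), `vip` (tibble feature_id,
#'   vip), `r2y`, `q2`, `cv_folds`.
#' @export
plsda <- function(table, meta, factor_name = NULL, n_components = 2,
                  cv_folds = 7, seed = 1) {
  if (inherits(table, "mtb_features")) {
    factor_name <- resolve_factor(meta, factor_name)
    keep <- bio_samples(meta)
    keep <- intersect(ft_samples(table), keep)
    x <- t(ft_matrix(table))[keep, , drop = FALSE]
    labels <- meta[[factor_name]][match(keep, meta$sample)]
  } else {
    x <- as.matrix(table)
    labels <- as.character(meta)
    if (length(labels) != nrow(x)) stop("labels must match rows of the matrix", call. = FALSE)
  }
  if (anyNA(x)) stop("PLS-DA requires a complete matrix", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("PLS-DA needs at least 2 groups", call. = FALSE)
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_comp) {
    stop(sprintf("n_components must be <= min(n_samples - 1, n_features) = %d", max_comp), call. = FALSE)
  }
  if (cv_folds > 1 && any(table(labels) < 2)) {
    stop("every group needs >= 2 samples for cross-validation", call. = FALSE)
  }

  fit <- nipals_pls2(x, onehot(labels, groups), n_components)

  q2 <- NA_real_
  if (cv_folds > 1) {
    q2 <- plsda_q2(x, labels, groups, n_components, cv_folds, seed)
  }

  scores <- tibble::tibble(sample = rownames(x) %||% paste0("s", seq_len(nrow(x))),
                           group = labels)
  st <- fit$scores
  colnames(st) <- paste0("C", seq_len(ncol(st)))
  scores <- dplyr::bind_cols(scores, tibble::as_tibble(st))
  lo <- fit$x_loadings
  colnames(lo) <- paste0("C", seq_len(ncol(lo)))
  loadings <- dplyr::bind_cols(tibble::tibble(feature_id = colnames(x)),
                               tibble::as_tibble(lo))
  structure(list(
    scores = scores, loadings = loadings, weights = fit$weights,
    explained_x = fit$explained_x, explained_y = fit$explained_y,
    vip = tibble::tibble(feature_id = colnames(x), vip = fit$vip),
    r2y = fit$r2y, q2 = q2, cv_folds = cv_folds,
    groups = groups, n_components = n_components,
    x_center = fit$x_center, y_center = fit$y_center, coef = fit$coef
  ), class = "mtb_plsda")
}

onehot <- function(labels, groups) {
  y <- matrix(0, length(labels), length(groups), dimnames = list(NULL, groups))
  y[cbind(seq_along(labels), match(labels, groups))] <- 1
  y
}

# NIPALS PLS2 with per-component deflation of X and Y
nipals_pls2 <- function(x, y, n_components, tol = 1e-10, max_iter = 500) {
  x_center <- colMeans(x)
  y_center <- colMeans(y)
  X <- sweep(x, 2, x_center)
  Y <- sweep(y, 2, y_center)
  ssx0 <- sum(X^2); ssy0 <- sum(Y^2)
  p_feat <- ncol(X)
  W <- matrix(0, p_feat, n_components)
  P <- matrix(0, p_feat, n_components)
  Q <- matrix(0, ncol(Y), n_components)
  Tm <- matrix(0, nrow(X), n_components)
  ssy_expl <- ssx_expl <- numeric(n_components)
  for (a in seq_len(n_components)) {
    u <- Y[, which.max(apply(Y, 2, stats::var))]
    t_old <- rep(Inf, nrow(X))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- crossprod(X, u)
      w <- w / sqrt(sum(w^2))
      tt <- X %*% w
      q <- crossprod(Y, tt) / sum(tt^2)
      u <- Y %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) { converged <- TRUE; break }
      t_old <- tt
    }
    if (!converged) stop(sprintf("NIPALS failed to converge for component %d", a), call. = FALSE)
    p_load <- crossprod(X, tt) / sum(tt^2)
    W[, a] <- w; P[, a] <- p_load; Q[, a] <- q; Tm[, a] <- tt
    ssy_expl[a] <- sum(tt^2) * sum(q^2)
    ssx_expl[a] <- sum(tt^2) * sum(p_load^2)
    X <- X - tt %*% t(p_load)
    Y <- Y - tt %*% t(q)
  }
  vip <- sqrt(p_feat * as.numeric(W^2 %*% ssy_expl) / sum(ssy_expl))
  # regression coefficients on the centred scale
  coef <- W %*% solve(crossprod(P, W)) %*% t(Q)
  list(
    scores = Tm, x_loadings = P, weights = W, y_loadings = Q,
    explained_x = ssx_expl / ssx0, explained_y = ssy_expl / ssy0,
    r2y = sum(ssy_expl) / ssy0, vip = vip,
    x_center = x_center, y_center = y_center, coef = coef
  )
}

predict_pls <- function(fit, x_new) {
  Xc <- sweep(as.matrix(x_new), 2, fit$x_center)
  sweep(Xc %*% fit$coef, 2, fit$y_center, "+")
}

# stratified fold assignment: within each group, shuffled round-robin
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (g in unique(labels)) {
      idx <- which(labels == g)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

plsda_q2 <- function(x, labels, groups, n_components, cv_folds, seed) {
  y <- onehot(labels, groups)
  fold <- stratified_folds(labels, cv_folds, seed)
  press <- tss <- 0
  for (f in sort(unique(fold))) {
    test <- fold == f
    if (!any(test) || all(test)) next
    if (length(unique(labels[!test])) < length(groups)) {
      stop("a cross-validation fold lost a whole group; reduce cv_folds", call. = FALSE)
    }
    nc <- min(n_components, sum(!test) - 1L)
    fit <- nipals_pls2(x[!test, , drop = FALSE], y[!test, , drop = FALSE], nc)
    pred <- predict_pls(fit, x[test, , drop = FALSE])
    press <- press + sum((y[test, , drop = FALSE] - pred)^2)
    mu <- colMeans(y[!test, , drop = FALSE])
    tss <- tss + sum(sweep(y[test, , drop = FALSE], 2, mu)^2)
  }
  1 - press / tss
}

#' Classify samples by a fitted PLS-DA model
#'
#' Assigns each sample to the class with the largest predicted class-matrix
#' column.
#'
#' @param object A `mtb_plsda` fit.
#' @param newdata Samples x features matrix (defaults to the training data
#'   via the stored coefficients is not kept; supply explicitly).
#' @return Character vector of predicted group labels.
#' @export
predict_plsda <- function(object, newdata) {
  pred <- predict_pls(object, newdata)
  object$groups[max.col(pred, ties.method = "first")]
}

#' @export
print.mtb_plsda <- function(x, ...) {
  cat(sprintf("# PLS-DA: %d components, %d groups; R2Y = %.3f, Q2 = %.3f (%d-fold CV)\n",
              x$n_components, length(x$groups), x$r2y, x$q2, x$cv_folds))
  invisible(x)
}

#' @rdname plsda
#' @param x A `mtb_plsda` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mtb_plsda <- function(x, ...) {
  dplyr::arrange(x$vip, dplyr::desc(.data$vip))
}

#' @rdname plsda
#' @exportS3Method generics::glance
glance.mtb_plsda <- function(x, ...) {
  tibble::tibble(n_components = x$n_components, r2y = x$r2y, q2 = x$q2,
                 cv_folds = x$cv_folds)
}

#' @rdname plsda
#' @param object A `mtb_plsda` object.
#' @exportS3Method ggplot2::autoplot
autoplot.mtb_plsda <- function(object, ...) {
  plot_scores(object$scores, object$explained_x, "PLS-DA score plot")
}
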