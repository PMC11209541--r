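#' Subset samples and groups
#'
#' Curates a dataset before analysis: keep only some groups of a metadata
#' factor and/or drop individual samples (e.g. outliers). QC samples are
#' retained unless explicitly excluded.
#'
#' @param table A [feature_table()].
#' @param meta A [sample_metadata()] tibble.
#' @param include_groups Group labels (under `factor_name`) to keep; `NULL`
#'   keeps all.
#' @param exclude_samples Sample names to drop; `NULL` drops none.
#' @param factor_name Metadata factor used for `include_groups`; defaults to
#'   the first declared factor.
#' @return A list with the filtered `table` and `meta`.
#' @export
subset_samples <- function(table, meta, include_groups = NULL,
                           exclude_samples = NULL, factor_name = NULL) {
  factor_name <- resolve_factor(meta, factor_name)
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(include_groups)) {
    unknown <- setdiff(include_groups, unique(meta[[factor_name]]))
    if (length(unknown) > 0) {
      stop(sprintf("unknown group(s) under factor '%s': %s", factor_name,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    keep <- meta[[factor_name]] %in% include_groups | meta$sample_type == "qc"
  }
  if (!is.null(exclude_samples)) {
    unknown <- setdiff(exclude_samples, meta$sample)
    if (length(unknown) > 0) {
      stop("unknown sample(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- keep & !(meta$sample %in% exclude_samples)
  }
  meta2 <- meta[keep, , drop = FALSE]
  attr(meta2, "factors") <- meta_factors(meta)
  attr(meta2, "internal_standard_feature") <- attr(meta, "internal_standard_feature")
  class(meta2) <- class(meta)
  list(table = ft_subset(table, samples = meta2$sample), meta = meta2)
}

group_columns <- function(table, meta, group, factor_name) {
  s <- meta$sample[meta[[factor_name]] == group & meta$sample_type == "biological"]
  s <- intersect(ft_samples(table), s)
  if (length(s) == 0) stop(sprintf("no samples in group '%s'", group), call. = FALSE)
  s
}

# align paired samples: returns list(a = cols, b = cols) in pair-token order
paired_columns <- function(meta, cols_a, cols_b) {
  if (!"pair" %in% names(meta)) stop("paired analysis needs a 'pair' column in the metadata", call. = FALSE)
  pa <- meta$pair[match(cols_a, meta$sample)]
  pb <- meta$pair[match(cols_b, meta$sample)]
  if (anyNA(pa) || anyNA(pb)) stop("sample(s) without a pairing token", call. = FALSE)
  if (!setequal(pa, pb) || anyDuplicated(pa) || anyDuplicated(pb)) {
    stop("pairing tokens must match the two groups 1:1", call. = FALSE)
  }
  list(a = cols_a[order(pa)], b = cols_b[order(pb)])
}

#' Per-feature fold change between two groups
#'
#' Computed on positive, untransformed intensities (use the `raw_table`
#' element of [run_preprocess()] output) so ratios remain interpretable as
#' concentration ratios. Unpaired: `mean(A)/mean(B)`. Paired: the geometric
#' mean over pairs of per-pair ratios, which is symmetric under swapping the
#' groups (`fc(A,B) = 1/fc(B,A)`).
#'
#' @param table A strictly positive [feature_table()].
#' @param meta A [sample_metadata()] tibble.
#' @param group_a,group_b Group labels under `factor_name` (fold change is
#'   A over B).
#' @param paired Use per-pair ratios (requires a `pair` metadata column).
#' @param factor_name Metadata factor; defaults to the first declared one.
#' @return A tibble: `feature_id`, `mean_a`, `mean_b`, `fold_change`,
#'   `log2_fc`, `direction`.
#' @export
fold_change <- function(table, meta, group_a, group_b, paired = FALSE,
                        factor_name = NULL) {
  factor_name <- resolve_factor(meta, factor_name)
  cols_a <- group_columns(table, meta, group_a, factor_name)
  cols_b <- group_columns(table, meta, group_b, factor_name)
  m <- ft_matrix(table)
  if (any(is.na(m[, c(cols_a, cols_b)])) || any(m[, c(cols_a, cols_b)] <= 0)) {
    stop("fold change requires complete, strictly positive intensities", call. = FALSE)
  }
  ma <- rowMeans(m[, cols_a, drop = FALSE])
  mb <- rowMeans(m[, cols_b, drop = FALSE])
  if (paired) {
    pc <- paired_columns(meta, cols_a, cols_b)
    ratios <- m[, pc$a, drop = FALSE] / m[, pc$b, drop = FALSE]
    fc <- exp(rowMeans(log(ratios)))
  } else {
    fc <- ma / mb
  }
  tibble::tibble(
    feature_id = table$feature_id,
    mean_a = unname(ma), mean_b = unname(mb),
    fold_change = unname(fc), log2_fc = unname(log2(fc)),
    direction = unname(sign(log2(fc)))
  )
}

#' Per-feature two-group t-tests
#'
#' Two-sided t-test per feature. Welch's unequal-variance test is the
#' default (group variances are rarely equal in metabolomics); Student's
#' pooled test with `equal_var = TRUE`, paired t on per-pair differences
#' with `paired = TRUE`. Fold changes are taken from `fc_table` (positive,
#' untransformed intensities — typically the `raw_table` of
#' [run_preprocess()]) while the test runs on `table` itself. When both
#' groups are constant and equal the statistic is 0 with p = 1; a constant
#' difference with non-zero mean gets p = 0 and is flagged in `note`.
#'
#' @inheritParams fold_change
#' @param equal_var Pooled-variance Student test instead of Welch.
#' @param fc_table Feature table used for fold change; defaults to `table`.
#' @return A `mtb_stats` tibble: `feature_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `log2_fc`, `direction`, `statistic`, `df`, `p_value`,
#'   `fdr`, `note`.
#' @export
t_tests <- function(table, meta, group_a, group_b, paired = FALSE,
                    equal_var = FALSE, factor_name = NULL, fc_table = NULL) {
  factor_name <- resolve_factor(meta, factor_name)
  cols_a <- group_columns(table, meta, group_a, factor_name)
  cols_b <- group_columns(table, meta, group_b, factor_name)
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  m <- ft_matrix(table)
  A <- m[, cols_a, drop = FALSE]
  B <- m[, cols_b, drop = FALSE]
  if (anyNA(A) || anyNA(B)) stop("t-tests require a complete (imputed) table", call. = FALSE)

  if (paired) {
    pc <- paired_columns(meta, cols_a, cols_b)
    D <- m[, pc$a, drop = FALSE] - m[, pc$b, drop = FALSE]
    n <- ncol(D)
    md <- rowMeans(D)
    sd_d <- apply(D, 1, stats::sd)
    se <- sd_d / sqrt(n)
    df <- rep(n - 1, nrow(m))
    tt <- md / se
  } else {
    na <- ncol(A); nb <- ncol(B)
    ma <- rowMeans(A); mb <- rowMeans(B)
    va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
    if (equal_var) {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- rep(na + nb - 2, nrow(m))
    } else {
      se <- sqrt(va / na + vb / nb)
      df <- (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    tt <- (ma - mb) / se
  }
  delta <- if (paired) rowMeans(m[, cols_a, drop = FALSE]) - rowMeans(m[, cols_b, drop = FALSE])
           else rowMeans(A) - rowMeans(B)
  note <- rep("", nrow(m))
  zero_se <- !is.finite(tt)
  tt[zero_se & delta == 0] <- 0
  note[zero_se & delta != 0] <- "zero within-group variance with unequal means"
  tt[zero_se & delta != 0] <- sign(delta[zero_se & delta != 0]) * Inf
  p <- 2 * stats::pt(-abs(tt), df)
  p[zero_se & delta == 0] <- 1
  p[zero_se & delta != 0] <- 0

  fc <- fold_change(if (is.null(fc_table)) table else fc_table,
                    meta, group_a, group_b, paired = paired, factor_name = factor_name)
  fc <- fc[match(table$feature_id, fc$feature_id), ]
  out <- tibble::tibble(
    feature_id = table$feature_id,
    mean_a = fc$mean_a, mean_b = fc$mean_b,
    fold_change = fc$fold_change, log2_fc = fc$log2_fc, direction = fc$direction,
    statistic = unname(tt), df = unname(df),
    p_value = unname(p), fdr = adjust_bh(unname(p)), note = note
  )
  attr(out, "comparison") <- c(a = group_a, b = group_b)
  attr(out, "test") <- if (paired) "paired t" else if (equal_var) "Student t" else "Welch t"
  class(out) <- c("mtb_stats", class(out))
  out
}

#' Per-feature one-way ANOVA
#'
#' Fixed-effects one-way F test per feature across all groups of a metadata
#' factor. With exactly two groups the F statistic equals the square of the
#' pooled-variance Student t. The reported `fold_change` is the ratio of the
#' largest to the smallest group mean on the `fc_table` scale.
#'
#' @inheritParams t_tests
#' @return A `mtb_stats` tibble: `feature_id`, group mean columns
#'   (`mean_<group>`), `fold_change`, `log2_fc`, `statistic` (F), `df1`,
#'   `df2`, `p_value`, `fdr`.
#' @export
anova_test <- function(table, meta, factor_name = NULL, fc_table = NULL) {
  factor_name <- resolve_factor(meta, factor_name)
  bio <- meta[meta$sample_type == "biological", ]
  groups <- split(bio$sample, bio[[factor_name]])
  groups <- lapply(groups, intersect, x = ft_samples(table))
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("ANOVA needs at least 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) {
    stop("group(s) of size 1: ", paste(names(groups)[lengths(groups) < 2], collapse = ", "), call. = FALSE)
  }
  m <- ft_matrix(table)
  cols <- unlist(groups, use.names = FALSE)
  if (anyNA(m[, cols])) stop("ANOVA requires a complete (imputed) table", call. = FALSE)

  k <- length(groups)
  n <- length(cols)
  gm <- vapply(groups, function(s) rowMeans(m[, s, drop = FALSE]), numeric(nrow(m)))
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1, dimnames = list(NULL, names(groups)))
  grand <- rowMeans(m[, cols, drop = FALSE])
  ssb <- as.numeric(gm^2 %*% lengths(groups)) - n * grand^2
  sst <- rowSums(m[, cols, drop = FALSE]^2) - n * grand^2
  ssw <- sst - ssb
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  degenerate <- !is.finite(f)
  f[degenerate & abs(ssb) < 1e-12] <- 0
  p[degenerate & abs(ssb) < 1e-12] <- 1
  # all groups constant and equal -> no evidence of difference
  zero_tot <- sst < 1e-12
  f[zero_tot] <- 0
  p[zero_tot] <- 1

  fm <- if (is.null(fc_table)) m else ft_matrix(fc_table)[table$feature_id, , drop = FALSE]
  gmean_fc <- vapply(groups, function(s) rowMeans(fm[, s, drop = FALSE]), numeric(nrow(m)))
  if (is.null(dim(gmean_fc))) gmean_fc <- matrix(gmean_fc, nrow = 1)
  fc <- apply(gmean_fc, 1, max) / apply(gmean_fc, 1, min)

  means <- tibble::as_tibble(stats::setNames(
    as.data.frame(gmean_fc), paste0("mean_", names(groups))
  ))
  out <- dplyr::bind_cols(
    tibble::tibble(feature_id = table$feature_id), means,
    tibble::tibble(
      fold_change = unname(fc), log2_fc = unname(log2(fc)),
      statistic = unname(f), df1 = df1, df2 = df2,
      p_value = unname(p), fdr = adjust_bh(unname(p))
    )
  )
  attr(out, "factor") <- factor_name
  attr(out, "test") <- "one-way ANOVA"
  class(out) <- c("mtb_stats", class(out))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped to 1 and monotone-enforced. Missing
#' entries pass through untouched.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- p_values
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' @export
print.mtb_stats <- function(x, ...) {
  test <- attr(x, "test")
  cmp <- attr(x, "comparison")
  hdr <- if (!is.null(cmp)) sprintf(" (%s vs %s)", cmp["a"], cmp["b"]) else ""
  cat(sprintf("# %s%s: %d features, %d at FDR < 0.05\n",
              test %||% "statistics", hdr, nrow(x), sum(x$fdr < 0.05, na.rm = TRUE)))
  NextMethod()
}
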