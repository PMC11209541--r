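#' Construct a feature table
#'
#' A feature table holds mass-feature intensities with features in rows and
#' samples in columns, the orientation produced by XCMS, MS-DIAL, MZmine and
#' similar peak-picking software. It is stored as a tibble whose first column
#' is `feature_id` (unique character identifiers, often an `mz_rt` composite)
#' followed by one numeric column per sample. Missing intensities are `NA`;
#' observed intensities must be finite and non-negative.
#'
#' @param x A data frame with a `feature_id` column (or feature IDs in the
#'   first column) and one numeric column per sample.
#' @return A `mtb_features` tibble.
#' @examples
#' ft <- feature_table(data.frame(
#'   feature_id = c("m100_t20", "m210_t45"),
#'   liver_1 = c(1200, 45), liver_2 = c(1100, NA)
#' ))
#' ft
#' @export
feature_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2) stop("a feature table needs a feature-ID column and at least one sample column", call. = FALSE)
  if (!"feature_id" %in% names(x)) names(x)[1] <- "feature_id"
  x <- dplyr::relocate(x, "feature_id")
  x$feature_id <- as.character(x$feature_id)
  samples <- setdiff(names(x), "feature_id")
  for (s in samples) {
    if (!is.numeric(x[[s]])) {
      stop(sprintf("sample column '%s' is not numeric", s), call. = FALSE)
    }
  }
  validate_feature_table(x)
  new_feature_table(x)
}

# derived stages (centering, scaling, log) legitimately produce negative
# values, so only axis checks apply here; the non-negativity contract is
# enforced on raw input by feature_table()/read_feature_table()
new_feature_table <- function(x) {
  ids <- x$feature_id
  if (anyDuplicated(ids)) {
    stop("duplicate feature IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  samples <- names(x)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample names: ", paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  }
  class(x) <- unique(c("mtb_features", class(tibble::tibble())))
  x
}

validate_feature_table <- function(x) {
  ids <- x$feature_id
  if (anyDuplicated(ids)) {
    stop("duplicate feature IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  samples <- names(x)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample names: ", paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(x[samples])
  bad <- which(!is.na(m) & (!is.finite(m) | m < 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "intensity must be missing or finite and >= 0; first offender: feature '%s', sample '%s'",
      ids[bad[1, 1]], samples[bad[1, 2]]
    ), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.mtb_features <- function(x, ...) {
  cat(sprintf(
    "# Feature table: %d features x %d samples (%.1f%% missing)\n",
    nrow(x), ncol(x) - 1L, 100 * mean(is.na(as.matrix(x[-1])))
  ))
  NextMethod()
}

#' Sample names of a feature table
#' @param table A [feature_table()].
#' @return Character vector of sample column names.
#' @export
ft_samples <- function(table) setdiff(names(table), "feature_id")

#' Intensity matrix of a feature table
#'
#' @param table A [feature_table()].
#' @return Numeric matrix, features in rows (rownames = feature IDs),
#'   samples in columns.
#' @export
ft_matrix <- function(table) {
  m <- as.matrix(table[ft_samples(table)])
  rownames(m) <- table$feature_id
  m
}

# rebuild a feature table from a features-by-samples matrix (derived data:
# negatives allowed)
ft_from_matrix <- function(m) {
  # built by hand so duplicate sample names survive until our own check
  cols <- c(list(feature_id = rownames(m) %||% paste0("f", seq_len(nrow(m)))),
            lapply(seq_len(ncol(m)), function(j) unname(m[, j])))
  names(cols) <- c("feature_id", colnames(m))
  out <- tibble::new_tibble(cols, nrow = nrow(m))
  new_feature_table(out)
}

# subset rows/columns while preserving the class
ft_subset <- function(table, features = NULL, samples = NULL) {
  out <- table
  if (!is.null(features)) out <- out[features, , drop = FALSE]
  if (!is.null(samples)) out <- out[, c("feature_id", samples), drop = FALSE]
  new_feature_table(tibble::as_tibble(out))
}

#' Construct sample metadata
#'
#' Per-sample annotations: one row per sample, a `sample` column, a
#' `sample_type` column (`"biological"`, `"qc"` or `"blank"`), an optional
#' `pair` column of pairing tokens for paired tests, and one or more factor
#' columns (group labels). Multiple factor columns support switching the
#' grouping used by each analysis.
#'
#' @param x A data frame with sample names in a `sample` column (or in the
#'   first column) and at least one factor column.
#' @param factors Character vector naming the factor columns. Defaults to all
#'   columns other than `sample`, `sample_type` and `pair`.
#' @param qc_label Group label marking pooled-QC samples (case-insensitive)
#'   when no `sample_type` column is present.
#' @param internal_standard_feature Optional feature ID of a spiked internal
#'   standard, used by internal-standard normalization.
#' @return A `mtb_metadata` tibble.
#' @examples
#' sample_metadata(data.frame(
#'   sample = c("liver_1", "liver_2", "QC_1"),
#'   tissue = c("liver", "liver", "QC")
#' ))
#' @export
sample_metadata <- function(x, factors = NULL, qc_label = "QC",
                            internal_standard_feature = NULL) {
  x <- tibble::as_tibble(x)
  if (!"sample" %in% names(x)) names(x)[1] <- "sample"
  x <- dplyr::relocate(x, "sample")
  x$sample <- as.character(x$sample)
  if (anyDuplicated(x$sample)) {
    stop("duplicate sample names in metadata: ",
         paste(unique(x$sample[duplicated(x$sample)]), collapse = ", "), call. = FALSE)
  }
  reserved <- c("sample", "sample_type", "pair")
  if (is.null(factors)) factors <- setdiff(names(x), reserved)
  if (length(factors) == 0) stop("metadata needs at least one factor column", call. = FALSE)
  if (!all(factors %in% names(x))) {
    stop("unknown factor column(s): ", paste(setdiff(factors, names(x)), collapse = ", "), call. = FALSE)
  }
  for (f in factors) {
    x[[f]] <- as.character(x[[f]])
    if (any(is.na(x[[f]]) | x[[f]] == "")) {
      i <- which(is.na(x[[f]]) | x[[f]] == "")[1]
      stop(sprintf("empty value for factor '%s' at sample '%s'", f, x$sample[i]), call. = FALSE)
    }
  }
  if (!"sample_type" %in% names(x)) {
    first <- x[[factors[1]]]
    x$sample_type <- ifelse(toupper(first) == toupper(qc_label), "qc", "biological")
  } else {
    x$sample_type <- tolower(as.character(x$sample_type))
  }
  bad_type <- setdiff(unique(x$sample_type), c("biological", "qc", "blank"))
  if (length(bad_type) > 0) {
    stop("sample_type must be biological/qc/blank; found: ", paste(bad_type, collapse = ", "), call. = FALSE)
  }
  if ("pair" %in% names(x)) x$pair <- as.character(x$pair)
  attr(x, "factors") <- factors
  attr(x, "internal_standard_feature") <- internal_standard_feature
  class(x) <- c("mtb_metadata", class(tibble::tibble()))
  x
}

#' @export
print.mtb_metadata <- function(x, ...) {
  cat(sprintf(
    "# Sample metadata: %d samples (%d QC), factors: %s\n",
    nrow(x), sum(x$sample_type == "qc"), paste(meta_factors(x), collapse = ", ")
  ))
  NextMethod()
}

#' Factor columns declared on a metadata table
#' @param meta A [sample_metadata()] tibble.
#' @return Character vector of factor column names.
#' @export
meta_factors <- function(meta) attr(meta, "factors")

# resolve a factor argument: default = first declared factor
resolve_factor <- function(meta, factor_name = NULL) {
  factors <- meta_factors(meta)
  if (is.null(factor_name)) return(factors[1])
  if (!factor_name %in% factors) {
    stop(sprintf("unknown metadata factor '%s' (declared: %s)", factor_name,
                 paste(factors, collapse = ", ")), call. = FALSE)
  }
  factor_name
}

qc_samples <- function(meta) meta$sample[meta$sample_type == "qc"]
bio_samples <- function(meta) meta$sample[meta$sample_type == "biological"]
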