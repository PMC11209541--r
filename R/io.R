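#' Read a feature table from CSV or XLSX
#'
#' Parses a mass-feature intensity table exported by peak-picking software
#' (features in rows, samples in columns; first column = feature IDs, header
#' row = sample names). Cells matching `missing_codes` are marked missing; by
#' default literal zeros are treated as missing too, the common convention
#' for peak-picking exports where a zero means "not detected".
#'
#' @param path Path to a `.csv`, `.xls` or `.xlsx` file.
#' @param format `"auto"` (from the file extension), `"csv"` or `"xlsx"`.
#' @param missing_codes Character tokens read as missing.
#' @param zero_as_missing Treat literal 0 as missing (default `TRUE`).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, format = c("auto", "csv", "xlsx"),
                               missing_codes = c("", "NA", "NaN"),
                               zero_as_missing = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xls", "xlsx")) "xlsx" else "csv"
  }
  raw <- if (format == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    na = character(), progress = FALSE, name_repair = "minimal")
  } else {
    readxl::read_excel(path, col_types = "text", .name_repair = "minimal")
  }
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("empty feature table: ", path, call. = FALSE)
  ids <- as.character(raw[[1]])
  samples <- names(raw)[-1]
  cells <- as.matrix(raw[-1])
  miss <- is.na(cells) | cells %in% missing_codes
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(!miss & is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("unparseable cell '%s' at feature '%s', sample '%s'",
                 cells[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], samples[bad[1, 2]]), call. = FALSE)
  }
  num[miss] <- NA_real_
  if (zero_as_missing) num[!is.na(num) & num == 0] <- NA_real_
  colnames(num) <- samples
  rownames(num) <- ids
  out <- ft_from_matrix(num)
  validate_feature_table(out)   # raw input: non-negative, finite
  out
}

#' Parse sample metadata out of sample column names
#'
#' Column-name convention: tokens joined by `delimiter`, one token per field
#' in `fields`, with the last token a replicate index (e.g. `liver_2` or
#' `ctrl_batch1_3`). Samples whose first token equals `qc_label`
#' (case-insensitive) are typed as pooled QC.
#'
#' @param sample_names Character vector of sample column names.
#' @param delimiter Single token-separator character (default `"_"`).
#' @param fields Ordered names for the leading tokens, one factor per field.
#' @param qc_label Label marking pooled-QC samples.
#' @return A [sample_metadata()] tibble with one factor per field.
#' @examples
#' parse_metadata_from_names(c("liver_1", "liver_2", "QC_1"), fields = "group")
#' @export
parse_metadata_from_names <- function(sample_names, delimiter = "_",
                                      fields = "group", qc_label = "QC") {
  stopifnot(nchar(delimiter) == 1, length(fields) >= 1)
  parts <- strsplit(sample_names, delimiter, fixed = TRUE)
  need <- length(fields) + 1L
  short <- lengths(parts) < need
  if (any(short)) {
    stop(sprintf(
      "sample name(s) do not split into %d '%s'-separated tokens (%d field(s) + replicate): %s",
      need, delimiter, length(fields), paste(sample_names[short], collapse = ", ")
    ), call. = FALSE)
  }
  cols <- purrr::map(seq_along(fields), function(i) purrr::map_chr(parts, i))
  names(cols) <- fields
  meta <- tibble::as_tibble(c(list(sample = sample_names), cols))
  sample_metadata(meta, factors = fields, qc_label = qc_label)
}

#' Read a sample metadata table
#'
#' First column = sample names; remaining columns become metadata factors,
#' except the reserved columns `sample_type` (biological/qc/blank) and
#' `pair` (pairing tokens for paired tests).
#'
#' @param path Path to a CSV file.
#' @inheritParams sample_metadata
#' @return A [sample_metadata()] tibble.
#' @export
read_metadata_table <- function(path, qc_label = "QC") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("empty metadata table: ", path, call. = FALSE)
  sample_metadata(raw, qc_label = qc_label)
}

#' Validate a feature table against its sample metadata
#'
#' Collects (rather than raises) coded problems: axis mismatches, duplicate
#' IDs, out-of-range intensities, incomplete factors, malformed pairing.
#' An empty `errors` list means the dataset satisfies every structural
#' invariant the pipeline relies on.
#'
#' @param table A [feature_table()].
#' @param meta A [sample_metadata()] tibble.
#' @return A `mtb_validation` list with `errors`, `warnings` (character
#'   vectors of coded messages) and summary counts `n_features`, `n_samples`,
#'   `n_qc`, `missing_fraction`.
#' @export
validate_dataset <- function(table, meta) {
  errors <- character()
  warnings <- character()
  samples <- ft_samples(table)
  m <- ft_matrix(table)

  if (anyDuplicated(table$feature_id)) errors <- c(errors, "E_DUP_FEATURE: duplicate feature IDs")
  if (anyDuplicated(samples)) errors <- c(errors, "E_DUP_SAMPLE: duplicate sample names")
  if (any(!is.na(m) & (!is.finite(m) | m < 0))) {
    errors <- c(errors, "E_BAD_INTENSITY: intensities must be missing or finite and >= 0")
  }
  missing_meta <- setdiff(samples, meta$sample)
  extra_meta <- setdiff(meta$sample, samples)
  if (length(missing_meta) > 0) {
    errors <- c(errors, paste0("E_META_MISSING: samples absent from metadata: ",
                               paste(missing_meta, collapse = ", ")))
  }
  if (length(extra_meta) > 0) {
    errors <- c(errors, paste0("E_META_EXTRA: metadata rows without a table column: ",
                               paste(extra_meta, collapse = ", ")))
  }
  factors <- meta_factors(meta)
  if (is.null(factors) || length(factors) == 0) {
    errors <- c(errors, "E_NO_FACTOR: metadata declares no factor")
  } else {
    for (f in factors) {
      if (any(is.na(meta[[f]]) | meta[[f]] == "")) {
        errors <- c(errors, sprintf("E_FACTOR_EMPTY: factor '%s' has empty values", f))
      }
    }
  }
  if ("pair" %in% names(meta)) {
    tokens <- meta$pair[!is.na(meta$pair) & meta$pair != ""]
    bad <- names(which(table(tokens) != 2))
    if (length(bad) > 0) {
      errors <- c(errors, paste0("E_PAIR: pairing token(s) not mapping exactly 2 samples: ",
                                 paste(bad, collapse = ", ")))
    }
  }
  n_qc <- sum(meta$sample_type == "qc")
  if (n_qc == 1) warnings <- c(warnings, "W_QC: a single QC sample cannot support RSD filtering")
  all_missing <- rowSums(!is.na(m)) == 0
  if (any(all_missing)) {
    warnings <- c(warnings, paste0("W_ALL_MISSING: feature(s) with no observed value: ",
                                   paste(table$feature_id[all_missing], collapse = ", ")))
  }

  structure(list(
    errors = errors, warnings = warnings,
    n_features = nrow(table), n_samples = length(samples), n_qc = n_qc,
    missing_fraction = mean(is.na(m))
  ), class = "mtb_validation")
}

#' @export
print.mtb_validation <- function(x, ...) {
  cat(sprintf("# Validation: %d features x %d samples (%d QC), %.1f%% missing\n",
              x$n_features, x$n_samples, x$n_qc, 100 * x$missing_fraction))
  if (length(x$errors) == 0) cat("  PASS: no errors\n") else {
    cat("  FAIL:\n"); for (e in x$errors) cat("  - ", e, "\n", sep = "")
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Write a tabular result to disk
#'
#' CSV output keeps full double precision (17 significant digits) so a
#' written table reads back bit-identical. XLSX output is not supported;
#' request CSV.
#'
#' @param x A data frame (feature table, statistics table, edge list, ...).
#' @param path Output file path.
#' @param format `"csv"` or `"xlsx"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "xlsx") {
    stop("xlsx writing is not supported; write csv instead", call. = FALSE)
  }
  if (nrow(x) == 0) stop("refusing to write an empty table", call. = FALSE)
  if (dir.exists(path)) stop("path is a directory: ", path, call. = FALSE)
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf_trim(df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# full-precision doubles without trailing-zero noise on integers
sprintf_trim <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) return(NA_character_)
    format(z, digits = 17, trim = TRUE)
  }, character(1))
  out
}
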