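#' Build a self-contained HTML report
#'
#' Assembles the analysis results into a single HTML document: project
#' header, introduction, and one section per entry of
#' `spec$included_sections`, each with the method and its parameters, a
#' key-numbers table, an inline result table (top rows) with the full table
#' embedded as a downloadable CSV, figures, and a templated explanation
#' paragraph whose interpolated numbers all also appear in the section's
#' key-numbers table. Figures and tables are embedded as `data:` URIs, so
#' the document needs no network access and no side-car files.
#'
#' Rendering is pure: for fixed inputs, spec and `timestamp` the output
#' bytes are identical (the wall clock is never read).
#'
#' @param spec A [report_spec()].
#' @param results Named list of inputs; sections require:
#'   `overview` — `table`, `meta`; `preprocessing` — `preprocessed`
#'   ([run_preprocess()] output); `univariate` — `univariate` (a
#'   `mtb_stats` table); `multivariate` — `pca` (optionally `plsda`);
#'   `clustering` — `clustering` (a `mtb_hclust` of samples) and
#'   `preprocessed`; `correlation_network` — `network`.
#' @param timestamp Injected generation timestamp (character); defaults to
#'   `spec$date`.
#' @return A `mtb_report` list: `html` (single character scalar) and
#'   `manifest` (tibble of section, artifact, checksum).
#' @export
build_report <- function(spec, results = list(), timestamp = spec$date) {
  stopifnot(inherits(spec, "mtb_reportspec"))
  manifest <- list()
  note_artifact <- function(section, artifact, content) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      section = section, artifact = artifact,
      checksum = digest::digest(content, algo = "sha256")
    )
  }
  sections_html <- character()
  for (sec in spec$included_sections) {
    built <- switch(sec,
      overview = section_overview(spec, results),
      preprocessing = section_preprocessing(spec, results),
      univariate = section_univariate(spec, results),
      multivariate = section_multivariate(spec, results),
      clustering = section_clustering(spec, results),
      correlation_network = section_network(spec, results)
    )
    for (nm in names(built$artifacts)) note_artifact(sec, nm, built$artifacts[[nm]])
    sections_html <- c(sections_html, built$html)
  }
  intro <- spec$introduction %||%
    glue_template("intro.md", list(project_name = spec$project_name))
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>", html_escape(spec$project_name), "</title>\n",
    "<style>", report_css(), "</style>\n</head>\n<body>\n",
    "<header>\n<h1>", html_escape(spec$project_name), "</h1>\n",
    "<p class=\"meta\">", html_escape(spec$authors_lab),
    " &mdash; ", html_escape(spec$date),
    " &mdash; generated ", html_escape(timestamp), "</p>\n</header>\n",
    "<section id=\"introduction\"><h2>Introduction</h2><p>",
    html_escape(intro), "</p></section>\n",
    paste(sections_html, collapse = "\n"),
    "\n</body>\n</html>\n"
  )
  structure(list(
    html = html,
    manifest = if (length(manifest)) dplyr::bind_rows(manifest) else
      tibble::tibble(section = character(), artifact = character(), checksum = character())
  ), class = "mtb_report")
}

#' Write a report bundle to disk
#' @param bundle A `mtb_report` from [build_report()].
#' @param path Output `.html` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "mtb_report"))
  writeLines(bundle$html, path, useBytes = TRUE)
  invisible(path)
}

#' @export
print.mtb_report <- function(x, ...) {
  cat(sprintf("# HTML report: %d sections, %d embedded artifacts, %.0f kB\n",
              length(unique(x$manifest$section)), nrow(x$manifest),
              nchar(x$html, type = "bytes") / 1024))
  invisible(x)
}

# ---- section builders -------------------------------------------------

need_result <- function(results, what, section) {
  for (w in what) {
    if (is.null(results[[w]])) {
      stop(sprintf("section '%s' needs results$%s", section, w), call. = FALSE)
    }
  }
}

section_overview <- function(spec, results) {
  need_result(results, c("table", "meta"), "overview")
  table <- results$table; meta <- results$meta
  rep <- validate_dataset(table, meta)
  fct <- meta_factors(meta)[1]
  vals <- list(
    n_features = rep$n_features, n_samples = rep$n_samples, n_qc = rep$n_qc,
    n_groups = length(unique(meta[[fct]][meta$sample_type == "biological"])),
    missing_pct = sprintf("%.1f%%", 100 * rep$missing_fraction)
  )
  key <- key_table(vals)
  group_tab <- dplyr::count(dplyr::filter(meta, .data$sample_type == "biological"),
                            .data[[fct]], name = "n_samples")
  expl <- glue_template("explain_overview.md", vals)
  html <- section_html("overview", "Dataset overview",
                       method = "Structural validation of the submitted feature table and metadata.",
                       key = key, tables = list(`Samples per group` = group_tab),
                       figures = list(), explanation = expl, spec = spec)
  list(html = html$html, artifacts = html$artifacts)
}

section_preprocessing <- function(spec, results) {
  need_result(results, c("preprocessed", "meta"), "preprocessing")
  pp <- results$preprocessed
  f <- pp$normalization_factors
  vals <- list(
    n_removed = nrow(pp$removed_features),
    n_kept = nrow(pp$table),
    factor_min = sprintf("%.3g", min(f)),
    factor_max = sprintf("%.3g", max(f))
  )
  key <- key_table(vals)
  method_line <- paste(
    sprintf("%s (%s%s)", pp$provenance$stage, pp$provenance$method,
            ifelse(pp$provenance$parameters == "", "",
                   paste0(", ", pp$provenance$parameters))),
    collapse = " &rarr; ")
  m <- ft_matrix(pp$table)
  tic <- tibble::tibble(
    sample = colnames(m),
    group = results$meta[[meta_factors(results$meta)[1]]][
      match(colnames(m), results$meta$sample)],
    total_intensity = colSums(m)
  )
  dens <- tidyr::pivot_longer(tibble::as_tibble(pp$table), -"feature_id",
                              names_to = "sample", values_to = "value")
  figs <- list(
    `TIC boxplot` = render_figure(tic, "tic_boxplot", spec),
    `Density plot` = render_figure(dens, "density", spec)
  )
  expl <- glue_template("explain_preprocessing.md", vals)
  tabs <- list(`Provenance` = pp$provenance)
  if (nrow(pp$removed_features) > 0) tabs$`Removed features (QC RSD)` <- pp$removed_features
  html <- section_html("preprocessing", "Preprocessing",
                       method = paste("Stages:", method_line),
                       key = key, tables = tabs, figures = figs,
                       explanation = expl, spec = spec)
  list(html = html$html, artifacts = html$artifacts)
}

section_univariate <- function(spec, results) {
  need_result(results, "univariate", "univariate")
  st <- results$univariate
  vals <- list(
    test_name = attr(st, "test") %||% "per-feature test",
    n_sig = sum(st$fdr < 0.05, na.rm = TRUE),
    n_tested = nrow(st)
  )
  key <- key_table(vals)
  top <- dplyr::arrange(st, .data$fdr)
  figs <- list()
  if (all(c("log2_fc", "fdr") %in% names(st))) {
    figs$`Volcano plot` <- render_figure(st, "volcano", spec)
  }
  expl <- glue_template("explain_univariate.md", vals)
  html <- section_html("univariate", "Univariate statistics",
                       method = sprintf("%s with Benjamini-Hochberg FDR control across %d features.",
                                        vals$test_name, vals$n_tested),
                       key = key, tables = list(`Top features` = top),
                       figures = figs, explanation = expl, spec = spec)
  list(html = html$html, artifacts = html$artifacts)
}

section_multivariate <- function(spec, results) {
  need_result(results, "pca", "multivariate")
  pca <- results$pca
  has_plsda <- !is.null(results$plsda)
  plsda_sentence <- if (has_plsda) {
    pl <- results$plsda
    sprintf(paste("The supervised PLS-DA model explains R2Y = %s of the group",
                  "structure with cross-validated Q2 = %s (%d-fold); Q2 well above 0",
                  "indicates group differences that survive cross-validation."),
            sprintf("%.2f", pl$r2y), sprintf("%.2f", pl$q2), pl$cv_folds)
  } else ""
  vals <- list(
    pc1_pct = sprintf("%.1f%%", 100 * pca$explained[1]),
    pc2_pct = if (pca$n_components >= 2) sprintf("%.1f%%", 100 * pca$explained[2]) else "NA",
    plsda_sentence = plsda_sentence
  )
  keyvals <- vals[c("pc1_pct", "pc2_pct")]
  if (has_plsda) {
    keyvals$r2y <- sprintf("%.2f", results$plsda$r2y)
    keyvals$q2 <- sprintf("%.2f", results$plsda$q2)
    keyvals$cv_folds <- results$plsda$cv_folds
  }
  key <- key_table(keyvals)
  sc <- pca$scores
  attr(sc, "explained") <- pca$explained
  figs <- list(`PCA scores` = render_figure(sc, "pca_scores", spec))
  tabs <- list(`PCA scores` = pca$scores, `PCA loadings` = pca$loadings)
  if (has_plsda) {
    scp <- results$plsda$scores
    attr(scp, "explained") <- results$plsda$explained_x
    figs$`PLS-DA scores` <- render_figure(scp, "plsda_scores", spec)
    tabs$`VIP scores` <- dplyr::arrange(results$plsda$vip, dplyr::desc(.data$vip))
  }
  expl <- glue_template("explain_multivariate.md", vals)
  html <- section_html("multivariate", "Multivariate analysis",
                       method = sprintf("PCA on the preprocessed table (%d components)%s.",
                                        pca$n_components,
                                        if (has_plsda) sprintf("; PLS-DA (NIPALS, %d components, %d-fold CV)",
                                                               results$plsda$n_components,
                                                               results$plsda$cv_folds) else ""),
                       key = key, tables = tabs, figures = figs,
                       explanation = expl, spec = spec)
  list(html = html$html, artifacts = html$artifacts)
}

section_clustering <- function(spec, results) {
  need_result(results, c("clustering", "preprocessed"), "clustering")
  cl <- results$clustering
  pp <- results$preprocessed
  vals <- list(axis = cl$axis, distance = cl$distance, linkage = cl$linkage)
  key <- key_table(vals)
  m <- ft_matrix(pp$table)
  sample_order <- if (cl$axis == "samples") cl$ordered_labels else colnames(m)
  feat_cl <- hierarchical_clustering(pp$table, axis = "features",
                                     distance = cl$distance, linkage = cl$linkage)
  long <- tidyr::pivot_longer(tibble::as_tibble(pp$table), -"feature_id",
                              names_to = "sample", values_to = "value")
  long$sample <- factor(long$sample, levels = sample_order)
  long$feature_id <- factor(long$feature_id, levels = feat_cl$ordered_labels)
  figs <- list(`Clustered heatmap` = render_figure(long, "heatmap_dendrogram", spec))
  expl <- glue_template("explain_clustering.md", vals)
  html <- section_html("clustering", "Hierarchical clustering",
                       method = sprintf("Agglomerative clustering of %s (%s distance, %s linkage).",
                                        cl$axis, cl$distance, cl$linkage),
                       key = key, tables = list(`Merge history` = tidy.mtb_hclust(cl)),
                       figures = figs, explanation = expl, spec = spec)
  list(html = html$html, artifacts = html$artifacts)
}

section_network <- function(spec, results) {
  need_result(results, "network", "correlation_network")
  nw <- results$network
  vals <- list(
    r_threshold = format(nw$r_threshold), fdr_threshold = format(nw$fdr_threshold),
    n_nodes = nrow(nw$nodes), n_edges = nrow(nw$edges)
  )
  key <- key_table(vals)
  figs <- list()
  if (nrow(nw$edges) > 0) {
    figs$`Network` <- render_figure(nw$edges, "network", spec)
  }
  expl <- glue_template("explain_correlation_network.md", vals)
  html <- section_html("correlation_network", "Correlation network",
                       method = sprintf("Correlation-threshold network: |r| >= %s and FDR <= %s.",
                                        vals$r_threshold, vals$fdr_threshold),
                       key = key,
                       tables = list(`Edges` = nw$edges, `Nodes` = nw$nodes),
                       figures = figs, explanation = expl, spec = spec)
  list(html = html$html, artifacts = html$artifacts)
}

# ---- html helpers -----------------------------------------------------

key_table <- function(vals) {
  vals <- vals[!vapply(vals, function(v) identical(v, ""), logical(1))]
  tibble::tibble(quantity = names(vals),
                 value = vapply(vals, function(v) paste(format(v), collapse = " "), character(1)))
}

section_html <- function(id, title, method, key, tables, figures, explanation, spec) {
  artifacts <- list()
  parts <- c(sprintf("<section id=\"%s\">", id),
             sprintf("<h2>%s</h2>", html_escape(title)),
             sprintf("<p class=\"method\"><strong>Method.</strong> %s</p>", method))
  parts <- c(parts, "<h3>Key numbers</h3>", html_table(key, max_rows = nrow(key)))
  artifacts[["key_numbers"]] <- key
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    parts <- c(parts,
               sprintf("<h3>%s</h3>", html_escape(nm)),
               html_table(tab, max_rows = 10),
               csv_download_link(tab, paste0(gsub("[^A-Za-z0-9]+", "_", tolower(nm)), ".csv")))
    artifacts[[paste0("table:", nm)]] <- tab
  }
  for (nm in names(figures)) {
    bytes <- figures[[nm]]
    parts <- c(parts,
               sprintf("<h3>%s</h3>", html_escape(nm)),
               embed_image(bytes, spec$figure_format, nm))
    artifacts[[paste0("figure:", nm)]] <- bytes
  }
  parts <- c(parts,
             sprintf("<p class=\"explanation\">%s</p>", html_escape(explanation)),
             "</section>")
  list(html = paste(parts, collapse = "\n"), artifacts = artifacts)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  # re-allow entities we intentionally emit
  x <- gsub("&amp;(mdash|rarr|ge|le);", "&\\1;", x)
  x
}

format_cell <- function(v) {
  if (is.numeric(v)) {
    vapply(v, function(z) {
      if (is.na(z)) "" else if (z == round(z) && abs(z) < 1e15) format(z, scientific = FALSE)
      else format(signif(z, 4))
    }, character(1))
  } else {
    ifelse(is.na(v), "", as.character(v))
  }
}

html_table <- function(df, max_rows = 10) {
  shown <- utils::head(df, max_rows)
  head_row <- paste0("<tr>", paste0("<th>", html_escape(names(shown)), "</th>", collapse = ""), "</tr>")
  body <- apply(as.data.frame(lapply(shown, format_cell)), 1, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(r), "</td>", collapse = ""), "</tr>")
  })
  note <- if (nrow(df) > max_rows) {
    sprintf("<p class=\"note\">Showing %d of %d rows; the full table is downloadable below.</p>",
            max_rows, nrow(df))
  } else ""
  paste0("<table>\n", head_row, "\n", paste(body, collapse = "\n"), "\n</table>\n", note)
}

csv_download_link <- function(df, filename) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(as.data.frame(df), tmp, row.names = FALSE)
  enc <- gsub("\n", "", jsonlite::base64_enc(readBin(tmp, "raw", file.info(tmp)$size)))
  sprintf("<p><a download=\"%s\" href=\"data:text/csv;base64,%s\">Download full table (CSV)</a></p>",
          filename, enc)
}

embed_image <- function(bytes, format, alt) {
  mime <- switch(format, png = "image/png", pdf = "application/pdf",
                 tiff = "image/tiff", svg = "image/svg+xml")
  enc <- gsub("\n", "", jsonlite::base64_enc(bytes))
  if (format == "pdf") {
    sprintf("<p><a download=\"%s.pdf\" href=\"data:%s;base64,%s\">Download figure (PDF)</a></p>",
            gsub("[^A-Za-z0-9]+", "_", tolower(alt)), mime, enc)
  } else {
    sprintf("<img alt=\"%s\" src=\"data:%s;base64,%s\"/>", html_escape(alt), mime, enc)
  }
}

glue_template <- function(template, vals) {
  path <- system.file("templates", template, package = "metabokit")
  if (path == "") stop("template not installed: ", template, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = " ")
  as.character(glue::glue_data(vals, txt))
}

report_css <- function() {
  paste(
    "body{font-family:Helvetica,Arial,sans-serif;max-width:900px;margin:2em auto;",
    "padding:0 1em;color:#222;line-height:1.5}",
    "h1{border-bottom:2px solid #444}h2{border-bottom:1px solid #bbb;margin-top:2em}",
    "table{border-collapse:collapse;font-size:0.85em;margin:0.5em 0}",
    "th,td{border:1px solid #ccc;padding:2px 8px;text-align:left}",
    "th{background:#f0f0f0}",
    "img{max-width:100%;border:1px solid #eee;margin:0.5em 0}",
    ".meta{color:#666}.note{color:#666;font-size:0.85em}",
    ".explanation{background:#f7f7f7;padding:0.8em;border-left:3px solid #888}",
    sep = "")
}
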