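#' Report specification
#'
#' Project header fields and presentation choices for [build_report()] and
#' [render_figure()].
#'
#' @param project_name Project title (non-empty).
#' @param authors_lab Lab / author names.
#' @param date ISO-8601 date string.
#' @param introduction Introductory text; `NULL` uses the template shipped
#'   with the package (original text, editable under `inst/templates/`).
#' @param included_sections Ordered subset of `"overview"`,
#'   `"preprocessing"`, `"univariate"`, `"multivariate"`, `"clustering"`,
#'   `"correlation_network"`.
#' @param figure_format `"png"`, `"pdf"`, `"tiff"` or `"svg"`.
#' @param palette `"default"`, `"viridis"` or `"grey"`.
#' @param aspect_ratio Width over height of figures (default 4/3).
#' @return A `mtb_reportspec` list.
#' @export
report_spec <- function(project_name, authors_lab = "", date = as.character(Sys.Date()),
                        introduction = NULL,
                        included_sections = c("overview", "preprocessing", "univariate",
                                              "multivariate", "clustering",
                                              "correlation_network"),
                        figure_format = c("png", "pdf", "tiff", "svg"),
                        palette = c("default", "viridis", "grey"),
                        aspect_ratio = 4 / 3) {
  if (!nzchar(project_name)) stop("project_name must be non-empty", call. = FALSE)
  all_sections <- c("overview", "preprocessing", "univariate", "multivariate",
                    "clustering", "correlation_network")
  included_sections <- match.arg(included_sections, all_sections, several.ok = TRUE)
  if (length(included_sections) == 0) stop("included_sections must be non-empty", call. = FALSE)
  if (is.na(as.Date(date, format = "%Y-%m-%d"))) {
    stop("date must be an ISO-8601 date (YYYY-MM-DD): ", date, call. = FALSE)
  }
  figure_format <- match.arg(figure_format)
  palette <- match.arg(palette)
  stopifnot(is.numeric(aspect_ratio), aspect_ratio > 0)
  structure(list(
    project_name = project_name, authors_lab = authors_lab, date = date,
    introduction = introduction, included_sections = included_sections,
    figure_format = figure_format, palette = palette, aspect_ratio = aspect_ratio
  ), class = "mtb_reportspec")
}

figure_schemas <- list(
  tic_boxplot = c("sample", "group", "total_intensity"),
  pca_scores = c("sample", "group", "PC1", "PC2"),
  plsda_scores = c("sample", "group", "C1", "C2"),
  volcano = c("feature_id", "log2_fc", "fdr"),
  heatmap_dendrogram = c("feature_id", "sample", "value"),
  density = c("sample", "value"),
  feature_boxplot = c("feature_id", "group", "value"),
  network = c("from", "to", "r")
)

apply_palette <- function(p, spec, discrete = TRUE) {
  switch(spec$palette,
    default = p,
    viridis = p + (if (discrete) ggplot2::scale_colour_viridis_d() else
      ggplot2::scale_colour_viridis_c()) ,
    grey = p + (if (discrete) ggplot2::scale_colour_grey(start = 0.1, end = 0.7) else p)
  )
}

#' Render a publication-style figure
#'
#' Draws one of the pipeline's standard plot kinds from a tidy data frame
#' and returns the encoded image bytes. Rendering is deterministic for a
#' fixed input, format, palette and aspect ratio (no wall-clock state, no
#' random jitter; network layouts are fixed circular layouts).
#'
#' Schemas (required columns): `tic_boxplot` sample/group/total_intensity;
#' `pca_scores` sample/group/PC1/PC2; `plsda_scores` sample/group/C1/C2;
#' `volcano` feature_id/log2_fc/fdr; `heatmap_dendrogram`
#' feature_id/sample/value (factor levels give the ordering); `density`
#' sample/value; `feature_boxplot` feature_id/group/value; `network`
#' from/to/r.
#'
#' @param plot_data Data frame matching the kind's schema.
#' @param kind One of the kinds above.
#' @param spec A [report_spec()].
#' @param path Optional path to also write the image to.
#' @return Raw vector of image bytes in `spec$figure_format`.
#' @export
render_figure <- function(plot_data, kind, spec, path = NULL) {
  if (!kind %in% names(figure_schemas)) {
    stop("unknown figure kind: ", kind, call. = FALSE)
  }
  need <- figure_schemas[[kind]]
  missing_cols <- setdiff(need, names(plot_data))
  if (length(missing_cols) > 0) {
    stop(sprintf("figure kind '%s' needs column(s): %s", kind,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  p <- build_plot(plot_data, kind, spec)
  render_bytes(p, spec, path)
}

build_plot <- function(d, kind, spec) {
  p <- switch(kind,
    tic_boxplot = ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$total_intensity,
                                                  colour = .data$group)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_point(size = 1.5) +
      ggplot2::labs(x = NULL, y = "Total ion intensity", title = "Total intensity by group") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)),
    pca_scores = plot_scores(d, attr(d, "explained") %||% c(NA, NA), "PCA score plot"),
    plsda_scores = plot_scores(d, attr(d, "explained") %||% c(NA, NA), "PLS-DA score plot"),
    volcano = {
      dd <- dplyr::mutate(d, neglog_fdr = -log10(pmax(.data$fdr, 1e-300)),
                          significant = .data$fdr < 0.05)
      ggplot2::ggplot(dd, ggplot2::aes(.data$log2_fc, .data$neglog_fdr,
                                       colour = .data$significant)) +
        ggplot2::geom_point(size = 1.2, alpha = 0.7) +
        ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "firebrick")) +
        ggplot2::labs(x = "log2 fold change", y = "-log10 FDR", title = "Volcano plot") +
        ggplot2::theme_bw()
    },
    heatmap_dendrogram = {
      ggplot2::ggplot(d, ggplot2::aes(.data$sample, .data$feature_id,
                                      fill = .data$value)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
        ggplot2::labs(x = NULL, y = NULL, title = "Clustered heatmap") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5),
                       axis.text.y = ggplot2::element_blank())
    },
    density = ggplot2::ggplot(d, ggplot2::aes(.data$value, group = .data$sample,
                                              colour = .data$sample)) +
      ggplot2::geom_density() +
      ggplot2::labs(x = "Intensity", y = "Density", title = "Feature intensity distributions") +
      ggplot2::theme_bw() +
      ggplot2::theme(legend.position = "none"),
    feature_boxplot = ggplot2::ggplot(d, ggplot2::aes(.data$group, .data$value,
                                                      colour = .data$group)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_point(size = 1) +
      ggplot2::facet_wrap(~feature_id, scales = "free_y") +
      ggplot2::labs(x = NULL, y = "Intensity", title = "Feature intensities") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)),
    network = plot_network_data(d)
  )
  apply_palette(p, spec)
}

# deterministic circular layout so figure bytes are reproducible
plot_network_data <- function(edges) {
  ids <- sort(unique(c(edges$from, edges$to)))
  theta <- seq(0, 2 * pi, length.out = length(ids) + 1)[seq_along(ids)]
  nodes <- tibble::tibble(id = ids, x = cos(theta), y = sin(theta))
  seg <- dplyr::left_join(edges, dplyr::rename(nodes, from = "id", x0 = "x", y0 = "y"),
                          by = "from")
  seg <- dplyr::left_join(seg, dplyr::rename(nodes, to = "id", x1 = "x", y1 = "y"),
                          by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       linewidth = abs(.data$r)),
                          colour = "grey50", alpha = 0.7) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 3,
                        colour = "steelblue") +
    ggplot2::geom_text(data = nodes, ggplot2::aes(.data$x * 1.12, .data$y * 1.12,
                                                  label = .data$id), size = 2.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Correlation network") +
    ggplot2::theme_void()
}

render_bytes <- function(p, spec, path = NULL) {
  width <- 7
  height <- width / spec$aspect_ratio
  tmp <- tempfile(fileext = paste0(".", spec$figure_format))
  on.exit(unlink(tmp))
  switch(spec$figure_format,
    png = {
      ragg::agg_png(tmp, width = width, height = height, units = "in", res = 150)
      print(p); grDevices::dev.off()
    },
    pdf = {
      grDevices::pdf(tmp, width = width, height = height)
      print(p); grDevices::dev.off()
    },
    tiff = {
      grDevices::tiff(tmp, width = width, height = height, units = "in", res = 150,
                      type = "cairo", compression = "lzw")
      print(p); grDevices::dev.off()
    },
    svg = {
      grDevices::svg(tmp, width = width, height = height)
      print(p); grDevices::dev.off()
    }
  )
  bytes <- readBin(tmp, "raw", file.info(tmp)$size)
  if (!is.null(path)) writeBin(bytes, path)
  bytes
}
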