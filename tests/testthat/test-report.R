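# shared pipeline results on the worked-example fixture
report_inputs <- local({
  fx <- worked_example_fixture()
  pp <- run_preprocess(fx$table, fx$meta, preprocess_config())
  st <- t_tests(pp$table, fx$meta, "buccal_gland", "liver", fc_table = pp$raw_table)
  list(
    table = fx$table, meta = fx$meta, preprocessed = pp, univariate = st,
    pca = pca_ord(pp$table, fx$meta),
    plsda = plsda(pp$table, fx$meta, cv_folds = 4, seed = 1),
    clustering = hierarchical_clustering(pp$table, axis = "samples"),
    network = correlation_network(correlation_matrix(pp$table))
  )
})

demo_spec <- function(...) {
  report_spec("Lamprey tissue demo", "Metabolomics core", "2026-01-15", ...)
}

test_that("figures render deterministic bytes with the requested format magic", {
  spec <- demo_spec()
  sc <- report_inputs$pca$scores
  b1 <- render_figure(sc, "pca_scores", spec)
  b2 <- render_figure(sc, "pca_scores", spec)
  expect_gt(length(b1), 1000)
  expect_identical(b1, b2)
  expect_equal(as.integer(b1[1:8]),
               c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)) # PNG magic

  tif <- render_figure(sc, "pca_scores", demo_spec(figure_format = "tiff"))
  expect_equal(rawToChar(tif[1:2]), "II") # little-endian TIFF
  svg <- render_figure(sc, "pca_scores", demo_spec(figure_format = "svg"))
  expect_match(rawToChar(svg[1:200]), "<\\?xml|<svg")
  pdf <- render_figure(sc, "pca_scores", demo_spec(figure_format = "pdf"))
  expect_equal(rawToChar(pdf[1:4]), "%PDF")
})

test_that("figure schemas are enforced and every kind renders", {
  spec <- demo_spec()
  expect_error(render_figure(data.frame(x = 1), "volcano", spec), "log2_fc")
  expect_error(render_figure(data.frame(x = 1), "nope", spec), "unknown")

  pp <- report_inputs$preprocessed
  m <- ft_matrix(pp$table)
  meta <- report_inputs$meta
  datasets <- list(
    tic_boxplot = tibble::tibble(
      sample = colnames(m),
      group = meta$group[match(colnames(m), meta$sample)],
      total_intensity = colSums(m)),
    volcano = report_inputs$univariate,
    density = tidyr::pivot_longer(tibble::as_tibble(pp$table), -feature_id,
                                  names_to = "sample", values_to = "value"),
    feature_boxplot = tidyr::pivot_longer(
      tibble::as_tibble(pp$table[1:4, ]), -feature_id,
      names_to = "sample", values_to = "value") |>
      dplyr::mutate(group = meta$group[match(sample, meta$sample)]),
    network = report_inputs$network$edges,
    plsda_scores = report_inputs$plsda$scores
  )
  for (kind in names(datasets)) {
    bytes <- render_figure(datasets[[kind]], kind, spec)
    expect_gt(length(bytes), 500)
  }
})

test_that("a minimal overview-only report carries the header and one section", {
  spec <- report_spec("Tiny", "Lab X", "2026-02-01", included_sections = "overview")
  b <- build_report(spec, list(table = report_inputs$table, meta = report_inputs$meta),
                    timestamp = "2026-02-01T08:00:00Z")
  expect_match(b$html, "Tiny")
  expect_match(b$html, "2026-02-01")
  expect_equal(length(gregexpr("<h2>", b$html)[[1]]), 2) # Introduction + overview
  expect_equal(unique(b$manifest$section), "overview")
})

test_that("a full report is self-contained, valid HTML, and pure given a timestamp", {
  spec <- demo_spec()
  b1 <- build_report(spec, report_inputs, timestamp = "2026-02-01T08:00:00Z")
  b2 <- build_report(spec, report_inputs, timestamp = "2026-02-01T08:00:00Z")
  expect_identical(b1$html, b2$html)

  # no external references anywhere
  expect_length(grep("(src|href)\\s*=\\s*[\"'](https?:)?//",
                     b1$html), 0)
  refs <- regmatches(b1$html, gregexpr("(src|href)=\"[^\"]{0,12}", b1$html))[[1]]
  expect_true(all(grepl("=\"data:", refs)))

  # parses as HTML with all six sections in order
  doc <- xml2::read_html(b1$html)
  ids <- xml2::xml_attr(xml2::xml_find_all(doc, "//section"), "id")
  expect_equal(ids, c("introduction", "overview", "preprocessing", "univariate",
                      "multivariate", "clustering", "correlation_network"))

  # manifest checksums match the embedded artifacts
  expect_gt(nrow(b1$manifest), 10)
  expect_identical(b1$manifest, b2$manifest)
})

test_that("explanation paragraphs only print numbers present in the key table", {
  spec <- demo_spec()
  b <- build_report(spec, report_inputs, timestamp = "2026-02-01T08:00:00Z")
  doc <- xml2::read_html(b$html)
  for (sec in xml2::xml_find_all(doc, "//section[@id!='introduction']")) {
    expl <- xml2::xml_text(xml2::xml_find_first(sec, ".//p[@class='explanation']"))
    key <- xml2::xml_text(xml2::xml_find_all(sec, ".//table[1]//td"))
    nums <- regmatches(expl, gregexpr("(?<![A-Za-z0-9])[0-9]+\\.?[0-9]*%?",
                                      expl, perl = TRUE))[[1]]
    # numbers interpolated by templates (not template prose constants like
    # "5%" or "0.05") must appear verbatim in the key-numbers table
    interpolated <- setdiff(nums, c("5%", "0.05", "2", "1000", "0"))
    section_text <- paste(key, collapse = " ")
    for (v in interpolated) {
      expect_match(section_text, v, fixed = TRUE,
                   label = sprintf("value %s of section %s", v,
                                   xml2::xml_attr(sec, "id")))
    }
  }
})

test_that("missing section inputs raise errors naming the section", {
  spec <- report_spec("X", date = "2026-01-01", included_sections = "univariate")
  expect_error(build_report(spec, list()), "univariate")
  expect_error(report_spec(""), "non-empty")
  expect_error(report_spec("X", date = "01/02/2026"), "ISO-8601")
})
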