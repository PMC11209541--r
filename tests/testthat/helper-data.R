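# small fixtures built in code

toy_table <- function(m = NULL) {
  if (is.null(m)) {
    m <- matrix(c(10, 12, 11, 100, 9, 11,
                  20, 22, 21, 200, 19, 21,
                  30, 33, 31, 300, 29, 31), nrow = 3, byrow = TRUE)
    dimnames(m) <- list(paste0("f", 1:3),
                        c("a_1", "a_2", "a_3", "b_1", "QC_1", "QC_2"))
  }
  feature_table(dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)),
                                 tibble::as_tibble(m, .name_repair = "minimal")))
}

toy_meta <- function(samples = c("a_1", "a_2", "a_3", "b_1", "QC_1", "QC_2")) {
  parse_metadata_from_names(samples, fields = "group")
}

# random positive feature table with groups and QCs
random_dataset <- function(n_features = 20, n_per_group = 4, n_qc = 3, seed = 7) {
  cfg <- sim_config(
    n_features = n_features,
    groups = c(g1 = n_per_group, g2 = n_per_group),
    n_qc = n_qc, seed = seed
  )
  simulate_dataset(cfg)
}

write_toy_csv <- function(path, cells) {
  writeLines(cells, path)
  path
}

# build a small xlsx at test time with the pre-installed python/openpyxl,
# for read-equivalence checks (no R xlsx writer is part of this stack)
make_xlsx <- function(rows, path) {
  data_json <- tempfile(fileext = ".json")
  jsonlite::write_json(rows, data_json, auto_unbox = TRUE, digits = NA, na = "null")
  py <- c(
    "import json, sys, openpyxl",
    sprintf("rows = json.load(open(%s))", jsonlite::toJSON(data_json, auto_unbox = TRUE)),
    "wb = openpyxl.Workbook()",
    "ws = wb.active",
    "for row in rows:",
    "    ws.append(row)",
    sprintf("wb.save(%s)", jsonlite::toJSON(path, auto_unbox = TRUE))
  )
  script <- tempfile(fileext = ".py")
  writeLines(py, script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  unlink(c(script, data_json))
  status == 0
}
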