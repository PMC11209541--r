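make_ft2 <- function(m) {
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  toy_table(m)
}

test_that("RSD follows the sample-sd definition and rejects degenerate input", {
  expect_equal(compute_rsd(c(10, 10, 10)), 0)
  expect_equal(compute_rsd(c(8, 10, 12)), 20) # sd 2, mean 10
  expect_error(compute_rsd(5), "at least 2")
  expect_error(compute_rsd(c(-1, 1)), "zero mean")
})

test_that("QC-RSD filter removes unstable features, monotonically in the threshold", {
  m <- rbind(c(5, 6, 8, 10, 12),   # QC rsd 20
             c(5, 6, 10, 10, 10),  # QC rsd 0
             c(5, 6, 5, 10, 30))   # QC rsd 86.6
  dimnames(m) <- list(paste0("f", 1:3), c("a_1", "a_2", "QC_1", "QC_2", "QC_3"))
  ft <- toy_table(m)
  meta <- toy_meta(colnames(m))

  keep30 <- qc_rsd_filter(ft, meta, 30)
  expect_equal(keep30$table$feature_id, c("f1", "f2"))
  expect_equal(keep30$removed$rsd_pct, compute_rsd(c(5, 10, 30)))

  keep15 <- qc_rsd_filter(ft, meta, 15)
  expect_equal(keep15$table$feature_id, "f2")
  expect_equal(keep15$removed$feature_id[1], "f3") # sorted by RSD descending
  expect_equal(keep15$removed$rsd_pct[2], 20)

  # threshold 0 removes everything with any QC variation
  keep0 <- qc_rsd_filter(ft, meta, 0)
  expect_equal(keep0$table$feature_id, "f2")

  # monotone: lower threshold removes a superset
  expect_true(all(keep30$removed$feature_id %in% keep15$removed$feature_id))
  # biological columns untouched
  expect_equal(ft_matrix(keep30$table)[, c("a_1", "a_2")], ft_matrix(ft)[1:2, c("a_1", "a_2")])
  expect_error(qc_rsd_filter(ft, toy_meta(c("a_1", "a_2", "b_1", "b_2", "QC_1")), 30),
               "2 QC")
})

test_that("PQN recovers exact dilution factors and matches the brute-force oracle", {
  # scalar-multiple construction: B = 2A; normalized columns must coincide
  m <- cbind(A_1 = c(1, 2, 3, 4), B_1 = c(2, 4, 6, 8))
  rownames(m) <- paste0("f", 1:4)
  res <- normalize_intensities(toy_table(m), toy_meta(colnames(m)), "pqn")
  expect_equal(unname(ft_matrix(res$table)[, 1]), unname(ft_matrix(res$table)[, 2]),
               tolerance = 1e-12)
  expect_equal(unname(res$factors[2] / res$factors[1]), 2, tolerance = 1e-12)

  # exact scalar factors for c in {0.5, 1, 3} against a QC reference
  set.seed(5)
  base <- rlnorm(30, 5, 1)
  scalars <- c(0.5, 1, 3)
  m2 <- cbind(QC_1 = base, QC_2 = base,
              g_1 = base * 0.5, g_2 = base * 1, g_3 = base * 3)
  rownames(m2) <- paste0("f", seq_len(30))
  meta2 <- toy_meta(colnames(m2))
  res2 <- normalize_intensities(toy_table(m2), meta2, "pqn")
  expect_equal(unname(res2$factors[c("g_1", "g_2", "g_3")]), scalars, tolerance = 1e-12)

  # random matrix vs oracle
  set.seed(8)
  m3 <- matrix(rlnorm(50 * 8, 5, 1), 50, 8)
  dimnames(m3) <- list(paste0("f", 1:50), paste0("g_", 1:8))
  res3 <- normalize_intensities(toy_table(m3), toy_meta(colnames(m3)), "pqn")
  want <- oracle_pqn(m3, ref_cols = seq_len(8)) # no QCs: reference = all samples
  expect_equal(unname(res3$factors), want$factors, tolerance = 1e-12)
  expect_equal(unname(ft_matrix(res3$table)), unname(want$m), tolerance = 1e-12)
})

test_that("PQN is idempotent when the reference is recomputed from normalized QCs", {
  sim <- random_dataset(n_features = 25, seed = 13)
  ft <- impute_missing(sim$table, "min5")
  once <- normalize_intensities(ft, sim$meta, "pqn")
  twice <- normalize_intensities(once$table, sim$meta, "pqn")
  expect_equal(unname(twice$factors), rep(1, length(twice$factors)), tolerance = 1e-10)
  expect_equal(ft_matrix(twice$table), ft_matrix(once$table), tolerance = 1e-10)
})

test_that("quantile normalization equalizes column multisets with the tie rule", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  res <- normalize_intensities(make_ft2(m), toy_meta(c("x_1", "y_1")), "quantile")
  expect_equal(unname(ft_matrix(res$table)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(ft_matrix(res$table)[, 2]), c(2.5, 3.5, 4.5))

  # ties get the mean of implicated reference positions
  mt <- cbind(s1 = c(5, 5, 1), s2 = c(2, 4, 6))
  got <- ft_matrix(normalize_intensities(make_ft2(mt),
                                         toy_meta(c("x_1", "y_1")), "quantile")$table)
  want <- oracle_quantile(mt)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)

  # property: identical multisets and equal column means on random data
  set.seed(21)
  mr <- matrix(rlnorm(40 * 5), 40, 5)
  gotr <- ft_matrix(normalize_intensities(make_ft2(mr),
                                          toy_meta(paste0("g_", 1:5)), "quantile")$table)
  for (j in 2:5) expect_equal(unname(sort(gotr[, j])), unname(sort(gotr[, 1])),
                              tolerance = 1e-12)
  expect_equal(unname(colMeans(gotr)), rep(mean(colMeans(apply(mr, 2, sort))), 5),
               tolerance = 1e-12)
})

test_that("baseline normalization equalizes per-sample means/medians", {
  m <- cbind(s1 = c(5, 10, 15), s2 = c(10, 20, 30)) # means 10, 20; grand 15
  res <- normalize_intensities(make_ft2(m), toy_meta(c("x_1", "y_1")), "baseline_mean")
  expect_equal(unname(res$factors), c(10 / 15, 20 / 15), tolerance = 1e-12)
  expect_equal(unname(colMeans(ft_matrix(res$table))), c(15, 15), tolerance = 1e-10)

  set.seed(31)
  mr <- matrix(rlnorm(30 * 6, 5, 1), 30, 6)
  res2 <- normalize_intensities(make_ft2(mr), toy_meta(paste0("g_", 1:6)), "baseline_median")
  med <- apply(ft_matrix(res2$table), 2, median)
  expect_equal(unname(med), rep(med[[1]], 6), tolerance = 1e-10)
})

test_that("internal-standard normalization uses the IS profile at original magnitude", {
  set.seed(41)
  m <- matrix(rlnorm(10 * 4, 5, 1), 10, 4)
  rownames(m) <- paste0("f", 1:10)
  colnames(m) <- paste0("g_", 1:4)
  meta <- toy_meta(colnames(m))
  attr(meta, "internal_standard_feature") <- "f1"
  res <- normalize_intensities(toy_table(m), meta, "internal_standard")
  # after normalization the IS feature is flat across samples
  is_row <- ft_matrix(res$table)["f1", ]
  expect_equal(unname(is_row), rep(exp(mean(log(m[1, ]))), 4), tolerance = 1e-12)
  # geometric-mean rescaling keeps factors centred on 1
  expect_equal(exp(mean(log(res$factors))), 1, tolerance = 1e-12)
  expect_error(normalize_intensities(toy_table(m), toy_meta(colnames(m)), "internal_standard"),
               "internal-standard")
})

test_that("log10 transform is exact and rejects non-positive cells", {
  m <- cbind(s1 = c(1, 10, 100))
  got <- ft_matrix(log_transform(make_ft2(m)))
  expect_equal(unname(got[, 1]), c(0, 1, 2))
  ones <- matrix(1, 3, 2)
  expect_true(all(ft_matrix(log_transform(make_ft2(ones))) == 0))
  mz <- cbind(s1 = c(0, 5, 5))
  expect_error(log_transform(make_ft2(mz)), "f1")
})

test_that("the six scalings follow their definitions", {
  m <- rbind(f = c(1, 2, 3))
  colnames(m) <- paste0("s", 1:3)
  sc <- function(method) unname(ft_matrix(scale_features(make_ft2(m), method))[1, ])
  expect_equal(sc("center"), c(-1, 0, 1))
  expect_equal(sc("auto"), c(-1, 0, 1))        # sd = 1
  expect_equal(sc("pareto"), c(-1, 0, 1))      # sqrt(sd) = 1
  expect_equal(sc("vast"), c(-2, 0, 2))        # (x-m)/s * m/s, m/s = 2
  expect_equal(sc("range"), c(-0.5, 0, 0.5))
  expect_equal(sc("level"), c(-0.5, 0, 0.5))   # (x-m)/m
})

test_that("auto scaling standardizes and all scalings are permutation-equivariant", {
  set.seed(51)
  m <- matrix(rlnorm(20 * 6), 20, 6)
  ft <- make_ft2(m)
  auto <- ft_matrix(scale_features(ft, "auto"))
  expect_equal(unname(rowMeans(auto)), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(auto, 1, sd)), rep(1, 20), tolerance = 1e-12)
  centred <- ft_matrix(scale_features(ft, "center"))
  expect_equal(apply(centred, 1, var), apply(ft_matrix(ft), 1, var), tolerance = 1e-12)

  perm <- sample(20)
  for (method in c("center", "auto", "pareto", "range", "vast", "level")) {
    full <- ft_matrix(scale_features(ft, method))
    shuffled <- ft_matrix(scale_features(make_ft2(m[perm, ]), method))
    expect_equal(unname(shuffled), unname(full[perm, ]), tolerance = 1e-12,
                 label = method)
  }
})

test_that("degenerate features error unless dropped by flag", {
  m <- rbind(c(2, 2, 2), c(1, 2, 3))
  expect_error(scale_features(make_ft2(m), "auto"), "f1")
  dropped <- scale_features(make_ft2(m), "auto", drop_degenerate = TRUE)
  expect_equal(dropped$feature_id, "f2")
})
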