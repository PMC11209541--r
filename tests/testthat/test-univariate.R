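# deterministic two-group dataset on the positive scale
two_group_ft <- function(m, groups = c("a", "a", "a", "b", "b", "b")) {
  colnames(m) <- paste0(groups, "_", stats::ave(seq_along(groups), groups, FUN = seq_along))
  rownames(m) <- paste0("f", seq_len(nrow(m)))
  list(table = toy_table(m), meta = parse_metadata_from_names(colnames(m), fields = "group"))
}

test_that("fold change follows the unpaired and paired definitions", {
  d <- two_group_ft(rbind(c(10, 10, 10, 2, 2, 2),
                          c(5, 5, 5, 5, 5, 5)))
  fc <- fold_change(d$table, d$meta, "a", "b")
  expect_equal(fc$fold_change, c(5, 1))
  expect_equal(fc$log2_fc, c(log2(5), 0))
  expect_equal(fc$direction, c(1, 0))

  # paired: geometric mean of per-pair ratios
  m <- rbind(c(2, 8, 1, 1))
  colnames(m) <- c("a_1", "a_2", "b_1", "b_2")
  rownames(m) <- "f1"
  meta <- parse_metadata_from_names(colnames(m), fields = "group")
  meta$pair <- c("p1", "p2", "p1", "p2")
  fcp <- fold_change(toy_table(m), meta, "a", "b", paired = TRUE)
  expect_equal(fcp$fold_change, 4) # sqrt(2 * 8)
  # symmetry under swap
  fcq <- fold_change(toy_table(m), meta, "b", "a", paired = TRUE)
  expect_equal(fcq$fold_change, 1 / 4)
})

test_that("Student t on [1,2,3] vs [4,5,6] matches the closed form", {
  d <- two_group_ft(rbind(c(1, 2, 3, 4, 5, 6)))
  st <- t_tests(d$table, d$meta, "a", "b", equal_var = TRUE)
  expect_equal(st$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(st$df, 4)
  expect_equal(st$p_value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(round(st$p_value, 5), 0.02131)
})

test_that("t-tests agree with stats::t.test across variants on random data", {
  set.seed(61)
  m <- matrix(rlnorm(15 * 8, 3, 0.4), 15, 8)
  d <- two_group_ft(m, groups = rep(c("a", "b"), each = 4))
  meta <- d$meta
  meta$pair <- rep(paste0("p", 1:4), 2)
  variants <- list(
    welch = list(paired = FALSE, equal_var = FALSE),
    student = list(paired = FALSE, equal_var = TRUE),
    paired = list(paired = TRUE, equal_var = FALSE)
  )
  for (nm in names(variants)) {
    v <- variants[[nm]]
    st <- t_tests(d$table, meta, "a", "b", paired = v$paired, equal_var = v$equal_var)
    for (i in seq_len(nrow(m))) {
      ref <- t.test(m[i, 1:4], m[i, 5:8], paired = v$paired, var.equal = v$equal_var)
      expect_equal(st$statistic[i], unname(ref$statistic), tolerance = 1e-10,
                   label = paste(nm, i))
      expect_equal(st$p_value[i], ref$p.value, tolerance = 1e-10)
      expect_equal(st$df[i], unname(ref$parameter), tolerance = 1e-10)
    }
  }
})

test_that("identical groups give statistic 0 and p 1", {
  d <- two_group_ft(rbind(c(1, 2, 3, 1, 2, 3), c(4, 4, 4, 4, 4, 4)))
  st <- t_tests(d$table, d$meta, "a", "b", equal_var = TRUE)
  expect_equal(st$statistic[1], 0)
  expect_equal(st$p_value[1], 1)
  # constant equal groups: zero variance, equal means -> 0 / 1, no error
  expect_equal(st$statistic[2], 0)
  expect_equal(st$p_value[2], 1)
  expect_equal(st$fold_change, c(1, 1))
})

test_that("one-way ANOVA matches hand-computed sums of squares and aov", {
  m <- rbind(c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  colnames(m) <- paste0(rep(c("a", "b", "c"), each = 3), "_", rep(1:3, 3))
  rownames(m) <- "f1"
  meta <- parse_metadata_from_names(colnames(m), fields = "group")
  an <- anova_test(toy_table(m), meta)
  expect_equal(an$statistic, 27, tolerance = 1e-12) # SSB 54/2 over SSW 6/6
  expect_equal(an$df1, 2)
  expect_equal(an$df2, 6)
  expect_equal(an$p_value, pf(27, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # against aov on random data
  set.seed(71)
  mr <- matrix(rlnorm(10 * 9, 2, 0.5), 10, 9)
  colnames(mr) <- colnames(m)
  rownames(mr) <- paste0("f", 1:10)
  anr <- anova_test(toy_table(mr), meta)
  g <- factor(rep(c("a", "b", "c"), each = 3))
  for (i in 1:10) {
    ref <- summary(aov(mr[i, ] ~ g))[[1]]
    expect_equal(anr$statistic[i], ref$`F value`[1], tolerance = 1e-10)
    expect_equal(anr$p_value[i], ref$`Pr(>F)`[1], tolerance = 1e-10)
  }

  # three identical groups
  m0 <- rbind(c(1, 2, 3, 1, 2, 3, 1, 2, 3))
  dimnames(m0) <- dimnames(m)
  an0 <- anova_test(toy_table(m0), meta)
  expect_equal(an0$statistic, 0)
  expect_equal(an0$p_value, 1)
})

test_that("two-group ANOVA F equals the squared Student t", {
  set.seed(73)
  m <- matrix(rlnorm(12 * 6, 3, 0.5), 12, 6)
  d <- two_group_ft(m)
  st <- t_tests(d$table, d$meta, "a", "b", equal_var = TRUE)
  an <- anova_test(d$table, d$meta)
  expect_equal(an$statistic, st$statistic^2, tolerance = 1e-10)
  expect_equal(an$p_value, st$p_value, tolerance = 1e-10)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(83)
  p <- runif(100)
  expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  # NAs pass through
  p[c(5, 50)] <- NA
  adj <- adjust_bh(p)
  expect_true(all(is.na(adj[c(5, 50)])))
  expect_equal(adj[-c(5, 50)], oracle_bh(p[-c(5, 50)]), tolerance = 1e-12)
  # FDR >= raw p featurewise
  expect_true(all(adj >= p, na.rm = TRUE))
})

test_that("StatTable invariants hold on simulated data", {
  sim <- random_dataset(n_features = 40, seed = 91)
  st <- t_tests(sim$table, sim$meta, "g1", "g2")
  expect_true(all(st$fdr >= st$p_value))
  expect_true(all(st$fold_change > 0))
  expect_equal(st$log2_fc, log2(st$fold_change), tolerance = 1e-12)
  expect_true(all(st$p_value >= 0 & st$p_value <= 1))
})

test_that("subset_samples filters consistently and keeps QCs", {
  sim <- random_dataset(seed = 97)
  ss <- subset_samples(sim$table, sim$meta, exclude_samples = "g1_1")
  expect_equal(length(ft_samples(ss$table)), length(ft_samples(sim$table)) - 1)
  expect_identical(ft_samples(ss$table), ss$meta$sample)

  keep <- subset_samples(sim$table, sim$meta, include_groups = c("g1", "g2"))
  expect_identical(ft_samples(keep$table), ft_samples(sim$table))

  only_g1 <- subset_samples(sim$table, sim$meta, include_groups = "g1")
  expect_true(all(only_g1$meta$group %in% c("g1", "QC")))

  expect_error(subset_samples(sim$table, sim$meta, include_groups = "nope"), "nope")
  expect_error(subset_samples(sim$table, sim$meta, exclude_samples = "ghost"), "ghost")
})
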