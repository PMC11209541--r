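test_that("single linkage on 1-D points follows the hand trace", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  rownames(x) <- c("p0", "p1", "p10")
  cl <- hierarchical_clustering(x, linkage = "single")
  expect_equal(cl$height, c(1, 9))
  # first merge is {p0, p1}
  expect_equal(sort(cl$merge[1, ]), c(-2, -1))
})

test_that("duplicate points merge at height zero first", {
  x <- matrix(c(3, 3, 8), ncol = 1)
  rownames(x) <- paste0("p", 1:3)
  cl <- hierarchical_clustering(x, linkage = "average")
  expect_equal(cl$height[1], 0)
})

test_that("merge heights match the naive all-pairs oracle for every linkage", {
  for (linkage in c("single", "complete", "average", "ward")) {
    for (seed in c(141, 142)) {
      set.seed(seed)
      x <- matrix(rnorm(8 * 3), 8, 3)
      rownames(x) <- paste0("p", 1:8)
      cl <- hierarchical_clustering(x, linkage = linkage)
      expect_equal(cl$height, oracle_hclust_heights(x, linkage), tolerance = 1e-10,
                   label = paste(linkage, seed))
      # merge heights non-decreasing, leaf order a permutation
      expect_true(all(diff(cl$height) >= -1e-12))
      expect_setequal(cl$order, seq_len(8))
    }
  }
})

test_that("clustering is invariant to input order up to relabeling", {
  set.seed(151)
  x <- matrix(rnorm(7 * 4), 7, 4)
  rownames(x) <- paste0("p", 1:7)
  cl <- hierarchical_clustering(x, linkage = "average")
  perm <- sample(7)
  cl2 <- hierarchical_clustering(x[perm, ], linkage = "average")
  expect_equal(cl$height, cl2$height, tolerance = 1e-12)
  # same tree on the labels: cophenetic distances agree
  coph1 <- as.matrix(stats::cophenetic(cl$hclust))
  coph2 <- as.matrix(stats::cophenetic(cl2$hclust))
  expect_equal(coph1, coph2[rownames(coph1), colnames(coph1)], tolerance = 1e-12)
})

test_that("deterministic leaf order puts the tighter subtree first", {
  # {10, 10.5} is tighter than {0, 2}; appears first regardless of index
  x <- matrix(c(0, 2, 10, 10.5), ncol = 1)
  rownames(x) <- c("a", "b", "c", "d")
  cl <- hierarchical_clustering(x, linkage = "single")
  expect_equal(cl$ordered_labels[1:2], c("c", "d"))
})

test_that("correlation distance rejects constant rows and newick export parses", {
  x <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(3, 2, 1))
  expect_error(hierarchical_clustering(x, distance = "correlation"), "a")
  cl <- hierarchical_clustering(x[2:3, ], linkage = "average")
  nwk <- as_newick(cl)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("b", "c"))
})

test_that("correlations, p-values and FDR follow the t transform", {
  x <- rbind(f1 = 1:5, f2 = 2 * (1:5) + 1, f3 = -(1:5))
  cm <- correlation_matrix(x)
  expect_equal(cm$r["f1", "f2"], 1, tolerance = 1e-12)
  expect_equal(cm$r["f1", "f3"], -1, tolerance = 1e-12)
  expect_equal(diag(cm$r), c(f1 = 1, f2 = 1, f3 = 1))

  # monotone nonlinear: spearman 1, pearson < 1
  y <- rbind(x = c(-2, -1, 0, 1, 2), ycube = c(-8, -1, 0, 1, 8))
  sp <- correlation_matrix(y, method = "spearman")
  pe <- correlation_matrix(y, method = "pearson")
  expect_equal(sp$r["x", "ycube"], 1, tolerance = 1e-12)
  expect_lt(pe$r["x", "ycube"], 1)

  # p-values equal cor.test on random data
  set.seed(163)
  z <- matrix(rnorm(4 * 10), 4, 10)
  rownames(z) <- paste0("f", 1:4)
  cmz <- correlation_matrix(z)
  for (i in 1:3) for (j in (i + 1):4) {
    ref <- cor.test(z[i, ], z[j, ])
    expect_equal(cmz$r[i, j], unname(ref$estimate), tolerance = 1e-10)
    expect_equal(cmz$p[i, j], ref$p.value, tolerance = 1e-10)
  }
  # FDR computed over the upper triangle
  expect_equal(cmz$fdr[upper.tri(cmz$fdr)],
               oracle_bh(cmz$p[upper.tri(cmz$p)]), tolerance = 1e-12)
  # constant feature warns and records NA
  zc <- rbind(z, f5 = rep(1, 10))
  expect_warning(cmc <- correlation_matrix(zc), "f5")
  expect_true(all(is.na(cmc$r["f5", setdiff(rownames(zc), "f5")])))
})

test_that("correlation network keeps exactly the double-thresholded edges", {
  set.seed(167)
  base <- rnorm(12)
  x <- rbind(f1 = base, f2 = base, f3 = rnorm(12))
  nw <- correlation_network(correlation_matrix(x), r_threshold = 0.8,
                            fdr_threshold = 0.05)
  expect_equal(nrow(nw$edges), 1)
  expect_setequal(c(nw$edges$from, nw$edges$to), c("f1", "f2"))
  # isolated nodes retained
  expect_setequal(nw$nodes$id, c("f1", "f2", "f3"))
  expect_equal(nw$nodes$degree[nw$nodes$id == "f3"], 0L)
  # no self-edges, unique undirected pairs
  expect_false(any(nw$edges$from == nw$edges$to))

  # edge count non-increasing in the r threshold
  set.seed(173)
  y <- matrix(rnorm(10 * 8), 10, 8)
  rownames(y) <- paste0("f", 1:10)
  cmy <- correlation_matrix(y)
  counts <- sapply(c(0, 0.3, 0.6, 0.9, 1), function(thr) {
    nrow(correlation_network(cmy, r_threshold = thr, fdr_threshold = 1)$edges)
  })
  expect_true(all(diff(counts) <= 0))
  expect_error(correlation_network(cmy, r_threshold = 1.2), "r_threshold")
  expect_error(correlation_network(cmy, fdr_threshold = 0), "fdr_threshold")

  # graphml export round-trips through igraph
  path <- tempfile(fileext = ".graphml")
  write_graphml(nw, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(g), 3)
  expect_equal(igraph::gsize(g), 1)
})
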