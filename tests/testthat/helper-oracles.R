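# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles with plain loops, so they share no code
# path with the package implementation they check.

# Benjamini-Hochberg step-up, computed literally from the definition
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  # step-up: adj[i] = min over j >= rank(i) of p_(j) * n / j, clipped at 1
  sorted <- p[ord]
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(sorted[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# exhaustive feature-space KNN imputation, mirroring the declared scheme:
# Euclidean distance over co-observed samples rescaled by sqrt(n/n_co),
# 1/d-weighted mean of the k nearest neighbours observed in the target
# sample, feature-mean fallback
oracle_knn_impute <- function(m, k) {
  p <- nrow(m); n <- ncol(m)
  out <- m
  for (i in seq_len(p)) {
    holes <- which(is.na(m[i, ]))
    if (length(holes) == 0) next
    d <- rep(Inf, p)
    for (jf in seq_len(p)) {
      if (jf == i) next
      co <- which(!is.na(m[i, ]) & !is.na(m[jf, ]))
      if (length(co) == 0) next
      d[jf] <- sqrt(sum((m[i, co] - m[jf, co])^2)) * sqrt(n / length(co))
    }
    nb <- order(d, seq_len(p))
    nb <- nb[is.finite(d[nb])]
    nb <- nb[seq_len(min(k, length(nb)))]
    for (s in holes) {
      donors <- nb[!is.na(m[nb, s])]
      if (length(donors) == 0) {
        out[i, s] <- mean(m[i, ], na.rm = TRUE)
      } else if (any(d[donors] == 0)) {
        out[i, s] <- mean(m[donors[d[donors] == 0], s])
      } else {
        w <- 1 / d[donors]
        out[i, s] <- sum(w * m[donors, s]) / sum(w)
      }
    }
  }
  out
}

# probabilistic quotient normalization from the definition, looped
oracle_pqn <- function(m, ref_cols) {
  ref <- apply(m[, ref_cols, drop = FALSE], 1, median)
  out <- m
  factors <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    quotients <- m[, j] / ref
    factors[j] <- median(quotients)
    out[, j] <- m[, j] / factors[j]
  }
  list(m = out, factors = factors)
}

# naive O(n^3) agglomerative clustering: merge heights only.
# single/complete/average recompute every inter-cluster distance from the
# original pairwise distances; ward applies the Lance-Williams update for
# Ward-on-distances (ward.D2 parameterization).
oracle_hclust_heights <- function(m, linkage) {
  d0 <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  dmat <- d0
  diag(dmat) <- Inf
  sizes <- rep(1, nrow(m))
  heights <- numeric(0)
  cluster_dist <- function(a, b) {
    pd <- d0[a, b, drop = FALSE]
    switch(linkage, single = min(pd), complete = max(pd), average = mean(pd))
  }
  while (length(clusters) > 1) {
    n <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dij <- if (linkage == "ward") dmat[i, j] else cluster_dist(clusters[[i]], clusters[[j]])
      if (dij < best[1]) best <- c(dij, i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    if (linkage == "ward") {
      # Lance-Williams for ward.D2 on squared distances
      ni <- sizes[i]; nj <- sizes[j]
      newrow <- sapply(seq_len(n), function(k) {
        if (k == i || k == j) return(Inf)
        nk <- sizes[k]
        sqrt(((ni + nk) * dmat[i, k]^2 + (nj + nk) * dmat[j, k]^2 -
                nk * dmat[i, j]^2) / (ni + nj + nk))
      })
      dmat[i, ] <- newrow; dmat[, i] <- newrow
      dmat <- dmat[-j, -j, drop = FALSE]
      sizes[i] <- ni + nj; sizes <- sizes[-j]
    } else {
      dmat <- dmat[-j, -j, drop = FALSE]
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  heights
}

# PCA eigenvalues via dense eigendecomposition of the covariance matrix
oracle_pca_eigenvalues <- function(x) {
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(cov(xc), symmetric = TRUE, only.values = TRUE)$values
  sort(ev, decreasing = TRUE)
}

# quantile normalization from the definition, ties -> mean of reference
# values at the tied sorted positions
oracle_quantile <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    for (i in seq_along(v)) {
      pos <- which(sort(v) == v[i])
      out[i, j] <- mean(ref[pos])
    }
  }
  out
}
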