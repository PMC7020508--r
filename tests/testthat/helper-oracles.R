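# Independent oracles, kept deliberately naive: brute-force linear algebra and
# literal transcriptions of the textbook algorithms, never calls into the code
# paths they check.

# PCA oracle: eigendecomposition of the sample covariance matrix of the
# variables (genes), scores = centered data %*% eigenvectors, signs fixed so
# each component's largest-magnitude loading is positive.
oracle_pca_scores <- function(mat_genes_by_samples, ncomp) {
  X <- t(mat_genes_by_samples)                      # samples x genes
  Xc <- scale(X, center = TRUE, scale = FALSE)
  C <- crossprod(Xc) / (nrow(Xc) - 1)               # gene covariance
  ev <- eigen(C, symmetric = TRUE)
  V <- ev$vectors[, seq_len(ncomp), drop = FALSE]
  for (k in seq_len(ncomp)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  Xc %*% V
}

# Exhaustive agglomeration oracle for small n: complete linkage on Euclidean
# distance, recomputing every cluster-pair distance from scratch each step.
oracle_agglomerate <- function(points_by_row, linkage = "complete") {
  n <- nrow(points_by_row)
  clusters <- lapply(seq_len(n), identity)
  merges <- list()
  heights <- numeric(0)
  dfun <- function(a, b) {
    d <- outer(a, b, Vectorize(function(i, j)
      sqrt(sum((points_by_row[i, ] - points_by_row[j, ])^2))))
    switch(linkage, complete = max(d), single = min(d), average = mean(d))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      d <- dfun(clusters[[i]], clusters[[j]])
      if (d < bestd) { bestd <- d; best <- c(j, i) }
    }
    merges[[length(merges) + 1L]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(members = merges, heights = heights)
}

# Leaf sets of each merge step of an hclust object, sorted, for comparison
# with the oracle's merge sequence.
hclust_merge_members <- function(hc) {
  memb <- vector("list", nrow(hc$merge))
  for (s in seq_len(nrow(hc$merge))) {
    grab <- function(id) if (id < 0) -id else memb[[id]]
    memb[[s]] <- sort(c(grab(hc$merge[s, 1]), grab(hc$merge[s, 2])))
  }
  memb
}

# LOWESS oracle: direct tricube-weighted local linear regression following
# Cleveland's published algorithm (single pass, no robustness iterations,
# exact fit at every point). x must be sorted and strictly increasing.
oracle_lowess <- function(x, y, f) {
  n <- length(x)
  ns <- max(2L, min(n, floor(f * n + 1e-7)))
  xrange <- x[n] - x[1]
  fitted <- numeric(n)
  for (i in seq_len(n)) {
    nleft <- 1L; nright <- ns
    while (nright < n) {
      d1 <- x[i] - x[nleft]
      d2 <- x[nright + 1L] - x[i]
      if (d1 > d2) { nleft <- nleft + 1L; nright <- nright + 1L } else break
    }
    h <- max(x[i] - x[nleft], x[nright] - x[i])
    h9 <- 0.999 * h; h1 <- 0.001 * h
    w <- numeric(n)
    for (j in nleft:n) {
      r <- abs(x[j] - x[i])
      if (r <= h9) {
        w[j] <- if (r > h1) (1 - (r / h)^3)^3 else 1
      } else if (x[j] > x[i]) break
    }
    a <- sum(w)
    if (a <= 0) { fitted[i] <- y[i]; next }
    w <- w / a
    fit <- sum(w * y)
    xbar <- sum(w * x)
    cc <- sum(w * (x - xbar)^2)
    if (sqrt(cc) > 0.001 * xrange) {
      b <- (x[i] - xbar) / cc
      fit <- fit + b * sum(w * (x - xbar) * y)
    }
    fitted[i] <- fit
  }
  fitted
}
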