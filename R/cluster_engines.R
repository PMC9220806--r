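# Clustering engines used for pseudoatom seeding. All operate on an n x 3
# coordinate matrix with per-point non-negative weights, and return an
# integer cluster assignment of length n with exactly k distinct labels
# (except mean shift, whose natural cluster count is reconciled by the
# caller). Everything is deterministic given the caller's RNG state.

# weighted k-means++ initialization
kmeanspp_init <- function(x, w, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i1 <- sample.int(n, 1L, prob = w)
  centers[1, ] <- x[i1, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  if (k > 1) for (c in 2:k) {
    p <- w * d2
    if (sum(p) <= 0) p <- rep(1, n)
    ic <- sample.int(n, 1L, prob = p)
    centers[c, ] <- x[ic, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[c, ])^2))
  }
  centers
}

assign_nearest <- function(x, centers) {
  max.col(-cross_dist2(x, centers), ties.method = "first")
}

# Multi-restart weighted k-means: keep the lowest-objective run.
weighted_kmeans_best <- function(x, w, k, n_restarts = 20L) {
  best <- NULL; best_obj <- Inf
  for (r in seq_len(n_restarts)) {
    fit <- weighted_kmeans(x, w, k)
    obj <- kmeans_objective(x, w, fit$assign, fit$centers)
    if (obj < best_obj) { best <- fit; best_obj <- obj }
  }
  best
}

# Lloyd iterations with per-point weights; empty clusters are reseeded at the
# point farthest from its current center.
weighted_kmeans <- function(x, w, k, iter_max = 50L, centers = NULL) {
  if (is.null(centers)) centers <- kmeanspp_init(x, w, k)
  assign <- assign_nearest(x, centers)
  for (it in seq_len(iter_max)) {
    for (c in seq_len(k)) {
      m <- assign == c
      if (!any(m)) {
        d2 <- rowSums((x - centers[assign, , drop = FALSE])^2)
        far <- which.max(d2)
        centers[c, ] <- x[far, ]
        assign[far] <- c
        m <- assign == c
      }
      ww <- w[m]
      centers[c, ] <- colSums(x[m, , drop = FALSE] * ww) / sum(ww)
    }
    new_assign <- assign_nearest(x, centers)
    if (all(new_assign == assign)) break
    assign <- new_assign
  }
  list(assign = assign, centers = centers)
}

kmeans_objective <- function(x, w, assign, centers) {
  sum(w * rowSums((x - centers[assign, , drop = FALSE])^2))
}

# isotropic weighted Gaussian mixture via EM, initialized from k-means
weighted_gmm <- function(x, w, k, iter_max = 40L) {
  km <- weighted_kmeans(x, w, k)
  mu <- km$centers
  n <- nrow(x)
  pi_k <- tabulate(km$assign, k) / n
  pi_k[pi_k <= 0] <- 1 / n
  s2 <- rep(max(stats::var(as.vector(x)) / k, 1e-4), k)
  for (it in seq_len(iter_max)) {
    d2 <- cross_dist2(x, mu)
    logp <- sweep(-d2 / (2 * rep(s2, each = n)), 2, log(pi_k) - 1.5 * log(s2), "+")
    m <- apply(logp, 1, max)
    r <- exp(logp - m)
    r <- r / rowSums(r)
    rw <- r * w
    nk <- colSums(rw)
    nk[nk < 1e-10] <- 1e-10
    mu_new <- crossprod(rw, x) / nk
    for (c in seq_len(k)) s2[c] <- max(sum(rw[, c] * rowSums(sweep(x, 2, mu_new[c, ])^2)) / (3 * nk[c]), 1e-4)
    pi_k <- nk / sum(nk)
    shift <- max(abs(mu_new - mu))
    mu <- mu_new
    if (shift < 1e-5) break
  }
  list(assign = assign_nearest(x, mu), centers = mu)
}

# agglomerative (Ward) on a weighted subsample, then nearest-centroid
# assignment of the full set
ward_cluster <- function(x, w, k, max_points = 3000L) {
  n <- nrow(x)
  if (n > max_points) {
    idx <- sample.int(n, max_points, prob = w)
  } else idx <- seq_len(n)
  hc <- stats::hclust(stats::dist(x[idx, , drop = FALSE]), method = "ward.D2")
  lab <- stats::cutree(hc, k = k)
  cent <- t(vapply(seq_len(k), function(c)
    colMeans(x[idx[lab == c], , drop = FALSE]), numeric(3)))
  list(assign = assign_nearest(x, cent), centers = cent)
}

# spectral clustering on a weighted subsample (normalized Laplacian, Gaussian
# affinity with median-distance bandwidth), then nearest-centroid assignment
spectral_cluster <- function(x, w, k, max_points = 1200L) {
  n <- nrow(x)
  if (n > max_points) idx <- sample.int(n, max_points, prob = w) else idx <- seq_len(n)
  xs <- x[idx, , drop = FALSE]
  d2 <- cross_dist2(xs, xs)
  sig2 <- stats::median(d2[d2 > 0]) / 4
  A <- exp(-d2 / (2 * sig2))
  diag(A) <- 0
  dg <- rowSums(A)
  dg[dg < 1e-12] <- 1e-12
  L <- diag(length(idx)) - sweep(sweep(A, 1, sqrt(dg), "/"), 2, sqrt(dg), "/")
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, order(ev$values)[seq_len(k)], drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn < 1e-12] <- 1
  U <- U / rn
  km <- weighted_kmeans(U, rep(1, nrow(U)), k)
  cent <- t(vapply(seq_len(k), function(c)
    colMeans(xs[km$assign == c, , drop = FALSE]), numeric(3)))
  list(assign = assign_nearest(x, cent), centers = cent)
}

# weighted Gaussian mean shift; returns modes and assignment (natural count)
mean_shift_cluster <- function(x, w, bandwidth, iter_max = 100L, tol = 1e-3,
                               merge_dist = NULL) {
  n <- nrow(x)
  merge_dist <- merge_dist %||% (bandwidth / 2)
  pts <- x
  for (it in seq_len(iter_max)) {
    d2 <- cross_dist2(pts, x)
    kern <- exp(-d2 / (2 * bandwidth^2))
    kw <- sweep(kern, 2, w, "*")
    s <- rowSums(kw)
    s[s < 1e-12] <- 1e-12
    new_pts <- (kw %*% x) / s
    shift <- max(sqrt(rowSums((new_pts - pts)^2)))
    pts <- new_pts
    if (shift < tol) break
  }
  # merge converged points into modes (greedy, order-stable)
  modes <- matrix(NA_real_, 0, 3)
  assign <- integer(n)
  for (i in seq_len(n)) {
    if (nrow(modes) > 0) {
      dd <- sqrt(rowSums(sweep(modes, 2, pts[i, ])^2))
      j <- which(dd < merge_dist)
      if (length(j)) { assign[i] <- j[1]; next }
    }
    modes <- rbind(modes, pts[i, ])
    assign[i] <- nrow(modes)
  }
  list(assign = assign, centers = modes)
}

# force an assignment to exactly k clusters: split the largest (by weight)
# with 2-means, or merge the closest center pair, until the count is exact
reconcile_cluster_count <- function(x, w, assign, centers, k) {
  repeat {
    kc <- nrow(centers)
    if (kc == k) break
    if (kc < k) {
      sizes <- vapply(seq_len(kc), function(c) sum(w[assign == c]), numeric(1))
      nmem <- tabulate(assign, kc)
      big <- order(-sizes)
      big <- big[nmem[big] >= 2][1]
      if (is.na(big)) stop("cannot split: all clusters are singletons")
      m <- which(assign == big)
      km <- weighted_kmeans(x[m, , drop = FALSE], w[m], 2L)
      assign[m[km$assign == 2]] <- kc + 1L
      centers[big, ] <- km$centers[1, ]
      centers <- rbind(centers, km$centers[2, ])
    } else {
      dd <- as.matrix(stats::dist(centers))
      dd[upper.tri(dd, diag = TRUE)] <- Inf
      ij <- arrayInd(which.min(dd), dim(dd))
      a <- min(ij); b <- max(ij)
      assign[assign == b] <- a
      assign[assign > b] <- assign[assign > b] - 1L
      centers <- centers[-b, , drop = FALSE]
      m <- assign == a
      centers[a, ] <- colSums(x[m, , drop = FALSE] * w[m]) / sum(w[m])
    }
  }
  list(assign = assign, centers = centers)
}
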