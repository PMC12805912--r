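# Shared fixtures built in code; all randomness is locally seeded.

# Small single-group truth with zero tissue offsets (raw values are directly
# on the model scale, so fits recover trace(G)/trace(R) without rescaling).
tiny_truth <- function(n = 20L, G = diag(0.5, 2), R = diag(1, 2),
                       tissues = paste0("t", 1:3), species = "sp",
                       season = "breeding", mu = c(0, 0)) {
  group_truth(species, season, n, mu = mu, G = G, R = R, tissues = tissues)
}

# Reduced sampler settings for fast unit tests.
fast_config <- function(seed = 1L, n_chains = 2L) {
  mm_config(n_iterations = 1500L, burn_in = 500L, thin = 5L,
            n_chains = n_chains, seed = seed)
}

# Random PSD 2x2 matrix.
random_psd <- function() {
  A <- matrix(rnorm(4), 2L)
  crossprod(A) + diag(1e-8, 2L)
}

# Monte-Carlo oracle: proportion of ellipse a's area covered by ellipse b,
# by rejection sampling uniformly inside a (via the unit-disc pullback).
mc_overlap <- function(a, b, n = 20000L) {
  # uniform points in the ellipse: map uniform disc through sqrt(q) * L
  q_a <- stats::qchisq(a$coverage, 2)
  La <- t(chol(a$covariance))
  r <- sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
  disc <- cbind(r * cos(th), r * sin(th))
  pts <- sweep(sqrt(q_a) * disc %*% t(La), 2, a$centroid, "+")
  # membership in b: Mahalanobis radius^2 <= chi2 quantile
  q_b <- stats::qchisq(b$coverage, 2)
  ctr <- sweep(pts, 2, b$centroid)
  Sinv <- solve(b$covariance)
  m2 <- rowSums((ctr %*% Sinv) * ctr)
  mean(m2 <= q_b)
}

# Point-in-polygon for a convex CCW polygon (used by coverage tests).
in_convex_polygon <- function(pts, P) {
  n <- nrow(P); j <- c(2:n, 1L)
  inside <- rep(TRUE, nrow(pts))
  s <- sum(P[, 1L] * P[j, 2L] - P[j, 1L] * P[, 2L])
  if (s < 0) { P <- P[rev(seq_len(n)), ]; j <- c(2:n, 1L) }
  for (i in seq_len(n)) {
    a <- P[i, ]; b <- P[j[i], ]
    d <- (b[1L] - a[1L]) * (pts[, 2L] - a[2L]) -
         (b[2L] - a[2L]) * (pts[, 1L] - a[1L])
    inside <- inside & d >= 0
  }
  inside
}

# Independent oracle: patristic distance by explicit path walking on the
# edge list (climb to root from both leaves, subtract the shared prefix).
brute_patristic <- function(phy) {
  n <- length(phy$tip.label)
  parent <- function(node) {
    r <- phy$edge[phy$edge[, 2] == node, 1]
    if (length(r) == 0) NA_integer_ else r
  }
  elen <- function(node) phy$edge.length[phy$edge[, 2] == node]
  path_to_root <- function(node) {
    nodes <- node; lens <- numeric(0)
    while (!is.na(parent(node))) {
      lens <- c(lens, elen(node))
      node <- parent(node)
      nodes <- c(nodes, node)
    }
    list(nodes = nodes, cum = c(0, cumsum(lens)))
  }
  D <- matrix(0, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  paths <- lapply(seq_len(n), path_to_root)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi_ <- paths[[i]]; pj <- paths[[j]]
    common <- intersect(pi_$nodes, pj$nodes)
    mrca_i <- min(match(common, pi_$nodes))
    mrca_j <- min(match(common, pj$nodes))
    D[i, j] <- D[j, i] <- pi_$cum[mrca_i] + pj$cum[mrca_j]
  }
  D
}

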