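# Internal numerical helpers shared across modules.

# Check a 2x2 (or k x k) matrix for symmetry within tolerance; returns the
# symmetrised matrix or aborts.
check_symmetric <- function(M, tol = 1e-8, arg = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    abort(sprintf("`%s` must be a square matrix.", arg), class = "nichepart_matrix_error")
  }
  if (max(abs(M - t(M))) > tol) {
    abort(sprintf("`%s` is asymmetric beyond tolerance %g.", arg, tol),
          class = "nichepart_matrix_error")
  }
  (M + t(M)) / 2
}

# Positive semi-definiteness within tolerance.
check_psd <- function(M, tol = 1e-8, arg = "matrix") {
  M <- check_symmetric(M, tol = tol, arg = arg)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    abort(sprintf("`%s` is not positive semi-definite (min eigenvalue %g).",
                  arg, min(ev)), class = "nichepart_matrix_error")
  }
  M
}

# Lower-triangular factor L with L %*% t(L) = M, tolerating PSD-but-singular
# matrices via the eigendecomposition.
psd_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M))
}

# One inverse-Wishart draw with scale S and degrees of freedom df:
# X ~ IW(S, df)  <=>  X^-1 ~ Wishart(df, S^-1).
rinvwishart <- function(df, S) {
  W <- rWishart(1L, df = df, Sigma = solve(S))[, , 1L]
  solve(W)
}

# Draws n rows from a bivariate normal with mean 0 and covariance Sigma.
rmvnorm2 <- function(n, Sigma) {
  L <- psd_sqrt(Sigma)
  matrix(rnorm(2L * n), n, 2L) %*% t(L)
}

# Runs `code` under a temporary RNG state seeded with `seed` (NULL = use the
# ambient stream).
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
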