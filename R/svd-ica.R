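# Randomized truncated SVD (Halko-Martinsson-Tropp): range finding with
# Gaussian test vectors and power iterations, then exact SVD of the small
# projected matrix. Deterministic given `seed`. Accurate to working precision
# for matrices with fast-decaying spectra, which movie matrices have.
randomized_svd <- function(X, k, seed, n_oversample = 10L, n_power = 2L) {
  m <- nrow(X); n <- ncol(X)
  k <- min(k, m, n)
  l <- min(k + n_oversample, m, n)
  withr::with_seed(seed, {
    Omega <- matrix(rnorm(n * l), n, l)
    Y <- X %*% Omega
    for (p in seq_len(n_power)) {
      Q <- qr.Q(qr(Y))
      Y <- X %*% crossprod(X, Q)
    }
    Q <- qr.Q(qr(Y))
    B <- crossprod(Q, X)          # l x n
    s <- svd(B, nu = k, nv = k)
    list(u = Q %*% s$u, d = s$d[seq_len(k)], v = s$v)
  })
}

# Symmetric fixed-point FastICA with tanh contrast on pre-whitened data
# Z (k x n, rows uncorrelated, unit variance). Returns the unmixing matrix W
# (k x k, orthonormal rows) with sources S = W Z. Deterministic given seed.
fast_ica <- function(Z, seed, max_iter = 200L, tol = 1e-6) {
  k <- nrow(Z); n <- ncol(Z)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  withr::with_seed(seed, {
    W <- sym_orth(matrix(rnorm(k * k), k, k))
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      WX <- W %*% Z
      G <- tanh(WX)
      Gp <- 1 - G^2
      W_new <- sym_orth(G %*% t(Z) / n - diag(rowMeans(Gp)) %*% W)
      delta <- max(abs(abs(rowSums(W_new * W)) - 1))
      W <- W_new
      if (delta < tol) { converged <- TRUE; break }
    }
    list(W = W, iterations = iter, converged = converged)
  })
}
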