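# Lawson-Hanson active-set nonnegative least squares: minimize ||Ax - b||^2
# subject to x >= 0. Suitable for the small systems solved here (ring-weight
# fits over a few dozen offsets).
nnls_solve <- function(A, b, tol = NULL) {
  n <- ncol(A)
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  if (is.null(tol)) tol <- 1e-10 * max(abs(AtA))
  x <- numeric(n)
  passive <- logical(n)
  w <- Atb - AtA %*% x
  iter <- 0L
  max_iter <- 3L * n
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      P <- which(passive)
      s[P] <- solve(AtA[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > tol)) break
      neg <- P[s[P] <= tol]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- Atb - AtA %*% x
  }
  as.numeric(x)
}
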