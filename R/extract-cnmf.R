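#' Configuration for the ring-background constrained NMF
#'
#' @param neuron_diameter_px expected soma diameter in pixels.
#' @param ring_diameter_px background-ring diameter; defaults to 1.5 times
#'   the neuron diameter, so the ring samples fluorescence just outside the
#'   largest somata.
#' @param max_iterations outer alternating iterations.
#' @param n_ring_updates number of leading iterations that refit the ring
#'   weights; afterwards the background is frozen and only the factor
#'   updates continue.
#' @param seed_corr_min,seed_pnr_min greedy seeding thresholds on the local
#'   correlation image and peak-to-noise ratio.
#' @param convergence_tol stop when the relative objective change falls below
#'   this.
#' @param merge_cos,merge_corr post-hoc merge thresholds on footprint cosine
#'   and trace correlation.
#' @param min_trace_snr post-hoc component quality floor: components whose
#'   trace peak falls below this multiple of the trace's noise level
#'   (median absolute temporal difference) are discarded.
#' @param seed integer seed (frame/pixel subsampling for the ring fit).
#' @return list of class `cnmf_ring_config`.
#' @export
cnmf_ring_config <- function(neuron_diameter_px = 8,
                             ring_diameter_px = 1.5 * neuron_diameter_px,
                             max_iterations = 8L,
                             n_ring_updates = 4L,
                             seed_corr_min = 0.8,
                             seed_pnr_min = 8,
                             convergence_tol = 1e-4,
                             merge_cos = 0.8,
                             merge_corr = 0.8,
                             min_trace_snr = 5,
                             seed = 1L) {
  stopifnot(neuron_diameter_px > 0, ring_diameter_px > neuron_diameter_px / 2,
            max_iterations >= 1, convergence_tol > 0)
  structure(list(neuron_diameter_px = neuron_diameter_px,
                 ring_diameter_px = ring_diameter_px,
                 max_iterations = as.integer(max_iterations),
                 n_ring_updates = as.integer(n_ring_updates),
                 seed_corr_min = seed_corr_min,
                 seed_pnr_min = seed_pnr_min,
                 convergence_tol = convergence_tol,
                 merge_cos = merge_cos, merge_corr = merge_corr,
                 min_trace_snr = min_trace_snr,
                 seed = as.integer(seed)),
            class = "cnmf_ring_config")
}

# local correlation image: mean correlation of each pixel's time course with
# its 8 neighbors, computed on a (filtered) movie
local_correlation_image <- function(movie) {
  d <- dim(movie)
  M <- matrix(movie, d[1] * d[2], d[3])
  mu <- rowMeans(M)
  sdv <- sqrt(rowMeans(M^2) - mu^2)
  sdv[sdv < 1e-12] <- Inf                      # flat pixels correlate with nothing
  Z <- array((M - mu) / sdv, dim = d)
  acc <- matrix(0, d[1], d[2]); cnt <- matrix(0, d[1], d[2])
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ry <- max(1, 1 + dy):min(d[1], d[1] + dy)
    rx <- max(1, 1 + dx):min(d[2], d[2] + dx)
    sy <- ry - dy; sx <- rx - dx
    pr <- rowMeans(matrix(Z[ry, rx, , drop = FALSE] * Z[sy, sx, , drop = FALSE],
                          length(ry) * length(rx), d[3]))
    acc[ry, rx] <- acc[ry, rx] + matrix(pr, length(ry), length(rx))
    cnt[ry, rx] <- cnt[ry, rx] + 1
  }
  acc / cnt
}

# per-pixel noise level: scaled median absolute temporal difference, robust to
# sparse calcium transients
pixel_noise <- function(M) {
  D <- abs(M[, -1, drop = FALSE] - M[, -ncol(M), drop = FALSE])
  apply(D, 1, median) / (0.6745 * sqrt(2))
}

# greedy seeding on corr x PNR with exclusion radius; candidates must be
# local maxima of the score in their 3x3 neighborhood
greedy_seeds <- function(corr_img, pnr_img, corr_min, pnr_min, excl_radius) {
  d <- dim(corr_img)
  score <- corr_img * pnr_img
  ok <- corr_img >= corr_min & pnr_img >= pnr_min
  is_max <- matrix(TRUE, d[1], d[2])
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ry <- max(1, 1 + dy):min(d[1], d[1] + dy)
    rx <- max(1, 1 + dx):min(d[2], d[2] + dx)
    is_max[ry, rx] <- is_max[ry, rx] &
      score[ry, rx] >= score[ry - dy, rx - dx]
  }
  score[!ok | !is_max] <- -Inf
  seeds <- NULL
  while (any(is.finite(score)) && max(score) > -Inf) {
    p <- which.max(score)
    r0 <- (p - 1) %% d[1] + 1; c0 <- (p - 1) %/% d[1] + 1
    seeds <- rbind(seeds, c(r0, c0))
    # suppress candidates within a euclidean disk of the accepted seed
    rr <- pmax(1, r0 - excl_radius):pmin(d[1], r0 + excl_radius)
    cc <- pmax(1, c0 - excl_radius):pmin(d[2], c0 + excl_radius)
    disk <- outer((rr - r0)^2, (cc - c0)^2, "+") <= excl_radius^2
    score[rr, cc][disk] <- -Inf
    score[p] <- -Inf
  }
  seeds
}

# integer ring offsets approximating a circle of the given radius
ring_offsets <- function(radius) {
  th <- seq(0, 2 * pi, length.out = 49L)[-49L]
  off <- unique(cbind(round(radius * sin(th)), round(radius * cos(th))))
  off[!(off[, 1] == 0 & off[, 2] == 0), , drop = FALSE]
}

# index map implementing pixel -> pixel + offset with border replication
shift_index <- function(H, W, dy, dx) {
  r <- pmin(pmax(rep(seq_len(H), W) + dy, 1), H)
  c <- pmin(pmax(rep(seq_len(W), each = H) + dx, 1), W)
  (c - 1L) * H + r
}

#' Ring-background constrained NMF extraction
#'
#' Simplified single-patch constrained nonnegative matrix factorization with
#' the ring model of background fluorescence. The movie matrix is modeled as
#' `Y ~ A C + b0 + B` with nonnegative spatial footprints `A` (support
#' constrained to a box around each seed), nonnegative traces `C`, a static
#' per-pixel baseline `b0` (temporal median), and a background `B` whose value
#' at each pixel is a learned nonnegative combination of the cell-free
#' residual on a ring of diameter `ring_diameter_px` centered on that pixel.
#' One weight vector is shared across pixels (translation-invariant ring),
#' fitted by nonnegative least squares on a pixel/frame subsample and accepted
#' only if it lowers the full residual, so the objective is non-increasing
#' across iterations.
#'
#' Steps: (1) greedy seeding from the product of the local-correlation and
#' peak-to-noise images of the bandpass-filtered movie; (2) alternating
#' ring-weight and hierarchical nonnegative least-squares updates of `A` and
#' `C`; (3) stop at `convergence_tol` relative objective change; (4) merge
#' footprint pairs with cosine and trace correlation both above the merge
#' thresholds. Because the ring radius exceeds the soma radius, smooth
#' out-of-focus background is absorbed by `B` while compact somata are not.
#'
#' @param movie `H x W x T` nonnegative array.
#' @param config a [cnmf_ring_config()].
#' @return `extraction_result`; `diagnostics` holds the per-iteration
#'   objective values, seeds, ring weights and iteration count.
#' @export
extract_cnmf_ring <- function(movie, config = cnmf_ring_config()) {
  d <- dim(movie)
  H <- d[1]; W <- d[2]; T_len <- d[3]
  if (any(!is.finite(movie))) stop("movie contains non-finite values")
  if (any(movie < 0)) stop("movie must be nonnegative")
  diam <- config$neuron_diameter_px
  # narrow cell-scale band for the seeding images: structure much larger
  # than a soma (out-of-focus background) must not generate seeds
  lo <- max(2, round(diam / 2)); hi <- min(round(1.5 * diam), min(H, W) - 1)
  filt <- spatial_bandpass(movie, c(lo, hi))
  Mf <- matrix(filt, H * W, T_len)
  noise <- pixel_noise(Mf)
  noise[noise < 1e-12] <- Inf
  pnr <- matrix(apply(Mf, 1, max) / noise, H, W)
  cimg <- local_correlation_image(filt)
  seeds <- greedy_seeds(cimg, pnr, config$seed_corr_min, config$seed_pnr_min,
                        excl_radius = max(2L, round(diam / 2)))
  seed_traces <- if (!is.null(seeds))
    pmax(Mf[(seeds[, 2] - 1L) * H + seeds[, 1], , drop = FALSE], 0)
  rm(filt, Mf)   # movie-sized temporaries; keep peak memory bounded
  if (is.null(seeds))
    return(extraction_result(array(0, dim = c(H, W, 0)),
                             matrix(0, 0, T_len), "cnmf_ring",
                             diagnostics = list(objective = numeric(0),
                                                n_seeds = 0L)))
  K <- nrow(seeds)
  Y <- matrix(movie, H * W, T_len)
  b0 <- apply(Y, 1, median)

  # support boxes and Gaussian-bump initialization
  rows <- rep(seq_len(H), W); cols <- rep(seq_len(W), each = H)
  support <- matrix(FALSE, H * W, K)
  A <- matrix(0, H * W, K)
  sig0 <- diam / 4
  for (k in seq_len(K)) {
    dy <- rows - seeds[k, 1]; dx <- cols - seeds[k, 2]
    box <- abs(dy) <= diam & abs(dx) <= diam
    support[, k] <- box
    bump <- exp(-(dy^2 + dx^2) / (2 * sig0^2))
    bump[!box] <- 0
    A[, k] <- bump
  }
  C <- seed_traces

  # ring machinery
  offs <- ring_offsets(config$ring_diameter_px / 2)
  idx <- apply(offs, 1, function(o) shift_index(H, W, o[1], o[2]))
  n_off <- nrow(offs)
  B <- matrix(0, H * W, T_len)
  w_ring <- numeric(n_off)

  t_sub <- sort(unique(round(seq(1, T_len, length.out = min(300L, T_len)))))
  interior <- which(rows > config$ring_diameter_px / 2 + 1 &
                    rows < H - config$ring_diameter_px / 2 &
                    cols > config$ring_diameter_px / 2 + 1 &
                    cols < W - config$ring_diameter_px / 2)
  p_sub <- with_substream(config$seed, "svd",
    if (length(interior) > 2000L) sort(sample(interior, 2000L)) else interior)

  AC <- A %*% C
  sqsum <- function(M) sum(M * M)
  Yr <- Y - b0                      # background-subtracted movie (B = 0 yet)
  objective <- sqsum(Yr - AC)

  # ring weights stabilize within a few refits; afterwards the background is
  # frozen and only the (monotone) HALS factor updates continue
  n_ring_updates <- min(config$n_ring_updates, config$max_iterations)

  for (it in seq_len(config$max_iterations)) {
    if (it <= n_ring_updates) {
      # --- ring background update (accept only if the objective drops)
      R_full <- Y - b0 - AC               # cell-free residual
      rm(AC)
      R_sub <- R_full[, t_sub, drop = FALSE]
      X <- matrix(0, length(p_sub) * length(t_sub), n_off)
      for (j in seq_len(n_off))
        X[, j] <- as.vector(R_sub[idx[p_sub, j], , drop = FALSE])
      w_new <- nnls_solve(X, as.vector(R_sub[p_sub, , drop = FALSE]))
      rm(X, R_sub)
      nz <- which(w_new > 1e-10)
      B_new <- matrix(0, H * W, T_len)
      for (j in nz)
        B_new <- B_new + w_new[j] * R_full[idx[, j], , drop = FALSE]
      if (sqsum(R_full - B_new) <= sqsum(R_full - B)) {
        B <- B_new
        w_ring <- w_new
        Yr <- Y - b0 - B
      }
      rm(R_full, B_new)
    } else {
      rm(AC)
    }
    for (sweep in seq_len(if (it <= 2) 2 else 1)) {
      AtY <- crossprod(A, Yr); AtA <- crossprod(A)
      for (k in seq_len(K)) {
        denom <- AtA[k, k]
        if (denom < 1e-12) next
        C[k, ] <- pmax(0, C[k, ] + (AtY[k, ] - AtA[k, ] %*% C) / denom)
      }
      YCt <- Yr %*% t(C); CCt <- tcrossprod(C)
      for (k in seq_len(K)) {
        denom <- CCt[k, k]
        if (denom < 1e-12) next
        ak <- pmax(0, A[, k] + (YCt[, k] - A %*% CCt[, k]) / denom)
        ak[!support[, k]] <- 0
        A[, k] <- ak
      }
    }
    AC <- A %*% C
    objective <- c(objective, sqsum(Yr - AC))
    n_obj <- length(objective)
    if (abs(objective[n_obj - 1] - objective[n_obj]) <=
        config$convergence_tol * objective[n_obj - 1]) break
  }

  # drop empty components, normalize footprints to peak 1
  keep <- apply(A, 2, max) > 1e-8 & apply(C, 1, max) > 1e-8
  A <- A[, keep, drop = FALSE]; C <- C[keep, , drop = FALSE]
  if (ncol(A) > 0) {
    pk <- apply(A, 2, max)
    A <- sweep(A, 2, pk, "/")
    C <- C * pk
  }
  # single post-hoc merge pass
  merged <- merge_components(A, C, config$merge_cos, config$merge_corr)
  A <- merged$A; C <- merged$C
  # component quality: discard traces without clear transients
  if (ncol(A) > 0 && config$min_trace_snr > 0) {
    snr <- apply(C, 1, function(x) {
      nz <- median(abs(diff(x))) / (0.6745 * sqrt(2))
      max(x) / max(nz, 1e-12)
    })
    qual <- snr >= config$min_trace_snr
    A <- A[, qual, drop = FALSE]; C <- C[qual, , drop = FALSE]
  }
  extraction_result(array(A, dim = c(H, W, ncol(A))), C, "cnmf_ring",
                    diagnostics = list(objective = objective,
                                       n_seeds = K, seeds = seeds,
                                       ring_weights = w_ring,
                                       iterations = length(objective) - 1L))
}

merge_components <- function(A, C, cos_min, corr_min) {
  K <- ncol(A)
  if (K < 2) return(list(A = A, C = C))
  An <- sweep(A, 2, sqrt(colSums(A^2)) + 1e-12, "/")
  cosm <- crossprod(An)
  corrm <- suppressWarnings(cor(t(C)))
  corrm[!is.finite(corrm)] <- 0
  groups <- seq_len(K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K)
    if (cosm[i, j] >= cos_min && corrm[i, j] >= corr_min)
      groups[groups == groups[j]] <- groups[i]
  ug <- unique(groups)
  if (length(ug) == K) return(list(A = A, C = C))
  A2 <- matrix(0, nrow(A), length(ug)); C2 <- matrix(0, length(ug), ncol(C))
  for (g in seq_along(ug)) {
    members <- which(groups == ug[g])
    a <- rowSums(A[, members, drop = FALSE])
    cc <- colSums(C[members, , drop = FALSE] *
                    apply(A[, members, drop = FALSE], 2, max))
    pk <- max(a)
    A2[, g] <- a / pk
    C2[g, ] <- cc * pk / sum(apply(A[, members, drop = FALSE], 2, max))
  }
  list(A = A2, C = C2)
}
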