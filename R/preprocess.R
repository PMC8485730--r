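#' Spatially downsample a movie by block averaging
#'
#' Each output pixel is the mean of a `factor x factor` block; the frame count
#' is unchanged. Shapes not divisible by the factor are cropped at the
#' trailing rows/columns (never padded, to avoid edge bias). Downsampling by
#' `a` then `b` equals downsampling by `a * b` on divisible shapes.
#'
#' @param movie `H x W x T` array.
#' @param factor positive integer.
#' @return downsampled `floor(H/f) x floor(W/f) x T` array.
#' @export
downsample_spatial <- function(movie, factor) {
  if (factor < 1 || factor != round(factor)) stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(movie)
  d <- dim(movie)
  H2 <- d[1] %/% factor; W2 <- d[2] %/% factor
  if (H2 < 1 || W2 < 1) stop("factor larger than the field of view")
  m <- movie[seq_len(H2 * factor), seq_len(W2 * factor), , drop = FALSE]
  # average rows then columns via dimension folding
  dim(m) <- c(factor, H2, W2 * factor * d[3])
  m <- colMeans(m)
  dim(m) <- c(H2, factor, W2 * d[3])
  m <- aperm(m, c(2, 1, 3))
  m <- colMeans(m)
  array(m, dim = c(H2, W2, d[3]))
}

#' Pixelwise dF/F
#'
#' `out(t, x) = (F(t, x) - F0(x)) / F0(x)` with the per-pixel baseline `F0`
#' either the temporal mean (default) or a lower temporal percentile.
#'
#' @param movie `H x W x T` array with strictly positive baseline.
#' @param baseline_method `"mean"` or `"percentile"`.
#' @param percentile percentile in (0, 100) used when
#'   `baseline_method = "percentile"` (default 10).
#' @return `H x W x T` array of relative fluorescence changes.
#' @export
compute_dff <- function(movie, baseline_method = c("mean", "percentile"),
                        percentile = 10) {
  baseline_method <- match.arg(baseline_method)
  d <- dim(movie)
  M <- matrix(movie, d[1] * d[2], d[3])
  F0 <- if (baseline_method == "mean") rowMeans(M)
        else apply(M, 1, quantile, probs = percentile / 100, names = FALSE)
  n_bad <- sum(F0 <= 0)
  if (n_bad > 0)
    stop(sprintf("baseline F0 is non-positive at %d pixel(s); dF/F undefined",
                 n_bad))
  array((M - F0) / F0, dim = d)
}

# Dense separable Gaussian blur with reflected boundaries, applied framewise.
# Implemented as two banded-matrix multiplications over the unfolded stack;
# on movie-sized arrays this is much faster than per-frame FFT filtering.
blur_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + x
    # reflect indices at the boundaries
    j <- ifelse(j < 1, 2 - j, j)
    j <- ifelse(j > n, 2 * n - j, j)
    for (q in seq_along(j)) B[i, j[q]] <- B[i, j[q]] + k[q]
  }
  B / rowSums(B)
}

gaussian_blur_stack <- function(movie, sigma) {
  d <- dim(movie)
  Bh <- blur_matrix(d[1], sigma)
  Bw <- blur_matrix(d[2], sigma)
  m <- matrix(movie, d[1], d[2] * d[3])
  m <- Bh %*% m
  m <- array(m, dim = d)
  m <- aperm(m, c(2, 1, 3))
  m <- matrix(m, d[2], d[1] * d[3])
  m <- Bw %*% m
  aperm(array(m, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
}

#' Spatial bandpass filter (difference of Gaussians)
#'
#' Per-frame difference of two Gaussian blurs. Pixel cutoffs map to Gaussian
#' widths as `sigma = cutoff / 4`, a convention fixed here (the narrow blur at
#' `sigma = low/4` suppresses structure smaller than `low` px; subtracting the
#' wide blur at `sigma = high/4` removes structure larger than `high` px,
#' including any spatially uniform offset). The default cutoffs (5, 31) px
#' bracket the size of cell bodies seen in dF/F data.
#'
#' @param movie `H x W x T` array.
#' @param cutoffs_px length-2 `(low, high)` pixel cutoffs, `low < high`, both
#'   smaller than the FOV.
#' @return filtered movie, zero-mean per frame up to boundary effects.
#' @export
spatial_bandpass <- function(movie, cutoffs_px = c(5, 31)) {
  d <- dim(movie)
  lo <- cutoffs_px[1]; hi <- cutoffs_px[2]
  if (!(lo < hi)) stop("low cutoff must be below high cutoff")
  if (hi >= min(d[1], d[2])) stop("cutoffs must be smaller than the FOV")
  gaussian_blur_stack(movie, lo / 4) - gaussian_blur_stack(movie, hi / 4)
}

# integer shift; shift = c(dy, dx) moves content down/right. Uncovered edge
# pixels take the frame median (a neutral fill that does not imprint a sharp
# artificial edge the way zero fill would).
shift_frame <- function(frame, dy, dx) {
  d <- dim(frame)
  out <- matrix(median(frame), d[1], d[2])
  src_r <- seq_len(d[1]) - dy
  src_c <- seq_len(d[2]) - dx
  ok_r <- src_r >= 1 & src_r <= d[1]
  ok_c <- src_c >= 1 & src_c <= d[2]
  out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' Inject rigid translation jitter into a movie
#'
#' Applies a given integer `(dy, dx)` shift per frame (zero-filled edges);
#' used to construct motion-correction round-trip tests.
#'
#' @param movie `H x W x T` array.
#' @param shifts `T x 2` integer matrix of per-frame `(dy, dx)`.
#' @return shifted movie.
#' @export
inject_jitter <- function(movie, shifts) {
  d <- dim(movie)
  stopifnot(nrow(shifts) == d[3], ncol(shifts) == 2)
  out <- movie
  for (t in seq_len(d[3]))
    if (shifts[t, 1] != 0 || shifts[t, 2] != 0)
      out[, , t] <- shift_frame(movie[, , t], shifts[t, 1], shifts[t, 2])
  out
}

#' Rigid motion correction by cross-correlation
#'
#' Estimates a per-frame translation maximizing the FFT cross-correlation
#' with a reference frame within `+- max_shift_px`, refines the peak to
#' subpixel precision by parabolic interpolation, and applies the (rounded)
#' opposite shift to each frame. Flat correlation surfaces (e.g. constant
#' frames) resolve to zero shift by tie-break.
#'
#' @param movie `H x W x T` array.
#' @param reference `H x W` reference frame (default: mean frame).
#' @param max_shift_px maximum allowed shift magnitude (must be below half
#'   the smaller FOV dimension).
#' @return list with `movie` (corrected) and `shifts` (`T x 2` matrix of the
#'   estimated subpixel frame displacements `(dy, dx)`; the applied
#'   correction is their rounded negation).
#' @export
motion_correct_rigid <- function(movie, reference = NULL, max_shift_px = 5) {
  d <- dim(movie)
  if (max_shift_px >= min(d[1], d[2]) / 2)
    stop("max_shift_px must be below half the field of view")
  if (is.null(reference)) reference <- apply(movie, c(1, 2), mean)
  stopifnot(identical(dim(reference), d[1:2]))
  ref_c <- reference - mean(reference)
  Fref <- Conj(fft(ref_c))
  # registration emphasizes static structure: clip the brightest tail so
  # transient somata (present in a frame, absent in the reference) do not
  # drag the correlation peak
  winsorize <- function(x) {
    q <- quantile(x, c(0.05, 0.90), names = FALSE)
    pmin(pmax(x, q[1]), q[2])
  }
  ref_w <- winsorize(reference)
  # normalized correlation over the valid overlap at a candidate lag; removes
  # the overlap-area penalty that biases plain FFT correlation toward zero
  # lag on smooth scenes
  ncc_at <- function(fr, dy, dx) {
    r1 <- max(1, 1 + dy):min(d[1], d[1] + dy)
    c1 <- max(1, 1 + dx):min(d[2], d[2] + dx)
    a <- fr[r1, c1]
    b <- ref_w[r1 - dy, c1 - dx]
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(as.vector(a), as.vector(b))
  }
  shifts <- matrix(0, d[3], 2)
  out <- movie
  lag_of <- function(i, n) if (i <= n / 2) i - 1 else i - 1 - n
  for (t in seq_len(d[3])) {
    fr_raw <- movie[, , t]
    fr <- winsorize(fr_raw)
    fr_c <- fr_raw - mean(fr_raw)
    if (sd(fr_c) == 0 || sd(ref_c) == 0) next  # tie-break: zero shift
    if (max_shift_px <= 8) {
      # small search ranges: exhaustive overlap-normalized search
      cand_y <- cand_x <- -max_shift_px:max_shift_px
    } else {
      # coarse integer peak from the FFT correlation, then +-3 refinement
      cc <- Re(fft(fft(fr_c) * Fref, inverse = TRUE)) / length(fr)
      ly <- vapply(seq_len(d[1]), lag_of, numeric(1), n = d[1])
      lx <- vapply(seq_len(d[2]), lag_of, numeric(1), n = d[2])
      ok <- outer(abs(ly) <= max_shift_px, abs(lx) <= max_shift_px)
      cc_ok <- cc
      cc_ok[!ok] <- -Inf
      pk <- which(cc_ok == max(cc_ok), arr.ind = TRUE)[1, ]
      dy0 <- ly[pk[1]]; dx0 <- lx[pk[2]]
      cand_y <- max(-max_shift_px, dy0 - 3):min(max_shift_px, dy0 + 3)
      cand_x <- max(-max_shift_px, dx0 - 3):min(max_shift_px, dx0 + 3)
    }
    ncc <- outer(cand_y, cand_x,
                 Vectorize(function(a, b) ncc_at(fr, a, b)))
    bi <- which(ncc == max(ncc), arr.ind = TRUE)[1, ]
    dy <- cand_y[bi[1]]; dx <- cand_x[bi[2]]
    # parabolic subpixel refinement on the normalized surface
    sub <- function(cm, c0, cp) {
      den <- cm - 2 * c0 + cp
      if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
    }
    at <- function(a, b) ncc_at(fr, a, b)
    dy_s <- if (abs(dy) < max_shift_px)
      dy + sub(at(dy - 1, dx), ncc[bi[1], bi[2]], at(dy + 1, dx)) else dy
    dx_s <- if (abs(dx) < max_shift_px)
      dx + sub(at(dy, dx - 1), ncc[bi[1], bi[2]], at(dy, dx + 1)) else dx
    shifts[t, ] <- c(dy_s, dx_s)
    if (dy != 0 || dx != 0)
      out[, , t] <- shift_frame(fr_raw, -dy, -dx)
  }
  list(movie = out, shifts = shifts)
}
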