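#' Generate spatial footprints for simulated somata
#'
#' Places `n_cells` compact somata in the field of view as isotropic 2D
#' Gaussian blobs. A cell of radius `r` (drawn uniformly from
#' `config$cell_radius_px`) has profile `exp(-d^2 / (2 sigma^2))` with
#' `sigma = r / 2`, truncated at `2 * sigma = r` from its center, so the
#' support diameter is `2 r` and every footprint peaks at exactly 1. Centers
#' are sampled uniformly at least `cell_radius_max` from the FOV edge and at
#' least one `cell_radius_max` apart (rejection sampling; placement failure
#' after a bounded number of attempts signals that the FOV is too small).
#'
#' @param config a [sim_config()].
#' @param centers optional `n x 2` matrix of (row, col) centers overriding
#'   random placement (used to construct deliberately overlapping pairs).
#' @return object of class `footprint_set`: list with `footprints`
#'   (`H x W x n` array, each plane max 1), `centers` (`n x 2`, 1-based
#'   row/col), `radii_px` (length `n`).
#' @export
generate_footprints <- function(config, centers = NULL) {
  H <- config$fov_px[1]; W <- config$fov_px[2]
  n <- config$n_cells
  r_max <- config$cell_radius_px[2]
  if (n == 0L) {
    return(structure(list(footprints = array(0, dim = c(H, W, 0)),
                          centers = matrix(0, 0, 2),
                          radii_px = numeric(0)),
                     class = "footprint_set"))
  }
  with_substream(config$seed, "footprints", {
    if (is.null(centers)) {
      if (H - 2 * r_max < 1 || W - 2 * r_max < 1)
        stop("FOV too small to place cells away from the edge")
      centers <- matrix(NA_real_, n, 2)
      placed <- 0L
      attempts <- 0L
      max_attempts <- 1000L * n
      while (placed < n) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop(sprintf(
            "could not place %d cells with min spacing %g px in a %dx%d FOV",
            n, r_max, H, W))
        cand <- c(runif(1, r_max + 1, H - r_max), runif(1, r_max + 1, W - r_max))
        if (placed == 0L ||
            min(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                   2, cand)^2))) >= r_max) {
          placed <- placed + 1L
          centers[placed, ] <- cand
        }
      }
    } else {
      centers <- as.matrix(centers)
      stopifnot(nrow(centers) == n, ncol(centers) == 2)
      if (any(centers[, 1] < 1 | centers[, 1] > H |
              centers[, 2] < 1 | centers[, 2] > W))
        stop("supplied centers fall outside the FOV")
    }
    radii <- runif(n, config$cell_radius_px[1], config$cell_radius_px[2])
    A <- array(0, dim = c(H, W, n))
    rows <- matrix(rep(seq_len(H), W), H, W)
    cols <- matrix(rep(seq_len(W), each = H), H, W)
    for (i in seq_len(n)) {
      sigma <- radii[i] / 2
      d2 <- (rows - centers[i, 1])^2 + (cols - centers[i, 2])^2
      blob <- exp(-d2 / (2 * sigma^2))
      blob[d2 > (2 * sigma)^2] <- 0
      A[, , i] <- blob / max(blob)
    }
    structure(list(footprints = A, centers = centers, radii_px = radii),
              class = "footprint_set")
  })
}

#' @export
print.footprint_set <- function(x, ...) {
  d <- dim(x$footprints)
  cat(sprintf("<footprint_set> %d cells in %d x %d px\n", d[3], d[1], d[2]))
  invisible(x)
}

# Flatten H x W x K footprints to an (H*W) x K matrix (column-major pixels).
flatten_footprints <- function(A) {
  d <- dim(A)
  matrix(A, d[1] * d[2], if (length(d) == 3) d[3] else 1)
}
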