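#' Seeded-ROI trace extraction
#'
#' The classical manual method: for each seed, the trace is the per-frame mean
#' pixel value inside a disk of `radius_px`, and the footprint is the disk
#' indicator. No background subtraction is performed — by construction the
#' method cannot separate somatic activity from low-spatial-frequency
#' background, which is exactly the failure mode the contamination benchmark
#' quantifies.
#'
#' @param movie `H x W x T` array.
#' @param seeds `n x 2` matrix of (row, col) disk centers (1-based pixels).
#' @param radius_px disk radius in pixels.
#' @return object of class `extraction_result` with `footprints`
#'   (`H x W x n`), `traces` (`n x T`), `method` = "roi", `diagnostics`.
#' @export
extract_roi <- function(movie, seeds, radius_px = 4) {
  d <- dim(movie)
  seeds <- as.matrix(seeds)
  if (nrow(seeds) > 0 &&
      (any(seeds[, 1] < 1 | seeds[, 1] > d[1]) ||
       any(seeds[, 2] < 1 | seeds[, 2] > d[2])))
    stop("ROI seed outside the field of view")
  n <- nrow(seeds)
  A <- array(0, dim = c(d[1], d[2], n))
  rows <- matrix(rep(seq_len(d[1]), d[2]), d[1], d[2])
  cols <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  M <- matrix(movie, d[1] * d[2], d[3])
  traces <- matrix(0, n, d[3])
  for (i in seq_len(n)) {
    disk <- (rows - seeds[i, 1])^2 + (cols - seeds[i, 2])^2 <= radius_px^2
    A[, , i] <- disk
    traces[i, ] <- colMeans(M[as.vector(disk), , drop = FALSE])
  }
  extraction_result(A, traces, "roi",
                    diagnostics = list(radius_px = radius_px))
}

# common constructor for all extraction methods
extraction_result <- function(footprints, traces, method,
                              diagnostics = list()) {
  stopifnot(dim(footprints)[3] == nrow(traces), all(footprints >= 0))
  structure(list(footprints = footprints, traces = traces,
                 method = method, diagnostics = diagnostics),
            class = "extraction_result")
}

#' Export footprint outlines as a label image
#'
#' Writes a single-page float TIFF in which each pixel carries the index of
#' the footprint with the largest weight there (0 = background), a compact
#' visual summary of an extraction.
#'
#' @param result an `extraction_result`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_footprint_labels <- function(result, path) {
  d <- dim(result$footprints)
  lab <- matrix(0, d[1], d[2])
  if (d[3] > 0) {
    A <- flatten_footprints(result$footprints)
    any_on <- rowSums(A) > 0
    lab[any_on] <- max.col(A[any_on, , drop = FALSE], ties.method = "first")
  }
  write_movie(array(lab, dim = c(d[1], d[2], 1)), path)
}

#' @export
print.extraction_result <- function(x, ...) {
  d <- dim(x$footprints)
  cat(sprintf("<extraction_result> method %s: %d components, %d x %d px, %d frames\n",
              x$method, d[3], d[1], d[2], ncol(x$traces)))
  invisible(x)
}
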