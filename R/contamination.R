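#' Generate stimulation-locked out-of-focus background contamination
#'
#' Models the broad rise in background fluorescence produced by out-of-plane
#' activation during stimulation as a separable (rank-1) spatiotemporal term:
#'
#' * spatial field: sum of 1-3 broad Gaussians (each `sigma >= FOV width / 4`)
#'   with random centers, normalized to peak 1 — strictly low spatial
#'   frequency relative to somata;
#' * temporal envelope: the stimulation-epoch indicator, weighted per epoch by
#'   frequency (envelope weight proportional to `f / max(f)`, mirroring the
#'   larger mean-fluorescence rise at higher stimulation frequency), convolved
#'   with the calcium kernel and rescaled so its peak equals
#'   `contamination_amplitude`.
#'
#' @param schedule a `stim_schedule`.
#' @param config a [sim_config()].
#' @return list with `spatial` (`H x W`, nonnegative, max 1 — all zero only
#'   for a degenerate FOV) and `temporal` (length `T`, nonnegative, peak
#'   `contamination_amplitude`; all zero when the schedule has no epochs).
#' @export
generate_contamination <- function(schedule, config) {
  H <- config$fov_px[1]; W <- config$fov_px[2]
  T_len <- schedule$T_frames
  with_substream(config$seed, "contamination", {
    n_blob <- sample(1:3, 1)
    rows <- matrix(rep(seq_len(H), W), H, W)
    cols <- matrix(rep(seq_len(W), each = H), H, W)
    spatial <- matrix(0, H, W)
    for (b in seq_len(n_blob)) {
      ctr <- c(runif(1, 1, H), runif(1, 1, W))
      sigma <- runif(1, W / 4, W / 2)
      spatial <- spatial +
        exp(-((rows - ctr[1])^2 + (cols - ctr[2])^2) / (2 * sigma^2))
    }
    spatial <- spatial / max(spatial)

    temporal <- numeric(T_len)
    ep <- schedule$epochs
    if (nrow(ep) > 0) {
      fmax <- max(ep$frequency_hz)
      ind <- numeric(T_len)
      for (i in seq_len(nrow(ep)))
        ind[epoch_frames(schedule, i)] <- ep$frequency_hz[i] / fmax
      k <- calcium_kernel(config$frame_rate_hz, config$kernel_rise_s,
                          config$kernel_decay_s)
      env <- convolve(ind, rev(k), type = "open")[seq_len(T_len)]
      env[env < 0] <- 0
      if (max(env) > 0)
        temporal <- env / max(env) * config$contamination_amplitude
    }
    list(spatial = spatial, temporal = temporal)
  })
}

#' Add out-of-focus contamination to a movie
#'
#' Adds the separable background term
#' `out[, , t] = movie[, , t] + amplitude * spatial * temporal[t]`.
#' Purely additive, so injection commutes with the other generative terms.
#'
#' @param movie `H x W x T` array.
#' @param spatial `H x W` nonnegative field.
#' @param temporal length-`T` nonnegative envelope.
#' @param amplitude extra scalar gain (default 1; the envelope usually already
#'   carries the amplitude).
#' @return contaminated movie, same shape.
#' @export
inject_contamination <- function(movie, spatial, temporal, amplitude = 1) {
  d <- dim(movie)
  if (!identical(dim(spatial), d[1:2]))
    stop("spatial field shape does not match movie frames")
  if (length(temporal) != d[3])
    stop("temporal envelope length does not match movie")
  M <- matrix(movie, d[1] * d[2], d[3])
  M <- M + amplitude * as.vector(spatial) %o% as.numeric(temporal)
  array(M, dim = d)
}
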