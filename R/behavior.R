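#' Generate a locomotor velocity trace
#'
#' Simulates open-field locomotion as a rectified Ornstein-Uhlenbeck process:
#' an AR(1) discretization mean-reverting to `mean_cmps` with relaxation time
#' `tau_s`, clipped at zero. The default parameterization yields both rest
#' (velocity < 0.5 cm/s, roughly a quarter of frames) and clear ambulation
#' (> 2 cm/s) epochs over long sessions, matching the behavioral mixture the
#' velocity-binned rate analysis requires.
#'
#' @param T_frames number of frames (>= 1).
#' @param config a [sim_config()] (uses `frame_rate_hz` and `seed`).
#' @param mean_cmps stationary mean of the unclipped process (cm/s).
#' @param sd_cmps stationary standard deviation (cm/s); 0 gives the constant
#'   mean trace.
#' @param tau_s relaxation time constant (s).
#' @return object of class `behavior_trace`: list with `velocity_cmps`
#'   (length `T_frames`, nonnegative) and `frame_rate_hz`.
#' @export
generate_velocity_trace <- function(T_frames, config, mean_cmps = 1.5,
                                    sd_cmps = 1.5, tau_s = 2) {
  stopifnot(T_frames >= 1, sd_cmps >= 0, tau_s > 0)
  dt <- 1 / config$frame_rate_hz
  a <- exp(-dt / tau_s)
  innov_sd <- sd_cmps * sqrt(1 - a^2)
  with_substream(config$seed, "velocity", {
    v <- numeric(T_frames)
    x <- mean_cmps + if (sd_cmps > 0) rnorm(1, 0, sd_cmps) else 0
    for (t in seq_len(T_frames)) {
      v[t] <- max(x, 0)
      x <- mean_cmps + a * (x - mean_cmps) +
        if (sd_cmps > 0) rnorm(1, 0, innov_sd) else 0
    }
    structure(list(velocity_cmps = v, frame_rate_hz = config$frame_rate_hz),
              class = "behavior_trace")
  })
}

#' @export
print.behavior_trace <- function(x, ...) {
  v <- x$velocity_cmps
  cat(sprintf(
    "<behavior_trace> %d frames @ %g fps; %.0f%% rest (< 0.5 cm/s), median %.2f cm/s\n",
    length(v), x$frame_rate_hz, 100 * mean(v < 0.5), median(v)))
  invisible(x)
}

#' Logical rest mask (velocity below 0.5 cm/s)
#'
#' Rest is defined as instantaneous locomotor velocity below 0.5 cm/s;
#' ambulation is its complement.
#'
#' @param behavior a `behavior_trace` or numeric velocity vector (cm/s).
#' @param threshold_cmps rest threshold, default 0.5 cm/s.
#' @return logical vector, `TRUE` for rest frames.
#' @export
rest_mask <- function(behavior, threshold_cmps = 0.5) {
  v <- if (inherits(behavior, "behavior_trace")) behavior$velocity_cmps
       else as.numeric(behavior)
  v < threshold_cmps
}
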