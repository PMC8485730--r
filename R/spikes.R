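#' Generate per-cell calcium event rasters
#'
#' Draws inhomogeneous Poisson event counts per cell and frame under the
#' paradigm encoded in the schedule:
#'
#' * Outside stimulation every cell fires at
#'   `lambda_i(t) = baseline_rate_hz * (1 + velocity_gain * v(t))`.
#' * Anesthetized paradigm: the striatum is quiescent between epochs
#'   (`baseline_rate_hz` should be ~0 for this paradigm); at each epoch of
#'   frequency `f` every cell is independently recruited with probability
#'   `recruit_prob[f]` (recruitment re-drawn per epoch, reproducing the
#'   heterogeneous responses to repeated identical stimuli), and a recruited
#'   cell fires at `stim_rate_hz` for the epoch duration.
#' * Awake paradigm: stimulation multiplies the ongoing velocity-modulated
#'   rate by `suppression_factor` (< 1), modeling the reduced striatal
#'   activity observed during awake stimulation.
#'
#' @param behavior a `behavior_trace` whose length matches the schedule.
#' @param schedule a `stim_schedule`.
#' @param footprints a `footprint_set` (fixes the number of cells).
#' @param config a [sim_config()].
#' @return list of class `event_raster`: `events` (`K x T` integer matrix),
#'   `frame_rate_hz`, and for the anesthetized paradigm `recruited`
#'   (`K x n_epochs` logical matrix).
#' @export
generate_spike_trains <- function(behavior, schedule, footprints, config) {
  v <- behavior$velocity_cmps
  T_len <- length(v)
  if (T_len != schedule$T_frames)
    stop(sprintf("behavior length (%d) does not match schedule length (%d)",
                 T_len, schedule$T_frames))
  K <- dim(footprints$footprints)[3]
  dt <- 1 / config$frame_rate_hz
  base <- config$baseline_rate_hz * (1 + config$velocity_gain * v)
  ep <- schedule$epochs
  with_substream(config$seed, "events", {
    events <- matrix(0L, K, T_len)
    recruited <- NULL
    if (K > 0L) {
      if (schedule$paradigm == "anesthetized") {
        lam <- matrix(rep(base, each = K), K, T_len)
        recruited <- matrix(FALSE, K, max(nrow(ep), 0L))
        for (i in seq_len(nrow(ep))) {
          f <- as.character(ep$frequency_hz[i])
          p <- config$recruit_prob[[f]]
          if (is.null(p))
            stop(sprintf("no recruit_prob entry for %s Hz", f))
          rec <- runif(K) < p
          recruited[, i] <- rec
          idx <- epoch_frames(schedule, i)
          lam[rec, idx] <- config$stim_rate_hz
          lam[!rec, idx] <- 0
        }
      } else {
        rate_t <- base
        on <- stim_mask(schedule)
        rate_t[on] <- rate_t[on] * config$suppression_factor
        lam <- matrix(rep(rate_t, each = K), K, T_len)
      }
      events[] <- rpois(K * T_len, lambda = as.vector(lam) * dt)
    }
    structure(list(events = events, frame_rate_hz = config$frame_rate_hz,
                   recruited = recruited),
              class = "event_raster")
  })
}
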