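#' Detect calcium events in extracted traces
#'
#' Simple deterministic transient detector: per cell, baseline = median and
#' scale = MAD of the trace; an event is marked at every local maximum
#' exceeding `baseline + threshold_mads * MAD`, with no second event within
#' `refractory_frames` (earlier/larger peaks win). An all-constant trace has
#' MAD 0 and yields zero events (epsilon floor on the scale).
#'
#' @param traces `K x T` numeric matrix.
#' @param frame_rate_hz frames per second (sets the default refractory
#'   window).
#' @param threshold_mads detection threshold in MAD units (default 3).
#' @param refractory_frames minimum spacing between events; default
#'   `ceiling(0.5 * frame_rate_hz)` (half a second).
#' @return `event_raster`: list with `events` (`K x T` integer) and
#'   `frame_rate_hz`.
#' @export
detect_events <- function(traces, frame_rate_hz, threshold_mads = 3,
                          refractory_frames = ceiling(0.5 * frame_rate_hz)) {
  stopifnot(all(is.finite(traces)))
  K <- nrow(traces); T_len <- ncol(traces)
  events <- matrix(0L, K, T_len)
  for (i in seq_len(K)) {
    x <- traces[i, ]
    scale <- max(mad(x), 1e-12)
    thr <- median(x) + threshold_mads * scale
    if (T_len < 3) next
    is_peak <- c(FALSE, x[2:(T_len - 1)] > x[1:(T_len - 2)] &
                        x[2:(T_len - 1)] >= x[3:T_len], FALSE) & x > thr
    peaks <- which(is_peak)
    if (length(peaks) == 0) next
    # enforce refractory period, keeping the larger peak of close pairs
    peaks <- peaks[order(-x[peaks], peaks)]
    kept <- integer(0)
    for (p in peaks)
      if (!length(kept) || all(abs(kept - p) > refractory_frames))
        kept <- c(kept, p)
    events[i, kept] <- 1L
  }
  structure(list(events = events, frame_rate_hz = frame_rate_hz,
                 recruited = NULL),
            class = "event_raster")
}

#' Population calcium event rate per frame
#'
#' The instantaneous calcium event rate at frame `t` is the total number of
#' events across all cells occurring in that frame.
#'
#' @param raster an `event_raster` (or `K x T` matrix).
#' @param per_second if `TRUE`, convert from events/frame to events/s.
#' @return numeric length-`T` vector.
#' @export
event_rate_timeseries <- function(raster, per_second = FALSE) {
  ev <- if (inherits(raster, "event_raster")) raster$events else raster
  rate <- colSums(ev)
  if (per_second) {
    stopifnot(inherits(raster, "event_raster"))
    rate <- rate * raster$frame_rate_hz
  }
  rate
}

#' Default velocity bin edges
#'
#' Rest bin `[0, 0.5)` cm/s followed by ambulation bins with finer widths at
#' low velocity and coarser widths at high velocity (all widths within
#' 0.5-2.5 cm/s); velocities above the last edge pool into an overflow bin.
#'
#' @return numeric vector of ascending interior edges (the implicit first
#'   edge is 0).
#' @export
default_velocity_edges <- function() c(0.5, 1.0, 1.5, 2.0, 2.5, 3.5, 5.0, 7.5, 10.0)

#' Bin per-frame event rates by locomotor velocity
#'
#' Assigns every frame to the half-open velocity bin containing it
#' (`[0, e1), [e1, e2), ..., [e_last, Inf)`; a velocity exactly at an edge
#' belongs to the bin above, so rest is strictly `< 0.5` cm/s) and returns
#' the per-bin mean rate and frame count.
#'
#' @param rate per-frame event rate (length `T`).
#' @param behavior `behavior_trace` or velocity vector (cm/s, length `T`).
#' @param edges ascending interior bin edges (default
#'   [default_velocity_edges()]).
#' @param frames optional logical/integer subset of frames to include.
#' @return object of class `velocity_binned_rates`: data.frame with
#'   `bin_low`, `bin_high` (Inf for overflow), `mean_rate`, `n_frames`.
#' @export
bin_rates_by_velocity <- function(rate, behavior,
                                  edges = default_velocity_edges(),
                                  frames = NULL) {
  v <- if (inherits(behavior, "behavior_trace")) behavior$velocity_cmps
       else as.numeric(behavior)
  if (length(rate) != length(v))
    stop("rate and velocity must have the same length")
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0))
    stop("edges must be strictly ascending and positive")
  if (!is.null(frames)) { rate <- rate[frames]; v <- v[frames] }
  full <- c(0, edges, Inf)
  idx <- findInterval(v, full)         # [full[i], full[i+1]) by default
  out <- data.frame(bin_low = full[-length(full)], bin_high = full[-1])
  out$mean_rate <- vapply(seq_len(nrow(out)),
                          function(b) if (any(idx == b)) mean(rate[idx == b]) else NA_real_,
                          numeric(1))
  out$n_frames <- vapply(seq_len(nrow(out)),
                         function(b) sum(idx == b), numeric(1))
  class(out) <- c("velocity_binned_rates", class(out))
  out
}

#' Normalize binned rates to the rest rate
#'
#' Divides every bin's mean rate by `rest_mean`, the animal's mean event rate
#' over unstimulated rest frames (velocity < 0.5 cm/s). When normalizing
#' stimulated conditions, `rest_mean` must still come from the same animal's
#' unstimulated rest frames, so all conditions share one reference.
#'
#' @param binned a `velocity_binned_rates`.
#' @param rest_mean positive scalar reference rate (same units as the binned
#'   rates).
#' @return `velocity_binned_rates` with a `normalized_rate` column.
#' @export
normalize_to_rest <- function(binned, rest_mean) {
  if (!is.numeric(rest_mean) || length(rest_mean) != 1 || rest_mean <= 0)
    stop("rest_mean must be a positive scalar (no rest frames, or a silent animal?)")
  binned$normalized_rate <- binned$mean_rate / rest_mean
  binned
}

#' Unstimulated rest-frame mean event rate
#'
#' Convenience reference for [normalize_to_rest()]: mean per-frame rate over
#' frames that are both at rest (velocity < 0.5 cm/s) and outside every
#' stimulation epoch.
#'
#' @param rate per-frame event rate.
#' @param behavior velocity trace.
#' @param schedule optional `stim_schedule`; when given, stimulation frames
#'   are excluded.
#' @return scalar mean rate.
#' @export
rest_reference_rate <- function(rate, behavior, schedule = NULL) {
  sel <- rest_mask(behavior)
  if (!is.null(schedule)) sel <- sel & !stim_mask(schedule)
  if (!any(sel)) stop("no unstimulated rest frames available")
  mean(rate[sel])
}
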