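#' Calcium transient kernel
#'
#' Causal double-exponential GCaMP kernel
#' `k(t) = exp(-t / tau_decay) - exp(-t / tau_rise)`, sampled at the frame
#' rate and normalized to peak 1. The kernel is truncated where the decay
#' term falls below `1e-4` of its peak.
#'
#' @param frame_rate_hz sampling rate (frames/s).
#' @param rise_s,decay_s rise and decay time constants in seconds
#'   (`decay_s > rise_s`).
#' @return numeric vector of kernel samples starting at lag 0, peak 1.
#' @export
calcium_kernel <- function(frame_rate_hz, rise_s = 0.1, decay_s = 0.6) {
  stopifnot(rise_s > 0, decay_s > rise_s, frame_rate_hz > 0)
  t_max <- decay_s * log(1e4)
  t <- seq(0, t_max, by = 1 / frame_rate_hz)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

#' Convolve an event raster with the calcium kernel
#'
#' Each cell's fluorescence trace is the superposition of one unit transient
#' per event: the row-wise causal convolution of the integer event raster with
#' [calcium_kernel()]. A single event therefore produces a trace that peaks at
#' exactly 1.
#'
#' @param events `K x T` nonnegative integer matrix of event counts.
#' @param config a [sim_config()].
#' @return `K x T` nonnegative numeric matrix of traces.
#' @export
convolve_calcium <- function(events, config) {
  stopifnot(is.matrix(events), all(events >= 0))
  k <- calcium_kernel(config$frame_rate_hz, config$kernel_rise_s,
                      config$kernel_decay_s)
  T_len <- ncol(events)
  L <- length(k)
  out <- matrix(0, nrow(events), T_len)
  # rasters are sparse: superpose one kernel per event directly (exact)
  for (i in seq_len(nrow(events))) {
    for (f in which(events[i, ] > 0)) {
      span <- f:min(T_len, f + L - 1L)
      out[i, span] <- out[i, span] + events[i, f] * k[seq_along(span)]
    }
  }
  dimnames(out) <- dimnames(events)
  out
}
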