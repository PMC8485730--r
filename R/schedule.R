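#' Build a deep-brain-stimulation schedule
#'
#' Lays out stimulation epochs for either experimental paradigm:
#'
#' * `"anesthetized"`: after a 10-s stimulation-free lead-in, 10-s epochs are
#'   applied in 1-min intervals (one epoch every 70 s), cycling through
#'   frequencies 30, 80, 130 Hz three times (nine epochs total when the
#'   recording is long enough). Default pulse width 140 us.
#' * `"awake"`: alternating 10-min stimulation-free and 10-min stimulation-on
#'   blocks, the ON blocks at 30 Hz then 130 Hz. Default 200 us pulse width,
#'   30 uA amplitude.
#'
#' Epoch frames are 0-based and half-open: an epoch `[start_frame, end_frame)`
#' contains frames `start_frame .. end_frame - 1`.
#'
#' @param paradigm `"anesthetized"` or `"awake"`.
#' @param T_frames recording length in frames.
#' @param frame_rate_hz frames per second.
#' @param amplitude_ua stimulation amplitude (uA). The anesthetized default of
#'   50 uA stands in for the per-animal titration used experimentally.
#' @param pulse_width_us pulse width (us); paradigm default if `NULL`.
#' @return object of class `stim_schedule`: list with `epochs` (data.frame
#'   `start_frame`, `end_frame`, `frequency_hz`, `amplitude_ua`,
#'   `pulse_width_us`), `paradigm`, `frame_rate_hz`, `T_frames`.
#' @export
build_stim_schedule <- function(paradigm = c("anesthetized", "awake"),
                                T_frames, frame_rate_hz,
                                amplitude_ua = NULL, pulse_width_us = NULL) {
  paradigm <- match.arg(paradigm)
  stopifnot(T_frames >= 1, frame_rate_hz > 0)
  fr <- frame_rate_hz
  if (paradigm == "anesthetized") {
    if (is.null(amplitude_ua)) amplitude_ua <- 50
    if (is.null(pulse_width_us)) pulse_width_us <- 140
    lead_s <- 10; epoch_s <- 10; cycle_s <- 70
    freqs <- rep(c(30, 80, 130), times = 3)
    starts <- round((lead_s + (seq_along(freqs) - 1) * cycle_s) * fr)
    ends <- starts + round(epoch_s * fr)
    keep <- ends <= T_frames
    min_frames <- ends[1]
    if (!any(keep))
      stop(sprintf(
        "T_frames = %d too short for an anesthetized schedule; need >= %d frames (%g s)",
        T_frames, min_frames, min_frames / fr))
    epochs <- data.frame(start_frame = starts[keep], end_frame = ends[keep],
                         frequency_hz = freqs[keep])
  } else {
    if (is.null(amplitude_ua)) amplitude_ua <- 30
    if (is.null(pulse_width_us)) pulse_width_us <- 200
    block_s <- 600
    freqs <- c(30, 130)
    starts <- round(block_s * fr) * c(1, 3)
    ends <- starts + round(block_s * fr)
    keep <- ends <= T_frames
    min_frames <- ends[1]
    if (!any(keep))
      stop(sprintf(
        "T_frames = %d too short for an awake schedule; need >= %d frames (%g s)",
        T_frames, min_frames, min_frames / fr))
    epochs <- data.frame(start_frame = starts[keep], end_frame = ends[keep],
                         frequency_hz = freqs[keep])
  }
  epochs$amplitude_ua <- amplitude_ua
  epochs$pulse_width_us <- pulse_width_us
  sched <- structure(list(epochs = epochs, paradigm = paradigm,
                          frame_rate_hz = fr, T_frames = as.integer(T_frames)),
                     class = "stim_schedule")
  validate_stim_schedule(sched)
}

validate_stim_schedule <- function(sched) {
  e <- sched$epochs
  if (nrow(e) > 0) {
    if (any(e$end_frame <= e$start_frame))
      stop("epochs must be non-empty half-open intervals")
    if (is.unsorted(e$start_frame, strictly = TRUE))
      stop("epochs must be sorted by start frame")
    if (any(e$start_frame[-1] < e$end_frame[-nrow(e)])) {
      bad <- which(e$start_frame[-1] < e$end_frame[-nrow(e)])
      stop(sprintf("overlapping epochs at rows %s",
                   paste(bad, bad + 1, sep = "-", collapse = ", ")))
    }
    if (any(e$start_frame < 0) || any(e$end_frame > sched$T_frames))
      stop("epochs must lie within the recording")
  }
  sched
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf("<stim_schedule> %s paradigm, %d epochs in %d frames @ %g fps\n",
              x$paradigm, nrow(x$epochs), x$T_frames, x$frame_rate_hz))
  if (nrow(x$epochs) > 0) print(x$epochs, row.names = FALSE)
  invisible(x)
}

# 1-based R frame indices covered by epoch row i
epoch_frames <- function(sched, i) {
  e <- sched$epochs[i, ]
  seq.int(e$start_frame + 1L, e$end_frame)
}

# length-T logical: TRUE where any stimulation epoch is on
stim_mask <- function(sched) {
  on <- logical(sched$T_frames)
  for (i in seq_len(nrow(sched$epochs))) on[epoch_frames(sched, i)] <- TRUE
  on
}

# per-frame stimulation frequency (0 where off)
stim_frequency_trace <- function(sched) {
  f <- numeric(sched$T_frames)
  for (i in seq_len(nrow(sched$epochs)))
    f[epoch_frames(sched, i)] <- sched$epochs$frequency_hz[i]
  f
}

#' Build a schedule from explicit epochs
#'
#' Low-level constructor for custom layouts (e.g. short test fixtures that
#' cannot fit the standard paradigm timing). Invariants (sorted,
#' non-overlapping, within the recording) are enforced.
#'
#' @param epochs data.frame with `start_frame`, `end_frame` (0-based,
#'   half-open), `frequency_hz`, and optionally `amplitude_ua`,
#'   `pulse_width_us`.
#' @param T_frames recording length in frames.
#' @param frame_rate_hz frames per second.
#' @param paradigm paradigm label selecting the rate model
#'   (`"anesthetized"` or `"awake"`).
#' @return a `stim_schedule`.
#' @export
stim_schedule_from_epochs <- function(epochs, T_frames, frame_rate_hz,
                                      paradigm = "anesthetized") {
  if (is.null(epochs$amplitude_ua)) epochs$amplitude_ua <- 50
  if (is.null(epochs$pulse_width_us)) epochs$pulse_width_us <- 140
  validate_stim_schedule(structure(
    list(epochs = as.data.frame(epochs), paradigm = paradigm,
         frame_rate_hz = frame_rate_hz, T_frames = as.integer(T_frames)),
    class = "stim_schedule"))
}

# empty schedule helper (no stimulation control condition)
empty_schedule <- function(T_frames, frame_rate_hz,
                           paradigm = "awake") {
  structure(list(epochs = data.frame(start_frame = integer(0),
                                     end_frame = integer(0),
                                     frequency_hz = numeric(0),
                                     amplitude_ua = numeric(0),
                                     pulse_width_us = numeric(0)),
                 paradigm = paradigm, frame_rate_hz = frame_rate_hz,
                 T_frames = as.integer(T_frames)),
            class = "stim_schedule")
}
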