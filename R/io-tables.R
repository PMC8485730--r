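# CSV readers/writers for behavior traces and stimulation schedules.
# Conventions: 0-based frame indices, half-open epoch intervals.

#' Write / read a behavior (velocity) trace as CSV
#'
#' Columns: `frame` (0-based), `velocity_cmps`. The frame rate is stored in a
#' `# frame_rate_hz:` comment header.
#'
#' @param behavior a `behavior_trace`.
#' @param path CSV file path.
#' @return `path` (write) or a `behavior_trace` (read).
#' @export
write_behavior <- function(behavior, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_rate_hz: %.10g", behavior$frame_rate_hz), con)
  write.csv(data.frame(frame = seq_along(behavior$velocity_cmps) - 1L,
                       velocity_cmps = behavior$velocity_cmps),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  hdr <- readLines(path, n = 1)
  fr <- as.numeric(sub("# frame_rate_hz:", "", hdr))
  if (!is.finite(fr)) stop("missing frame_rate_hz header")
  df <- read.csv(path, comment.char = "#")
  if (!all(c("frame", "velocity_cmps") %in% names(df)))
    stop("behavior CSV must have columns frame, velocity_cmps")
  if (any(df$velocity_cmps < 0))
    stop(sprintf("negative velocity at %d row(s)", sum(df$velocity_cmps < 0)))
  if (!identical(df$frame, seq_len(nrow(df)) - 1L) &&
      !all(df$frame == seq_len(nrow(df)) - 1))
    stop("frame column must be contiguous and 0-based")
  structure(list(velocity_cmps = df$velocity_cmps, frame_rate_hz = fr),
            class = "behavior_trace")
}

#' Write / read a stimulation schedule as CSV
#'
#' Columns: `start_frame`, `end_frame` (0-based, half-open), `frequency_hz`,
#' `amplitude_ua`, `pulse_width_us`. Paradigm, frame rate and recording
#' length are stored in comment headers; schedule invariants (sorted,
#' non-overlapping, within the recording) are enforced on load.
#'
#' @param schedule a `stim_schedule`.
#' @param path CSV file path.
#' @return `path` (write) or a `stim_schedule` (read).
#' @export
write_schedule <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# paradigm: %s", schedule$paradigm),
               sprintf("# frame_rate_hz: %.10g", schedule$frame_rate_hz),
               sprintf("# t_frames: %d", schedule$T_frames)), con)
  write.csv(schedule$epochs, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  hdr <- readLines(path, n = 3)
  paradigm <- trimws(sub("# paradigm:", "", hdr[1]))
  fr <- as.numeric(sub("# frame_rate_hz:", "", hdr[2]))
  T_frames <- as.integer(sub("# t_frames:", "", hdr[3]))
  if (!is.finite(fr) || is.na(T_frames))
    stop("schedule CSV missing paradigm/frame_rate_hz/t_frames headers")
  df <- read.csv(path, comment.char = "#")
  required <- c("start_frame", "end_frame", "frequency_hz", "amplitude_ua",
                "pulse_width_us")
  if (!all(required %in% names(df)))
    stop(sprintf("schedule CSV must have columns: %s",
                 paste(required, collapse = ", ")))
  sched <- structure(list(epochs = df[required], paradigm = paradigm,
                          frame_rate_hz = fr, T_frames = T_frames),
                     class = "stim_schedule")
  validate_stim_schedule(sched)
}

#' Write analysis tables
#'
#' Plain-CSV writers for the tidy outputs of the analysis module.
#'
#' @param x a `velocity_binned_rates` or `activation_counts` data.frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
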