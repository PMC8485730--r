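#' Standard fixture configurations
#'
#' Three deterministic problem sizes used throughout the test-suite and
#' benchmark: `tiny` (16 x 16 px, 200 frames, 3 cells — runs end-to-end in
#' seconds), `small` (64 x 64, 2000 frames, 15 cells), and `bench`
#' (100 x 100, 4000 frames, 30 cells — the method-comparison substrate).
#'
#' @param size one of `"tiny"`, `"small"`, `"bench"`.
#' @param seed integer seed.
#' @param ... overrides forwarded to [sim_config()].
#' @return a [sim_config()].
#' @export
fixture_config <- function(size = c("tiny", "small", "bench"), seed = 1L, ...) {
  size <- match.arg(size)
  base <- switch(size,
    tiny  = list(fov_px = c(16L, 16L), n_cells = 3L,
                 cell_radius_px = c(2, 3)),
    small = list(fov_px = c(64L, 64L), n_cells = 15L),
    bench = list(fov_px = c(100L, 100L), n_cells = 30L))
  do.call(sim_config, modifyList(c(base, list(seed = seed)), list(...)))
}

#' Fixture length in frames
#' @param size fixture label as in [fixture_config()].
#' @return frame count.
#' @export
fixture_frames <- function(size = c("tiny", "small", "bench")) {
  switch(match.arg(size), tiny = 200L, small = 2000L, bench = 4000L)
}

#' Generate a fixture bundle on disk
#'
#' Simulates the fixture session (anesthetized paradigm for `tiny`/`bench`
#' lengths, which fit the 10-s epoch layout) and writes movie (TIFF),
#' ground truth (RDS), behavior and schedule (CSV) into `dir`.
#'
#' @param size fixture label.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param paradigm stimulation paradigm; default `"anesthetized"`.
#' @return invisible list of written paths plus the `ground_truth`.
#' @export
make_fixtures <- function(size = c("tiny", "small", "bench"),
                          dir = tempfile("fixture_"), seed = 1L,
                          paradigm = "anesthetized") {
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- fixture_config(size, seed = seed)
  T_frames <- fixture_frames(size)
  # the tiny fixture is too short for the standard 70-s epoch cycle; use a
  # compressed two-epoch layout with the same structure
  schedule <- if (size == "tiny" && paradigm == "anesthetized")
    stim_schedule_from_epochs(
      data.frame(start_frame = c(40L, 120L), end_frame = c(80L, 160L),
                 frequency_hz = c(30, 130)),
      T_frames, cfg$frame_rate_hz, paradigm = "anesthetized")
  else NULL
  truth <- simulate_session(cfg, T_frames, paradigm = paradigm,
                            schedule = schedule)
  paths <- list(
    movie = file.path(dir, "movie.tif"),
    truth_rds = file.path(dir, "ground_truth.rds"),
    behavior = file.path(dir, "behavior.csv"),
    schedule = file.path(dir, "schedule.csv"))
  write_movie(truth$movie, paths$movie)
  saveRDS(truth[setdiff(names(truth), "movie")], paths$truth_rds)
  write_behavior(truth$behavior, paths$behavior)
  write_schedule(truth$schedule, paths$schedule)
  invisible(c(paths, list(truth = truth)))
}
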