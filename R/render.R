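#' Render a movie from ground-truth components
#'
#' Composes each frame as
#' `baseline + sum_i footprint_i * trace_i(t) + spatial * temporal(t) + noise`
#' with i.i.d. Gaussian pixel noise of standard deviation `config$noise_sd`,
#' clipped at zero. With zero noise the composition is exact: all generative
#' terms are nonnegative so clipping never engages and the movie can be
#' decomposed back into its components to floating tolerance.
#'
#' @param truth a `ground_truth` object (see [simulate_session()]).
#' @param config a [sim_config()].
#' @return `H x W x T` numeric array.
#' @export
render_movie <- function(truth, config) {
  A <- truth$footprints$footprints
  d <- dim(A)
  H <- d[1]; W <- d[2]; K <- d[3]
  T_len <- ncol(truth$traces)
  if (K > 0 && nrow(truth$traces) != K)
    stop("traces/footprints cell-count mismatch")
  if (!identical(dim(truth$baseline_image), c(H, W)))
    stop("baseline image shape mismatch")
  if (length(truth$contamination_temporal) != T_len)
    stop("contamination envelope length mismatch")
  M <- matrix(as.vector(truth$baseline_image), H * W, T_len)
  if (K > 0)
    M <- M + flatten_footprints(A) %*% truth$traces
  M <- M + as.vector(truth$contamination_spatial) %o%
    as.numeric(truth$contamination_temporal)
  if (config$noise_sd > 0) {
    with_substream(config$seed, "noise", {
      M <- M + rnorm(length(M), 0, config$noise_sd)
    })
    M[M < 0] <- 0
  }
  array(M, dim = c(H, W, T_len))
}

#' Simulate a full imaging session with ground truth
#'
#' High-level generator tying the simulation module together: footprints,
#' velocity trace, stimulation schedule, event raster, calcium traces,
#' static background, out-of-focus contamination, and the rendered movie.
#' The static background is a smooth random field (broad Gaussian bumps)
#' centered on `config$baseline_level`, kept strictly positive so dF/F is
#' well defined.
#'
#' @param config a [sim_config()].
#' @param T_frames session length in frames.
#' @param paradigm `"anesthetized"`, `"awake"`, or `"none"` (no stimulation).
#' @param render if `FALSE`, skip movie rendering (ground truth only) —
#'   useful for event-statistics studies that never touch pixels.
#' @param centers optional fixed footprint centers (see
#'   [generate_footprints()]).
#' @param schedule optional pre-built `stim_schedule` overriding the standard
#'   paradigm layout (its `paradigm` label still selects the rate model).
#' @return list of class `ground_truth` with elements `footprints`, `traces`,
#'   `events`, `recruited`, `baseline_image`, `contamination_spatial`,
#'   `contamination_temporal`, `behavior`, `schedule`, `config`, and `movie`
#'   (`NULL` when `render = FALSE`).
#' @export
simulate_session <- function(config, T_frames, paradigm = "awake",
                             render = TRUE, centers = NULL, schedule = NULL) {
  fp <- generate_footprints(config, centers = centers)
  behavior <- generate_velocity_trace(T_frames, config)
  if (is.null(schedule)) {
    schedule <- if (paradigm == "none")
      empty_schedule(T_frames, config$frame_rate_hz)
    else build_stim_schedule(paradigm, T_frames, config$frame_rate_hz)
  } else {
    stopifnot(inherits(schedule, "stim_schedule"),
              schedule$T_frames == T_frames)
  }
  raster <- generate_spike_trains(behavior, schedule, fp, config)
  traces <- convolve_calcium(raster$events, config)
  H <- config$fov_px[1]; W <- config$fov_px[2]
  baseline <- with_substream(config$seed, "baseline", {
    rows <- matrix(rep(seq_len(H), W), H, W)
    cols <- matrix(rep(seq_len(W), each = H), H, W)
    # broad illumination gradient plus medium-scale neuropil/vessel relief
    field <- matrix(0, H, W)
    for (b in 1:3) {
      ctr <- c(runif(1, 1, H), runif(1, 1, W))
      sigma <- runif(1, W / 3, W)
      field <- field +
        exp(-((rows - ctr[1])^2 + (cols - ctr[2])^2) / (2 * sigma^2))
    }
    n_bumps <- max(20L, round(H * W / 200))
    relief <- matrix(0, H, W)
    for (b in seq_len(n_bumps)) {
      ctr <- c(runif(1, 1, H), runif(1, 1, W))
      sigma <- runif(1, W / 20, W / 6)
      relief <- relief + runif(1, -1, 1) *
        exp(-((rows - ctr[1])^2 + (cols - ctr[2])^2) / (2 * sigma^2))
    }
    relief <- relief / sd(relief)
    # one-photon FOVs are dominated by static structure (vasculature,
    # out-of-focus neuropil): give the relief ~30% contrast and keep the
    # image strictly positive
    base <- config$baseline_level *
      (0.7 + 0.5 * field / max(field) + 0.3 * relief)
    pmax(base, 0.1 * config$baseline_level)
  })
  contam <- generate_contamination(schedule, config)
  truth <- structure(list(
    footprints = fp, traces = traces, events = raster$events,
    recruited = raster$recruited, baseline_image = baseline,
    contamination_spatial = contam$spatial,
    contamination_temporal = contam$temporal,
    behavior = behavior, schedule = schedule, config = config,
    movie = NULL), class = "ground_truth")
  if (render) truth$movie <- render_movie(truth, config)
  truth
}

#' @export
print.ground_truth <- function(x, ...) {
  d <- dim(x$footprints$footprints)
  cat(sprintf(
    "<ground_truth> %d cells, %d x %d px, %d frames (%s paradigm)%s\n",
    d[3], d[1], d[2], ncol(x$traces),
    x$schedule$paradigm,
    if (is.null(x$movie)) " [not rendered]" else ""))
  invisible(x)
}
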