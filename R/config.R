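#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every generator
#' in the simulation module. Defaults describe a parkinsonian-mouse striatal
#' recording: tens of GCaMP6m-expressing somata imaged at 20 frames/s over a
#' structured background, with subthalamic stimulation either recruiting cells
#' (anesthetized paradigm) or suppressing ongoing activity (awake paradigm).
#'
#' @param fov_px integer length-2, field of view in pixels `(height, width)`.
#' @param frame_rate_hz acquisition rate in frames per second.
#' @param n_cells number of simulated somata.
#' @param cell_radius_px length-2 `(min, max)` soma radius in pixels. A cell of
#'   radius `r` is rendered as an isotropic Gaussian of `sigma = r / 2`
#'   truncated at `2 * sigma`, so its support diameter is `2 * r`.
#' @param baseline_rate_hz mean per-cell calcium event rate at rest (events/s).
#' @param velocity_gain slope `beta` of the linear rate law
#'   `lambda(v) = baseline_rate_hz * (1 + beta * v)`, per cm/s.
#' @param recruit_prob named numeric vector mapping stimulation frequency (Hz,
#'   as names) to the per-epoch probability that a cell is recruited.
#' @param stim_rate_hz event rate of a recruited cell during a stimulation
#'   epoch (anesthetized paradigm).
#' @param suppression_factor multiplicative factor (< 1) applied to the ongoing
#'   rate during awake stimulation epochs.
#' @param kernel_rise_s,kernel_decay_s rise and decay time constants (s) of the
#'   double-exponential GCaMP6m transient kernel; decay must exceed rise.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param contamination_amplitude peak amplitude of the stimulation-locked
#'   out-of-focus background envelope, in the same units as cell peaks
#'   (a unit event transient peaks at 1).
#' @param baseline_level mean level of the static background image.
#' @param seed integer seed; all generator randomness derives from it through
#'   fixed per-component substream offsets.
#'
#' @return object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_cells = 5, fov_px = c(32, 32), seed = 1)
sim_config <- function(fov_px = c(100L, 100L),
                       frame_rate_hz = 20,
                       n_cells = 30L,
                       cell_radius_px = c(3, 5),
                       baseline_rate_hz = 0.2,
                       velocity_gain = 0.5,
                       recruit_prob = c("30" = 0.1, "80" = 0.4, "130" = 0.5),
                       stim_rate_hz = 3,
                       suppression_factor = 0.6,
                       kernel_rise_s = 0.1,
                       kernel_decay_s = 0.6,
                       noise_sd = 0.05,
                       contamination_amplitude = 2,
                       baseline_level = 1,
                       seed = 1L) {
  cfg <- list(
    fov_px = as.integer(fov_px),
    frame_rate_hz = frame_rate_hz,
    n_cells = as.integer(n_cells),
    cell_radius_px = as.numeric(cell_radius_px),
    baseline_rate_hz = baseline_rate_hz,
    velocity_gain = velocity_gain,
    recruit_prob = recruit_prob,
    stim_rate_hz = stim_rate_hz,
    suppression_factor = suppression_factor,
    kernel_rise_s = kernel_rise_s,
    kernel_decay_s = kernel_decay_s,
    noise_sd = noise_sd,
    contamination_amplitude = contamination_amplitude,
    baseline_level = baseline_level,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$fov_px) != 2L || any(cfg$fov_px < 16L))
    stop("fov_px must be two integers >= 16")
  if (cfg$frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (cfg$n_cells < 0L) stop("n_cells must be nonnegative")
  if (length(cfg$cell_radius_px) != 2L || any(cfg$cell_radius_px <= 0) ||
      cfg$cell_radius_px[1] > cfg$cell_radius_px[2])
    stop("cell_radius_px must be positive (min, max)")
  if (cfg$baseline_rate_hz < 0) stop("baseline_rate_hz must be nonnegative")
  if (cfg$velocity_gain < 0) stop("velocity_gain must be nonnegative")
  if (is.null(names(cfg$recruit_prob)) ||
      any(is.na(suppressWarnings(as.numeric(names(cfg$recruit_prob))))))
    stop("recruit_prob must be named by stimulation frequency in Hz")
  if (any(cfg$recruit_prob < 0 | cfg$recruit_prob > 1))
    stop("recruit_prob values must lie in [0, 1]")
  if (cfg$suppression_factor < 0 || cfg$suppression_factor > 1)
    stop("suppression_factor must lie in [0, 1]")
  if (cfg$kernel_rise_s <= 0 || cfg$kernel_decay_s <= 0)
    stop("kernel time constants must be positive")
  if (cfg$kernel_decay_s <= cfg$kernel_rise_s)
    stop("kernel_decay_s must exceed kernel_rise_s")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (cfg$contamination_amplitude < 0)
    stop("contamination_amplitude must be nonnegative")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  fov %d x %d px, %g fps, %d cells (radius %g-%g px)\n",
              x$fov_px[1], x$fov_px[2], x$frame_rate_hz, x$n_cells,
              x$cell_radius_px[1], x$cell_radius_px[2]))
  cat(sprintf("  rates: baseline %g Hz, velocity gain %g /(cm/s), stim %g Hz, suppression %g\n",
              x$baseline_rate_hz, x$velocity_gain, x$stim_rate_hz,
              x$suppression_factor))
  cat(sprintf("  recruit_prob: %s\n",
              paste(sprintf("%s Hz=%g", names(x$recruit_prob), x$recruit_prob),
                    collapse = ", ")))
  cat(sprintf("  kernel rise/decay %g/%g s, noise sd %g, contamination %g, seed %d\n",
              x$kernel_rise_s, x$kernel_decay_s, x$noise_sd,
              x$contamination_amplitude, x$seed))
  invisible(x)
}

# Fixed substream offsets: every generator draws from seed + offset so that
# components are independently reproducible and the whole session is
# deterministic given one integer seed.
.substream <- c(footprints = 101L, velocity = 202L, events = 303L,
                contamination = 404L, baseline = 505L, noise = 606L,
                ica = 707L, svd = 808L)

with_substream <- function(seed, component, code) {
  off <- .substream[[component]]
  withr::with_seed((as.integer(seed) + off) %% .Machine$integer.max, code)
}
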