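#' Score contamination rejection of an extraction result
#'
#' Quantifies how much of the stimulation-locked out-of-focus background
#' leaked into the extracted traces: for each trace, the Pearson correlation
#' with the ground-truth contamination envelope is computed over the
#' stimulation-containing frames (epoch frames plus a kernel-decay tail), and
#' the median absolute value is reported. Low values mean the method rejected
#' the background. The median pairwise inter-trace correlation (near 1 when
#' every trace is the same global artifact) and footprint precision/recall
#' complete the score.
#'
#' @param result an `extraction_result`.
#' @param truth a `ground_truth` with a non-constant contamination envelope.
#' @return list with `median_abs_corr`, `median_pairwise_corr` (`NA` for
#'   fewer than two traces), `precision`, `recall`, `n_traces`,
#'   `constant_traces` flag.
#' @export
score_rejection <- function(result, truth) {
  env <- truth$contamination_temporal
  if (sd(env) == 0)
    stop("contamination envelope is constant; rejection score undefined")
  frames <- which(env > 0.01 * max(env))
  # widen to include the pre-onset baseline for contrast
  frames <- sort(unique(c(frames, which(stim_mask(truth$schedule)))))
  if (length(frames) < 3) frames <- seq_along(env)
  tr <- result$traces
  n <- nrow(tr)
  constant <- FALSE
  if (n == 0) {
    med_corr <- NA_real_
  } else {
    cors <- vapply(seq_len(n), function(i) {
      x <- tr[i, frames]
      if (sd(x) == 0) { constant <<- TRUE; return(0) }
      cor(x, env[frames])
    }, numeric(1))
    med_corr <- median(abs(cors))
  }
  pair <- NA_real_
  if (n >= 2) {
    cm <- suppressWarnings(cor(t(tr)))
    cm[!is.finite(cm)] <- 0
    pair <- median(cm[upper.tri(cm)])
  }
  m <- match_components(result, truth)
  list(median_abs_corr = med_corr, median_pairwise_corr = pair,
       precision = m$precision, recall = m$recall,
       n_traces = n, constant_traces = constant,
       abs_corrs = if (n > 0) abs(cors) else numeric(0))
}

#' Run the extraction-method contamination benchmark
#'
#' Generates one synthetic session with stimulation-locked out-of-focus
#' contamination and scores each extraction method's ability to reject it,
#' with and without spatial bandpass prefiltering. The substrate mirrors the
#' design of injecting simulated contamination into a normal recording: cells
#' fire from their ongoing velocity-modulated rates (stimulation does not
#' alter somatic activity here), while the epochs drive only the
#' low-spatial-frequency background term — so any correlation between an
#' extracted trace and the contamination envelope measures background
#' leakage, not physiology. Epochs of 10 s are laid out every 30 s (a
#' compressed layout so short benchmark movies contain several epochs),
#' cycling through 30/80/130 Hz. ROI seeds and the PCA/ICA component count
#' are taken from ground truth (seeded at the true centers, 1.5 cells-worth
#' of components), so the comparison isolates background handling rather
#' than cell detection.
#'
#' The headline property this benchmark makes quantitative: the ring-model
#' constrained NMF rejects the low-spatial-frequency background best, spatial
#' bandpass prefiltering improves ROI/PCA-ICA rejection, and raw ROI/PCA-ICA
#' leak the artifact into every trace.
#'
#' @param config a [sim_config()]; contamination amplitude should be
#'   comparable to (e.g. twice) the median cell peak.
#' @param T_frames session length in frames.
#' @param substrate_rate_hz per-cell event rate of the benchmark substrate.
#'   The default (0.05 events/s) reflects the sparse striatal activity of the
#'   recordings the contamination comparison targets; it overrides
#'   `config$baseline_rate_hz` for this benchmark only.
#' @param methods character subset of
#'   `c("roi", "pca_ica", "cnmf_ring")`.
#' @param bandpass logical vector: run the pipeline without (`FALSE`) and/or
#'   with (`TRUE`) the spatial bandpass prefilter. The constrained NMF is
#'   always run on the unfiltered movie (its background model is the point).
#' @param cutoffs_px bandpass cutoffs in pixels.
#' @return object of class `bench_report`: data.frame with one row per
#'   (method, bandpass) combination and the scores of [score_rejection()].
#'   Attribute `truth` carries the session; attribute `family` gives the
#'   pooled median |correlation| over all traces of each processing family
#'   (`ring_nmf`, `bandpassed`, `raw`), the quantity the headline ordering
#'   is stated on.
#' @export
run_method_comparison <- function(config, T_frames = 4000L,
                                  methods = c("roi", "pca_ica", "cnmf_ring"),
                                  bandpass = c(FALSE, TRUE),
                                  cutoffs_px = c(5, 31),
                                  substrate_rate_hz = 0.05) {
  fr <- config$frame_rate_hz
  config$baseline_rate_hz <- substrate_rate_hz
  # keep the prefilter applicable on small fields of view
  cutoffs_px[2] <- min(cutoffs_px[2], min(config$fov_px) - 1)
  if (cutoffs_px[1] >= cutoffs_px[2])
    cutoffs_px[1] <- max(2, cutoffs_px[2] %/% 2)
  starts <- round(seq(10, by = 30, length.out = 100) * fr)
  ends <- starts + round(10 * fr)
  keep <- ends <= T_frames
  if (!any(keep)) stop("T_frames too short for a benchmark schedule")
  sched <- stim_schedule_from_epochs(
    data.frame(start_frame = starts[keep], end_frame = ends[keep],
               frequency_hz = rep_len(c(30, 80, 130), sum(keep))),
    T_frames, fr, paradigm = "awake")
  # stimulation must not alter somatic rates in the benchmark substrate
  config$suppression_factor <- 1
  truth <- simulate_session(config, T_frames, paradigm = "awake",
                            schedule = sched)
  movie <- truth$movie
  rows <- list()
  corrs <- list()
  filtered <- NULL
  for (bp in bandpass) {
    if (bp && is.null(filtered)) {
      filtered <- spatial_bandpass(movie, cutoffs_px)
      filtered <- filtered - min(filtered)  # keep factorization input nonnegative
    }
    input <- if (bp) filtered else movie
    for (m in methods) {
      if (m == "cnmf_ring" && bp) next
      res <- tryCatch(switch(m,
        roi = extract_roi(input, truth$footprints$centers,
                          radius_px = mean(config$cell_radius_px)),
        pca_ica = extract_pca_ica(input,
                                  n_components = ceiling(1.5 * config$n_cells),
                                  mu = 0.5, seed = config$seed),
        cnmf_ring = extract_cnmf_ring(input,
          cnmf_ring_config(neuron_diameter_px = 2 * mean(config$cell_radius_px),
                           seed = config$seed))),
        error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          method = m, bandpass = bp, median_abs_corr = NA_real_,
          median_pairwise_corr = NA_real_, precision = NA_real_,
          recall = NA_real_, n_traces = 0L,
          error = conditionMessage(res))
        next
      }
      sc <- score_rejection(res, truth)
      corrs[[paste(m, bp)]] <- sc$abs_corrs
      rows[[length(rows) + 1]] <- data.frame(
        method = m, bandpass = bp,
        median_abs_corr = sc$median_abs_corr,
        median_pairwise_corr = sc$median_pairwise_corr,
        precision = sc$precision, recall = sc$recall,
        n_traces = sc$n_traces, error = NA_character_)
    }
  }
  report <- do.call(rbind, rows)
  class(report) <- c("bench_report", class(report))
  attr(report, "truth") <- truth
  pool <- function(keys) {
    v <- unlist(corrs[names(corrs) %in% keys])
    if (length(v)) median(v) else NA_real_
  }
  attr(report, "family") <- c(
    ring_nmf = pool("cnmf_ring FALSE"),
    bandpassed = pool(c("roi TRUE", "pca_ica TRUE")),
    raw = pool(c("roi FALSE", "pca_ica FALSE")))
  report
}
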