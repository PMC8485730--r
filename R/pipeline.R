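# Pipeline configuration, stage orchestration and the command-line interface.

.pipeline_schema <- list(
  seed = NULL, outdir = NULL, log_level = NULL,
  sim = c("size", "paradigm", "t_frames", "fov_px", "frame_rate_hz",
          "n_cells", "cell_radius_px", "baseline_rate_hz", "velocity_gain",
          "recruit_prob", "stim_rate_hz", "suppression_factor",
          "kernel_rise_s", "kernel_decay_s", "noise_sd",
          "contamination_amplitude", "baseline_level"),
  preprocess = c("downsample_factor_1", "downsample_factor_2",
                 "motion_correct", "max_shift_px", "dff", "bandpass",
                 "bandpass_cutoffs_px"),
  extract = c("methods", "roi_radius_px", "n_components", "mu",
              "neuron_diameter_px", "ring_diameter_px", "max_iterations"),
  bench = c("n_seeds", "methods"),
  analysis = c("velocity_edges", "threshold_mads", "refractory_frames",
               "k_mads", "dunn_adjust")
)

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file with sections `sim`, `preprocess`, `extract`, `bench`,
#' `analysis` plus global `seed`, `outdir` and `log_level`; unknown keys are
#' rejected so typos fail before any stage runs.
#'
#' @param path YAML file.
#' @param overrides named list merged over the file contents (e.g. a
#'   command-line `--seed`).
#' @return validated nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config error: top level must be a mapping")
  cfg <- modifyList(cfg, overrides)
  bad_top <- setdiff(names(cfg), names(.pipeline_schema))
  if (length(bad_top))
    stop(sprintf("config error: unknown top-level key(s): %s",
                 paste(bad_top, collapse = ", ")))
  for (sec in intersect(names(cfg), c("sim", "preprocess", "extract",
                                      "bench", "analysis"))) {
    bad <- setdiff(names(cfg[[sec]]), .pipeline_schema[[sec]])
    if (length(bad))
      stop(sprintf("config error: unknown key(s) in '%s': %s",
                   sec, paste(bad, collapse = ", ")))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$outdir)) cfg$outdir <- "stimscope_out"
  if (is.null(cfg$log_level)) cfg$log_level <- "info"
  structure(cfg, class = "pipeline_config")
}

pipe_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[stimscope] %s", sprintf(...)))
}

sim_config_from_pipeline <- function(cfg) {
  s <- cfg$sim
  if (!is.null(s$size)) {
    extra <- s[setdiff(names(s), c("size", "paradigm", "t_frames"))]
    if (!is.null(extra$recruit_prob)) extra$recruit_prob <- unlist(extra$recruit_prob)
    do.call(fixture_config, c(list(size = s$size, seed = cfg$seed), extra))
  } else {
    fields <- s[setdiff(names(s), c("paradigm", "t_frames"))]
    if (!is.null(fields$recruit_prob)) fields$recruit_prob <- unlist(fields$recruit_prob)
    do.call(sim_config, c(fields, list(seed = cfg$seed)))
  }
}

artifact <- function(cfg, name) file.path(cfg$outdir, name)

require_artifact <- function(cfg, name, producer) {
  p <- artifact(cfg, name)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s'; run the '%s' stage first", p, producer),
         call. = FALSE)
  p
}

# stamp the outdir with the seed and a hash of the generating configuration
# so artifact provenance is auditable and reruns comparable
write_manifest <- function(cfg, sc) {
  tmp <- tempfile()
  saveRDS(sc, tmp, compress = FALSE)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(list(seed = cfg$seed, config_md5 = h),
                       artifact(cfg, "manifest.json"), auto_unbox = TRUE)
}

stage_simulate <- function(cfg) {
  sc <- sim_config_from_pipeline(cfg)
  write_manifest(cfg, sc)
  size <- if (!is.null(cfg$sim$size)) cfg$sim$size else NULL
  t_frames <- if (!is.null(cfg$sim$t_frames)) cfg$sim$t_frames
              else fixture_frames(size %||% "small")
  paradigm <- cfg$sim$paradigm %||% "anesthetized"
  pipe_log(cfg, "simulate: %d frames, paradigm %s, seed %d",
           t_frames, paradigm, cfg$seed)
  if (!is.null(size)) {
    make_fixtures(size, dir = cfg$outdir, seed = cfg$seed, paradigm = paradigm)
  } else {
    truth <- simulate_session(sc, t_frames, paradigm = paradigm)
    write_movie(truth$movie, artifact(cfg, "movie.tif"))
    saveRDS(truth[setdiff(names(truth), "movie")],
            artifact(cfg, "ground_truth.rds"))
    write_behavior(truth$behavior, artifact(cfg, "behavior.csv"))
    write_schedule(truth$schedule, artifact(cfg, "schedule.csv"))
  }
  invisible(0L)
}

stage_preprocess <- function(cfg) {
  movie <- read_movie(require_artifact(cfg, "movie.tif", "simulate"))
  p <- cfg$preprocess
  f1 <- p$downsample_factor_1 %||% 1L
  f2 <- p$downsample_factor_2 %||% 1L
  if (f1 > 1) movie <- downsample_spatial(movie, f1)
  shifts <- NULL
  if (isTRUE(p$motion_correct)) {
    mc <- motion_correct_rigid(movie, max_shift_px = p$max_shift_px %||% 5)
    movie <- mc$movie
    shifts <- mc$shifts
  }
  if (f2 > 1) movie <- downsample_spatial(movie, f2)
  if (isTRUE(p$dff)) movie <- compute_dff(movie)
  if (isTRUE(p$bandpass))
    movie <- spatial_bandpass(movie,
                              unlist(p$bandpass_cutoffs_px) %||% c(5, 31))
  pipe_log(cfg, "preprocess: output %s", paste(dim(movie), collapse = " x "))
  write_movie(movie, artifact(cfg, "preprocessed.tif"))
  if (!is.null(shifts))
    write.csv(data.frame(frame = seq_len(nrow(shifts)) - 1L,
                         dy = shifts[, 1], dx = shifts[, 2]),
              artifact(cfg, "shifts.csv"), row.names = FALSE)
  invisible(0L)
}

stage_extract <- function(cfg) {
  movie <- read_movie(require_artifact(cfg, "preprocessed.tif", "preprocess"))
  movie <- movie - min(movie)    # factorization input must be nonnegative
  truth <- readRDS(require_artifact(cfg, "ground_truth.rds", "simulate"))
  e <- cfg$extract
  methods <- unlist(e$methods) %||% "cnmf_ring"
  for (m in methods) {
    pipe_log(cfg, "extract: %s", m)
    res <- switch(m,
      roi = extract_roi(movie, truth$footprints$centers,
                        radius_px = e$roi_radius_px %||% 4),
      pca_ica = extract_pca_ica(
        movie,
        n_components = e$n_components %||%
          ceiling(1.5 * nrow(truth$footprints$centers)),
        mu = e$mu %||% 0.5, seed = cfg$seed),
      cnmf_ring = extract_cnmf_ring(movie, cnmf_ring_config(
        neuron_diameter_px = e$neuron_diameter_px %||% 8,
        ring_diameter_px = e$ring_diameter_px %||%
          1.5 * (e$neuron_diameter_px %||% 8),
        max_iterations = e$max_iterations %||% 8L,
        seed = cfg$seed)),
      stop(sprintf("config error: unknown extraction method '%s'", m)))
    saveRDS(res, artifact(cfg, sprintf("extraction_%s.rds", m)))
  }
  invisible(0L)
}

stage_bench <- function(cfg) {
  sc <- sim_config_from_pipeline(cfg)
  report <- run_method_comparison(sc,
    T_frames = cfg$sim$t_frames %||%
      fixture_frames(cfg$sim$size %||% "small"))
  attr(report, "truth") <- NULL
  write_table_csv(report, artifact(cfg, "bench_report.csv"))
  jsonlite::write_json(as.data.frame(report), artifact(cfg, "bench_report.json"),
                       auto_unbox = TRUE, digits = NA)
  pipe_log(cfg, "bench: %d rows", nrow(report))
  invisible(0L)
}

stage_analyze <- function(cfg) {
  a <- cfg$analysis
  behavior <- read_behavior(require_artifact(cfg, "behavior.csv", "simulate"))
  schedule <- read_schedule(require_artifact(cfg, "schedule.csv", "simulate"))
  ex_files <- list.files(cfg$outdir, pattern = "^extraction_.*\\.rds$",
                         full.names = TRUE)
  traces <- if (length(ex_files)) {
    readRDS(ex_files[[1]])$traces
  } else {
    readRDS(require_artifact(cfg, "ground_truth.rds", "simulate"))$traces
  }
  raster <- detect_events(traces, behavior$frame_rate_hz,
                          threshold_mads = a$threshold_mads %||% 3)
  rate <- event_rate_timeseries(raster)
  edges <- unlist(a$velocity_edges) %||% default_velocity_edges()
  binned <- bin_rates_by_velocity(rate, behavior, edges = edges,
                                  frames = !stim_mask(schedule))
  rest <- tryCatch(rest_reference_rate(rate, behavior, schedule),
                   error = function(e) NA_real_)
  if (is.finite(rest) && rest > 0) binned <- normalize_to_rest(binned, rest)
  write_table_csv(binned, artifact(cfg, "binned_rates.csv"))
  counts <- count_activated_cells(traces, schedule, k_mads = a$k_mads %||% 3)
  write_table_csv(counts, artifact(cfg, "activation_counts.csv"))
  stats_out <- list()
  freqs <- unique(counts$frequency_hz)
  if (length(freqs) >= 2 && all(table(counts$frequency_hz) >= 2)) {
    groups <- split(counts$n_activated, counts$frequency_hz)
    kw <- kruskal_wallis(groups)
    stats_out <- list(kruskal_wallis = list(H = kw$H, df = kw$df,
                                            p_value = kw$p_value),
                      dunn = dunn_posthoc(groups,
                                          adjust = a$dunn_adjust %||% "holm"),
                      groups = names(groups))
  }
  jsonlite::write_json(stats_out, artifact(cfg, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  pipe_log(cfg, "analyze: rest rate %.3f events/frame", rest)
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the pipeline from the command line
#'
#' Thin argument-parsing wrapper over the pipeline stages. Subcommands:
#' `simulate`, `preprocess`, `extract`, `bench`, `analyze`, `all`. Flags:
#' `--config <yaml>` (required), `--seed <int>`, `--outdir <dir>`,
#' `--log-level <info|quiet>`.
#'
#' @param args character vector of command-line arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit status: 0 success, 2 configuration error, 3 missing
#'   upstream artifact.
#' @export
cli_run <- function(args) {
  subcommands <- c("simulate", "preprocess", "extract", "bench", "analyze", "all")
  if (length(args) < 1 || !(args[1] %in% subcommands)) {
    message("usage: stimscope <", paste(subcommands, collapse = "|"),
            "> --config <yaml> [--seed N] [--outdir DIR] [--log-level LVL]")
    return(2L)
  }
  sub <- args[1]
  args <- args[-1]
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% c("config", "seed", "outdir", "log-level") ||
        i == length(args)) {
      message(sprintf("config error: bad argument '%s'", args[i]))
      return(2L)
    }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (is.null(opt$config)) {
    message("config error: --config is required")
    return(2L)
  }
  overrides <- list()
  if (!is.null(opt$seed)) overrides$seed <- as.integer(opt$seed)
  if (!is.null(opt$outdir)) overrides$outdir <- opt$outdir
  if (!is.null(opt[["log-level"]])) overrides$log_level <- opt[["log-level"]]
  cfg <- tryCatch(pipeline_config(opt$config, overrides),
                  error = function(e) e)
  if (inherits(cfg, "error")) {
    message(conditionMessage(cfg))
    return(2L)
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (sub == "all")
    c("simulate", "preprocess", "extract", "analyze")
  else sub
  for (s in stages) {
    res <- tryCatch(switch(s,
      simulate = stage_simulate(cfg),
      preprocess = stage_preprocess(cfg),
      extract = stage_extract(cfg),
      bench = stage_bench(cfg),
      analyze = stage_analyze(cfg)),
      error = function(e) e)
    if (inherits(res, "error")) {
      message(conditionMessage(res))
      return(if (grepl("missing artifact", conditionMessage(res))) 3L
             else if (grepl("config error", conditionMessage(res))) 2L
             else 1L)
    }
  }
  0L
}
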