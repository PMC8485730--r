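# Shared in-code fixtures. Everything is generated at test time from fixed
# seeds; nothing is read from disk.

tiny_cfg <- function(seed = 1L, ...) fixture_config("tiny", seed = seed, ...)
small_cfg <- function(seed = 1L, ...) fixture_config("small", seed = seed, ...)

# short no-stimulation session used across preprocessing tests
quiet_session <- function(seed = 1L, T_frames = 30L, ...) {
  simulate_session(small_cfg(seed = seed, baseline_rate_hz = 0, ...),
                   T_frames, paradigm = "none")
}

# two-epoch compressed anesthetized schedule that fits short recordings
mini_anesthetized_schedule <- function(T_frames, frame_rate_hz = 20,
                                       freqs = c(30, 130)) {
  n <- length(freqs)
  starts <- round(seq(40, by = 80, length.out = n))
  stim_schedule_from_epochs(
    data.frame(start_frame = starts, end_frame = starts + 40L,
               frequency_hz = freqs),
    T_frames, frame_rate_hz, paradigm = "anesthetized")
}

# two overlapping somata firing in perfect synchrony under repeated
# stimulation epochs (the component-separation stress case)
synchronous_pair_session <- function(seed) {
  cfg <- sim_config(fov_px = c(48, 48), n_cells = 2, cell_radius_px = c(4, 4),
                    baseline_rate_hz = 0, noise_sd = 0.05,
                    contamination_amplitude = 0, seed = seed)
  sched <- stim_schedule_from_epochs(
    data.frame(start_frame = seq(40, by = 80, length.out = 6),
               end_frame = seq(80, by = 80, length.out = 6),
               frequency_hz = 130), 520, 20)
  truth <- simulate_session(cfg, 520, paradigm = "anesthetized",
                            centers = rbind(c(24, 22), c(28, 26)),
                            schedule = sched)
  truth$events[2, ] <- truth$events[1, ]
  truth$traces <- convolve_calcium(truth$events, cfg)
  truth$movie <- render_movie(truth, cfg)
  truth
}

# write a schedule without construction-time validation, then load it
write_then_read_schedule <- function(sched, path) {
  con <- file(path, "w")
  writeLines(c(sprintf("# paradigm: %s", sched$paradigm),
               sprintf("# frame_rate_hz: %.10g", sched$frame_rate_hz),
               sprintf("# t_frames: %d", sched$T_frames)), con)
  utils::write.csv(sched$epochs, con, row.names = FALSE)
  close(con)
  read_schedule(path)
}

# wrap bare footprints in an extraction_result (zero traces)
extraction_result_for_test <- function(footprints) {
  stimscope:::extraction_result(footprints,
                                matrix(0, dim(footprints)[3], 10), "test")
}

# naive reference implementations used as oracles -------------------------

# Kruskal-Wallis H with tie correction, coded independently of the package
naive_kruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / corr
  list(H = H, p = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# Dunn z statistics, coded independently of the package
naive_dunn <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  ties <- table(x)
  sig2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1)))
  out <- NULL
  for (i in seq_along(groups)[-length(groups)])
    for (j in (i + 1):length(groups)) {
      z <- (rbar[i] - rbar[j]) / sqrt(sig2 * (1 / n[i] + 1 / n[j]))
      out <- rbind(out, data.frame(i = i, j = j, z = as.numeric(z),
                                   p = 2 * stats::pnorm(-abs(z))))
    }
  out
}

# brute-force optimal assignment by permutation enumeration (small n)
brute_force_match <- function(S, min_sim = 0.5) {
  nf <- nrow(S); nt <- ncol(S)
  n <- max(nf, nt)
  Sq <- matrix(0, n, n)
  Sq[seq_len(nf), seq_len(nt)] <- S
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -Inf; best_p <- NULL
  for (p in perms(seq_len(n))) {
    s <- sum(Sq[cbind(seq_len(n), p)])
    if (s > best) { best <- s; best_p <- p }
  }
  pairs <- data.frame(found = seq_len(n), truth = best_p)
  pairs <- pairs[pairs$found <= nf & pairs$truth <= nt, ]
  pairs$sim <- S[cbind(pairs$found, pairs$truth)]
  pairs[pairs$sim >= min_sim, ]
}
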