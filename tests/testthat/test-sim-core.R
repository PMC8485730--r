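test_that("footprint generation respects count, normalization and support", {
  cfg <- sim_config(n_cells = 0, fov_px = c(32, 32), seed = 1)
  fp0 <- generate_footprints(cfg)
  expect_equal(dim(fp0$footprints), c(32, 32, 0))
  expect_equal(nrow(fp0$centers), 0)

  cfg1 <- sim_config(n_cells = 1, fov_px = c(32, 32), cell_radius_px = c(3, 3),
                     seed = 7)
  fp1 <- generate_footprints(cfg1)
  blob <- fp1$footprints[, , 1]
  expect_equal(max(blob), 1)
  on_rows <- range(which(rowSums(blob) > 0))
  on_cols <- range(which(colSums(blob) > 0))
  expect_lte(diff(on_rows) + 1, 12)
  expect_lte(diff(on_cols) + 1, 12)

  cfgn <- sim_config(n_cells = 10, fov_px = c(64, 64), seed = 3)
  expect_identical(generate_footprints(cfgn), generate_footprints(cfgn))
  # centers honor the minimum spacing
  fpn <- generate_footprints(cfgn)
  dmat <- as.matrix(dist(fpn$centers))
  expect_gte(min(dmat[upper.tri(dmat)]), cfgn$cell_radius_px[2])
})

test_that("footprint placement fails gracefully when the FOV is too crowded", {
  cfg <- sim_config(n_cells = 200, fov_px = c(20, 20), seed = 1)
  expect_error(generate_footprints(cfg), "place")
})

test_that("velocity trace is nonnegative, deterministic, and mixes rest with movement", {
  cfg <- sim_config(seed = 11)
  b1 <- generate_velocity_trace(1, cfg)
  expect_length(b1$velocity_cmps, 1)
  expect_gte(b1$velocity_cmps, 0)

  b <- generate_velocity_trace(20000, cfg)
  expect_true(all(b$velocity_cmps >= 0))
  rest_frac <- mean(b$velocity_cmps < 0.5)
  expect_gt(rest_frac, 0.2)
  expect_lt(rest_frac, 0.8)
  expect_gt(mean(b$velocity_cmps > 2), 0.2)
  expect_identical(b, generate_velocity_trace(20000, cfg))

  const <- generate_velocity_trace(50, cfg, sd_cmps = 0)
  expect_equal(unique(const$velocity_cmps), 1.5)
})

test_that("anesthetized schedule lays out 9 epochs of 10 s in 1-min intervals", {
  T_frames <- 20 * (9 * 70 + 10)
  sched <- build_stim_schedule("anesthetized", T_frames, 20)
  expect_equal(nrow(sched$epochs), 9)
  expect_true(all(sched$epochs$end_frame - sched$epochs$start_frame == 200))
  expect_equal(sched$epochs$frequency_hz, rep(c(30, 80, 130), 3))
  expect_equal(unique(sched$epochs$pulse_width_us), 140)
  gaps <- sched$epochs$start_frame[-1] - sched$epochs$end_frame[-9]
  expect_true(all(gaps == 60 * 20))
})

test_that("awake schedule alternates 10-min OFF/ON blocks at 30 then 130 Hz", {
  fr <- 20
  sched <- build_stim_schedule("awake", 3000 * fr, fr)
  expect_equal(sched$epochs$frequency_hz, c(30, 130))
  expect_equal(sched$epochs$start_frame, c(600, 1800) * fr)
  expect_equal(unique(sched$epochs$pulse_width_us), 200)
  expect_equal(unique(sched$epochs$amplitude_ua), 30)
  # sorted and non-overlapping is enforced on construction
  e <- sched$epochs
  expect_true(all(e$start_frame[-1] >= e$end_frame[-nrow(e)]))
})

test_that("too-short recordings are rejected with the minimum length", {
  expect_error(build_stim_schedule("anesthetized", 100, 20), "need >= ")
  expect_error(build_stim_schedule("awake", 1000, 20), "need >= ")
})

test_that("spike trains follow the paradigm rate laws", {
  cfg <- sim_config(n_cells = 8, fov_px = c(32, 32), baseline_rate_hz = 0,
                    seed = 5)
  fp <- generate_footprints(cfg)
  beh <- generate_velocity_trace(400, cfg)
  sched <- empty_sched <- stimscope:::empty_schedule(400, 20)
  raster <- generate_spike_trains(beh, sched, fp, cfg)
  expect_true(all(raster$events == 0))

  # awake rate law: more events during fast locomotion
  cfga <- sim_config(n_cells = 60, fov_px = c(128, 128), baseline_rate_hz = 1,
                     velocity_gain = 0.5, seed = 6)
  fpa <- generate_footprints(cfga)
  beha <- generate_velocity_trace(12000, cfga)
  scha <- stimscope:::empty_schedule(12000, 20)
  ra <- generate_spike_trains(beha, scha, fpa, cfga)
  rate <- colSums(ra$events)
  fast <- beha$velocity_cmps > 2
  rest <- beha$velocity_cmps < 0.5
  expect_gt(mean(rate[fast]), mean(rate[rest]))

  # mismatched lengths error
  expect_error(generate_spike_trains(beh, scha, fpa, cfga), "length")
})

test_that("anesthetized recruitment is frequency-dependent on average", {
  probs <- c("30" = 0.1, "80" = 0.4, "130" = 0.5)
  mean_counts <- c("30" = 0, "80" = 0, "130" = 0)
  for (s in 1:6) {
    cfg <- sim_config(n_cells = 50, fov_px = c(128, 128),
                      baseline_rate_hz = 0, recruit_prob = probs, seed = s)
    fp <- generate_footprints(cfg)
    T_frames <- 20 * (9 * 70 + 10)
    sched <- build_stim_schedule("anesthetized", T_frames, 20)
    beh <- generate_velocity_trace(T_frames, cfg)
    ra <- generate_spike_trains(beh, sched, fp, cfg)
    n_rec <- colSums(ra$recruited)
    for (f in names(probs))
      mean_counts[f] <- mean_counts[f] +
        mean(n_rec[sched$epochs$frequency_hz == as.numeric(f)])
  }
  mean_counts <- mean_counts / 6
  expect_lt(mean_counts["30"], mean_counts["80"])
  expect_lt(mean_counts["30"], mean_counts["130"])
  # 80 and 130 Hz are comparable (binomial means 20 vs 25 of 50)
  expect_lt(abs(mean_counts["80"] - mean_counts["130"]), 10)
})

test_that("calcium convolution is causal, normalized and linear", {
  cfg <- sim_config(seed = 1)
  z <- matrix(0L, 2, 100)
  expect_true(all(convolve_calcium(z, cfg) == 0))

  k <- calcium_kernel(cfg$frame_rate_hz, cfg$kernel_rise_s, cfg$kernel_decay_s)
  T_len <- length(k) + 60L
  one <- matrix(0L, 1, T_len); one[1, 1] <- 1L
  tr <- convolve_calcium(one, cfg)
  expect_equal(max(tr), 1, tolerance = 1e-12)
  expect_equal(tr[1, seq_along(k)], k, tolerance = 1e-8)

  two <- matrix(0L, 1, T_len); two[1, c(10, 25)] <- 1L
  manual <- numeric(T_len + length(k))
  manual[10 + seq_along(k) - 1] <- k
  manual[25 + seq_along(k) - 1] <- manual[25 + seq_along(k) - 1] + k
  expect_equal(convolve_calcium(two, cfg)[1, ], manual[seq_len(T_len)],
               tolerance = 1e-8)
})

test_that("contamination is low-spatial-frequency and stimulation-locked", {
  cfg <- sim_config(fov_px = c(64, 64), contamination_amplitude = 1.5, seed = 9)
  sched0 <- stimscope:::empty_schedule(500, 20)
  c0 <- generate_contamination(sched0, cfg)
  expect_true(all(c0$temporal == 0))
  expect_equal(max(c0$spatial), 1)
  expect_true(all(c0$spatial >= 0))

  sched <- mini_anesthetized_schedule(400)
  cc <- generate_contamination(sched, cfg)
  expect_equal(max(cc$temporal), 1.5)
  e1 <- sched$epochs[1, ]
  expect_equal(sum(cc$temporal[1:e1$start_frame]), 0)     # silent before onset
  expect_gt(cc$temporal[e1$end_frame], 0)                 # active during epoch
  # decays after offset
  expect_lt(cc$temporal[e1$end_frame + 30], max(cc$temporal[1:e1$end_frame]))

  # spectral check: dominant spatial frequency below the cell-scale cutoff
  sp <- cc$spatial - mean(cc$spatial)
  P <- Mod(fft(sp))^2
  freqs_cyc <- outer(c(0:32, -31:-1) / 64, c(0:32, -31:-1) / 64,
                     function(a, b) sqrt(a^2 + b^2))
  dominant <- freqs_cyc[which.max(P)]
  expect_lt(dominant, 1 / 31)
})

test_that("movie rendering conserves its components exactly at zero noise", {
  cfg <- small_cfg(seed = 4, noise_sd = 0)
  truth <- simulate_session(cfg, 200, paradigm = "none")
  HW <- prod(cfg$fov_px)
  recon <- matrix(truth$baseline_image, HW, 200) +
    stimscope:::flatten_footprints(truth$footprints$footprints) %*% truth$traces +
    as.vector(truth$contamination_spatial) %o% truth$contamination_temporal
  err <- max(abs(recon - matrix(truth$movie, HW, 200))) / max(truth$movie)
  expect_lt(err, 1e-10)
})

test_that("rendered noise matches the configured standard deviation", {
  cfg <- small_cfg(seed = 8, noise_sd = 0.07, baseline_rate_hz = 0,
                   contamination_amplitude = 0)
  truth <- simulate_session(cfg, 500, paradigm = "none")
  resid <- matrix(truth$movie, prod(cfg$fov_px), 500) -
    matrix(truth$baseline_image, prod(cfg$fov_px), 500)
  expect_equal(sd(resid), 0.07, tolerance = 0.05 * 0.07)
})

test_that("simulation is bit-identical under the same seed and differs across seeds", {
  cfg <- tiny_cfg(seed = 42)
  t1 <- simulate_session(cfg, 100, paradigm = "none")
  t2 <- simulate_session(cfg, 100, paradigm = "none")
  expect_identical(t1$movie, t2$movie)
  expect_identical(t1$events, t2$events)
  t3 <- simulate_session(tiny_cfg(seed = 43), 100, paradigm = "none")
  expect_false(identical(t1$movie, t3$movie))
})

test_that("anesthetized sessions are quiescent without stimulation", {
  cfg <- small_cfg(seed = 2, baseline_rate_hz = 0)
  sched <- stimscope:::empty_schedule(600, 20)
  sched$paradigm <- "anesthetized"
  truth <- simulate_session(cfg, 600, paradigm = "anesthetized",
                            schedule = sched)
  expect_equal(sum(truth$events), 0)
})
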