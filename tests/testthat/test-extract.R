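test_that("ROI extraction averages disks and cannot reject global signals", {
  truth <- quiet_session(seed = 3, T_frames = 60, baseline_rate_hz = 0.5)
  res <- extract_roi(truth$movie, truth$footprints$centers, radius_px = 4)
  expect_equal(nrow(res$traces), 15)
  expect_true(all(res$footprints %in% c(0, 1)))

  # seed at a blob center recovers its trace (no contamination present)
  m <- match_components(res, truth)
  active <- m$pairs[!is.na(m$pairs$trace_corr), ]
  expect_true(all(active$trace_corr[
    vapply(active$truth, function(i) sd(truth$traces[i, ]) > 0, logical(1))] > 0.9))

  # a uniform global flash leaks into every ROI trace
  flash <- sin(seq(0, 4 * pi, length.out = 60))^2
  contaminated <- inject_contamination(truth$movie,
                                       matrix(1, 64, 64), flash)
  res2 <- extract_roi(contaminated, truth$footprints$centers, radius_px = 4)
  cors <- apply(res2$traces, 1, function(x) cor(x, flash))
  expect_true(all(cors > 0.9))

  expect_true(all(extract_roi(array(0, c(16, 16, 5)),
                              cbind(8, 8))$traces == 0))
  expect_error(extract_roi(truth$movie, cbind(200, 8)), "outside")
})

test_that("PCA/ICA separates asynchronous cells but is deterministic given a seed", {
  cfg <- sim_config(fov_px = c(48, 48), n_cells = 2, cell_radius_px = c(4, 4),
                    baseline_rate_hz = 0, noise_sd = 0.03,
                    contamination_amplitude = 0, seed = 2)
  truth <- simulate_session(cfg, 600, paradigm = "none",
                            centers = rbind(c(14, 14), c(34, 34)))
  # hand-built asynchronous alternating event trains
  truth$events[] <- 0L
  truth$events[1, seq(20, 580, by = 80)] <- 1L
  truth$events[2, seq(60, 580, by = 80)] <- 1L
  truth$traces <- convolve_calcium(truth$events, cfg)
  truth$movie <- render_movie(truth, cfg)

  res <- extract_pca_ica(truth$movie, n_components = 2, mu = 0.5, seed = 5)
  m <- match_components(res, truth)
  expect_equal(nrow(m$pairs), 2)
  expect_true(all(m$pairs$cosine >= 0.8))

  res2 <- extract_pca_ica(truth$movie, n_components = 2, mu = 0.5, seed = 5)
  expect_identical(res$footprints, res2$footprints)
  expect_identical(res$traces, res2$traces)
})

test_that("ring-background CNMF recovers clean cells with a monotone objective", {
  cfg <- small_cfg(seed = 2)
  truth <- simulate_session(cfg, 1000, paradigm = "none")
  res <- extract_cnmf_ring(truth$movie,
                           cnmf_ring_config(neuron_diameter_px = 8, seed = 2))
  expect_true(all(diff(res$diagnostics$objective) <= 1e-8))
  expect_true(all(res$footprints >= 0))
  expect_true(all(res$traces >= 0))
  m <- match_components(res, truth)
  expect_gte(m$recall, 0.9)
  expect_gte(median(m$pairs$cosine), 0.8)
  expect_gte(median(m$pairs$trace_corr), 0.9)
})

test_that("CNMF on an empty movie returns an empty result", {
  res <- extract_cnmf_ring(array(0, c(32, 32, 80)),
                           cnmf_ring_config(neuron_diameter_px = 6))
  expect_equal(nrow(res$traces), 0)
  bad <- array(1, c(32, 32, 10)); bad[1, 1, 1] <- NA
  expect_error(extract_cnmf_ring(bad, cnmf_ring_config()), "finite")
})

test_that("component matching is optimal, permutation invariant, and thresholded", {
  cfg <- tiny_cfg(seed = 9)
  truth <- simulate_session(cfg, 50, paradigm = "none")
  fp <- truth$footprints$footprints
  self <- extraction_result_for_test(fp)
  m <- match_components(self, truth$footprints)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(m$pairs$truth[order(m$pairs$found)], 1:3)

  perm <- extraction_result_for_test(fp[, , c(3, 1, 2)])
  mp <- match_components(perm, truth$footprints)
  expect_equal(mp$pairs$truth[order(mp$pairs$found)], c(3, 1, 2))

  # 3 found vs 2 true with one spurious: recall 1, precision 2/3
  spurious <- fp[, , c(1, 2, 1)]
  spurious[, , 3] <- 0
  spurious[2:5, 2:5, 3] <- 1   # corner blob unlike any truth
  truth2 <- truth$footprints
  truth2$footprints <- fp[, , 1:2]
  ms <- match_components(extraction_result_for_test(spurious), truth2)
  expect_equal(ms$recall, 1)
  expect_equal(ms$precision, 2 / 3)
})

test_that("hungarian assignment agrees with brute force on random problems", {
  set.seed(31)
  for (r in 1:20) {
    nf <- sample(2:5, 1); nt <- sample(2:5, 1)
    S <- matrix(runif(nf * nt), nf, nt)
    bf <- brute_force_match(S, min_sim = 0)
    n <- max(nf, nt)
    cost <- matrix(0, n, n)
    cost[seq_len(nf), seq_len(nt)] <- -S
    hung <- stimscope:::hungarian_assign(cost)
    total_h <- sum(vapply(seq_len(nf), function(i) {
      j <- hung[i]
      if (j <= nt) S[i, j] else 0
    }, numeric(1)))
    expect_equal(total_h, sum(bf$sim), tolerance = 1e-12)
  }
})

test_that("nnls solutions are nonnegative and match the unconstrained fit when feasible", {
  set.seed(8)
  for (r in 1:20) {
    A <- matrix(runif(40 * 5), 40, 5)
    x_true <- runif(5)
    b <- A %*% x_true
    x <- stimscope:::nnls_solve(A, b)
    expect_true(all(x >= 0))
    expect_equal(as.numeric(x), as.numeric(x_true), tolerance = 1e-6)
    # with a negative-leaning target the solution stays feasible and optimal
    b2 <- A %*% c(-1, runif(4))
    x2 <- stimscope:::nnls_solve(A, b2)
    expect_true(all(x2 >= -1e-12))
    # KKT: gradient nonpositive on the zero set, ~0 on the active set
    g <- crossprod(A, b2 - A %*% x2)
    expect_true(all(g[x2 <= 1e-10] <= 1e-6))
    expect_true(all(abs(g[x2 > 1e-10]) <= 1e-6))
  }
})

test_that("randomized SVD matches base svd on small matrices", {
  set.seed(4)
  X <- matrix(rnorm(60 * 40), 60, 40) %*% diag(c(10, 5, rep(0.1, 38)))
  rs <- stimscope:::randomized_svd(X, 5, seed = 1)
  bs <- svd(X, nu = 5, nv = 5)
  # the separated leading values are exact; the noise-floor tail is not
  expect_equal(rs$d[1:2], bs$d[1:2], tolerance = 1e-8)
  for (j in 1:2)   # leading subspace agreement up to sign
    expect_gt(abs(sum(rs$u[, j] * bs$u[, j])), 1 - 1e-8)
})
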