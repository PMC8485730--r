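# stimscope

Simulation and analysis of miniscope calcium imaging during deep brain
stimulation.

## What problem this addresses

Head-mounted single-photon microendoscopes (miniscopes) make it possible to
record GCaMP calcium signals from dozens of striatal neurons in freely moving
parkinsonian mice while the subthalamic nucleus receives deep-brain-stimulation
(DBS) trains. Analyzing such recordings is hard for a specific physical
reason: electrical stimulation recruits cells synchronously and evokes broad
out-of-focus fluorescence from cells outside the focal plane, and this
low-spatial-frequency background leaks into naive trace extraction. stimscope
is for computational neuroscientists and methods developers who want a fully
controlled, ground-truth testbed for this setting: it generates synthetic
sessions (movie, behavior, stimulation schedule, contamination — with every
latent variable known), implements the standard preprocessing chain and three
neural-signal identification methods, and reproduces the downstream event
statistics used to characterize stimulation-evoked striatal activity.

## The models at its core

**Generative model.** Each movie frame is
`F(x,t) = b(x) + Σ_i a_i(x) c_i(t) + s(x) g(t) + ε(x,t)`: a static structured
background `b`, Gaussian somatic footprints `a_i` with traces `c_i` (Poisson
events convolved with a double-exponential GCaMP6m kernel, unit transient
peak), a rank-1 stimulation-locked contamination term `s(x) g(t)` (broad
Gaussians × kernel-smoothed epoch indicator), and i.i.d. Gaussian noise.
Firing follows `λ_i(t) = λ0 (1 + β v(t))` with locomotor velocity `v`
(rectified Ornstein–Uhlenbeck); under anesthetized stimulation, cells are
recruited per epoch with frequency-dependent probability; under awake
stimulation the ongoing rate is multiplied by a suppression factor.

**Extraction.** Seeded-ROI disk averaging; PCA/ICA with spatiotemporal
de-mixing (randomized truncated SVD + fixed-point ICA, 3-SD thresholded
maps); and a simplified constrained NMF `Y ≈ A C + b0 + B` whose background
`B` follows the ring model — each pixel's background is a learned nonnegative
combination of the cell-free residual on a surrounding ring (diameter 1.5×
the neuron diameter), fitted by nonnegative least squares with a monotone
objective.

**Statistics.** Per-frame population calcium event rates, velocity-binned
(rest = `[0, 0.5)` cm/s, half-open bins) and normalized to the animal's
unstimulated rest rate; activated-cell counts per stimulation epoch
(mean-over-epoch > pre-epoch baseline + 3 MAD); Kruskal–Wallis with Dunn's
tie-corrected post-hoc tests.

## Worked example

```r
library(stimscope)

cfg <- fixture_config("small", seed = 1)     # 64x64 px, 15 cells, 20 fps
truth <- simulate_session(cfg, 2000, paradigm = "none")
res <- extract_cnmf_ring(truth$movie,
                         cnmf_ring_config(neuron_diameter_px = 8, seed = 1))
m <- match_components(res, truth)
cat(sprintf("recall %.2f, precision %.2f, median footprint cosine %.3f\n",
            m$recall, m$precision, median(m$pairs$cosine)))
#> recall 1.00, precision 0.88, median footprint cosine 1.000
```

All 15 simulated somata are recovered (recall 1.00) with footprints
essentially identical to ground truth (median cosine 1.000); precision 0.88
means two extra low-amplitude components survived the quality filter.
Downstream, the same session's event raster yields the velocity-rate
relationship:

```r
rate <- event_rate_timeseries(truth$events)
nb <- normalize_to_rest(bin_rates_by_velocity(rate, truth$behavior),
                        rest_reference_rate(rate, truth$behavior))
nb[1:3, c("bin_low", "bin_high", "normalized_rate", "n_frames")]
#>   bin_low bin_high normalized_rate n_frames
#> 1     0.0      0.5        1.000000      478
#> 2     0.5      1.0        1.378846      200
#> 3     1.0      1.5        1.816769      226
```

The rest bin is exactly 1 by construction and the normalized rate rises with
velocity (the simulated rate law is `1 + 0.5 v`; at this short session length
the per-bin means are still noisy — the acceptance script recovers the slope
within a few percent on a 50-minute raster).

A YAML-driven command line covers the full pipeline
(`simulate | preprocess | extract | bench | analyze | all`):

```sh
Rscript inst/scripts/stimscope.R all --config config.yaml --seed 1
```

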