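test_that("the transform chain is zero on zero input and nonnegative", {
  out <- pt_transform(rep(0, 200), fs = 100, fmin = 0, fmax = 20, ninte = 0.1)
  expect_equal(out, rep(0, 200))
  set.seed(30)
  out2 <- pt_transform(rnorm(300), fs = 100, fmin = 0.5, fmax = 20, ninte = 0.1)
  expect_equal(length(out2), 300)
  expect_true(all(out2 >= 0))
})

test_that("a pure in-band sinusoid squares to twice the frequency", {
  fs <- 100
  t <- seq_len(1000) / fs
  v <- sin(2 * pi * 2 * t)
  # derivative of sin(2 pi f t) is 2 pi f cos(...): squaring doubles the
  # frequency and a short integrator leaves the envelope nearly flat
  out <- pt_transform(v, fs, fmin = 0.5, fmax = 20, ninte = 0.04)
  mid <- out[200:800]
  # dominant oscillation at 4 Hz: autocorrelation peaks every fs/4 = 25 samples
  osc <- mid - mean(mid)
  lag25 <- stats::cor(osc[-(1:25)], osc[seq_len(length(osc) - 25)])
  expect_gt(lag25, 0.9)
  # envelope flatness: windowed maxima vary by < 10%
  env <- vapply(split(mid, (seq_along(mid) - 1) %/% 100), max, numeric(1))
  expect_lt((max(env) - min(env)) / max(env), 0.1)
})

test_that("out-of-band energy is strongly attenuated", {
  fs <- 100
  t <- seq_len(1000) / fs
  in_band <- pt_transform(sin(2 * pi * 5 * t), fs, 0, 20, 0.1)
  out_band <- pt_transform(sin(2 * pi * 40 * t), fs, 0, 20, 0.1)
  expect_lt(mean(out_band) / mean(in_band), 0.01)
})

test_that("transform rejects invalid corner frequencies", {
  expect_error(pt_transform(rnorm(100), 100, 0, 50, 0.1), "Nyquist")
  expect_error(pt_transform(rnorm(100), 100, 10, 5, 0.1), "fmin")
  expect_error(pt_config(fmax = 0, fmin = 0), "fmin")
  expect_error(pt_config(ninte = 0), "ninte")
})

test_that("peak search returns strict local maxima only", {
  expect_equal(pt_peak_search(c(0, 1, 0, 2, 0)), c(1L, 3L))
  expect_equal(pt_peak_search(seq(0, 1, length.out = 50)), integer())
  expect_equal(pt_peak_search(c(1, 1, 1)), integer())
  expect_equal(pt_peak_search(c(0, 1)), integer())
})

test_that("a multi-step recording yields at least one raw peak per step", {
  lib <- make_library(3, seed = 31)
  sim <- simulate_recording(sim_config(n_steps = 5, seed = 32), lib)
  tr <- pt_transform(sim$recording$samples[2, ], 100, 0, 6, 0.08)
  peaks <- pt_peak_search(tr)
  expect_gte(length(peaks), 5)
  ann <- sim$annotations
  hits <- vapply(seq_len(nrow(ann)), function(j)
    any(peaks >= ann$start[j] & peaks < ann$end[j]), logical(1))
  expect_true(all(hits))
})

test_that("the activity gate keeps only high-activity neighbourhoods", {
  v <- c(rep(0, 100), sin(seq_len(100) / 3), rep(0, 100))
  peaks <- c(50L, 150L, 250L)
  kept <- pt_activity_gate(peaks, v, neigh = 10, noise_level = 0.1)
  expect_equal(kept, 150L)
  # noise_level = 0 is the identity
  expect_equal(pt_activity_gate(peaks, v, 10, 0), peaks)
})

test_that("gate levels between rest and step activity separate the peaks", {
  lib <- make_library(3, seed = 33)
  sim <- simulate_recording(sim_config(n_steps = 5, seed = 34), lib)
  v <- sim$recording$samples[2, ]
  tr <- pt_transform(v, 100, 0, 6, 0.08)
  peaks <- pt_peak_search(tr)
  kept <- pt_activity_gate(peaks, v, neigh = 5, noise_level = 0.4)
  ann <- sim$annotations
  inside <- vapply(kept, function(p)
    any(ann$start <= p & p < ann$end), logical(1))
  expect_true(all(inside))
  expect_gte(length(kept), 5)
})

test_that("grid search is exhaustive with first-in-grid tie-breaking", {
  lib <- make_library(3, seed = 35)
  sims <- lapply(1:2, function(i)
    simulate_recording(sim_config(n_steps = 8, seed = 40 + i), lib))
  recs <- lapply(sims, `[[`, "recording")
  anns <- lapply(sims, `[[`, "annotations")

  # single-point grids return that configuration
  g1 <- list(fmin = 0, fmax = 6, ninte = 0.08, neigh = 3, noise_level = 0.4)
  gs1 <- pt_grid_search(recs, anns, grids = g1)
  expect_equal(gs1$best_config$fmax, 6)
  expect_equal(nrow(gs1$table), 1)

  # a config that detects nothing loses to one that works
  g2 <- list(fmin = 0, fmax = 6, ninte = 0.08, neigh = 3,
             noise_level = c(1e6, 0.4))
  gs2 <- pt_grid_search(recs, anns, grids = g2)
  expect_equal(gs2$best_config$noise_level, 0.4)

  # the reported best is never below any evaluated configuration
  g3 <- list(fmin = 0, fmax = c(6, 12), ninte = c(0.08, 0.3), neigh = 3,
             noise_level = c(0.2, 0.4))
  gs3 <- pt_grid_search(recs, anns, grids = g3)
  expect_equal(gs3$best_f, max(gs3$table$f_measure))

  expect_error(pt_grid_search(recs, anns, grids = list(fmin = 0)), "empty grid")
})

test_that("pt_detect composes the chain and respects the peak mode", {
  lib <- make_library(3, seed = 36)
  sim <- simulate_recording(sim_config(n_steps = 6, seed = 37), lib)
  cfg <- pt_config(0, 6, 0.08, neigh = 3, noise_level = 0.4)
  det <- pt_detect(sim$recording, cfg)
  expect_s3_class(det, "pt_detection")
  expect_true(all(det$peaks >= 0 & det$peaks < n_samples(sim$recording)))
  expect_output(print(det), "pt_detection")

  # every-other mode selects the 2nd, 4th, ... raw local maxima
  tr <- pt_transform(sim$recording$samples[2, ], 100, 0, 20, 0.1)
  raw <- pt_peak_search(tr)
  leg <- pt_detect(sim$recording, pt_preset_ying(), peak_mode = "every_other")
  expect_true(all(leg$peaks %in% raw[seq(2, length(raw), by = 2)]))
})
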