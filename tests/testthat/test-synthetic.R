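test_that("template and library generation are deterministic in the seed", {
  l1 <- make_library(5, seed = 50)
  l2 <- make_library(5, seed = 50)
  for (i in 1:5) expect_identical(l1[[i]]$samples, l2[[i]]$samples)
  l3 <- make_library(5, seed = 51)
  expect_false(identical(l1[[1]]$samples, l3[[1]]$samples))
})

test_that("generated templates satisfy the template invariants", {
  tpl <- make_template(80)
  expect_s3_class(tpl, "step_template")
  expect_equal(n_samples(tpl), 80)
  expect_true(all(tpl$sd > 0))
  expect_equal(unname(apply(tpl$samples, 1, function(v) sqrt(mean((v - mean(v))^2)))),
               rep(1, 3), tolerance = 1e-12)
  expect_error(make_template(1), "np")
  expect_error(make_template(500), "np")
})

test_that("library durations are uniform over the requested range", {
  lib <- make_library(10, duration_range = c(65, 96), seed = 52)
  lens <- template_lengths(lib)
  expect_true(all(lens >= 65 & lens <= 96))

  big <- make_library(1000, duration_range = c(65, 96), seed = 53)
  lens <- template_lengths(big)
  counts <- table(factor(lens, levels = 65:96))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("resampling is exact on its fixed points and affine signals", {
  tpl <- make_template(80, label = "orig")
  expect_equal(resample_template(tpl, 80)$samples, tpl$samples, tolerance = 1e-12)

  ramp <- step_template(rbind(seq(0, 1, length.out = 40),
                              seq(5, -3, length.out = 40),
                              seq(-1, 1, length.out = 40)))
  for (len in c(25, 40, 77)) {
    r <- resample_template(ramp, len)
    expect_equal(unname(r$samples[1, ]), seq(0, 1, length.out = len), tolerance = 1e-12)
    expect_equal(unname(r$samples[2, ]), seq(5, -3, length.out = len), tolerance = 1e-12)
  }

  # round trip Np -> 2 Np -> Np on a smooth template: <= 1% RMS error
  up <- resample_template(tpl, 160)
  back <- resample_template(up, 80)
  rms <- sqrt(mean((back$samples - tpl$samples)^2))
  expect_lt(rms / sqrt(mean(tpl$samples^2)), 0.01)
})

test_that("noise-free unit-gain plants correlate exactly at their lags", {
  lib <- make_library(3, seed = 54)
  cfg <- sim_config(n_steps = 6, noise_sigma = 0, gain_range = c(1, 1),
                    dc_offset_range = c(0, 0), seed = 55)
  sim <- simulate_recording(cfg, lib)
  ann <- sim$annotations
  for (i in seq_len(nrow(ann))) {
    p_idx <- sim$truth$template_index[i]
    tpl <- lib[[p_idx]]
    for (k in 1:3) {
      tr <- sliding_correlation(sim$recording$samples[k, ], tpl$samples[k, ])
      expect_equal(tr$values[ann$start[i] + 1], 1, tolerance = 1e-9)
    }
  }
})

test_that("simulated recordings are reproducible and internally consistent", {
  lib <- make_library(4, seed = 56)
  cfg <- sim_config(n_steps = 12, seed = 57)
  s1 <- simulate_recording(cfg, lib)
  s2 <- simulate_recording(cfg, lib)
  expect_identical(s1$recording$samples, s2$recording$samples)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$truth, s2$truth)

  ann <- s1$annotations
  expect_true(all(ann$start >= 0 & ann$end <= n_samples(s1$recording)))
  expect_true(all(diff(ann$start) > 0))
  o <- order(ann$start)
  expect_true(all(ann$start[o][-1] >= ann$end[o][-nrow(ann)]))

  # leading rest: noise only, so its std is close to noise_sigma
  for (k in 1:3) {
    rest <- s1$recording$samples[k, 1:100]
    expect_lt(abs(sqrt(mean((rest - mean(rest))^2)) - 0.05) / 0.05, 0.2)
  }
})

test_that("low-amplitude steps are labelled uturn with sub-gate gains", {
  lib <- make_library(3, seed = 58)
  cfg <- sim_config(n_steps = 40, lowamp_fraction = 0.3, seed = 59)
  sim <- simulate_recording(cfg, lib)
  low <- sim$truth$lowamp
  expect_true(any(low) && any(!low))
  expect_true(all(sim$annotations$step_type[low] == "uturn"))
  expect_true(all(sim$annotations$step_type[!low] == "normal"))
  expect_true(all(sim$truth$gain[low] < 0.1))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_steps = 0), "n_steps")
  expect_error(sim_config(noise_sigma = -1), "noise_sigma")
  lib <- make_library(2, seed = 60)
  expect_error(
    simulate_recording(sim_config(n_steps = 100, max_samples = 500, seed = 1), lib),
    "exceeds the cap")
})

test_that("resampled plants stay within the configured duration range", {
  lib <- make_library(3, duration_range = c(65, 96), seed = 61)
  cfg <- sim_config(n_steps = 15, resample_steps = TRUE,
                    duration_range = c(70, 80), seed = 62)
  sim <- simulate_recording(cfg, lib)
  dur <- sim$annotations$end - sim$annotations$start
  expect_true(all(dur >= 70 & dur <= 80))
})
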