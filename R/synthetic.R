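# Uniform integer draw on [lo, hi] that is safe when lo == hi (base
# sample() would interpret a scalar as 1:n).
sample_range <- function(lo, hi, n = 1) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards, so simulation results depend only on the
# seed argument.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic-recording configuration
#'
#' Conditions of the simulated walking protocol: a leading rest, a sequence
#' of steps separated by foot-flat rests, and a trailing rest. Defaults
#' mirror the experimental conditions the detector assumes: 100 Hz
#' sampling, step durations uniform over 65-96 samples, foot-flat rests of
#' 30-60 samples, white sensor noise at 5% of the (unit) template
#' amplitude, per-step gain variation of +/- 20%, and per-component DC
#' offsets emulating sensor-orientation bias.
#'
#' @param fs sampling rate in Hz.
#' @param n_steps number of steps (>= 1).
#' @param duration_range \code{c(min, max)} step duration in samples; steps
#'   are resampled to a random length in this range only when
#'   \code{resample_steps = TRUE} (by default each step keeps its
#'   template's native duration).
#' @param rest_range \code{c(min, max)} inter-step rest length in samples.
#' @param edge_rest leading and trailing rest length in samples.
#' @param noise_sigma additive white Gaussian noise level, as a fraction of
#'   the per-component template standard deviation.
#' @param gain_range per-step amplitude multiplier range.
#' @param dc_offset_range per-component constant offset range.
#' @param lowamp_fraction fraction of steps scaled to a small amplitude
#'   (turning-step-like, labelled \code{uturn}); their gain is drawn from
#'   \code{lowamp_gain_range}.
#' @param lowamp_gain_range gain range for low-amplitude steps (below the
#'   default amplitude gate \eqn{\mu} = 0.1).
#' @param resample_steps if TRUE, each planted step is linearly resampled
#'   to a target duration drawn from \code{duration_range}.
#' @param max_samples cap on the total recording length.
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(fs = 100, n_steps = 30, duration_range = c(65, 96),
                       rest_range = c(30, 60), edge_rest = 100,
                       noise_sigma = 0.05, gain_range = c(0.8, 1.2),
                       dc_offset_range = c(-0.5, 0.5),
                       lowamp_fraction = 0, lowamp_gain_range = c(0.02, 0.08),
                       resample_steps = FALSE,
                       max_samples = 500000, seed = 1) {
  stopifnot(fs > 0, n_steps >= 1, noise_sigma >= 0,
            length(duration_range) == 2, diff(duration_range) >= 0,
            length(rest_range) == 2, diff(rest_range) >= 0,
            length(gain_range) == 2, diff(gain_range) >= 0,
            lowamp_fraction >= 0, lowamp_fraction <= 1, edge_rest >= 0)
  structure(list(fs = fs, n_steps = as.integer(n_steps),
                 duration_range = as.integer(duration_range),
                 rest_range = as.integer(rest_range),
                 edge_rest = as.integer(edge_rest),
                 noise_sigma = noise_sigma, gain_range = gain_range,
                 dc_offset_range = dc_offset_range,
                 lowamp_fraction = lowamp_fraction,
                 lowamp_gain_range = lowamp_gain_range,
                 resample_steps = isTRUE(resample_steps),
                 max_samples = max_samples, seed = seed),
            class = "sim_config")
}

# Default morphology parameters of a synthetic step. Gyro and Z-axis
# acceleration use centres/widths as fractions of the step duration;
# burst frequencies are in Hz; the vertical-acceleration humps use rise
# and decay time constants in samples (impact and swing timescales do not
# stretch with step duration). The vertical channel carries a weak
# foot-lift hump and a dominant swing hump, each with a sharp rise and a
# slow decay; the Z-acceleration carries oscillatory spiky bursts at both
# ends (heel-off and heel-strike); the angular velocity is a smooth
# positive swing lobe flanked by two negative dips (sum of 3 signed
# Gaussians). All components are tapered to zero at the template edges so
# a planted step joins the foot-flat rest without a discontinuity.
default_shape <- function() {
  list(gyr_amp = c(1, 0.45, 0.45), gyr_centers = c(0.5, 0.12, 0.88),
       gyr_widths = c(0.16, 0.06, 0.06),
       accz_amp = c(0.7, 1), accz_centers = c(0.10, 0.88),
       accz_widths = c(0.05, 0.05), accz_freqs = c(7, 8),
       accv_amp = c(0.14, 1), accv_onsets = c(0.06, 0.34),
       accv_rise = c(5, 5.2), accv_decay = c(14, 35),
       accv_ripple = 0, accv_ripple_freq = 12)
}

# Jitter shape parameters (multiplicative on amplitudes, widths and time
# constants, additive on centres/onsets) to diversify a generated library.
jitter_shape <- function(shape, amount = 0.2) {
  j <- function(v) v * stats::runif(length(v), 1 - amount, 1 + amount)
  shape$gyr_amp <- j(shape$gyr_amp)
  shape$gyr_widths <- j(shape$gyr_widths)
  shape$accz_amp <- j(shape$accz_amp)
  shape$accz_widths <- j(shape$accz_widths)
  shape$accz_freqs <- j(shape$accz_freqs)
  shape$accv_amp <- j(shape$accv_amp)
  shape$accv_rise <- shape$accv_rise * stats::runif(2, 0.9, 1.1)
  shape$accv_decay <- j(shape$accv_decay)
  shift <- function(v, s) pmin(0.9, pmax(0.03, v + stats::runif(length(v), -s, s)))
  shape$gyr_centers <- shift(shape$gyr_centers, 0.02)
  shape$accz_centers <- shift(shape$accz_centers, 0.02)
  shape$accv_onsets <- shift(shape$accv_onsets, 0.02)
  shape
}

#' Generate a parametric step template
#'
#' Builds a 3-component synthetic step of duration \code{np}: a biphasic
#' angular-velocity swing (sum of three signed Gaussians), oscillatory
#' spiky acceleration bursts at heel-off and heel-strike on the Z axis,
#' and on the vertical axis a weak foot-lift hump followed by a dominant
#' swing hump, each rising sharply and decaying slowly. All components are
#' tapered to zero at the edges (a planted step must join foot-flat rest
#' smoothly) and normalized to unit population standard deviation, so the
#' simulator's gains and noise levels are expressed relative to the
#' template amplitude.
#'
#' @param np template duration in samples (2..200).
#' @param shape morphology parameter list (see source); \code{NULL} for
#'   defaults. A positive \code{shape$accv_ripple} superimposes an
#'   oscillation of that relative amplitude (at
#'   \code{shape$accv_ripple_freq} Hz) on the vertical swing hump,
#'   producing steps whose transformed profile carries several strong
#'   peaks (a deliberately peak-search-hostile morphology).
#' @param label,step_type template metadata.
#' @return A \code{\link{step_template}}.
#' @export
make_template <- function(np = 80, shape = NULL, label = "synthetic",
                          step_type = "normal") {
  if (np < 2 || np > 200) stop("np must be in [2, 200]")
  if (is.null(shape)) shape <- default_shape()
  s <- seq(0, 1, length.out = np)
  t <- seq_len(np)
  gauss <- function(c, w) exp(-(s - c)^2 / (2 * w^2))
  burst <- function(c, w, f, ph) gauss(c, w) * sin(2 * pi * f * (s - c) * np / 100 + ph)
  hump <- function(onset, rise, decay) {  # sharp smooth rise, slow decay
    x <- t - onset * np
    z <- ifelse(x > 0, (1 - exp(-(x / rise)^2)) * exp(-x / decay), 0)
    if (max(z) > 0) z / max(z) else z
  }

  gyr <- shape$gyr_amp[1] * gauss(shape$gyr_centers[1], shape$gyr_widths[1]) -
         shape$gyr_amp[2] * gauss(shape$gyr_centers[2], shape$gyr_widths[2]) -
         shape$gyr_amp[3] * gauss(shape$gyr_centers[3], shape$gyr_widths[3])
  accz <- shape$accz_amp[1] * burst(shape$accz_centers[1], shape$accz_widths[1],
                                    shape$accz_freqs[1], 0.3) +
          shape$accz_amp[2] * burst(shape$accz_centers[2], shape$accz_widths[2],
                                    shape$accz_freqs[2], 1.1)
  main <- hump(shape$accv_onsets[2], shape$accv_rise[2], shape$accv_decay[2])
  if (!is.null(shape$accv_ripple) && shape$accv_ripple > 0) {
    # oscillation carried by the decay only (delayed smooth window), so its
    # spectrum stays narrow around the carrier frequency
    xw <- t - shape$accv_onsets[2] * np - 12
    rip_win <- ifelse(xw > 0,
                      (1 - exp(-(xw / 8)^2)) * exp(-xw / shape$accv_decay[2]), 0)
    main <- main + shape$accv_ripple * rip_win *
      sin(2 * pi * shape$accv_ripple_freq * t / 100)
  }
  accv <- shape$accv_amp[1] * hump(shape$accv_onsets[1], shape$accv_rise[1],
                                   shape$accv_decay[1]) +
          shape$accv_amp[2] * main

  m <- rbind(accz, accv, gyr)
  # raised-cosine edge taper
  nt <- min(12L, np %/% 3L)
  if (nt > 0L) {
    w <- rep(1, np)
    w[seq_len(nt)] <- (1 - cos(pi * (seq_len(nt) - 1) / nt)) / 2
    w[np + 1L - seq_len(nt)] <- w[seq_len(nt)]
    m <- sweep(m, 2, w, `*`)
  }
  sds <- apply(m, 1, pop_sd)
  if (any(sds == 0))
    stop("degenerate shape parameters: constant component")
  m <- m / sds
  step_template(m, label = label, step_type = step_type)
}

#' Generate a synthetic template library
#'
#' Draws \code{n_templates} templates with durations sampled uniformly in
#' \code{duration_range} and shape parameters jittered independently per
#' template.
#'
#' @param n_templates number of templates (>= 1).
#' @param duration_range \code{c(min, max)} duration in samples.
#' @param seed RNG seed.
#' @param multipeak if TRUE, superimpose a strong in-band ripple on the
#'   vertical swing hump, yielding the peak-search-hostile morphology
#'   (see \code{\link{make_template}}).
#' @return A \code{\link{template_library}}.
#' @export
make_library <- function(n_templates = 10, duration_range = c(65, 96),
                         seed = 1, multipeak = FALSE) {
  stopifnot(n_templates >= 1)
  with_seed(seed, {
    templates <- lapply(seq_len(n_templates), function(i) {
      np <- sample_range(duration_range[1], duration_range[2])
      shape <- jitter_shape(default_shape())
      if (multipeak) shape$accv_ripple <- 0.6
      make_template(np, shape, label = sprintf("synthetic_%02d", i),
                    step_type = "normal")
    })
    template_library(templates)
  })
}

#' Resample a template to a target duration
#'
#' Per-component linear-interpolation resampling; endpoints are preserved
#' and affine signals are reproduced exactly at any length.
#'
#' @param p a \code{\link{step_template}}.
#' @param target_len new duration in samples (>= 2).
#' @return A \code{\link{step_template}} of duration \code{target_len}.
#' @export
resample_template <- function(p, target_len) {
  stopifnot(inherits(p, "step_template"), target_len >= 2)
  np <- n_samples(p)
  if (target_len == np) return(p)
  xin <- seq(0, 1, length.out = np)
  xout <- seq(0, 1, length.out = target_len)
  m <- t(apply(p$samples, 1, function(v) stats::approx(xin, v, xout)$y))
  step_template(m, label = p$label, step_type = p$step_type)
}

#' Simulate a ground-truthed recording
#'
#' Plants \code{n_steps} randomly chosen library templates (optionally
#' resampled to random target durations), each scaled by a per-step gain,
#' separated by foot-flat rests, between leading and trailing rest
#' segments. White Gaussian noise at \code{noise_sigma} times the
#' (unit) per-component template standard deviation is added everywhere,
#' and per-component DC offsets are applied last. The ground truth records
#' the exact planted intervals with step types, generating template index
#' and gain.
#'
#' @param config a \code{\link{sim_config}}.
#' @param library a \code{\link{template_library}} to draw steps from.
#' @param id recording identifier.
#' @return List with \code{recording} (a \code{\link{step_recording}}),
#'   \code{annotations} (a \code{\link{step_intervals}} data frame) and
#'   \code{truth} (data frame with the planted template index and gain per
#'   step).
#' @export
simulate_recording <- function(config = sim_config(), library, id = "synthetic") {
  stopifnot(inherits(config, "sim_config"), inherits(library, "template_library"))
  with_seed(config$seed, {
    n <- config$n_steps
    tpl_idx <- sample.int(length(library), n, replace = TRUE)
    durations <- vapply(tpl_idx, function(i) n_samples(library[[i]]), integer(1))
    if (config$resample_steps)
      durations <- sample_range(config$duration_range[1],
                                config$duration_range[2], n)
    rests <- sample_range(config$rest_range[1], config$rest_range[2], n)
    is_lowamp <- stats::runif(n) < config$lowamp_fraction
    gains <- ifelse(is_lowamp,
                    stats::runif(n, config$lowamp_gain_range[1], config$lowamp_gain_range[2]),
                    stats::runif(n, config$gain_range[1], config$gain_range[2]))
    total <- 2L * config$edge_rest + sum(durations) + sum(rests[-n])
    if (total > config$max_samples)
      stop("requested recording length ", total, " exceeds the cap ",
           config$max_samples)
    m <- matrix(0, nrow = 3, ncol = total)
    pos <- config$edge_rest  # 0-based start of next step
    starts <- integer(n)
    for (i in seq_len(n)) {
      tpl <- library[[tpl_idx[i]]]
      if (durations[i] != n_samples(tpl))
        tpl <- resample_template(tpl, durations[i])
      cols <- (pos + 1L):(pos + durations[i])
      m[, cols] <- m[, cols] + gains[i] * tpl$samples
      starts[i] <- pos
      pos <- pos + durations[i] + if (i < n) rests[i] else config$edge_rest
    }
    if (config$noise_sigma > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, config$noise_sigma), nrow = 3)
    dc <- stats::runif(3, config$dc_offset_range[1], config$dc_offset_range[2])
    m <- m + dc
    ann <- step_intervals(starts, starts + durations,
                          step_type = ifelse(is_lowamp, "uturn", "normal"))
    list(recording = step_recording(m, fs = config$fs, id = id),
         annotations = ann,
         truth = data.frame(template_index = tpl_idx, gain = gains,
                            duration = durations, lowamp = is_lowamp))
  })
}
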