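#' Pan-Tompkins baseline configuration
#'
#' Parameters of the adapted Pan-Tompkins detector: bandpass corner
#' frequencies, moving-window integration length, and the two activity-gate
#' parameters that suppress peaks found during rest.
#'
#' @param fmin high-pass corner in Hz; 0 means no high-pass (low-pass only).
#' @param fmax low-pass corner in Hz; must be below the Nyquist frequency.
#' @param ninte integration window length in seconds.
#' @param neigh activity-gate neighbourhood half-width in samples (>= 1).
#' @param noise_level activity-gate standard-deviation threshold, in raw
#'   signal units (>= 0; 0 disables the gate).
#' @return A list of class \code{pt_config}.
#' @export
pt_config <- function(fmin = 0, fmax = 20, ninte = 0.1, neigh = 10,
                      noise_level = 0) {
  if (fmin < 0 || fmax <= fmin) stop("need 0 <= fmin < fmax")
  if (ninte <= 0) stop("ninte must be > 0")
  if (neigh < 1) stop("neigh must be >= 1")
  if (noise_level < 0) stop("noise_level must be >= 0")
  structure(list(fmin = fmin, fmax = fmax, ninte = ninte,
                 neigh = as.integer(neigh), noise_level = noise_level),
            class = "pt_config")
}

#' Legacy Pan-Tompkins preset
#'
#' The historical step-counting parametrization (fmin = 0 Hz, fmax = 20 Hz,
#' integration window 0.1 s) used with the sequential every-other-peak
#' selection rule, shipped for qualitative comparison with the revised
#' local-maxima peak search.
#'
#' @param neigh,noise_level activity-gate parameters (the gate is a later
#'   addition, applied to both peak-search modes).
#' @return A \code{\link{pt_config}}.
#' @export
pt_preset_ying <- function(neigh = 10, noise_level = 0) {
  pt_config(fmin = 0, fmax = 20, ninte = 0.1, neigh = neigh,
            noise_level = noise_level)
}

#' Pan-Tompkins preprocessing chain
#'
#' Applies, in order: zero-phase Butterworth bandpass (order 4, filtered
#' forward and backward so peak positions are not lag-shifted; low-pass
#' only when \code{fmin = 0}), first difference scaled by \code{fs},
#' elementwise squaring, and a centred moving average of
#' \code{round(ninte * fs)} samples whose edge windows shrink (no padding,
#' avoiding spurious edge peaks). Output has the input's length and is
#' nonnegative everywhere.
#'
#' @param v one raw signal component.
#' @param fs sampling rate in Hz.
#' @param fmin,fmax bandpass corners in Hz (\code{fmax < fs/2}).
#' @param ninte integration window in seconds.
#' @return Numeric vector, same length as \code{v}.
#' @export
pt_transform <- function(v, fs, fmin = 0, fmax = 20, ninte = 0.1) {
  if (fmax >= fs / 2)
    stop("config error: fmax (", fmax, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz")
  if (fmin < 0 || fmax <= fmin) stop("config error: need 0 <= fmin < fmax")
  bt <- if (fmin <= 0) {
    signal::butter(4, fmax / (fs / 2), type = "low")
  } else {
    signal::butter(4, c(fmin, fmax) / (fs / 2), type = "pass")
  }
  vf <- as.numeric(signal::filtfilt(bt, v))
  n <- length(vf)
  d <- c(diff(vf), 0) * fs
  d[n] <- d[n - 1]
  u <- d^2
  w <- max(1L, as.integer(round(ninte * fs)))
  h1 <- (w - 1L) %/% 2L
  h2 <- w - 1L - h1
  cs <- cumsum(c(0, u))
  lo <- pmax(1L, seq_len(n) - h1)
  hi <- pmin(n, seq_len(n) + h2)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Peak search on the transformed signal
#'
#' Returns the strict local maxima of the transformed signal (greater than
#' both nearest neighbours; boundaries excluded), which prevents the
#' multiple detections produced by the historical sequential peak-pairing
#' rule.
#'
#' @param transformed output of \code{\link{pt_transform}}.
#' @return Integer vector of 0-based peak indices, ascending.
#' @export
pt_peak_search <- function(transformed) {
  n <- length(transformed)
  if (n < 3L) return(integer())
  mid <- 2:(n - 1L)
  idx <- mid[transformed[mid] > transformed[mid - 1L] &
             transformed[mid] > transformed[mid + 1L]]
  as.integer(idx - 1L)  # 0-based
}

#' Activity gate: drop peaks in low-activity regions
#'
#' A peak is kept iff the population standard deviation of the raw
#' component over the symmetric neighbourhood \code{[peak - neigh,
#' peak + neigh]} (clipped to the signal bounds) is at least
#' \code{noise_level}. With \code{noise_level = 0} the gate is the
#' identity.
#'
#' @param peaks 0-based peak indices.
#' @param v the raw signal component the chain was applied to.
#' @param neigh neighbourhood half-width in samples.
#' @param noise_level standard-deviation threshold.
#' @return The surviving subset of \code{peaks}.
#' @export
pt_activity_gate <- function(peaks, v, neigh, noise_level) {
  if (length(peaks) == 0L || noise_level <= 0) return(peaks)
  n <- length(v)
  keep <- vapply(peaks, function(p) {
    i <- p + 1L  # 1-based center
    pop_sd(v[max(1L, i - neigh):min(n, i + neigh)]) >= noise_level
  }, logical(1))
  peaks[keep]
}

#' Pan-Tompkins step detection
#'
#' Full baseline chain on one component of a recording (default: the
#' vertical acceleration, the component the historical adaptations used):
#' \code{\link{pt_transform}}, \code{\link{pt_peak_search}} (or the legacy
#' every-other-peak rule), then \code{\link{pt_activity_gate}}. The result
#' is a list of step peaks; start and end times are not recovered by this
#' method.
#'
#' @param x a \code{\link{step_recording}}.
#' @param config a \code{\link{pt_config}}.
#' @param component component index 1..3 (default 2, vertical acceleration).
#' @param peak_mode \code{"local_maxima"} (revised rule) or
#'   \code{"every_other"} (legacy sequential rule: every other peak,
#'   starting with the second).
#' @return Object of class \code{pt_detection}: list with \code{peaks}
#'   (0-based indices), \code{config}, \code{component}, \code{peak_mode}.
#' @export
pt_detect <- function(x, config = pt_config(), component = 2L,
                      peak_mode = c("local_maxima", "every_other")) {
  stopifnot(inherits(x, "step_recording"), inherits(config, "pt_config"))
  peak_mode <- match.arg(peak_mode)
  v <- x$samples[component, ]
  tr <- pt_transform(v, x$fs, config$fmin, config$fmax, config$ninte)
  peaks <- pt_peak_search(tr)
  if (peak_mode == "every_other" && length(peaks) >= 2L)
    peaks <- peaks[seq(2L, length(peaks), by = 2L)]
  else if (peak_mode == "every_other")
    peaks <- integer()
  peaks <- pt_activity_gate(peaks, v, config$neigh, config$noise_level)
  structure(list(peaks = peaks, config = config, component = component,
                 peak_mode = peak_mode, id = x$id),
            class = "pt_detection")
}

#' @export
print.pt_detection <- function(x, ...) {
  cat(sprintf("<pt_detection> '%s': %d peak(s) [%s, component %d]\n",
              x$id, length(x$peaks), x$peak_mode, x$component))
  invisible(x)
}

#' Grid-search tuning of the Pan-Tompkins baseline
#'
#' Exhaustive search over the product of the five parameter grids. Each
#' configuration is run on every recording and scored against its
#' annotations with the peak-only matching rule
#' (\code{\link{evaluate_peaks}}); counts are pooled across recordings and
#' the configuration with the highest F-measure is returned. Ties are
#' broken by first-in-grid-order (the first grid varies fastest).
#'
#' @param recordings list of \code{\link{step_recording}} objects.
#' @param annotations list of \code{\link{step_intervals}} (same length).
#' @param grids named list with numeric vectors \code{fmin}, \code{fmax},
#'   \code{ninte}, \code{neigh}, \code{noise_level} (all nonempty).
#' @param component component index passed to \code{\link{pt_detect}}.
#' @return List of class \code{pt_grid_search}: \code{best_config},
#'   \code{best_f}, \code{best_precision}, \code{best_recall}, and
#'   \code{table} (one row per configuration).
#' @export
pt_grid_search <- function(recordings, annotations,
                           grids = list(fmin = 0, fmax = c(6, 8, 12),
                                        ninte = c(0.05, 0.08, 0.12),
                                        neigh = c(3, 5, 10),
                                        noise_level = c(0.2, 0.3, 0.4)),
                           component = 2L) {
  stopifnot(length(recordings) >= 1L, length(recordings) == length(annotations))
  needed <- c("fmin", "fmax", "ninte", "neigh", "noise_level")
  for (nm in needed)
    if (is.null(grids[[nm]]) || length(grids[[nm]]) == 0L)
      stop("config error: empty grid for parameter '", nm, "'")
  full <- expand.grid(grids[needed], KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(full))
  best <- NULL
  for (i in seq_len(nrow(full))) {
    g <- full[i, ]
    if (g$fmax <= g$fmin) next  # invalid corner pair: not a candidate
    cfg <- pt_config(g$fmin, g$fmax, g$ninte, g$neigh, g$noise_level)
    tot <- c(correct = 0, peaks = 0, found = 0, ann = 0)
    for (j in seq_along(recordings)) {
      ev <- evaluate_peaks(pt_detect(recordings[[j]], cfg, component = component),
                           annotations[[j]])
      tot <- tot + c(ev$n_correct, ev$n_peaks, ev$n_found, ev$n_annotated)
    }
    precision <- if (tot["peaks"] > 0) tot["correct"] / tot["peaks"] else NA_real_
    recall <- if (tot["ann"] > 0) tot["found"] / tot["ann"] else NA_real_
    f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else -Inf
    rows[[i]] <- cbind(full[i, ], precision = unname(precision),
                       recall = unname(recall), f_measure = unname(f))
    if (is.null(best) || f > best$f) {
      best <- list(config = cfg, f = f, precision = unname(precision),
                   recall = unname(recall))
    }
  }
  if (is.null(best)) stop("no valid configuration in the grids")
  structure(list(best_config = best$config, best_f = unname(best$f),
                 best_precision = best$precision, best_recall = best$recall,
                 table = do.call(rbind, rows[!vapply(rows, is.null, logical(1))])),
            class = "pt_grid_search")
}

#' @export
print.pt_grid_search <- function(x, ...) {
  cat(sprintf("<pt_grid_search> %d configuration(s); best F = %.4f (P %.4f, R %.4f)\n",
              nrow(x$table), x$best_f, x$best_precision, x$best_recall))
  cat(sprintf("  best: fmin %g, fmax %g Hz, ninte %g s, neigh %d, noise_level %g\n",
              x$best_config$fmin, x$best_config$fmax, x$best_config$ninte,
              x$best_config$neigh, x$best_config$noise_level))
  invisible(x)
}
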