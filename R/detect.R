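#' Detector configuration
#'
#' @param lam correlation threshold \eqn{\lambda} in [0, 1] (default 0.6):
#'   greedy selection stops once the best remaining candidate scores below
#'   it, so every detected step has score >= \code{lam}.
#' @param mu amplitude-ratio threshold \eqn{\mu} >= 0 (default 0.1): a
#'   detected step is discarded when the standard deviation of its signal
#'   segment, on the matched component, is below \code{mu} times the
#'   template's standard deviation.
#' @return A list of class \code{detector_config}.
#' @export
detector_config <- function(lam = 0.6, mu = 0.1) {
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1)
    stop("lam must be a single number in [0, 1]")
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    stop("mu must be a single number >= 0")
  structure(list(lam = lam, mu = mu), class = "detector_config")
}

#' Greedy non-overlapping candidate selection
#'
#' Visits candidates in strictly decreasing score order (ties broken by
#' earliest lag, then lowest template index, then component order, making
#' the result deterministic). A candidate is accepted iff its interval
#' \code{[t, t + Np)} contains no sample of a previously accepted step; on
#' acceptance all its samples become forbidden. Iteration stops when every
#' sample is forbidden, the candidate list is exhausted, or the best
#' remaining score drops below \code{lam}. Abutting intervals (end of one
#' equals start of the next) do not overlap.
#'
#' @param candidates data frame from \code{\link{find_local_maxima}}.
#' @param template_lengths integer vector of per-template durations Np
#'   (see \code{\link{template_lengths}}).
#' @param nx signal length in samples.
#' @param lam correlation threshold \eqn{\lambda}.
#' @return A \code{\link{step_intervals}} data frame of pairwise-disjoint
#'   detected steps, sorted by start time, with provenance columns filled.
#' @export
greedy_select <- function(candidates, template_lengths, nx, lam = 0.6) {
  empty <- step_intervals()
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  # Pre-filtering to scores >= lam is equivalent to the stop condition:
  # candidates below lam can never be visited before the loop stops.
  candidates <- candidates[candidates$score >= lam, , drop = FALSE]
  if (nrow(candidates) == 0L) return(empty)
  ord <- order(-candidates$score, candidates$t, candidates$p_index, candidates$k)
  candidates <- candidates[ord, , drop = FALSE]
  forbidden <- logical(nx)
  n_free <- nx
  acc_start <- integer(); acc_p <- integer(); acc_k <- integer(); acc_r <- numeric()
  for (i in seq_len(nrow(candidates))) {
    if (n_free == 0L) break
    t0 <- candidates$t[i]
    np <- template_lengths[candidates$p_index[i]]
    if (t0 + np > nx) next
    span <- (t0 + 1L):(t0 + np)  # 1-based view of [t0, t0 + np)
    if (any(forbidden[span])) next
    forbidden[span] <- TRUE
    n_free <- n_free - np
    acc_start <- c(acc_start, t0)
    acc_p <- c(acc_p, candidates$p_index[i])
    acc_k <- c(acc_k, candidates$k[i])
    acc_r <- c(acc_r, candidates$score[i])
  }
  if (length(acc_start) == 0L) return(empty)
  o <- order(acc_start)
  step_intervals(acc_start[o], acc_start[o] + template_lengths[acc_p[o]],
                 step_type = "unknown",
                 template_index = acc_p[o], component = acc_k[o],
                 score = acc_r[o])
}

#' Discard low-amplitude detections
#'
#' Post-processing amplitude gate: a detected step is discarded iff the
#' population standard deviation of the signal over its interval, on the
#' single component that produced the detection, is below \code{mu} times
#' the matched template's standard deviation on that component. This
#' removes spurious matches during rest, where the scale invariance of the
#' correlation would otherwise accept near-zero noise that happens to have
#' a step-like shape.
#'
#' @param steps detected \code{\link{step_intervals}} with provenance.
#' @param x the \code{\link{step_recording}} that was searched.
#' @param library the \code{\link{template_library}} used.
#' @param mu amplitude-ratio threshold \eqn{\mu}.
#' @return The surviving subset of \code{steps}.
#' @export
reject_low_amplitude <- function(steps, x, library, mu = 0.1) {
  if (nrow(steps) == 0L) return(steps)
  keep <- vapply(seq_len(nrow(steps)), function(i) {
    k <- steps$component[i]
    seg <- x$samples[k, (steps$start[i] + 1L):steps$end[i]]
    tpl <- library[[steps$template_index[i]]]
    pop_sd(seg) >= mu * tpl$sd[k]
  }, logical(1))
  steps[keep, , drop = FALSE]
}

#' Detect steps by template matching
#'
#' End-to-end detector: sliding Pearson correlations of every library
#' template component along the matching signal component
#' (\code{\link{correlation_tensor}}), extraction of strict local
#' correlation maxima (\code{\link{find_local_maxima}}), greedy placement
#' of non-overlapping steps above \eqn{\lambda}
#' (\code{\link{greedy_select}}) and the \eqn{\mu} amplitude gate
#' (\code{\link{reject_low_amplitude}}). Deterministic: identical inputs
#' give identical outputs.
#'
#' @param x a \code{\link{step_recording}}.
#' @param library a \code{\link{template_library}}.
#' @param config a \code{\link{detector_config}} (defaults
#'   \eqn{\lambda = 0.6}, \eqn{\mu = 0.1}).
#' @return An object of class \code{step_detection}: list with
#'   \code{steps} (a \code{\link{step_intervals}} data frame),
#'   \code{config}, \code{n_samples}, \code{fs} and \code{id}.
#' @examples
#' lib <- make_library(3, seed = 1)
#' sim <- simulate_recording(sim_config(n_steps = 5, seed = 2), lib)
#' det <- detect_steps(sim$recording, lib)
#' det
#' @export
detect_steps <- function(x, library, config = detector_config()) {
  stopifnot(inherits(x, "step_recording"), inherits(library, "template_library"),
            inherits(config, "detector_config"))
  tracks <- correlation_tensor(x, library)
  cands <- find_local_maxima(tracks)
  steps <- greedy_select(cands, template_lengths(library), n_samples(x),
                         lam = config$lam)
  steps <- reject_low_amplitude(steps, x, library, mu = config$mu)
  structure(list(steps = steps, config = config, n_samples = n_samples(x),
                 fs = x$fs, id = x$id),
            class = "step_detection")
}

#' @export
print.step_detection <- function(x, ...) {
  cat(sprintf("<step_detection> '%s': %d step(s) in %d samples (lambda = %g, mu = %g)\n",
              x$id, nrow(x$steps), x$n_samples, x$config$lam, x$config$mu))
  if (nrow(x$steps)) {
    show <- utils::head(x$steps, 10)
    print.data.frame(show, row.names = FALSE, digits = 4)
    if (nrow(x$steps) > 10) cat("... and", nrow(x$steps) - 10, "more\n")
  }
  invisible(x)
}

#' @export
summary.step_detection <- function(object, ...) {
  s <- object$steps
  dur <- s$end - s$start
  out <- list(n_steps = nrow(s),
              duration_samples = if (nrow(s)) summary(dur) else NULL,
              score = if (nrow(s)) summary(s$score) else NULL,
              cadence_steps_per_min =
                if (nrow(s) > 1)
                  60 * object$fs * (nrow(s) - 1) / (s$start[nrow(s)] - s$start[1])
                else NA_real_)
  class(out) <- "summary.step_detection"
  out
}

#' @export
print.summary.step_detection <- function(x, ...) {
  cat("Steps detected:", x$n_steps, "\n")
  if (!is.null(x$duration_samples)) {
    cat("Step duration [samples]:\n"); print(x$duration_samples)
    cat("Correlation score:\n"); print(x$score)
    cat(sprintf("Cadence: %.1f steps/min\n", x$cadence_steps_per_min))
  }
  invisible(x)
}

#' @export
as.data.frame.step_detection <- function(x, ...) as.data.frame(x$steps)

#' Plot a recording with detected steps
#'
#' Draws the three components stacked, with detected step intervals shaded
#' and (optionally) annotated intervals outlined.
#'
#' @param x a \code{step_detection}.
#' @param recording the \code{\link{step_recording}} that was searched.
#' @param annotations optional \code{\link{step_intervals}} ground truth.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.step_detection <- function(x, recording, annotations = NULL, ...) {
  stopifnot(inherits(recording, "step_recording"))
  old <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  tt <- seq_len(n_samples(recording)) - 1L
  for (k in 1:3) {
    v <- recording$samples[k, ]
    plot(tt, v, type = "l", xlab = "", ylab = STEP_COMPONENTS[k], ...)
    if (nrow(x$steps))
      graphics::rect(x$steps$start, min(v), x$steps$end, max(v),
                     col = grDevices::adjustcolor("steelblue", 0.25),
                     border = NA)
    if (!is.null(annotations) && nrow(annotations))
      graphics::rect(annotations$start, min(v), annotations$end, max(v),
                     border = "darkred", lty = 2, col = NA)
  }
  invisible(x)
}
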