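#' Sensitivity sweep over the detector thresholds
#'
#' Evaluates detector precision and recall over a grid of \eqn{\lambda}
#' values (with \eqn{\mu} held at its default) and a grid of \eqn{\mu}
#' values (with \eqn{\lambda} held at its default), one axis at a time.
#' The correlation tensor and candidate set of each recording are computed
#' once and reused across grid points: \eqn{\lambda} only changes the
#' greedy stop condition and \eqn{\mu} only filters accepted steps, so the
#' result is identical to independent \code{\link{detect_steps}} runs.
#'
#' @param recordings list of \code{\link{step_recording}} objects.
#' @param annotations list of \code{\link{step_intervals}} (same length).
#' @param library a \code{\link{template_library}}.
#' @param lam_grid,mu_grid numeric vectors of threshold values (nonempty).
#' @param lam_default,mu_default the value at which the other axis is held.
#' @return Data frame of class \code{step_sweep} with columns
#'   \code{parameter} ("lambda" or "mu"), \code{value}, \code{lam},
#'   \code{mu}, \code{precision}, \code{recall} (means over recordings).
#' @export
run_sweep <- function(recordings, annotations, library,
                      lam_grid = seq(0.5, 0.8, by = 0.1),
                      mu_grid = c(0.05, 0.1, 0.15),
                      lam_default = 0.6, mu_default = 0.1) {
  stopifnot(length(recordings) >= 1L, length(recordings) == length(annotations))
  if (length(lam_grid) == 0L || length(mu_grid) == 0L)
    stop("config error: empty threshold grid")
  lens <- template_lengths(library)
  prep <- lapply(recordings, function(x) {
    cands <- find_local_maxima(correlation_tensor(x, library))
    list(x = x, cands = cands, nx = n_samples(x))
  })
  eval_point <- function(lam, mu) {
    reports <- lapply(seq_along(prep), function(i) {
      st <- greedy_select(prep[[i]]$cands, lens, prep[[i]]$nx, lam = lam)
      st <- reject_low_amplitude(st, prep[[i]]$x, library, mu = mu)
      evaluate_detection(st, annotations[[i]])
    })
    s <- summarize_evaluations(reports)
    c(precision = unname(s$precision["mean"]), recall = unname(s$recall["mean"]))
  }
  rows <- list()
  for (lam in lam_grid) {
    pr <- eval_point(lam, mu_default)
    rows[[length(rows) + 1L]] <- data.frame(parameter = "lambda", value = lam,
                                            lam = lam, mu = mu_default,
                                            precision = pr["precision"],
                                            recall = pr["recall"])
  }
  for (mu in mu_grid) {
    pr <- eval_point(lam_default, mu)
    rows[[length(rows) + 1L]] <- data.frame(parameter = "mu", value = mu,
                                            lam = lam_default, mu = mu,
                                            precision = pr["precision"],
                                            recall = pr["recall"])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("step_sweep", "data.frame")
  out
}

#' Plot a threshold sweep
#'
#' Precision and recall against each swept threshold, one panel per axis.
#'
#' @param x a \code{step_sweep} data frame from \code{\link{run_sweep}}.
#' @param ... passed to \code{matplot}.
#' @return \code{x}, invisibly.
#' @export
plot.step_sweep <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (par_name in c("lambda", "mu")) {
    d <- x[x$parameter == par_name, ]
    if (!nrow(d)) next
    graphics::matplot(d$value, cbind(d$precision, d$recall), type = "b",
                      pch = c(1, 2), lty = 1, xlab = par_name,
                      ylab = "score", ylim = c(0, 1), ...)
    graphics::legend("bottomleft", c("precision", "recall"), pch = c(1, 2),
                     lty = 1, col = 1:2, bty = "n")
  }
  invisible(x)
}
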