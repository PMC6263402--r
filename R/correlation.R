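#' Pearson correlation with degenerate-window sentinel
#'
#' Plain Pearson correlation \code{cov(y,z) / (sd(y) sd(z))} computed with
#' population moments (divide by n; the ratio is identical with sample
#' moments, the convention is fixed for reproducibility). If either vector
#' has zero standard deviation the value is the sentinel 0 with attribute
#' \code{degenerate = TRUE} rather than an error: constant windows occur
#' legitimately during foot-flat rest, and 0 ("no evidence of a step") keeps
#' the greedy ordering total.
#'
#' @param y,z numeric vectors of equal length n >= 2.
#' @return Correlation in [-1, 1], with attribute \code{degenerate}.
#' @export
pearson_cor <- function(y, z) {
  n <- length(y)
  if (length(z) != n) stop("y and z must have equal length")
  if (n < 2L) stop("need at least 2 samples")
  my <- mean(y); mz <- mean(z)
  sy <- sqrt(mean((y - my)^2)); sz <- sqrt(mean((z - mz)^2))
  if (sy == 0 || sz == 0)
    return(structure(0, degenerate = TRUE))
  r <- mean((y - my) * (z - mz)) / (sy * sz)
  structure(min(1, max(-1, r)), degenerate = FALSE)
}

# Relative variance threshold below which a signal window is treated as
# constant. Scaled by the window's mean square so that exact-constant
# windows computed through running sums (which leave O(eps) cancellation
# residue) are flagged, while genuinely small noise variance is not.
DEGENERATE_REL_VAR <- 1e-12

#' Sliding Pearson correlation of a template component along a signal
#'
#' Computes \code{r(t) = cor(p_k, x_k[t : t + Np))} for every 0-based lag
#' \code{t} in \code{0 .. Nx - Np}, via FFT cross-correlation and running
#' sums; results match direct per-lag evaluation to well within 1e-9.
#' Lags whose signal window is (numerically) constant carry the sentinel
#' value 0 and are flagged in the \code{degenerate} mask.
#'
#' @param x_k numeric signal component (length Nx).
#' @param p_k numeric template component (length Np <= Nx, nonzero sd).
#' @return A list of class \code{correlation_track} with \code{values}
#'   (length Nx - Np + 1, clipped to [-1, 1]) and \code{degenerate}
#'   (logical mask). Fields \code{k} and \code{p_index} are filled by
#'   \code{\link{correlation_tensor}}.
#' @export
sliding_correlation <- function(x_k, p_k) {
  nx <- length(x_k); np <- length(p_k)
  if (np > nx) stop("template longer than signal (Np = ", np, ", Nx = ", nx, ")")
  if (np < 2L) stop("template component must have Np >= 2")
  sp <- pop_sd(p_k)
  if (sp == 0) stop("template component has zero standard deviation")
  q <- p_k - mean(p_k)
  # sliding dot products sum(q * window) == np * cov_pop (window mean drops
  # out because sum(q) = 0)
  sxy <- stats::convolve(x_k, q, type = "filter")
  cs1 <- cumsum(c(0, x_k))
  cs2 <- cumsum(c(0, x_k^2))
  nlag <- nx - np + 1L
  idx <- seq_len(nlag)
  s1 <- cs1[idx + np] - cs1[idx]
  s2 <- cs2[idx + np] - cs2[idx]
  mx <- s1 / np
  varx <- pmax(0, s2 / np - mx^2)
  meansq <- s2 / np
  degenerate <- varx <= DEGENERATE_REL_VAR * pmax(meansq, .Machine$double.xmin)
  r <- numeric(nlag)
  ok <- !degenerate
  r[ok] <- (sxy[ok] / np) / (sqrt(varx[ok]) * sp)
  r <- pmin(1, pmax(-1, r))
  structure(list(k = NA_integer_, p_index = NA_integer_,
                 values = r, degenerate = degenerate),
            class = "correlation_track")
}

#' Sliding correlations for every (component, template) pair
#'
#' Applies \code{\link{sliding_correlation}} to all 3 components of every
#' library template, yielding up to \code{3 * NP} tracks. Templates longer
#' than the signal are skipped with a warning; if no template fits, this is
#' an error.
#'
#' @param x a \code{\link{step_recording}}.
#' @param library a \code{\link{template_library}}.
#' @return List of \code{correlation_track} objects with \code{k}
#'   (component 1..3) and \code{p_index} (1-based template index) filled.
#' @export
correlation_tensor <- function(x, library) {
  stopifnot(inherits(x, "step_recording"), inherits(library, "template_library"))
  nx <- n_samples(x)
  tracks <- list()
  skipped <- 0L
  for (p_index in seq_along(library$templates)) {
    tpl <- library[[p_index]]
    if (n_samples(tpl) > nx) {
      skipped <- skipped + 1L
      next
    }
    for (k in 1:3) {
      tr <- sliding_correlation(x$samples[k, ], tpl$samples[k, ])
      tr$k <- k
      tr$p_index <- p_index
      tracks[[length(tracks) + 1L]] <- tr
    }
  }
  if (skipped > 0L)
    warning(skipped, " template(s) longer than the signal were skipped")
  if (length(tracks) == 0L)
    stop("no usable template: all templates are longer than the signal")
  tracks
}

#' Extract candidate step placements (local correlation maxima)
#'
#' A lag \code{t} is a candidate iff its correlation is strictly greater
#' than both nearest temporal neighbours. Boundary lags (first and last of
#' a track) are never candidates, plateaus of equal values yield none, and
#' degenerate (sentinel 0) lags are excluded.
#'
#' @param tracks list of \code{correlation_track} objects (from
#'   \code{\link{correlation_tensor}}).
#' @return A data frame with columns \code{k}, \code{p_index},
#'   \code{t} (0-based lag) and \code{score}.
#' @export
find_local_maxima <- function(tracks) {
  stopifnot(length(tracks) > 0L)
  out <- lapply(tracks, function(tr) {
    v <- tr$values
    n <- length(v)
    if (n < 3L)
      return(data.frame(k = integer(), p_index = integer(),
                        t = integer(), score = numeric()))
    mid <- 2:(n - 1L)
    is_max <- v[mid] > v[mid - 1L] & v[mid] > v[mid + 1L] & !tr$degenerate[mid]
    idx <- mid[is_max]
    data.frame(k = rep.int(tr$k, length(idx)),
               p_index = rep.int(tr$p_index, length(idx)),
               t = idx - 1L,  # 0-based lag
               score = v[idx])
  })
  do.call(rbind, out)
}
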