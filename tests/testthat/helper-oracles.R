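# Independent reference implementations used as oracles. They are kept
# deliberately naive (direct definitions, no shared code with the package
# internals they check).

# Direct per-lag Pearson correlation. stats::cor (sample moments) equals the
# population-moment ratio: the 1/n vs 1/(n-1) factors cancel.
naive_sliding_cor <- function(x, p) {
  np <- length(p)
  vapply(0:(length(x) - np), function(t0) {
    win <- x[(t0 + 1):(t0 + np)]
    if (stats::sd(win) == 0 || stats::sd(p) == 0) return(0)
    min(1, max(-1, stats::cor(p, win)))
  }, numeric(1))
}

# Greedy selection by full re-sort and re-scan each iteration: at every
# step, scan the entire remaining candidate list for the best admissible
# candidate (same tie-break order as the contract), accept it, forbid its
# samples, repeat.
naive_greedy <- function(candidates, template_lengths, nx, lam) {
  forbidden <- logical(nx)
  out <- NULL
  repeat {
    if (nrow(candidates) == 0L || all(forbidden)) break
    ord <- order(-candidates$score, candidates$t, candidates$p_index, candidates$k)
    candidates <- candidates[ord, , drop = FALSE]
    if (candidates$score[1] < lam) break
    placed <- FALSE
    drop <- integer()
    for (i in seq_len(nrow(candidates))) {
      if (candidates$score[i] < lam) break
      t0 <- candidates$t[i]
      np <- template_lengths[candidates$p_index[i]]
      if (t0 + np > nx) { drop <- c(drop, i); next }
      span <- (t0 + 1):(t0 + np)
      if (any(forbidden[span])) { drop <- c(drop, i); next }
      forbidden[span] <- TRUE
      out <- rbind(out, candidates[i, ])
      drop <- c(drop, i)
      placed <- TRUE
      break
    }
    if (!placed) break
    candidates <- candidates[-drop, , drop = FALSE]
  }
  if (is.null(out)) return(step_intervals())
  o <- order(out$t)
  step_intervals(out$t[o], out$t[o] + template_lengths[out$p_index[o]],
                 template_index = out$p_index[o], component = out$k[o],
                 score = out$score[o])
}

# Random candidate set over a signal of length nx.
random_candidates <- function(n, nx, n_templates, template_lengths) {
  data.frame(k = sample(1:3, n, replace = TRUE),
             p_index = sample(n_templates, n, replace = TRUE),
             t = sample(0:(nx - max(template_lengths)), n, replace = TRUE),
             score = stats::runif(n, 0.3, 1))
}

# Tiny deterministic 3-component template: linearly independent rows with
# nonzero variance.
toy_template <- function(np = 20, label = "toy") {
  s <- seq_len(np)
  step_template(rbind(sin(s / 2), cos(s / 3), s / np - 0.5), label = label)
}

# Recording containing copies of `tpl` at the given 0-based starts.
plant_recording <- function(tpl, starts, nx, gain = 1, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, 3, nx)
  gain <- rep_len(gain, length(starts))
  for (i in seq_along(starts)) {
    cols <- (starts[i] + 1):(starts[i] + ncol(tpl$samples))
    m[, cols] <- m[, cols] + gain[i] * tpl$samples
  }
  if (noise > 0) m <- m + matrix(stats::rnorm(length(m), 0, noise), 3)
  step_recording(m, fs = 100, id = "planted")
}
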