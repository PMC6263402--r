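# Midpoint-containment matching shared by both passes. Items of `from` are
# visited in ascending start order; an item is matched iff its interval
# midpoint (start + end) / 2, half-open convention, lies inside a not yet
# claimed interval of `to` (start_to <= m < end_to; first claim wins, the
# earliest containing interval is taken). Each `to` interval can be claimed
# at most once within a pass.
match_midpoints <- function(from, to) {
  nf <- nrow(from); nt <- nrow(to)
  pairs <- matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("from_index", "to_index")))
  if (nf == 0L || nt == 0L)
    return(list(pairs = pairs,
                unmatched_from = seq_len(nf), unmatched_to = seq_len(nt)))
  claimed <- logical(nt)
  ord_to <- order(to$start)
  res_from <- integer(); res_to <- integer()
  for (i in order(from$start)) {
    m <- (from$start[i] + from$end[i]) / 2
    for (j in ord_to) {
      if (!claimed[j] && to$start[j] <= m && m < to$end[j]) {
        claimed[j] <- TRUE
        res_from <- c(res_from, i); res_to <- c(res_to, j)
        break
      }
    }
  }
  list(pairs = cbind(from_index = res_from, to_index = res_to),
       unmatched_from = setdiff(seq_len(nf), res_from),
       unmatched_to = setdiff(seq_len(nt), res_to))
}

#' Precision pass: match detected steps to annotations
#'
#' A detected step is correct iff the midpoint of its start and end times
#' lies inside an annotated step; an annotated step can be claimed only
#' once, so when several detections correspond to the same annotated step
#' all but one are false. Detections are processed in ascending start
#' order (first claim wins).
#'
#' @param detected,annotated \code{\link{step_intervals}} data frames.
#' @return List with \code{pairs} (matrix of detected/annotated row
#'   indices), \code{unmatched_detected}, \code{unmatched_annotated}.
#' @export
match_precision_pass <- function(detected, annotated) {
  m <- match_midpoints(detected, annotated)
  list(pairs = cbind(detected_index = m$pairs[, 1],
                     annotated_index = m$pairs[, 2]),
       unmatched_detected = m$unmatched_from,
       unmatched_annotated = m$unmatched_to)
}

#' Recall pass: match annotations to detected steps
#'
#' Symmetric rule: an annotated step is detected iff its midpoint lies
#' inside a detected step, and a detected step can serve at most one
#' annotated step. Annotations are processed in ascending start order.
#'
#' @inheritParams match_precision_pass
#' @return List with \code{pairs} (annotated/detected row indices),
#'   \code{unmatched_annotated}, \code{unmatched_detected}.
#' @export
match_recall_pass <- function(detected, annotated) {
  m <- match_midpoints(annotated, detected)
  list(pairs = cbind(annotated_index = m$pairs[, 1],
                     detected_index = m$pairs[, 2]),
       unmatched_annotated = m$unmatched_from,
       unmatched_detected = m$unmatched_to)
}

#' Signed timing errors of correctly detected steps
#'
#' For each pair of the precision pass: \code{dstart = start_d - start_a},
#' \code{dend = end_d - end_a}, \code{dduration = (end_d - start_d) -
#' (end_a - start_a)}, all signed and in samples.
#'
#' @param detected,annotated \code{\link{step_intervals}} data frames.
#' @param pairs pair matrix from \code{\link{match_precision_pass}}.
#' @return Data frame with columns \code{dstart}, \code{dend},
#'   \code{dduration}, \code{step_type} (of the annotated step), one row
#'   per correct detection.
#' @export
delta_metrics <- function(detected, annotated, pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(dstart = numeric(), dend = numeric(),
                      dduration = numeric(), step_type = character()))
  di <- pairs[, 1]; ai <- pairs[, 2]
  data.frame(dstart = detected$start[di] - annotated$start[ai],
             dend = detected$end[di] - annotated$end[ai],
             dduration = (detected$end[di] - detected$start[di]) -
                         (annotated$end[ai] - annotated$start[ai]),
             step_type = annotated$step_type[ai])
}

#' Event-level evaluation of a detection against annotations
#'
#' Computes precision (correct detections / total detections), recall
#' (detected annotations / total annotations), and the signed timing
#' errors of the correct detections (from the precision-pass pairing),
#' with median absolute errors stratified by annotated step type. With 0
#' detections the precision is \code{NA} (no false alarms, nothing to
#' score); with 0 annotations the recall is \code{NA}.
#'
#' @param detected a \code{\link{step_intervals}} data frame or a
#'   \code{step_detection} object.
#' @param annotated a \code{\link{step_intervals}} data frame.
#' @return An object of class \code{step_eval}: list with
#'   \code{precision}, \code{recall}, \code{n_detected},
#'   \code{n_annotated}, \code{n_correct}, \code{n_found},
#'   \code{deltas} (data frame), \code{median_abs} (by step type).
#' @export
evaluate_detection <- function(detected, annotated) {
  if (inherits(detected, "step_detection")) detected <- detected$steps
  prec_pass <- match_precision_pass(detected, annotated)
  rec_pass <- match_recall_pass(detected, annotated)
  n_det <- nrow(detected); n_ann <- nrow(annotated)
  n_correct <- nrow(prec_pass$pairs)
  n_found <- nrow(rec_pass$pairs)
  deltas <- delta_metrics(detected, annotated, prec_pass$pairs)
  med_abs <- if (nrow(deltas)) {
    types <- unique(deltas$step_type)
    do.call(rbind, lapply(types, function(ty) {
      d <- deltas[deltas$step_type == ty, ]
      data.frame(step_type = ty, n = nrow(d),
                 dstart = stats::median(abs(d$dstart)),
                 dend = stats::median(abs(d$dend)),
                 dduration = stats::median(abs(d$dduration)))
    }))
  } else {
    data.frame(step_type = character(), n = integer(), dstart = numeric(),
               dend = numeric(), dduration = numeric())
  }
  structure(list(precision = if (n_det > 0) n_correct / n_det else NA_real_,
                 recall = if (n_ann > 0) n_found / n_ann else NA_real_,
                 n_detected = n_det, n_annotated = n_ann,
                 n_correct = n_correct, n_found = n_found,
                 deltas = deltas, median_abs = med_abs),
            class = "step_eval")
}

#' @export
print.step_eval <- function(x, ...) {
  cat(sprintf("<step_eval> precision %.4f (%d/%d), recall %.4f (%d/%d)\n",
              x$precision, x$n_correct, x$n_detected,
              x$recall, x$n_found, x$n_annotated))
  if (nrow(x$median_abs)) {
    cat("Median absolute errors [samples] by step type:\n")
    print.data.frame(x$median_abs, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Aggregate evaluation reports across recordings
#'
#' Per-recording precision and recall are averaged with their standard
#' deviations (matching per-exercise averaging); timing errors are pooled
#' and summarized as medians of absolute values by step type. Step types
#' with zero steps are absent from the table, not reported as zero.
#'
#' @param reports list of \code{step_eval} objects.
#' @return List of class \code{step_eval_summary} with \code{precision}
#'   and \code{recall} (each \code{c(mean, sd)}), \code{n_recordings},
#'   \code{median_abs} (pooled, by step type) and \code{counts}.
#' @export
summarize_evaluations <- function(reports) {
  stopifnot(length(reports) >= 1L)
  prec <- vapply(reports, function(r) r$precision, numeric(1))
  rec <- vapply(reports, function(r) r$recall, numeric(1))
  all_d <- do.call(rbind, lapply(reports, function(r) r$deltas))
  med_abs <- if (!is.null(all_d) && nrow(all_d)) {
    do.call(rbind, lapply(unique(all_d$step_type), function(ty) {
      d <- all_d[all_d$step_type == ty, ]
      data.frame(step_type = ty, n = nrow(d),
                 dstart = stats::median(abs(d$dstart)),
                 dend = stats::median(abs(d$dend)),
                 dduration = stats::median(abs(d$dduration)))
    }))
  } else {
    data.frame(step_type = character(), n = integer(), dstart = numeric(),
               dend = numeric(), dduration = numeric())
  }
  structure(list(precision = c(mean = mean(prec, na.rm = TRUE),
                               sd = stats::sd(prec[!is.na(prec)])),
                 recall = c(mean = mean(rec, na.rm = TRUE),
                            sd = stats::sd(rec[!is.na(rec)])),
                 n_recordings = length(reports),
                 median_abs = med_abs,
                 counts = c(detected = sum(vapply(reports, function(r) r$n_detected, numeric(1))),
                            annotated = sum(vapply(reports, function(r) r$n_annotated, numeric(1))),
                            correct = sum(vapply(reports, function(r) r$n_correct, numeric(1))),
                            found = sum(vapply(reports, function(r) r$n_found, numeric(1))))),
            class = "step_eval_summary")
}

#' @export
print.step_eval_summary <- function(x, ...) {
  cat(sprintf("<step_eval_summary> %d recording(s)\n", x$n_recordings))
  cat(sprintf("  precision: %.4f (sd %.4f)\n", x$precision["mean"], x$precision["sd"]))
  cat(sprintf("  recall:    %.4f (sd %.4f)\n", x$recall["mean"], x$recall["sd"]))
  if (nrow(x$median_abs)) {
    cat("  median |error| [samples] by step type:\n")
    print.data.frame(x$median_abs, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Evaluate peak-only detections against annotated steps
#'
#' Scoring rule for the Pan-Tompkins baseline, which yields step peaks
#' without start/end times: a peak is correct iff it lies inside a not yet
#' claimed annotated interval (precision), and an annotated step is
#' detected iff it contains a not yet claimed peak (recall). No timing
#' errors are defined for peaks.
#'
#' @param peaks integer vector of 0-based peak sample indices, or a
#'   \code{pt_detection} object.
#' @param annotated a \code{\link{step_intervals}} data frame.
#' @return List of class \code{peak_eval} with \code{precision},
#'   \code{recall}, \code{f_measure} and counts.
#' @export
evaluate_peaks <- function(peaks, annotated) {
  if (inherits(peaks, "pt_detection")) peaks <- peaks$peaks
  peaks <- sort(peaks)
  n_pk <- length(peaks); n_ann <- nrow(annotated)
  claimed <- logical(n_ann)
  correct <- 0L
  for (pk in peaks) {
    j <- which(!claimed & annotated$start <= pk & pk < annotated$end)
    if (length(j)) { claimed[j[1]] <- TRUE; correct <- correct + 1L }
  }
  used <- logical(n_pk)
  found <- 0L
  for (j in seq_len(n_ann)) {
    i <- which(!used & peaks >= annotated$start[j] & peaks < annotated$end[j])
    if (length(i)) { used[i[1]] <- TRUE; found <- found + 1L }
  }
  precision <- if (n_pk > 0) correct / n_pk else NA_real_
  recall <- if (n_ann > 0) found / n_ann else NA_real_
  f <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(precision = precision, recall = recall, f_measure = f,
                 n_peaks = n_pk, n_annotated = n_ann,
                 n_correct = correct, n_found = found),
            class = "peak_eval")
}

#' @export
print.peak_eval <- function(x, ...) {
  cat(sprintf("<peak_eval> precision %.4f, recall %.4f, F %.4f (%d peaks / %d steps)\n",
              x$precision, x$recall, x$f_measure, x$n_peaks, x$n_annotated))
  invisible(x)
}
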