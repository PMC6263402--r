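#' Build a step interval table
#'
#' Steps are half-open sample intervals \code{[start, end)} with 0-based
#' indices. Detected steps additionally carry their provenance: the
#' 1-based index of the matched template, the component \code{k} (1..3 in
#' canonical order) whose correlation produced the match, and the
#' correlation score.
#'
#' @param start,end integer vectors, 0-based, \code{start < end}.
#' @param step_type character vector (recycled), see
#'   \code{\link{step_components}} for types.
#' @param template_index,component,score provenance columns for detected
#'   steps (NA for annotations).
#' @return A \code{data.frame} of class \code{step_intervals}, sorted as
#'   given, with columns \code{start}, \code{end}, \code{step_type},
#'   \code{template_index}, \code{component}, \code{score}.
#' @export
step_intervals <- function(start = integer(), end = integer(),
                           step_type = "unknown",
                           template_index = NA_integer_,
                           component = NA_integer_,
                           score = NA_real_) {
  n <- length(start)
  if (length(end) != n) stop("start and end must have equal length")
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0L)) stop("interval starts must be >= 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop("invalid interval at row ", bad, ": start (", start[bad],
         ") must be < end (", end[bad], ")")
  }
  step_type <- rep_len(as.character(step_type), n)
  unknown <- !step_type %in% STEP_TYPES
  if (any(unknown)) step_type[unknown] <- "unknown"
  df <- data.frame(start = start, end = end, step_type = step_type,
                   template_index = rep_len(as.integer(template_index), n),
                   component = rep_len(as.integer(component), n),
                   score = rep_len(as.numeric(score), n))
  class(df) <- c("step_intervals", "data.frame")
  df
}

#' Read step annotations from CSV
#'
#' Expects columns \code{start,end} and optionally \code{step_type};
#' indices are 0-based, intervals half-open. Rows with \code{start >= end}
#' raise an error naming the row; overlapping intervals only warn (real
#' annotations may abut or overlap slightly) and are kept.
#'
#' @param path annotations CSV path.
#' @return A \code{\link{step_intervals}} data frame (annotated kind).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotations file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("start", "end") %in% names(df)))
    stop("annotations must have columns start,end: ", path)
  st <- if ("step_type" %in% names(df)) df$step_type else "unknown"
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("invalid annotation at row ", bad[1], ": start >= end")
  out <- step_intervals(df$start, df$end, step_type = st)
  if (nrow(out) > 1L) {
    o <- order(out$start)
    s <- out$start[o]; e <- out$end[o]
    if (any(s[-1] < e[-length(e)]))
      warning("overlapping annotated intervals in ", path, " (kept)")
  }
  out
}

#' Write step annotations to CSV
#'
#' @param steps a \code{\link{step_intervals}} data frame.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_annotations <- function(steps, path) {
  utils::write.csv(steps[, c("start", "end", "step_type")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write detected steps to JSON
#'
#' Serializes a detection list losslessly (start, end, step_type,
#' template_index, component, score). Scores are written in full double
#' precision.
#'
#' @param steps a \code{\link{step_intervals}} data frame.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_detections <- function(steps, path) {
  recs <- lapply(seq_len(nrow(steps)), function(i) {
    list(start = steps$start[i], end = steps$end[i],
         step_type = steps$step_type[i],
         template_index = steps$template_index[i],
         component = steps$component[i],
         score = steps$score[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read detected steps from JSON
#'
#' Inverse of \code{\link{write_detections}}.
#'
#' @param path detections JSON path.
#' @return A \code{\link{step_intervals}} data frame.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("detections file not found: ", path)
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (length(recs) == 0L) return(step_intervals())
  g <- function(field, default) {
    vapply(recs, function(r) {
      v <- r[[field]]
      if (is.null(v)) default else as.vector(v, mode = typeof(default))
    }, default)
  }
  step_intervals(g("start", NA_real_), g("end", NA_real_),
                 step_type = g("step_type", NA_character_),
                 template_index = g("template_index", NA_real_),
                 component = g("component", NA_real_),
                 score = g("score", NA_real_))
}
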