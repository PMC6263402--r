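#' Construct a step recording
#'
#' A recording is a 3 x Nx numeric matrix of inertial samples (rows in the
#' canonical component order, see \code{\link{step_components}}) together
#' with its sampling rate. The sampling rate is metadata for the template
#' detector (whose thresholds are all expressed in samples) but is required
#' by the Pan-Tompkins baseline's bandpass filter.
#'
#' @param samples numeric 3 x Nx matrix, one row per component.
#' @param fs sampling rate in Hz (> 0).
#' @param id free-text identifier.
#' @return An object of class \code{step_recording} with elements
#'   \code{samples}, \code{fs}, \code{id}.
#' @export
step_recording <- function(samples, fs = 100, id = "recording") {
  samples <- as.matrix(samples)
  if (nrow(samples) != 3L)
    stop("a recording must have exactly 3 component rows, got ", nrow(samples))
  if (ncol(samples) < 1L)
    stop("empty recording: Nx must be >= 1")
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples)))
    stop("recording contains non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  rownames(samples) <- STEP_COMPONENTS
  structure(list(samples = samples, fs = as.numeric(fs), id = as.character(id)),
            class = "step_recording")
}

#' Number of samples in a recording or template
#'
#' @param x a \code{step_recording} or \code{step_template}.
#' @return Integer number of samples (Nx or Np).
#' @export
n_samples <- function(x) ncol(x$samples)

#' @export
print.step_recording <- function(x, ...) {
  cat(sprintf("<step_recording> '%s': %d samples @ %g Hz (%.2f s)\n",
              x$id, n_samples(x), x$fs, n_samples(x) / x$fs))
  invisible(x)
}

#' Read a recording from a delimited text file
#'
#' Reads a CSV with one sample per row and one column per component, and
#' reorders the mapped columns into the canonical component order. Rows
#' containing any missing value are dropped with a warning.
#'
#' @param path CSV file path (header row required).
#' @param column_map named character vector mapping canonical component
#'   names (\code{acc_z}, \code{acc_v}, \code{gyr_y}) to column names in
#'   the file. Defaults to identity.
#' @param fs sampling rate in Hz.
#' @param id recording identifier; defaults to the file name.
#' @return A \code{\link{step_recording}}.
#' @export
read_recording <- function(path,
                           column_map = stats::setNames(STEP_COMPONENTS, STEP_COMPONENTS),
                           fs = 100, id = NULL) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  column_map <- column_map[STEP_COMPONENTS]
  if (any(is.na(column_map)))
    stop("column_map must name all three components: ",
         paste(STEP_COMPONENTS, collapse = ", "))
  missing_cols <- setdiff(unname(column_map), names(df))
  if (length(missing_cols))
    stop("format error: column '", missing_cols[[1]], "' not found in ", path)
  if (nrow(df) == 0L) stop("empty recording: ", path, " has no data rows")
  cols <- lapply(unname(column_map), function(cn) {
    raw <- df[[cn]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & trimws(as.character(raw)) != "")
    if (length(bad))
      stop("parse error: non-numeric value in column '", cn, "' at data row ",
           bad[[1]])
    val
  })
  m <- do.call(rbind, cols)
  drop_rows <- which(apply(!is.finite(m), 2, any))
  if (length(drop_rows)) {
    warning(length(drop_rows), " row(s) with missing values dropped from ", path)
    m <- m[, -drop_rows, drop = FALSE]
  }
  if (ncol(m) == 0L) stop("empty recording: no complete rows in ", path)
  step_recording(m, fs = fs, id = if (is.null(id)) basename(path) else id)
}

#' Write a recording to CSV
#'
#' Inverse of \code{\link{read_recording}} with the identity column map:
#' one sample per row, canonical component names as header.
#'
#' @param x a \code{step_recording}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(x, path) {
  stopifnot(inherits(x, "step_recording"))
  df <- as.data.frame(t(x$samples))
  names(df) <- STEP_COMPONENTS
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
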