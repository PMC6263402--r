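#' Construct a step template
#'
#' A template is a short 3 x Np exemplar of one step, in the same canonical
#' component order as recordings. Per-component population standard
#' deviations are cached at construction (they renormalize every sliding
#' correlation window and feed the amplitude gate).
#'
#' @param samples numeric 3 x Np matrix (Np >= 2).
#' @param label free-text label (e.g. "healthy", "neurological").
#' @param step_type one of \code{normal}, \code{initiation},
#'   \code{termination}, \code{uturn}, \code{unknown}.
#' @return An object of class \code{step_template} with elements
#'   \code{samples}, \code{label}, \code{step_type} and \code{sd}
#'   (named per-component population standard deviations).
#' @export
step_template <- function(samples, label = "template", step_type = "unknown") {
  samples <- as.matrix(samples)
  if (nrow(samples) != 3L)
    stop("a template must have exactly 3 component rows, got ", nrow(samples))
  if (ncol(samples) < 2L)
    stop("template '", label, "' must have Np >= 2 samples")
  storage.mode(samples) <- "double"
  if (!all(is.finite(samples)))
    stop("template '", label, "' contains non-finite samples")
  step_type <- match.arg(step_type, STEP_TYPES)
  sds <- apply(samples, 1, pop_sd)
  if (any(sds == 0))
    stop("template '", label, "' rejected: component ",
         STEP_COMPONENTS[which(sds == 0)[1]], " has zero variance")
  rownames(samples) <- STEP_COMPONENTS
  structure(list(samples = samples, label = as.character(label),
                 step_type = step_type, sd = stats::setNames(sds, STEP_COMPONENTS)),
            class = "step_template")
}

#' @export
print.step_template <- function(x, ...) {
  cat(sprintf("<step_template> '%s' (%s): Np = %d\n",
              x$label, x$step_type, n_samples(x)))
  invisible(x)
}

#' Construct a template library
#'
#' An ordered collection of \code{\link{step_template}} objects. The order
#' is significant: the template index is the deterministic tie-break key in
#' greedy selection and the provenance recorded with each detection.
#'
#' @param templates list of \code{step_template} objects (>= 1).
#' @return An object of class \code{template_library}.
#' @export
template_library <- function(templates) {
  if (!is.list(templates) || length(templates) == 0L)
    stop("library must contain >= 1 template")
  ok <- vapply(templates, inherits, logical(1), what = "step_template")
  if (!all(ok)) stop("all elements must be step_template objects")
  structure(list(templates = templates), class = "template_library")
}

#' @export
length.template_library <- function(x) length(x$templates)

#' @export
`[[.template_library` <- function(x, i) x$templates[[i]]

#' @export
print.template_library <- function(x, ...) {
  lens <- vapply(x$templates, n_samples, integer(1))
  cat(sprintf("<template_library> %d templates, durations %d-%d samples\n",
              length(x), min(lens), max(lens)))
  invisible(x)
}

#' Template lengths
#'
#' @param library a \code{template_library}.
#' @return Integer vector of per-template durations Np, in library order.
#' @export
template_lengths <- function(library) {
  vapply(library$templates, n_samples, integer(1))
}

#' Read a template library from a JSON manifest
#'
#' The manifest lists template CSV files (paths relative to the manifest's
#' directory) with labels and step types:
#' \preformatted{
#' {"templates": [{"file": "t01.csv", "label": "healthy",
#'                 "step_type": "normal"}, ...]}
#' }
#' Each template file is a 3-column CSV in canonical component order.
#' Templates with a zero-variance component are rejected with an error
#' naming their label. Manifest order is preserved.
#'
#' @param manifest_path path to the manifest JSON.
#' @return A \code{\link{template_library}}.
#' @export
read_library <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::fromJSON(manifest_path, simplifyDataFrame = FALSE)
  entries <- man$templates
  if (is.null(entries) || length(entries) == 0L)
    stop("library must contain >= 1 template")
  base <- dirname(manifest_path)
  templates <- lapply(entries, function(e) {
    f <- file.path(base, e$file)
    if (!file.exists(f)) stop("template file not found: ", f)
    df <- utils::read.csv(f)
    if (ncol(df) < 3L)
      stop("template '", e$file, "' must have 3 columns, got ", ncol(df))
    m <- t(as.matrix(df[, 1:3]))
    step_template(m,
                  label = if (is.null(e$label)) e$file else e$label,
                  step_type = if (is.null(e$step_type)) "unknown" else e$step_type)
  })
  template_library(templates)
}

#' Write a template library to a directory
#'
#' Writes one CSV per template plus a \code{manifest.json} readable by
#' \code{\link{read_library}}.
#'
#' @param library a \code{template_library}.
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_library <- function(library, dir) {
  stopifnot(inherits(library, "template_library"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- lapply(seq_along(library$templates), function(i) {
    tpl <- library[[i]]
    fn <- sprintf("template_%03d.csv", i)
    df <- as.data.frame(t(tpl$samples))
    names(df) <- STEP_COMPONENTS
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     file.path(dir, fn), row.names = FALSE, quote = FALSE)
    list(file = fn, label = tpl$label, step_type = tpl$step_type)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(templates = entries), manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
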