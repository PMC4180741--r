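# Accessors and show methods for the core classes.

#' @describeIn Frame-class the intensity matrix.
#' @param object,x a `Frame`.
#' @export
setGeneric("frameData", function(object) standardGeneric("frameData"))
setMethod("frameData", "Frame", function(object) object@data)

#' @describeIn Frame-class the exclusion mask (TRUE = excluded).
#' @export
setGeneric("frameMask", function(object) standardGeneric("frameMask"))
setMethod("frameMask", "Frame", function(object) object@mask)

#' @describeIn Frame-class the per-pixel 1-sigma uncertainties.
#' @export
setGeneric("frameSigma", function(object) standardGeneric("frameSigma"))
setMethod("frameSigma", "Frame", function(object) object@sigma)

#' @describeIn Frame-class the monitor (incident-flux proxy).
#' @export
setGeneric("frameMonitor", function(object) standardGeneric("frameMonitor"))
setMethod("frameMonitor", "Frame", function(object) object@monitor)

#' @describeIn Frame-class the scan (motor) position vector.
#' @export
setGeneric("scanPosition", function(object) standardGeneric("scanPosition"))
setMethod("scanPosition", "Frame", function(object) object@scanPos)

#' @describeIn Frame-class descriptors of the corrections applied so far.
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
setMethod("provenance", "Frame", function(object) object@provenance)

setMethod("dim", "Frame", function(x) dim(x@data))

setMethod("show", "Frame", function(object) {
  d <- dim(object@data)
  cat(sprintf("Frame %d x %d px | monitor %.6g | %d px masked (%.1f%%)\n",
              d[1], d[2], object@monitor, sum(object@mask),
              100 * mean(object@mask)))
  if (length(object@scanPos))
    cat("  scan position:",
        paste(sprintf("%s=%.6g", names(object@scanPos), object@scanPos),
              collapse = ", "), "\n")
  if (nzchar(object@sourcePath))
    cat("  source:", object@sourcePath, "\n")
  if (length(object@provenance))
    cat("  corrections:", paste(object@provenance, collapse = " -> "), "\n")
})

setMethod("show", "ExperimentGeometry", function(object) {
  cat(sprintf(
    "ExperimentGeometry (%s)\n  wavelength %.5g nm | distance %.6g mm\n",
    object@mode, object@wavelength, object@distance))
  cat(sprintf("  beam center (%.3f, %.3f) px | pixel (%.4g, %.4g) mm\n",
              object@beamCenter[1], object@beamCenter[2],
              object@pixelSize[1], object@pixelSize[2]))
  if (object@mode == "grazing")
    cat(sprintf("  incidence %.4g deg\n", object@incidence))
})

setMethod("show", "QMap", function(object) {
  d <- dim(object@q)
  cat(sprintf("QMap %d x %d px (%s), q in [%.4g, %.4g] nm^-1\n",
              d[1], d[2], object@geometry@mode,
              min(object@q), max(object@q)))
})

#' @describeIn Curve-class bin abscissa.
#' @param object,x a `Curve`.
#' @export
setGeneric("curveX", function(object) standardGeneric("curveX"))
setMethod("curveX", "Curve", function(object) object@x)

#' @describeIn Curve-class mean intensity per bin.
#' @export
setGeneric("curveY", function(object) standardGeneric("curveY"))
setMethod("curveY", "Curve", function(object) object@y)

#' @describeIn Curve-class uncertainty of the bin mean.
#' @export
setGeneric("curveSigma", function(object) standardGeneric("curveSigma"))
setMethod("curveSigma", "Curve", function(object) object@sigma)

#' @describeIn Curve-class contributing-pixel count per bin.
#' @export
setGeneric("curveN", function(object) standardGeneric("curveN"))
setMethod("curveN", "Curve", function(object) object@nPix)

setMethod("length", "Curve", function(x) length(x@x))

setMethod("show", "Curve", function(object) {
  cat(sprintf("Curve (%s), %d bins, x in [%.5g, %.5g], %d empty\n",
              object@kind, length(object@x),
              if (length(object@x)) min(object@x) else NA,
              if (length(object@x)) max(object@x) else NA,
              sum(object@nPix == 0)))
})

#' Convert a Curve to a data.frame
#' @param x a [Curve-class].
#' @param row.names,optional,... passed through (unused).
#' @return data.frame with columns x, y, sigma, n_pix.
#' @export
as.data.frame.Curve <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(x = x@x, y = x@y, sigma = x@sigma, n_pix = x@nPix)
}
setMethod("as.data.frame", "Curve", as.data.frame.Curve)

#' @describeIn FitResult-class fitted parameter vector (ties applied).
#' @param object a `FitResult`.
#' @export
setGeneric("fitParameters", function(object) standardGeneric("fitParameters"))
setMethod("fitParameters", "FitResult", function(object) object@par)

#' @describeIn FitResult-class 1-sigma parameter uncertainties.
#' @export
setGeneric("fitStderr", function(object) standardGeneric("fitStderr"))
setMethod("fitStderr", "FitResult", function(object) object@stderr)

#' @describeIn FitResult-class TRUE if the optimizer converged.
#' @export
setGeneric("fitConverged", function(object) standardGeneric("fitConverged"))
setMethod("fitConverged", "FitResult", function(object) object@converged)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %s (red. chi^2 = %.5g, %d evals)\n",
              if (object@converged) "converged" else "NOT converged",
              object@redchi, object@nEval))
  p <- object@par; s <- object@stderr[names(p)]
  for (nm in names(p))
    cat(sprintf("  %-14s %12.6g +/- %.4g\n", nm, p[[nm]],
                if (is.na(s[[nm]])) NA_real_ else s[[nm]]))
})

setMethod("nrow", "DataTable", function(x) length(x@rows))
setMethod("ncol", "DataTable", function(x) length(x@colTypes))
setMethod("colnames", "DataTable", function(x) names(x@colTypes))

#' @describeIn DataTable-class declared column types.
#' @param object,x a `DataTable`.
#' @export
setGeneric("columnTypes", function(object) standardGeneric("columnTypes"))
setMethod("columnTypes", "DataTable", function(object) object@colTypes)

#' Append one row to a DataTable
#' @param table a [DataTable-class].
#' @param row named list of cells; cells must match declared column types,
#'   missing columns are filled with NA/NULL.
#' @return The table with the row appended.
#' @export
setGeneric("appendRow", function(table, row) standardGeneric("appendRow"))
setMethod("appendRow", "DataTable", function(table, row) {
  stopifnot(is.list(row))
  for (nm in names(row)) {
    if (!nm %in% names(table@colTypes))
      stop(sprintf("no declared column '%s'", nm))
    if (!.cellTypeOk(row[[nm]], table@colTypes[[nm]]))
      stop(sprintf("cell '%s' does not match declared type '%s'",
                   nm, table@colTypes[[nm]]))
  }
  table@rows[[length(table@rows) + 1L]] <- row
  table
})

#' Scalar/text view of a DataTable
#'
#' Returns the scalar, text and image-ref columns as a data.frame (curve
#' columns are dropped); the row order is processing order.
#' @param x a [DataTable-class].
#' @param row.names,optional,... passed through (unused).
#' @export
as.data.frame.DataTable <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  keep <- names(x@colTypes)[x@colTypes != "curve"]
  cols <- lapply(keep, function(nm) {
    vapply(x@rows, function(r) {
      v <- r[[nm]]
      if (is.null(v) || length(v) != 1) {
        if (x@colTypes[[nm]] == "scalar") NA_real_ else NA_character_
      } else v
    }, if (x@colTypes[[nm]] == "scalar") numeric(1) else character(1))
  })
  names(cols) <- keep
  as.data.frame(cols, optional = TRUE, check.names = FALSE)
}
setMethod("as.data.frame", "DataTable", as.data.frame.DataTable)

setMethod("show", "DataTable", function(object) {
  cat(sprintf("DataTable: %d rows x %d columns\n",
              length(object@rows), length(object@colTypes)))
  if (length(object@colTypes))
    cat(" ", paste(sprintf("%s<%s>", names(object@colTypes),
                           object@colTypes), collapse = ", "), "\n")
})

setMethod("show", "PluginDescriptor", function(object) {
  cat(sprintf("Plugin '%s' (%s): %d inputs -> %d outputs\n",
              object@name, object@category,
              length(object@inputs), length(object@outputs)))
})

setMethod("show", "PipelineGraph", function(object) {
  cat(sprintf("PipelineGraph with %d nodes: %s\n", length(object@nodes),
              paste(names(object@nodes), collapse = ", ")))
})
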