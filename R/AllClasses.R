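#' @import methods
NULL

#' Experiment geometry for a scattering setup
#'
#' Holds the calibration constants that map detector pixels to reciprocal
#' space: X-ray wavelength, sample-to-detector distance, direct-beam position,
#' pixel pitch, and (for grazing incidence) the incidence angle.
#'
#' Units are fixed across the package: wavelength in nm, distances in mm,
#' momentum transfer in nm^-1, angles in degrees. Pixel coordinates are
#' 0-based with the image origin at the top-left corner, x increasing along
#' columns and y along rows; "up" on the detector corresponds to decreasing
#' row index. The detector is assumed flat and orthogonal to the beam.
#' In grazing mode the beam centre is the direct-beam spot (not the specular
#' reflection).
#'
#' @slot wavelength X-ray wavelength, nm.
#' @slot distance sample-to-detector distance, mm.
#' @slot beamCenter numeric(2), direct-beam position (x0, y0) in pixels;
#'   fractional values allowed.
#' @slot pixelSize numeric(2), pixel pitch (px, py) in mm.
#' @slot incidence grazing incidence angle alpha_i, degrees (grazing mode).
#' @slot mode `"transmission"` or `"grazing"`.
#' @export
setClass("ExperimentGeometry",
  representation(
    wavelength = "numeric",
    distance   = "numeric",
    beamCenter = "numeric",
    pixelSize  = "numeric",
    incidence  = "numeric",
    mode       = "character"
  ),
  prototype(incidence = 0, mode = "transmission")
)

setValidity("ExperimentGeometry", function(object) {
  msg <- character()
  if (length(object@wavelength) != 1 || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive number (nm)")
  if (length(object@distance) != 1 || !is.finite(object@distance) ||
      object@distance <= 0)
    msg <- c(msg, "distance must be a single positive number (mm)")
  if (length(object@beamCenter) != 2 || any(!is.finite(object@beamCenter)))
    msg <- c(msg, "beamCenter must be two finite pixel coordinates (x0, y0)")
  if (length(object@pixelSize) != 2 || any(!is.finite(object@pixelSize)) ||
      any(object@pixelSize <= 0))
    msg <- c(msg, "pixelSize must be two positive numbers (mm)")
  if (!object@mode %in% c("transmission", "grazing"))
    msg <- c(msg, "mode must be 'transmission' or 'grazing'")
  if (object@mode == "grazing" &&
      (length(object@incidence) != 1 || !is.finite(object@incidence) ||
       object@incidence < 0))
    msg <- c(msg, "grazing mode requires incidence >= 0 (degrees)")
  if (length(msg)) msg else TRUE
})

#' Construct an ExperimentGeometry
#'
#' @param wavelength X-ray wavelength, nm.
#' @param distance sample-to-detector distance, mm.
#' @param beamCenter direct-beam position `c(x0, y0)`, pixels (0-based,
#'   fractional allowed).
#' @param pixelSize pixel pitch `c(px, py)`, mm; a scalar is recycled.
#' @param incidence grazing incidence angle, degrees; only used in grazing
#'   mode.
#' @param mode `"transmission"` (default) or `"grazing"`.
#' @return An [ExperimentGeometry-class] object.
#' @examples
#' geom <- experimentGeometry(wavelength = 0.1, distance = 1000,
#'                            beamCenter = c(63.5, 63.5), pixelSize = 0.5)
#' @export
experimentGeometry <- function(wavelength, distance, beamCenter,
                               pixelSize, incidence = 0,
                               mode = c("transmission", "grazing")) {
  mode <- match.arg(mode)
  if (length(pixelSize) == 1) pixelSize <- rep(pixelSize, 2)
  new("ExperimentGeometry",
      wavelength = as.numeric(wavelength),
      distance = as.numeric(distance),
      beamCenter = as.numeric(beamCenter),
      pixelSize = as.numeric(pixelSize),
      incidence = as.numeric(incidence),
      mode = mode)
}

#' Per-pixel reciprocal-space maps
#'
#' Element-wise maps from detector pixels to scattering coordinates:
#' modulus `q` and azimuth `chi` for every pixel, plus the in-plane /
#' out-of-plane components `qy`, `qz` in grazing mode. Built once per
#' geometry and detector shape with [buildQMap()] and reused across frames.
#'
#' @slot q per-pixel momentum-transfer modulus, nm^-1.
#' @slot chi per-pixel azimuth, degrees in [0, 360), counterclockwise from
#'   the +x detector axis.
#' @slot qy,qz grazing-mode in-plane and out-of-plane components, nm^-1
#'   (0 x 0 matrices in transmission mode).
#' @slot geometry the [ExperimentGeometry-class] the map was built from.
#' @export
setClass("QMap",
  representation(
    q = "matrix", chi = "matrix",
    qy = "matrix", qz = "matrix",
    geometry = "ExperimentGeometry"
  )
)

setValidity("QMap", function(object) {
  msg <- character()
  if (!identical(dim(object@q), dim(object@chi)))
    msg <- c(msg, "q and chi must have identical dimensions")
  if (any(object@q < 0, na.rm = TRUE))
    msg <- c(msg, "q must be non-negative everywhere")
  if (object@geometry@mode == "grazing" &&
      !identical(dim(object@q), dim(object@qy)))
    msg <- c(msg, "grazing mode requires qy/qz of the detector shape")
  if (length(msg)) msg else TRUE
})

#' A detector frame
#'
#' One 2-D detector exposure: the count array, a pixel mask, per-pixel
#' uncertainties, the incident-flux monitor, and optional scan metadata.
#' Corrections ([subtractBackground()], [normalizeMonitor()], [binPixels()])
#' return new frames with the applied step appended to `provenance`.
#'
#' The uncertainty model is Poisson counting statistics at read time,
#' sigma = sqrt(max(counts, 1)), propagated to first order by every
#' correction; it feeds the weighted least-squares fits downstream.
#'
#' @slot data 2-D intensity array (counts; may go negative after background
#'   subtraction).
#' @slot sigma per-pixel 1-sigma uncertainties, same shape.
#' @slot mask logical matrix, `TRUE` = pixel excluded from all statistics.
#' @slot monitor incident-flux proxy (scalar, > 0).
#' @slot exposure exposure time, s.
#' @slot scanPos named numeric of motor positions (may be empty).
#' @slot sourcePath originating file, or `""` for in-memory frames.
#' @slot provenance character vector of applied correction descriptors.
#' @export
setClass("Frame",
  representation(
    data = "matrix", sigma = "matrix", mask = "matrix",
    monitor = "numeric", exposure = "numeric",
    scanPos = "numeric", sourcePath = "character",
    provenance = "character"
  ),
  prototype(monitor = 1, exposure = 1, scanPos = numeric(),
            sourcePath = "", provenance = character())
)

setValidity("Frame", function(object) {
  msg <- character()
  if (!identical(dim(object@data), dim(object@mask)))
    msg <- c(msg, "data and mask must have identical shapes")
  if (!identical(dim(object@data), dim(object@sigma)))
    msg <- c(msg, "data and sigma must have identical shapes")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical (TRUE = excluded)")
  if (length(object@monitor) != 1 || !is.finite(object@monitor) ||
      object@monitor <= 0)
    msg <- c(msg, "monitor must be a single positive number")
  if (length(object@data) > 0 && all(object@mask))
    msg <- c(msg, "fully masked frame (masked fraction must be < 1)")
  if (any(object@sigma < 0, na.rm = TRUE))
    msg <- c(msg, "sigma must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a detector Frame
#'
#' @param data numeric matrix of intensities (rows = detector rows).
#' @param mask logical (or 0/1) matrix, nonzero/`TRUE` = excluded; defaults
#'   to nothing excluded.
#' @param sigma per-pixel uncertainties; defaults to the Poisson estimate
#'   `sqrt(pmax(data, 1))`.
#' @param monitor incident-flux proxy, > 0.
#' @param exposure exposure time, s.
#' @param scanPos named numeric of motor positions.
#' @param sourcePath originating file path.
#' @return A [Frame-class].
#' @export
detectorFrame <- function(data, mask = NULL, sigma = NULL, monitor = 1,
                          exposure = 1, scanPos = numeric(),
                          sourcePath = "") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(data), ncol(data))
  } else {
    mask <- as.matrix(mask)
    if (!is.logical(mask)) mask <- mask != 0
  }
  if (is.null(sigma)) sigma <- sqrt(pmax(data, 1))
  new("Frame", data = data, sigma = as.matrix(sigma), mask = mask,
      monitor = as.numeric(monitor), exposure = as.numeric(exposure),
      scanPos = scanPos, sourcePath = sourcePath,
      provenance = character())
}

#' A 1-D reduced profile
#'
#' The result of radial/azimuthal integration or a GISAXS line cut: bin
#' abscissa, mean intensity per bin, propagated uncertainty, and the number
#' of contributing pixels. Bins with no contributing pixels carry `NaN`
#' intensity (not zero), so fits can drop them.
#'
#' @slot x bin abscissa (q in nm^-1, qy/qz in nm^-1, or chi in degrees);
#'   strictly increasing.
#' @slot y mean intensity per bin (`NaN` where empty).
#' @slot sigma uncertainty of the bin mean.
#' @slot nPix number of contributing (unmasked, in-range) pixels per bin.
#' @slot kind `"radial"`, `"azimuthal"` or `"cut"`.
#' @export
setClass("Curve",
  representation(
    x = "numeric", y = "numeric", sigma = "numeric",
    nPix = "numeric", kind = "character"
  ),
  prototype(kind = "radial")
)

setValidity("Curve", function(object) {
  msg <- character()
  n <- length(object@x)
  if (length(object@y) != n || length(object@sigma) != n ||
      length(object@nPix) != n)
    msg <- c(msg, "x, y, sigma and nPix must have equal lengths")
  if (n > 1 && any(diff(object@x) <= 0))
    msg <- c(msg, "x must be strictly increasing")
  if (any(object@nPix < 0))
    msg <- c(msg, "nPix must be non-negative")
  if (any(object@nPix == 0 & is.finite(object@y)))
    msg <- c(msg, "bins with nPix = 0 must carry NaN intensity")
  if (length(msg)) msg else TRUE
})

#' Construct a Curve
#' @param x,y,sigma,nPix equal-length numeric vectors (see [Curve-class]).
#' @param kind `"radial"`, `"azimuthal"` or `"cut"`.
#' @return A [Curve-class].
#' @export
scatterCurve <- function(x, y, sigma = rep(NA_real_, length(x)),
                         nPix = rep(1, length(x)),
                         kind = c("radial", "azimuthal", "cut")) {
  kind <- match.arg(kind)
  new("Curve", x = as.numeric(x), y = as.numeric(y),
      sigma = as.numeric(sigma), nPix = as.numeric(nPix), kind = kind)
}

#' A composite peak model
#'
#' An arbitrary sum of Gaussian, Lorentzian and pseudo-Voigt peaks on a
#' background (constant, linear, quadratic or power-law). Peaks are
#' parameterised by amplitude (peak height), centre, and full width at half
#' maximum; the pseudo-Voigt adds a mixing parameter eta in [0, 1]
#' (eta = 0 reduces to Gaussian, eta = 1 to Lorentzian, amplitude/centre/
#' width shared).
#'
#' Parameters may be tied to each other (e.g. the second peak centre fixed
#' 180 degrees above the first) via `ties`; tied parameters are eliminated
#' from the fit. An optional `period` wraps all peaks cyclically — used for
#' azimuthal profiles, where a peak near 0/360 degrees must reappear on the
#' other side.
#'
#' @slot peaks list of components, each
#'   `list(shape =, amplitude =, center =, fwhm =, eta =)`.
#' @slot background `list(type =, coef =)` with `type` one of
#'   `"constant"`, `"linear"`, `"quadratic"`, `"power"`.
#' @slot ties list of `list(target =, source =, scale =, offset =)` linear
#'   parameter ties (`target = scale * source + offset`).
#' @slot period wrap period for cyclic abscissae (numeric(0) = none).
#' @export
setClass("PeakModel",
  representation(
    peaks = "list", background = "list", ties = "list", period = "numeric"
  ),
  prototype(ties = list(), period = numeric())
)

setValidity("PeakModel", function(object) {
  msg <- character()
  for (p in object@peaks) {
    if (!p$shape %in% c("gaussian", "lorentzian", "pseudo_voigt"))
      msg <- c(msg, sprintf("unknown peak shape '%s'", p$shape))
    if (!is.null(p$fwhm) && is.finite(p$fwhm) && p$fwhm <= 0)
      msg <- c(msg, "peak fwhm must be > 0")
    if (identical(p$shape, "pseudo_voigt") &&
        (is.null(p$eta) || p$eta < 0 || p$eta > 1))
      msg <- c(msg, "pseudo-Voigt mixing eta must lie in [0, 1]")
  }
  bt <- object@background$type
  if (!is.null(bt) && !bt %in% c("constant", "linear", "quadratic", "power"))
    msg <- c(msg, sprintf("unknown background type '%s'", bt))
  pn <- peakParamNames(object)
  for (t in object@ties) {
    if (!all(c(t$target, t$source) %in% pn))
      msg <- c(msg, sprintf("tie references unknown parameter '%s' or '%s'",
                            t$target, t$source))
  }
  if (length(msg)) msg else TRUE
})

#' Result of a least-squares peak fit
#'
#' Fitted parameter values with 1-sigma uncertainties, the reduced
#' chi-square, and a convergence flag. Non-convergence is data, not an
#' error: series processing continues and flags the frame.
#'
#' @slot par named numeric of all model parameters (ties applied).
#' @slot stderr named numeric of 1-sigma uncertainties (NA where not
#'   determined).
#' @slot redchi reduced chi-square of the weighted residuals.
#' @slot converged logical convergence flag.
#' @slot nEval number of function evaluations / iterations used.
#' @slot message optimizer status message.
#' @slot model the [PeakModel-class] with fitted values substituted.
#' @export
setClass("FitResult",
  representation(
    par = "numeric", stderr = "numeric", redchi = "numeric",
    converged = "logical", nEval = "integer", message = "character",
    model = "PeakModel"
  )
)

setValidity("FitResult", function(object) {
  if (object@converged && any(object@stderr < 0, na.rm = TRUE))
    return("uncertainties must be >= 0 when converged")
  TRUE
})

#' The framework's typed result table
#'
#' A table-like database accumulating one row per processed data set. Each
#' column has a declared type from `{scalar, curve, image-ref, text}`;
#' columns correspond to plug-in outputs (namespaced `node.output`), rows to
#' data sets in processing order. Images are stored as path references,
#' never as pixels.
#'
#' @slot colTypes named character, column name -> declared type.
#' @slot rows list of named lists; each cell must match its column type.
#' @export
setClass("DataTable",
  representation(colTypes = "character", rows = "list"),
  prototype(colTypes = character(), rows = list())
)

.cellTypeOk <- function(value, type) {
  if (is.null(value)) return(TRUE)   # failed plug-in: empty cell
  switch(type,
    scalar = is.numeric(value) && length(value) == 1,
    curve = is(value, "Curve") || (length(value) == 1 && is.na(value)),
    `image-ref` = is.character(value) && length(value) == 1,
    text = is.character(value) && length(value) == 1,
    FALSE)
}

setValidity("DataTable", function(object) {
  msg <- character()
  tn <- names(object@colTypes)
  if (length(tn) != length(unique(tn)))
    msg <- c(msg, "column names must be unique")
  bad <- setdiff(object@colTypes, c("scalar", "curve", "image-ref", "text"))
  if (length(bad))
    msg <- c(msg, paste("unknown column type:", paste(bad, collapse = ", ")))
  for (r in object@rows) {
    for (nm in names(r)) {
      if (!nm %in% tn) {
        msg <- c(msg, sprintf("cell '%s' has no declared column", nm))
      } else if (!.cellTypeOk(r[[nm]], object@colTypes[[nm]])) {
        msg <- c(msg, sprintf("cell '%s' does not match type '%s'",
                              nm, object@colTypes[[nm]]))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an empty DataTable
#' @param colTypes named character, column name -> type in
#'   `{scalar, curve, image-ref, text}`.
#' @return A [DataTable-class] with zero rows.
#' @export
dataTable <- function(colTypes = character()) {
  new("DataTable", colTypes = colTypes, rows = list())
}

#' A plug-in descriptor
#'
#' Declares a processing unit for the pipeline: its configuration
#' parameters, typed inputs and outputs, and the function implementing it.
#' Base plug-ins read or derive data; export plug-ins write table contents
#' to files.
#'
#' @slot name unique plug-in name.
#' @slot category `"base"` or `"export"`.
#' @slot parameters list of `list(name =, type =, default =)` exposed to
#'   configuration.
#' @slot inputs named character, input port -> type.
#' @slot outputs named character, output port -> type (names unique).
#' @slot fun `function(inputs, params)` returning a named list matching
#'   `outputs`.
#' @export
setClass("PluginDescriptor",
  representation(
    name = "character", category = "character", parameters = "list",
    inputs = "character", outputs = "character", fun = "function"
  ),
  prototype(category = "base", parameters = list())
)

setValidity("PluginDescriptor", function(object) {
  msg <- character()
  if (length(object@name) != 1 || !nzchar(object@name))
    msg <- c(msg, "plug-in needs a non-empty name")
  if (!object@category %in% c("base", "export"))
    msg <- c(msg, "category must be 'base' or 'export'")
  allTypes <- c("scalar", "curve", "image-ref", "text")
  if (length(object@outputs) &&
      (is.null(names(object@outputs)) ||
       anyDuplicated(names(object@outputs))))
    msg <- c(msg, "output names must be present and unique")
  if (!all(object@outputs %in% allTypes))
    msg <- c(msg, "output types must be scalar/curve/image-ref/text")
  if (!all(object@inputs %in% allTypes))
    msg <- c(msg, "input types must be scalar/curve/image-ref/text")
  if (length(msg)) msg else TRUE
})

#' Construct a plug-in descriptor
#' @param name unique plug-in name.
#' @param fun `function(inputs, params)` -> named list matching `outputs`.
#' @param inputs,outputs named character vectors, port -> type
#'   (`scalar`, `curve`, `image-ref`, `text`).
#' @param parameters list of `list(name =, type =, default =)`.
#' @param category `"base"` or `"export"`.
#' @return A [PluginDescriptor-class].
#' @export
scatterPlugin <- function(name, fun, inputs = character(),
                          outputs = character(), parameters = list(),
                          category = c("base", "export")) {
  new("PluginDescriptor", name = name, category = match.arg(category),
      parameters = parameters, inputs = inputs, outputs = outputs,
      fun = fun)
}

#' A validated wiring of plug-ins
#'
#' Nodes are named plug-in instances with bound parameters; each input port
#' is wired to an upstream `node.output` reference (or to the per-dataset
#' `source.path`). The wiring must be acyclic and type-consistent; see
#' [validateGraph()].
#'
#' @slot nodes named list of
#'   `list(plugin = <name>, params = <list>, inputs = <named character>)`.
#' @export
setClass("PipelineGraph", representation(nodes = "list"))

#' Construct a pipeline graph
#' @param nodes named list; each element
#'   `list(plugin =, params = list(), inputs = c(port = "node.output"))`.
#'   The reserved reference `"source.path"` (type text) denotes the
#'   per-dataset file path.
#' @return A [PipelineGraph-class] (unvalidated; see [validateGraph()]).
#' @export
pipelineGraph <- function(nodes) {
  stopifnot(is.list(nodes), !is.null(names(nodes)), all(nzchar(names(nodes))))
  new("PipelineGraph", nodes = nodes)
}
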