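# Built-in plug-ins: frame reading, ROI statistics, integrations, cuts,
# and the bone T/rho analyses. User plug-ins are added via
# discoverPlugins(); see scatterPlugin() for the descriptor contract.

.needGeometry <- function(params) {
  g <- params$geometry
  if (is.null(g)) stop("plug-in parameter 'geometry' is required")
  if (!is(g, "ExperimentGeometry")) stop("'geometry' must be an ExperimentGeometry")
  g
}

#' Built-in plug-in registry
#'
#' The base plug-ins shipped with the package:
#' \describe{
#'   \item{reader}{reads a detector frame from `source.path`; parameters
#'     `mask` (logical matrix), `normalizeMonitor` (flag).}
#'   \item{roi_stats}{min/max/average/sum of a rectangular pixel region;
#'     parameters `x`, `y`, `width`, `height`.}
#'   \item{radial_profile}{azimuthally averaged I(q); parameters
#'     `geometry`, `qBreaks`, optional `chiRange`.}
#'   \item{azimuthal_profile}{I(chi) over an annulus; parameters
#'     `geometry`, `qRange`, `chiBreaks`.}
#'   \item{gisaxs_cut}{horizontal/vertical/arbitrary line cut; parameters
#'     `geometry`, `direction`, `at`, `roiWidth`, `angle`, `reduce`.}
#'   \item{porod_t}{Porod fit + invariant + T parameter from a radial
#'     curve; parameter `qFitRange`.}
#'   \item{rho}{degree-of-alignment rho, peak centre and predominant
#'     orientation from an azimuthal curve.}
#'   \item{roi_average}{average intensity of a q-space annulus sector,
#'     for orientation-selective scan maps; parameters `geometry`,
#'     `qRange`, `chiRange`.}
#' }
#' @return named list of [PluginDescriptor-class] objects.
#' @export
builtinPlugins <- function() {
  regs <- list(
    scatterPlugin(
      "reader",
      function(inputs, params) {
        fr <- readFrame(inputs$path)
        if (!is.null(params$mask)) fr@mask <- fr@mask | params$mask
        if (isTRUE(params$normalizeMonitor)) fr <- normalizeMonitor(fr)
        list(frame = fr)
      },
      inputs = c(path = "text"), outputs = c(frame = "image-ref"),
      parameters = list(
        list(name = "mask", type = "image-ref", default = NULL),
        list(name = "normalizeMonitor", type = "scalar", default = FALSE))),
    scatterPlugin(
      "roi_stats",
      function(inputs, params) {
        st <- roiStats(inputs$frame, params$x, params$y,
                       params$width, params$height)
        st[c("min", "max", "average", "sum")]
      },
      inputs = c(frame = "image-ref"),
      outputs = c(min = "scalar", max = "scalar", average = "scalar",
                  sum = "scalar"),
      parameters = list(
        list(name = "x", type = "scalar", default = 0),
        list(name = "y", type = "scalar", default = 0),
        list(name = "width", type = "scalar", default = 10),
        list(name = "height", type = "scalar", default = 10))),
    scatterPlugin(
      "radial_profile",
      function(inputs, params) {
        geom <- .needGeometry(params)
        qmap <- buildQMap(dim(inputs$frame), geom)
        list(curve = radialProfile(inputs$frame, qmap, params$qBreaks,
                                   chiRange = params$chiRange))
      },
      inputs = c(frame = "image-ref"), outputs = c(curve = "curve"),
      parameters = list(
        list(name = "geometry", type = "text", default = NULL),
        list(name = "qBreaks", type = "curve", default = NULL),
        list(name = "chiRange", type = "curve", default = NULL))),
    scatterPlugin(
      "azimuthal_profile",
      function(inputs, params) {
        geom <- .needGeometry(params)
        qmap <- buildQMap(dim(inputs$frame), geom)
        list(curve = azimuthalProfile(inputs$frame, qmap, params$qRange,
                                      params$chiBreaks %||%
                                        seq(0, 360, by = 5)))
      },
      inputs = c(frame = "image-ref"), outputs = c(curve = "curve"),
      parameters = list(
        list(name = "geometry", type = "text", default = NULL),
        list(name = "qRange", type = "curve", default = NULL),
        list(name = "chiBreaks", type = "curve", default = NULL))),
    scatterPlugin(
      "gisaxs_cut",
      function(inputs, params) {
        geom <- .needGeometry(params)
        qmap <- buildQMap(dim(inputs$frame), geom)
        list(curve = gisaxsCut(inputs$frame, qmap,
                               direction = params$direction %||%
                                 "horizontal",
                               at = params$at %||% 0,
                               roiWidth = params$roiWidth,
                               angle = params$angle,
                               reduce = params$reduce %||% "mean"))
      },
      inputs = c(frame = "image-ref"), outputs = c(curve = "curve"),
      parameters = list(
        list(name = "geometry", type = "text", default = NULL),
        list(name = "direction", type = "text", default = "horizontal"),
        list(name = "at", type = "scalar", default = 0),
        list(name = "roiWidth", type = "scalar", default = NULL))),
    scatterPlugin(
      "porod_t",
      function(inputs, params) {
        res <- boneTParameter(inputs$curve, params$qFitRange)
        list(T = res$T, J = res$J, P = res$P, B = res$B)
      },
      inputs = c(curve = "curve"),
      outputs = c(T = "scalar", J = "scalar", P = "scalar", B = "scalar"),
      parameters = list(
        list(name = "qFitRange", type = "curve", default = NULL))),
    scatterPlugin(
      "rho",
      function(inputs, params) {
        res <- rhoParameter(inputs$curve)
        list(rho = res$rho, chi0 = res$chi0,
             orientation = res$orientation)
      },
      inputs = c(curve = "curve"),
      outputs = c(rho = "scalar", chi0 = "scalar",
                  orientation = "scalar")),
    scatterPlugin(
      "roi_average",
      function(inputs, params) {
        geom <- .needGeometry(params)
        qmap <- buildQMap(dim(inputs$frame), geom)
        sel <- qmap@q >= params$qRange[1] & qmap@q <= params$qRange[2] &
          !frameMask(inputs$frame)
        if (!is.null(params$chiRange))
          sel <- sel & .inChiRange(qmap@chi, params$chiRange)
        if (!any(sel)) stop("empty q/chi selection")
        list(average = mean(frameData(inputs$frame)[sel]))
      },
      inputs = c(frame = "image-ref"), outputs = c(average = "scalar"),
      parameters = list(
        list(name = "geometry", type = "text", default = NULL),
        list(name = "qRange", type = "curve", default = NULL),
        list(name = "chiRange", type = "curve", default = NULL)))
  )
  names(regs) <- vapply(regs, function(p) p@name, character(1))
  regs
}

#' Build geometry and pipeline from a config list
#'
#' The config (typically YAML) has a `geometry` block
#' (`wavelength_nm`, `distance_mm`, `beam_center_px`, `pixel_size_mm`,
#' `incidence_deg`, `mode`) and a `pipeline` block: a named map of nodes,
#' each with `plugin`, optional `params`, and `inputs`
#' (port -> `node.output` reference). The geometry object is injected
#' into every node's params as `geometry`.
#'
#' @param config named list, e.g. from `yaml::read_yaml()`.
#' @param path a YAML config file (for `readPipelineConfig`).
#' @return list with `geometry` and `graph`.
#' @export
pipelineFromConfig <- function(config) {
  g <- config$geometry
  geom <- NULL
  if (!is.null(g)) {
    geom <- experimentGeometry(
      wavelength = g$wavelength_nm, distance = g$distance_mm,
      beamCenter = unlist(g$beam_center_px),
      pixelSize = unlist(g$pixel_size_mm),
      incidence = g$incidence_deg %||% 0,
      mode = g$mode %||% "transmission")
  }
  graph <- NULL
  if (!is.null(config$pipeline)) {
    nodes <- lapply(config$pipeline, function(nd) {
      params <- nd$params %||% list()
      # YAML 1.1 reads the bare keys y/n as booleans; map them back
      names(params)[names(params) == "TRUE"] <- "y"
      names(params)[names(params) == "FALSE"] <- "n"
      for (nm in names(params))
        if (is.list(params[[nm]]) && is.null(names(params[[nm]])))
          params[[nm]] <- unlist(params[[nm]])
      if (!is.null(geom)) params$geometry <- geom
      list(plugin = nd$plugin, params = params,
           inputs = unlist(nd$inputs) %||% character())
    })
    graph <- pipelineGraph(nodes)
  }
  list(geometry = geom, graph = graph)
}

#' @rdname pipelineFromConfig
#' @export
readPipelineConfig <- function(path) {
  pipelineFromConfig(yaml::read_yaml(path))
}
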