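# Composite peak models and deterministic weighted least-squares fitting.
#
# Peak parameterisation (amplitude = peak height, w = FWHM):
#   Gaussian    A * exp(-4 ln2 (x - x0)^2 / w^2)
#   Lorentzian  A * (w/2)^2 / ((x - x0)^2 + (w/2)^2)
#   pseudo-Voigt eta * L + (1 - eta) * G, shared A, x0, w (the common
#   powder-diffraction form).
# Closed-form areas: Gaussian A*w*sqrt(pi / (4 ln2)); Lorentzian A*w*pi/2.

#' Peak component constructors
#'
#' Build one component of a [PeakModel-class]. `amplitude` is the peak
#' height, `center` the position, `fwhm` the full width at half maximum;
#' the pseudo-Voigt mixing `eta` interpolates between the Gaussian
#' (`eta = 0`) and Lorentzian (`eta = 1`) limits.
#'
#' @param amplitude peak height (>= 0 in a physical model).
#' @param center peak position (same units as the fitted abscissa).
#' @param fwhm full width at half maximum, > 0.
#' @param eta pseudo-Voigt mixing parameter in [0, 1].
#' @return a component list for [peakModel()].
#' @export
gaussianPeak <- function(amplitude, center, fwhm)
  list(shape = "gaussian", amplitude = amplitude, center = center,
       fwhm = fwhm)

#' @rdname gaussianPeak
#' @export
lorentzianPeak <- function(amplitude, center, fwhm)
  list(shape = "lorentzian", amplitude = amplitude, center = center,
       fwhm = fwhm)

#' @rdname gaussianPeak
#' @export
pseudoVoigtPeak <- function(amplitude, center, fwhm, eta = 0.5)
  list(shape = "pseudo_voigt", amplitude = amplitude, center = center,
       fwhm = fwhm, eta = eta)

#' Assemble a composite peak model
#'
#' @param peaks list of components from [gaussianPeak()],
#'   [lorentzianPeak()], [pseudoVoigtPeak()].
#' @param background `list(type =, coef =)`; types `"constant"` (coef c0),
#'   `"linear"` (c0, c1), `"quadratic"` (c0, c1, c2), `"power"`
#'   (amplitude, exponent: c0 * x^c1).
#' @param ties list of linear parameter ties
#'   `list(target =, source =, scale = 1, offset = 0)`, e.g. the second
#'   peak centre fixed 180 degrees above the first:
#'   `list(target = "p2.center", source = "p1.center", offset = 180)`.
#' @param period optional wrap period for cyclic abscissae (e.g. 360 for
#'   azimuthal profiles): every peak is evaluated also at +/- one period.
#' @return A [PeakModel-class].
#' @export
peakModel <- function(peaks, background = list(type = "constant", coef = 0),
                      ties = list(), period = numeric()) {
  ties <- lapply(ties, function(t) {
    if (is.null(t$scale)) t$scale <- 1
    if (is.null(t$offset)) t$offset <- 0
    t
  })
  new("PeakModel", peaks = peaks, background = background, ties = ties,
      period = as.numeric(period))
}

.bgNCoef <- c(constant = 1L, linear = 2L, quadratic = 3L, power = 2L)

# flat named parameter vector of a model
peakParamNames <- function(model) {
  nm <- character()
  for (i in seq_along(model@peaks)) {
    p <- model@peaks[[i]]
    base <- sprintf("p%d", i)
    nm <- c(nm, paste0(base, c(".amplitude", ".center", ".fwhm")))
    if (p$shape == "pseudo_voigt") nm <- c(nm, paste0(base, ".eta"))
  }
  bt <- model@background$type
  if (!is.null(bt))
    nm <- c(nm, paste0("bg.c", seq_len(.bgNCoef[[bt]]) - 1L))
  nm
}

modelParamVector <- function(model) {
  v <- numeric()
  for (i in seq_along(model@peaks)) {
    p <- model@peaks[[i]]
    base <- sprintf("p%d", i)
    v[paste0(base, ".amplitude")] <- p$amplitude
    v[paste0(base, ".center")] <- p$center
    v[paste0(base, ".fwhm")] <- p$fwhm
    if (p$shape == "pseudo_voigt") v[paste0(base, ".eta")] <- p$eta
  }
  bt <- model@background$type
  if (!is.null(bt)) {
    coef <- rep(0, .bgNCoef[[bt]])
    coef[seq_along(model@background$coef)] <- model@background$coef
    v[paste0("bg.c", seq_along(coef) - 1L)] <- coef
  }
  v
}

applyTies <- function(par, ties) {
  for (t in ties) par[[t$target]] <- t$scale * par[[t$source]] + t$offset
  par
}

modelWithParams <- function(model, par) {
  for (i in seq_along(model@peaks)) {
    base <- sprintf("p%d", i)
    model@peaks[[i]]$amplitude <- par[[paste0(base, ".amplitude")]]
    model@peaks[[i]]$center <- par[[paste0(base, ".center")]]
    model@peaks[[i]]$fwhm <- par[[paste0(base, ".fwhm")]]
    if (model@peaks[[i]]$shape == "pseudo_voigt")
      model@peaks[[i]]$eta <- par[[paste0(base, ".eta")]]
  }
  bt <- model@background$type
  if (!is.null(bt))
    model@background$coef <-
      unname(par[paste0("bg.c", seq_len(.bgNCoef[[bt]]) - 1L)])
  model
}

.peakShape <- function(shape, x, A, x0, w, eta = 0) {
  g <- A * exp(-4 * log(2) * (x - x0)^2 / w^2)
  if (shape == "gaussian") return(g)
  l <- A * (w / 2)^2 / ((x - x0)^2 + (w / 2)^2)
  if (shape == "lorentzian") return(l)
  eta * l + (1 - eta) * g
}

#' Evaluate a peak model
#'
#' Sums all peak components and the background at the given abscissae.
#' With a `period` set, each peak is also evaluated shifted by +/- one
#' period (cyclic wrap, adequate for widths well below the period).
#'
#' @param model a [PeakModel-class].
#' @param x numeric abscissae.
#' @param par optional named parameter vector overriding the model values
#'   (ties are applied first).
#' @return numeric vector of model intensities.
#' @export
evaluatePeakModel <- function(model, x, par = NULL) {
  if (is.null(par)) par <- modelParamVector(model)
  par <- applyTies(par, model@ties)
  y <- numeric(length(x))
  shifts <- if (length(model@period))
    c(-model@period, 0, model@period) else 0
  for (i in seq_along(model@peaks)) {
    p <- model@peaks[[i]]
    base <- sprintf("p%d", i)
    A <- par[[paste0(base, ".amplitude")]]
    x0 <- par[[paste0(base, ".center")]]
    w <- par[[paste0(base, ".fwhm")]]
    eta <- if (p$shape == "pseudo_voigt") par[[paste0(base, ".eta")]] else 0
    for (s in shifts)
      y <- y + .peakShape(p$shape, x, A, x0 + s, w, eta)
  }
  bt <- model@background$type
  if (!is.null(bt)) {
    cf <- par[paste0("bg.c", seq_len(.bgNCoef[[bt]]) - 1L)]
    y <- y + switch(bt,
      constant = cf[[1]],
      linear = cf[[1]] + cf[[2]] * x,
      quadratic = cf[[1]] + cf[[2]] * x + cf[[3]] * x^2,
      power = cf[[1]] * x^cf[[2]])
  }
  y
}

#' Closed-form area of one peak component
#'
#' Gaussian area `A w sqrt(pi/(4 ln 2))`; Lorentzian area `A w pi / 2`;
#' pseudo-Voigt the eta-weighted combination.
#' @param shape `"gaussian"`, `"lorentzian"` or `"pseudo_voigt"`.
#' @param amplitude,fwhm,eta peak parameters.
#' @return the integrated peak area.
#' @export
peakArea <- function(shape, amplitude, fwhm, eta = 0) {
  ga <- amplitude * fwhm * sqrt(pi / (4 * log(2)))
  la <- amplitude * fwhm * pi / 2
  switch(shape, gaussian = ga, lorentzian = la,
         pseudo_voigt = eta * la + (1 - eta) * ga,
         stop("unknown shape"))
}

#' Fit a composite peak model to a curve
#'
#' Deterministic weighted least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}): residuals `(y - f(x)) / sigma` with weights
#' `1/sigma^2`, unit weights where sigma is absent or non-positive.
#' NaN bins are dropped. Parameter ties are eliminated before optimization
#' and re-applied to the result; box bounds are honoured. Non-convergence
#' does not raise: the returned [FitResult-class] carries
#' `converged = FALSE` with the inputs echoed, so series processing can
#' continue.
#'
#' @param curve a [Curve-class] (or list/data.frame with x, y, optional
#'   sigma).
#' @param model a [PeakModel-class] holding the initial values.
#' @param lower,upper optional named bound vectors (entries for any subset
#'   of the free parameters). Initial values outside the bounds are an
#'   error, raised before optimization.
#' @param maxIter maximum optimizer iterations.
#' @return A [FitResult-class].
#' @export
fitCurve <- function(curve, model, lower = NULL, upper = NULL,
                     maxIter = 200) {
  if (is(curve, "Curve")) {
    x <- curve@x; y <- curve@y; sigma <- curve@sigma
  } else {
    x <- curve$x; y <- curve$y
    sigma <- if (!is.null(curve$sigma)) curve$sigma else
      rep(NA_real_, length(x))
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; sigma <- sigma[keep]
  w <- ifelse(is.finite(sigma) & sigma > 0, 1 / sigma, 1)

  init <- modelParamVector(model)
  tied <- vapply(model@ties, `[[`, character(1), "target")
  free <- setdiff(names(init), tied)
  if (length(x) <= length(free))
    stop("fewer finite data points than free parameters")

  lo <- rep(-Inf, length(free)); names(lo) <- free
  hi <- rep(Inf, length(free)); names(hi) <- free
  if (!is.null(lower)) lo[intersect(names(lower), free)] <-
      lower[intersect(names(lower), free)]
  if (!is.null(upper)) hi[intersect(names(upper), free)] <-
      upper[intersect(names(upper), free)]
  if (any(init[free] < lo | init[free] > hi))
    stop("initial parameter values lie outside the stated bounds")

  resid <- function(p) {
    full <- init
    full[free] <- p
    (y - evaluatePeakModel(model, x, full)) * w
  }

  failure <- function(msg) {
    new("FitResult", par = applyTies(init, model@ties),
        stderr = setNames(rep(NA_real_, length(init)), names(init)),
        redchi = NA_real_, converged = FALSE, nEval = 0L,
        message = msg, model = model)
  }

  res <- tryCatch(
    minpack.lm::nls.lm(par = init[free], fn = resid, lower = lo, upper = hi,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxIter)),
    error = function(e) NULL)
  if (is.null(res)) return(failure("optimizer error"))

  full <- init
  full[free] <- res$par
  full <- applyTies(full, model@ties)
  dof <- max(length(x) - length(free), 1)
  redchi <- sum(res$fvec^2) / dof
  converged <- res$info %in% c(1, 2, 3)

  # 1-sigma uncertainties from the local curvature, scaled by red. chi^2
  se <- setNames(rep(NA_real_, length(init)), names(init))
  cov <- tryCatch(solve(res$hessian), error = function(e) NULL)
  if (!is.null(cov)) {
    dg <- diag(cov)
    dg[dg < 0] <- NA_real_
    se[free] <- sqrt(dg * redchi)
  }
  for (t in model@ties) se[[t$target]] <- abs(t$scale) * se[[t$source]]

  new("FitResult", par = full, stderr = se, redchi = redchi,
      converged = converged, nEval = as.integer(res$niter),
      message = res$message, model = modelWithParams(model, full))
}

#' Fit a model across an ordered series of curves
#'
#' Fits every curve sequentially. With `propagate = TRUE` frame k is
#' initialized from frame k-1's converged parameters (tracking slowly
#' drifting peaks, as in time-resolved GISAXS series); on non-convergence
#' the initial model is restored for the next frame and processing
#' continues — no frame aborts the series.
#'
#' @param curves list of [Curve-class] objects, in frame order.
#' @param model initial [PeakModel-class].
#' @param propagate carry converged parameters forward as the next frame's
#'   initial values.
#' @param lower,upper bounds passed to [fitCurve()].
#' @param maxIter per-frame iteration cap.
#' @return data.frame with one row per frame: `frame`, `converged`,
#'   `redchi`, `n_eval`, one column per model parameter and one
#'   `<par>_err` column per uncertainty.
#' @export
fitSeries <- function(curves, model, propagate = TRUE,
                      lower = NULL, upper = NULL, maxIter = 200) {
  current <- model
  rows <- vector("list", length(curves))
  failFit <- function(msg) new(
    "FitResult", par = applyTies(modelParamVector(model), model@ties),
    stderr = setNames(rep(NA_real_, length(modelParamVector(model))),
                      names(modelParamVector(model))),
    redchi = NA_real_, converged = FALSE, nEval = 0L, message = msg,
    model = model)
  for (k in seq_along(curves)) {
    fit <- tryCatch(
      fitCurve(curves[[k]], current, lower = lower, upper = upper,
               maxIter = maxIter),
      error = function(e) failFit(conditionMessage(e)))
    p <- fitParameters(fit)
    s <- fitStderr(fit)
    rows[[k]] <- c(list(frame = k, converged = fitConverged(fit),
                        redchi = fit@redchi, n_eval = fit@nEval),
                   as.list(p),
                   setNames(as.list(s), paste0(names(s), "_err")))
    current <- if (propagate && fitConverged(fit)) fit@model else model
  }
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
}
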