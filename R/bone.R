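# Bone-mineral nanostructure parameters from reduced SAXS profiles.
#
# For a two-phase system with sharp interfaces the high-q tail follows
# Porod's law, I(q) -> P/q^4 + B (B a constant fluctuation background).
# With the scattering invariant J = int (I - B) q^2 dq, the stereological
# mean-thickness measure is T = 4 J / (pi P): for dilute particles this is
# the volume-to-surface chord length 4V/S (a sphere of radius R gives
# T = 4R/3; a thin platelet gives its thickness). The derivation is laid
# out in the methods vignette. The degree-of-alignment parameter rho is
# the oriented fraction of the azimuthal intensity: a constrained two-peak
# fit of I(chi) with the peaks 180 degrees apart, rho = A_peaks /
# (A_peaks + A_background), in [0, 1].

#' Porod fit of the high-q tail
#'
#' Linear regression of `I q^4` against `q^4` over the fit range: the
#' intercept is the Porod constant P, the slope the fluctuation
#' background B. A non-positive P is flagged invalid (the pattern is not
#' Porod-like).
#'
#' @param curve radial [Curve-class] I(q).
#' @param qRange `c(qmin, qmax)` of the tail to fit (>= 5 points).
#' @return list with `P`, `B`, `qRange`, `valid`.
#' @export
porodFit <- function(curve, qRange) {
  q <- curveX(curve); y <- curveY(curve)
  keep <- is.finite(y) & q >= qRange[1] & q <= qRange[2]
  if (sum(keep) < 5)
    stop("Porod fit needs at least 5 finite points in the q range")
  q4 <- q[keep]^4
  fit <- stats::lm(Iq4 ~ q4, data = data.frame(Iq4 = y[keep] * q4, q4 = q4))
  P <- unname(stats::coef(fit)[1])
  B <- unname(stats::coef(fit)[2])
  valid <- is.finite(P) && P > 0
  if (!valid)
    logMsg("warning", "non-positive Porod constant (P = %.4g): not Porod-like",
           P)
  list(P = P, B = B, qRange = qRange, valid = valid)
}

#' Scattering invariant J
#'
#' Evaluates `J = int_0^inf (I(q) - B) q^2 dq` as the trapezoid over the
#' measured range plus a constant low-q extension
#' `(I(qmin) - B) qmin^3 / 3` and the analytic Porod tail
#' `int_qmax^inf (P/q^4) q^2 dq = P / qmax`.
#'
#' @param curve radial [Curve-class] I(q).
#' @param P,B Porod constant and fluctuation background from [porodFit()].
#' @param qMax upper end of the measured integration range (defaults to the
#'   last finite point); the analytic tail takes over beyond it.
#' @return the invariant J (intensity * nm^-3).
#' @export
porodInvariant <- function(curve, P, B, qMax = NULL) {
  q <- curveX(curve); y <- curveY(curve)
  keep <- is.finite(y)
  q <- q[keep]; y <- y[keep]
  if (!is.null(qMax)) { y <- y[q <= qMax]; q <- q[q <= qMax] }
  if (length(q) < 2) stop("invariant needs at least two finite points")
  integrand <- (y - B) * q^2
  if (mean(tail(integrand, max(3, length(q) %/% 10))) < 0)
    warning("negative I - B tail near qMax: check the Porod background")
  measured <- pracma::trapz(q, integrand)
  lowq <- (y[1] - B) * q[1]^3 / 3
  tailJ <- P / q[length(q)]
  measured + lowq + tailJ
}

#' Mean-thickness parameter T
#'
#' `T = 4 J / (pi P)`; intensity units cancel, so T is invariant under
#' rescaling of I.
#' @param J scattering invariant from [porodInvariant()].
#' @param P Porod constant, > 0.
#' @return T in nm.
#' @export
tParameter <- function(J, P) {
  if (!is.finite(P) || P <= 0)
    stop("T parameter requires a valid (positive) Porod constant")
  4 * J / (pi * P)
}

#' End-to-end T parameter from a radial profile
#'
#' Convenience chain [porodFit()] -> [porodInvariant()] -> [tParameter()].
#' @param curve radial [Curve-class] I(q).
#' @param qFitRange high-q range for the Porod regression.
#' @return list with `T`, `J`, `P`, `B`, `valid`.
#' @export
boneTParameter <- function(curve, qFitRange) {
  pf <- porodFit(curve, qFitRange)
  if (!pf$valid)
    return(list(T = NaN, J = NaN, P = pf$P, B = pf$B, valid = FALSE))
  J <- porodInvariant(curve, pf$P, pf$B, qMax = qFitRange[2])
  list(T = tParameter(J, pf$P), J = J, P = pf$P, B = pf$B, valid = TRUE)
}

#' Degree-of-alignment parameter rho from an azimuthal profile
#'
#' Fits a constant background plus two Gaussian peaks constrained to equal
#' amplitude and width with centres chi0 and chi0 + 180 degrees (wrapped at
#' the 360-degree period). The oriented fraction is
#' `rho = A_peaks / (A_peaks + A_bg)` with `A_peaks` the total fitted peak
#' area over one period and `A_bg = background level * 360`. With
#' `denominator = "background"` the alternative reading
#' `rho = A_peaks / A_bg` is reported instead (unbounded above).
#'
#' The predominant particle orientation is perpendicular to the azimuthal
#' intensity maximum (SAXS streak geometry): `(chi0 + 90) mod 180` degrees.
#'
#' @param curve azimuthal [Curve-class] I(chi) covering [0, 360).
#' @param maxGapFraction largest tolerated fraction of empty bins.
#' @param denominator `"total"` (default, rho in [0, 1]) or
#'   `"background"`.
#' @return list with `rho`, `chi0`, `fwhm`, `orientation`, `converged`,
#'   `fit` (the [FitResult-class]). On non-convergence `rho` is NaN.
#' @export
rhoParameter <- function(curve, maxGapFraction = 0.2,
                         denominator = c("total", "background")) {
  denominator <- match.arg(denominator)
  chi <- curveX(curve); y <- curveY(curve)
  ok <- is.finite(y)
  if (mean(!ok) > maxGapFraction)
    stop(sprintf("azimuthal coverage gap %.0f%% exceeds the tolerated %.0f%%",
                 100 * mean(!ok), 100 * maxGapFraction))
  b0 <- stats::quantile(y[ok], 0.1, names = FALSE)
  a0 <- max(y[ok]) - b0
  chi0 <- chi[ok][which.max(y[ok])] %% 180
  model <- peakModel(
    peaks = list(gaussianPeak(a0, chi0, 40),
                 gaussianPeak(a0, chi0 + 180, 40)),
    background = list(type = "constant", coef = max(b0, 0)),
    ties = list(
      list(target = "p2.amplitude", source = "p1.amplitude"),
      list(target = "p2.center", source = "p1.center", offset = 180),
      list(target = "p2.fwhm", source = "p1.fwhm")),
    period = 360)
  fit <- fitCurve(curve, model,
                  lower = c(p1.amplitude = 0, p1.fwhm = 2, bg.c0 = 0),
                  upper = c(p1.fwhm = 170))
  if (!fitConverged(fit)) {
    logMsg("warning", "rho fit did not converge; reporting NaN")
    return(list(rho = NaN, chi0 = NaN, fwhm = NaN, orientation = NaN,
                converged = FALSE, fit = fit))
  }
  p <- fitParameters(fit)
  aPeaks <- 2 * peakArea("gaussian", p[["p1.amplitude"]], p[["p1.fwhm"]])
  aBg <- p[["bg.c0"]] * 360
  rho <- if (denominator == "total") aPeaks / (aPeaks + aBg) else
    aPeaks / aBg
  chi0 <- p[["p1.center"]] %% 360
  list(rho = rho, chi0 = chi0, fwhm = p[["p1.fwhm"]],
       orientation = (chi0 + 90) %% 180, converged = TRUE, fit = fit)
}

#' Assemble scan-grid maps of T, rho and orientation
#'
#' Places per-frame results on the (possibly incomplete) scan grid spanned
#' by the motor positions. Missing grid points are NaN; duplicate positions
#' are resolved last-wins with a warning. Orientation is returned both in
#' degrees (mod 180) and as unit-vector components for quiver-style maps.
#'
#' @param results data.frame with columns `x`, `y` (scan positions) and any
#'   of `T`, `rho`, `orientation`.
#' @return list with `xs`, `ys` (sorted unique positions) and matrices
#'   `T`, `rho`, `orientation`, `ux`, `uy` (`length(ys) x length(xs)`).
#' @export
boneMap <- function(results) {
  stopifnot(all(c("x", "y") %in% names(results)))
  xs <- sort(unique(results$x)); ys <- sort(unique(results$y))
  key <- paste(results$x, results$y)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    warning(sprintf("duplicate scan position(s) %s: last wins",
                    paste(dup, collapse = "; ")))
    results <- results[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  grid <- function(col) {
    m <- matrix(NaN, length(ys), length(xs))
    if (!col %in% names(results)) return(m)
    for (k in seq_len(nrow(results))) {
      i <- match(results$y[k], ys); j <- match(results$x[k], xs)
      m[i, j] <- results[[col]][k]
    }
    m
  }
  ori <- grid("orientation")
  list(xs = xs, ys = ys, T = grid("T"), rho = grid("rho"),
       orientation = ori,
       ux = cos(ori * pi / 180), uy = sin(ori * pi / 180))
}
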