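# Synthetic detector frames with analytic ground truth.
#
# Three emulated situations: dilute polydisperse-sphere SAXS (Porod q^-4
# tail, for the T-parameter chain), centrosymmetric anisotropic patterns
# with a known azimuthal distribution (for the rho chain), and GISAXS-like
# frame series with drifting symmetric side maxima (for sequential cut +
# fit). Counting noise is Poisson with an explicit seed; the noiseless
# expectation is also available for exact tests. Same seed + parameters
# give bit-identical output.

#' Schulz size-distribution moments
#'
#' The Schulz (gamma) distribution with mean `R0` and relative width
#' `poly` = sigma/R0 has closed-form raw moments
#' `<R^n> = R0^n prod_{k=1..n} (z + k) / (z + 1)^n` with
#' `z + 1 = 1 / poly^2`. `poly = 0` degenerates to monodisperse.
#'
#' @param R0 mean radius, nm.
#' @param poly relative width sigma/R0 (>= 0).
#' @param n moment order(s).
#' @return numeric vector of `<R^n>`.
#' @export
schulzMoments <- function(R0, poly, n) {
  vapply(n, function(k) {
    if (poly <= 0) return(R0^k)
    z1 <- 1 / poly^2                 # z + 1
    R0^k * prod(z1 - 1 + seq_len(k)) / z1^k
  }, numeric(1))
}

# squared sphere form factor F^2(x), F(x) = 3 (sin x - x cos x) / x^3
.sphereFF2 <- function(x) {
  f <- ifelse(x < 1e-4, 1 - x^2 / 10,
              3 * (sin(x) - x * cos(x)) / x^3)
  f^2
}

# Gauss-Legendre nodes/weights over the Schulz density (numerically
# normalized); list(R =, w =) with sum(w) = 1
.schulzQuad <- function(R0, poly, nNodes = 41) {
  if (poly <= 0) return(list(R = R0, w = 1))
  z1 <- 1 / poly^2
  lo <- max(R0 * 1e-3, R0 * (1 - 6 * poly))
  hi <- R0 * (1 + 9 * poly)
  gl <- pracma::gaussLegendre(nNodes, lo, hi)
  dens <- stats::dgamma(gl$x, shape = z1, rate = z1 / R0)
  w <- gl$w * dens
  list(R = gl$x, w = w / sum(w))
}

#' Dilute polydisperse-sphere scattering frame
#'
#' Plants the intensity-weighted sphere form factor on the detector:
#' `I(q) = flux * <R^6 F^2(qR)> / <R^6> + background`, the average taken
#' over a Schulz size distribution (each sphere scatters with its volume
#' squared, so larger spheres dominate). The default 10% relative width
#' damps the form-factor oscillations enough for stable Porod fits. The
#' high-q asymptote is Porod's law with analytic constant
#' `P = flux * (9/2) <R^2> / <R^6>`, and the planted mean thickness is
#' `T = (4/3) <R^3> / <R^2>` (= 4R/3 when monodisperse).
#'
#' @param geom transmission [ExperimentGeometry-class].
#' @param shape detector dimensions `c(nrow, ncol)`.
#' @param radius mean sphere radius R0, nm.
#' @param poly Schulz relative width sigma/R0 (0 = monodisperse).
#' @param flux forward-scattering intensity scale, counts.
#' @param background flat background level, counts.
#' @param seed RNG seed for the Poisson noise.
#' @param noise Poisson-sample the expectation (`FALSE` returns the exact
#'   noiseless expectation).
#' @return list with `frame` ([Frame-class]) and `truth` (list: `P`, `T`,
#'   `background`, `flux`, `radius`, `poly`, plus the moments used).
#' @export
spherePattern <- function(geom, shape = c(160, 160), radius = 2,
                          poly = 0.1, flux = 5e4, background = 2,
                          seed = 1, noise = TRUE) {
  stopifnot(radius > 0)
  qmap <- buildQMap(shape, geom)
  quad <- .schulzQuad(radius, poly)
  q <- as.vector(qmap@q)
  wr6 <- quad$w * quad$R^6
  acc <- numeric(length(q))
  for (i in seq_along(quad$R))
    acc <- acc + wr6[i] * .sphereFF2(q * quad$R[i])
  expect <- flux * acc / sum(wr6) + background
  if (max(q) * radius < 8)
    warning("q coverage too small for a clean Porod tail (q_max R < 8)")
  data <- if (noise) withSeed(seed, stats::rpois(length(expect), expect))
          else expect
  m2 <- schulzMoments(radius, poly, 2)
  m3 <- schulzMoments(radius, poly, 3)
  m6 <- schulzMoments(radius, poly, 6)
  list(frame = detectorFrame(matrix(data, shape[1], shape[2]),
                             sourcePath = ""),
       truth = list(P = flux * 4.5 * m2 / m6,
                    T = (4 / 3) * m3 / m2,
                    background = background, flux = flux,
                    radius = radius, poly = poly,
                    momR2 = m2, momR3 = m3, momR6 = m6))
}

# wrapped unit-height Gaussian evaluated with +/- one period
.wrappedGauss <- function(chi, chi0, fwhm, period = 360) {
  g <- function(d) exp(-4 * log(2) * d^2 / fwhm^2)
  g(chi - chi0) + g(chi - chi0 - period) + g(chi - chi0 + period)
}

#' Centrosymmetric anisotropic scattering frame
#'
#' Plants `I(q, chi) = flux * S(q) * [b + a (g(chi; chi0) +
#' g(chi; chi0 + 180))]` with g a wrapped unit-height Gaussian of width
#' `peakFwhm` and S(q) a smooth radial envelope. Because the azimuthal
#' factor is separable, the annulus-averaged azimuthal profile preserves
#' the planted peak-to-background area ratio exactly: the ground truth is
#' `A_peaks = 2 a peakFwhm sqrt(pi/(4 ln 2))`, `A_bg = 360 b`, and
#' `rho_true = A_peaks / (A_peaks + A_bg)`.
#'
#' @param geom transmission [ExperimentGeometry-class].
#' @param shape detector dimensions `c(nrow, ncol)`.
#' @param chi0 first azimuthal peak centre, degrees.
#' @param a peak-to-background amplitude ratio (anisotropy amplitude).
#' @param b background level (relative).
#' @param peakFwhm azimuthal peak width, degrees.
#' @param flux intensity scale, counts.
#' @param xi radial correlation length of the envelope
#'   `S(q) = 1 / (1 + (q xi)^2)`, nm.
#' @param seed,noise as in [spherePattern()].
#' @return list with `frame` and `truth` (`rho`, `chi0`, `orientation`,
#'   `aPeaks`, `aBg`, ...).
#' @export
anisotropicPattern <- function(geom, shape = c(128, 128), chi0 = 40,
                               a = 5, b = 1, peakFwhm = 30, flux = 1000,
                               xi = 1, seed = 1, noise = TRUE) {
  stopifnot(a >= 0, b >= 0)
  qmap <- buildQMap(shape, geom)
  s <- 1 / (1 + (qmap@q * xi)^2)
  az <- b + a * (.wrappedGauss(qmap@chi, chi0, peakFwhm) +
                 .wrappedGauss(qmap@chi, chi0 + 180, peakFwhm))
  expect <- flux * s * az
  data <- if (noise) withSeed(seed, stats::rpois(length(expect),
                                                 as.vector(expect)))
          else as.vector(expect)
  aPeaks <- 2 * a * peakFwhm * sqrt(pi / (4 * log(2)))
  aBg <- 360 * b
  list(frame = detectorFrame(matrix(data, shape[1], shape[2])),
       truth = list(rho = aPeaks / (aPeaks + aBg),
                    chi0 = chi0 %% 360,
                    orientation = (chi0 + 90) %% 180,
                    aPeaks = aPeaks, aBg = aBg,
                    peakFwhm = peakFwhm, a = a, b = b))
}

#' GISAXS-like frame series with drifting side maxima
#'
#' Each frame carries symmetric side maxima at `+/- qyStar(k)` (Lorentzian
#' in qy, planted full width `fwhm`) on an exponentially decaying diffuse
#' background in qz, emulating in-situ sputter-deposition series where the
#' in-plane correlation peak drifts as clusters grow. Frames are written
#' as numbered 16-bit TIFFs next to a tab-separated manifest recording the
#' planted trajectory.
#'
#' @param geom grazing-mode [ExperimentGeometry-class].
#' @param nFrames number of frames (>= 1).
#' @param qyTrajectory numeric vector of length `nFrames` (planted
#'   `qyStar` per frame, nm^-1), or a function of the frame index.
#' @param fwhm side-maximum full width in qy, nm^-1.
#' @param shape detector dimensions `c(nrow, ncol)`.
#' @param peakAmp,bgAmp peak and diffuse-background amplitudes, counts.
#' @param qzDecay 1/e decay constant of the diffuse background, nm^-1.
#' @param outDir output directory (created if needed).
#' @param seed RNG seed; frame k uses `seed + k` so any subsequence is
#'   reproducible.
#' @param noise Poisson-sample the frames.
#' @param write write TIFFs + manifest (otherwise frames are only
#'   returned).
#' @return list with `manifest` (data.frame: frame, file, qy_star, fwhm)
#'   and `frames` (list of [Frame-class]).
#' @export
gisaxsSeries <- function(geom, nFrames, qyTrajectory, fwhm = 0.08,
                         shape = c(100, 160), peakAmp = 400, bgAmp = 50,
                         qzDecay = 0.4, outDir = NULL, seed = 1,
                         noise = TRUE, write = !is.null(outDir)) {
  stopifnot(nFrames >= 1)
  qyStar <- if (is.function(qyTrajectory))
    vapply(seq_len(nFrames), qyTrajectory, numeric(1))
  else rep_len(qyTrajectory, nFrames)
  qmap <- buildQMap(shape, geom)
  env <- exp(-pmax(qmap@qz, 0) / qzDecay)
  lor <- function(qy, c0) (fwhm / 2)^2 / ((qy - c0)^2 + (fwhm / 2)^2)
  if (write) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  frames <- vector("list", nFrames)
  files <- character(nFrames)
  for (k in seq_len(nFrames)) {
    expect <- env * (bgAmp +
                     peakAmp * (lor(qmap@qy, qyStar[k]) +
                                lor(qmap@qy, -qyStar[k])))
    data <- if (noise)
      withSeed(seed + k, stats::rpois(length(expect), as.vector(expect)))
    else as.vector(expect)
    m <- matrix(data, shape[1], shape[2])
    frames[[k]] <- detectorFrame(m)
    if (write) {
      files[k] <- file.path(outDir, sprintf("frame_%05d.tif", k))
      writeFrameTIFF(round(m), files[k])
    }
  }
  manifest <- data.frame(frame = seq_len(nFrames), file = files,
                         qy_star = qyStar, fwhm = fwhm)
  if (write)
    utils::write.table(manifest, file.path(outDir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  list(manifest = manifest, frames = frames)
}

#' Default synthetic-experiment geometries
#'
#' The transmission geometry emulates a bone scanning-SAXS setup
#' (lambda = 0.1 nm, D = 500 mm, 1 mm pixels, beam centred); with the
#' default 160 x 160 detector it covers q up to ~10 nm^-1, enough Porod
#' tail for 2 nm particles. The grazing geometry uses the sputter-series
#' conditions (lambda = 0.096 nm, alpha_i = 0.5 deg, 0.172 mm PILATUS
#' pixels) at D = 1000 mm so a 160-column detector spans qy ~ +/-0.9
#' nm^-1, with the direct beam near the bottom of the frame.
#'
#' @param mode `"transmission"` or `"grazing"`.
#' @param shape detector dimensions the beam centre is placed for.
#' @return An [ExperimentGeometry-class].
#' @export
synthGeometry <- function(mode = c("transmission", "grazing"),
                          shape = if (match.arg(mode) == "transmission")
                            c(160, 160) else c(100, 160)) {
  mode <- match.arg(mode)
  if (mode == "transmission") {
    experimentGeometry(wavelength = 0.1, distance = 500,
                       beamCenter = (rev(shape) - 1) / 2,
                       pixelSize = 1.0)
  } else {
    experimentGeometry(wavelength = 0.096, distance = 1000,
                       beamCenter = c((shape[2] - 1) / 2, shape[1] - 3),
                       pixelSize = 0.172, incidence = 0.5,
                       mode = "grazing")
  }
}
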