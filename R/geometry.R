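# Pixel -> reciprocal-space mapping for transmission and grazing setups.
#
# Conventions (documented once, used everywhere): pixel coordinates are
# 0-based, x along columns, y along rows, origin top-left; "up" on the
# detector is decreasing row index. Azimuth chi is measured counterclockwise
# from the +x detector axis, degrees in [0, 360). The detector is flat and
# orthogonal to the beam.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

# mm offsets of pixel coords from the beam centre; dyUp positive upwards.
.pixelOffsets <- function(x, y, geom) {
  list(dx = (x - geom@beamCenter[1]) * geom@pixelSize[1],
       dyUp = (geom@beamCenter[2] - y) * geom@pixelSize[2])
}

#' Map transmission-mode pixels to (q, chi)
#'
#' The scattering angle of a pixel at in-plane distance r (mm) from the
#' beam centre is 2theta = atan(r / D); the momentum-transfer modulus is
#' q = (4 pi / lambda) sin(theta). The azimuth chi is the counterclockwise
#' angle from the +x detector axis, in degrees in [0, 360); it is undefined
#' at the beam centre and reported as 0 there.
#'
#' @param x,y pixel coordinates (0-based; x = column, y = row); vectors of
#'   equal length, fractional values allowed.
#' @param geom an [ExperimentGeometry-class] in transmission mode.
#' @return list with numeric vectors `q` (nm^-1) and `chi` (degrees).
#' @examples
#' geom <- experimentGeometry(0.1, 1000, c(0, 0), 1)
#' pixelToQ(100, 0, geom)$q   # ~6.260 nm^-1
#' @export
pixelToQ <- function(x, y, geom) {
  stopifnot(is(geom, "ExperimentGeometry"))
  validObject(geom)
  if (geom@mode != "transmission")
    stop("pixelToQ requires transmission mode; see pixelToGisaxsQ")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("pixel coordinates must be finite")
  off <- .pixelOffsets(x, y, geom)
  r <- sqrt(off$dx^2 + off$dyUp^2)
  twoTheta <- atan(r / geom@distance)
  q <- (4 * pi / geom@wavelength) * sin(twoTheta / 2)
  chi <- (atan2(off$dyUp, off$dx) * .rad2deg) %% 360
  chi[r == 0] <- 0
  list(q = q, chi = chi)
}

#' Map grazing-incidence pixels to (qy, qz)
#'
#' Standard GISAXS kinematics in the small-angle regime. With psi the
#' in-plane (horizontal) scattering angle and alpha_f the exit angle,
#' psi = atan(dx / D), alpha_f = atan(dy_up / D) - alpha_i (dy_up measured
#' upward from the direct-beam spot):
#' qy = (2 pi / lambda) sin(psi) cos(alpha_f),
#' qz = (2 pi / lambda) (sin(alpha_i) + sin(alpha_f)).
#' The component qx is neglected (small-angle contract). The beam centre is
#' the direct-beam spot, not the specular reflection; at it qy = qz = 0 and
#' alpha_f = -alpha_i.
#'
#' @inheritParams pixelToQ
#' @param geom an [ExperimentGeometry-class] in grazing mode.
#' @return list with numeric vectors `qy`, `qz` (nm^-1).
#' @export
pixelToGisaxsQ <- function(x, y, geom) {
  stopifnot(is(geom, "ExperimentGeometry"))
  validObject(geom)
  if (geom@mode != "grazing")
    stop("pixelToGisaxsQ requires grazing mode")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("pixel coordinates must be finite")
  off <- .pixelOffsets(x, y, geom)
  ai <- geom@incidence * .deg2rad
  psi <- atan(off$dx / geom@distance)
  af <- atan(off$dyUp / geom@distance) - ai
  if (any(af < -ai - pi / 2))
    stop("exit angle below -alpha_i - 90 degrees: undefined geometry")
  k <- 2 * pi / geom@wavelength
  list(qy = k * sin(psi) * cos(af),
       qz = k * (sin(ai) + sin(af)))
}

.qmapCache <- new.env(parent = emptyenv())

#' Build per-pixel reciprocal-space maps for a detector
#'
#' Applies [pixelToQ()] (and in grazing mode [pixelToGisaxsQ()]) to every
#' pixel centre of an `nrow x ncol` detector. Maps are cached per
#' (geometry, shape) and reused across frames. In grazing mode the modulus
#' is q = sqrt(qy^2 + qz^2) (qx neglected) and chi is measured in the
#' (qy, qz) plane.
#'
#' @param shape integer(2), detector dimensions `c(nrow, ncol)`.
#' @param geom an [ExperimentGeometry-class].
#' @param cache reuse a previously built map for the same geometry/shape.
#' @return A [QMap-class].
#' @export
buildQMap <- function(shape, geom, cache = TRUE) {
  stopifnot(length(shape) == 2, all(shape >= 1))
  validObject(geom)
  key <- paste(c(shape, geom@wavelength, geom@distance, geom@beamCenter,
                 geom@pixelSize, geom@incidence, geom@mode), collapse = "|")
  if (cache && !is.null(.qmapCache[[key]])) return(.qmapCache[[key]])
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  # pixel-centre coordinate grids (0-based)
  xg <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  yg <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  if (geom@mode == "transmission") {
    m <- pixelToQ(as.vector(xg), as.vector(yg), geom)
    qm <- new("QMap",
              q = matrix(m$q, nr, nc), chi = matrix(m$chi, nr, nc),
              qy = matrix(numeric(), 0, 0), qz = matrix(numeric(), 0, 0),
              geometry = geom)
  } else {
    m <- pixelToGisaxsQ(as.vector(xg), as.vector(yg), geom)
    qy <- matrix(m$qy, nr, nc); qz <- matrix(m$qz, nr, nc)
    q <- sqrt(qy^2 + qz^2)
    chi <- (atan2(qz, qy) * .rad2deg) %% 360
    chi[q == 0] <- 0
    qm <- new("QMap", q = q, chi = chi, qy = qy, qz = qz, geometry = geom)
  }
  if (cache) .qmapCache[[key]] <- qm
  qm
}
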