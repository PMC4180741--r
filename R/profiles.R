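# Reduction of 2-D frames to 1-D curves.
#
# Binning is pixel-centre histogramming ("simple box integration"): each
# unmasked pixel contributes its full intensity to the single bin its
# centre falls in; no pixel splitting. Bins are half-open [lo, hi), the
# last bin closed. Empty bins carry NaN so downstream fits can drop them.

# bin index in 1..(length(breaks)-1) for values inside the break range
# (half-open bins, last bin closed); NA outside
.binIndex <- function(v, breaks) {
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  idx[idx < 1L | idx > length(breaks) - 1L] <- NA_integer_
  idx
}

# chi range test supporting wrap-around (lo > hi means the arc through 0)
.inChiRange <- function(chi, range) {
  lo <- range[1] %% 360; hi <- range[2] %% 360
  if (lo <= hi) chi >= lo & chi <= hi else chi >= lo | chi <= hi
}

.accumulateCurve <- function(x, bin, vals, sig2, nbins, kind) {
  ok <- !is.na(bin)
  n <- tabulate(bin[ok], nbins)
  ysum <- rep(0, nbins); vsum <- rep(0, nbins)
  if (any(ok)) {
    s <- rowsum(cbind(vals[ok], sig2[ok]), bin[ok])
    at <- as.integer(rownames(s))
    ysum[at] <- s[, 1]; vsum[at] <- s[, 2]
  }
  y <- ifelse(n > 0, ysum / n, NaN)
  sigma <- ifelse(n > 0, sqrt(vsum) / pmax(n, 1), NaN)
  scatterCurve(x, y, sigma, n, kind)
}

#' Radial (azimuthally averaged) profile I(q)
#'
#' Histograms unmasked pixels into q bins and averages their intensities:
#' `y[i]` is the mean intensity of pixels whose q falls in
#' `[qBreaks[i], qBreaks[i+1])` (last bin closed), `sigma[i]` the
#' propagated uncertainty of that mean. Intensity is conserved:
#' `sum(y * nPix)` equals the summed intensity of all contributing pixels.
#'
#' @param frame a [Frame-class].
#' @param qmap the [QMap-class] for the frame's geometry/shape.
#' @param qBreaks increasing vector of bin edges, nm^-1.
#' @param chiRange optional `c(lo, hi)` azimuth restriction in degrees
#'   (wrap-around allowed, e.g. `c(350, 10)`).
#' @return A [Curve-class] (kind `"radial"`, x = bin midpoints).
#' @export
radialProfile <- function(frame, qmap, qBreaks, chiRange = NULL) {
  stopifnot(is(frame, "Frame"), is(qmap, "QMap"))
  if (!identical(dim(frame@data), dim(qmap@q)))
    stop("frame and q-map shapes differ")
  if (length(qBreaks) < 2 || any(diff(qBreaks) <= 0))
    stop("qBreaks must be an increasing vector of at least two edges")
  sel <- !frame@mask
  if (!is.null(chiRange)) sel <- sel & .inChiRange(qmap@chi, chiRange)
  bin <- .binIndex(as.vector(qmap@q), qBreaks)
  bin[!as.vector(sel)] <- NA_integer_
  if (all(is.na(bin)))
    warning("all pixels masked or out of range: all-NaN profile")
  mid <- (head(qBreaks, -1) + tail(qBreaks, -1)) / 2
  .accumulateCurve(mid, bin, as.vector(frame@data),
                   as.vector(frame@sigma)^2, length(qBreaks) - 1L, "radial")
}

#' Azimuthal profile I(chi) over a q annulus
#'
#' Averages unmasked pixels with q in `qRange` (closed interval) into
#' azimuth bins. For anisotropic centrosymmetric patterns the profile shows
#' two peaks separated by 180 degrees.
#'
#' @param frame a [Frame-class].
#' @param qmap matching [QMap-class].
#' @param qRange `c(qmin, qmax)` annulus, nm^-1.
#' @param chiBreaks increasing bin edges partitioning [0, 360), degrees.
#' @return A [Curve-class] (kind `"azimuthal"`).
#' @export
azimuthalProfile <- function(frame, qmap, qRange,
                             chiBreaks = seq(0, 360, by = 5)) {
  stopifnot(is(frame, "Frame"), is(qmap, "QMap"))
  if (!identical(dim(frame@data), dim(qmap@q)))
    stop("frame and q-map shapes differ")
  inQ <- qmap@q >= qRange[1] & qmap@q <= qRange[2]
  sel <- inQ & !frame@mask
  if (!any(sel))
    stop("empty annulus: no unmasked pixels in the requested q range")
  bin <- .binIndex(as.vector(qmap@chi), chiBreaks)
  bin[!as.vector(sel)] <- NA_integer_
  mid <- (head(chiBreaks, -1) + tail(chiBreaks, -1)) / 2
  .accumulateCurve(mid, bin, as.vector(frame@data),
                   as.vector(frame@sigma)^2, length(chiBreaks) - 1L,
                   "azimuthal")
}

#' GISAXS line cut through reciprocal space
#'
#' Horizontal cuts (out-of-plane cuts) run along qy, averaging pixels with
#' `|qz - at| <= roiWidth/2` per detector column; vertical cuts (detector
#' cuts) run along qz, averaging over `|qy - at| <= roiWidth/2` per row.
#' An arbitrary-direction cut projects pixels onto the axis at `angle`
#' degrees (counterclockwise from +qy) through the point (0, `at`) and
#' histograms the signed distance along it, keeping pixels within
#' `roiWidth/2` of the axis. Integrating over a finite ROI width trades
#' resolution for statistics.
#'
#' @param frame a [Frame-class].
#' @param qmap grazing-mode [QMap-class].
#' @param direction `"horizontal"`, `"vertical"` or `"arbitrary"`.
#' @param at centre of the ROI band: the qz (horizontal) or qy (vertical)
#'   coordinate of the cut, nm^-1.
#' @param roiWidth full ROI width, nm^-1 (at least one pixel's q extent).
#' @param angle direction in degrees for `direction = "arbitrary"`.
#' @param reduce per-bin statistic, `"mean"` (default) or `"median"`
#'   (median intensity profiles; sigma is then NA).
#' @return A [Curve-class] (kind `"cut"`).
#' @export
gisaxsCut <- function(frame, qmap,
                      direction = c("horizontal", "vertical", "arbitrary"),
                      at = 0, roiWidth = NULL, angle = NULL,
                      reduce = c("mean", "median")) {
  direction <- match.arg(direction)
  reduce <- match.arg(reduce)
  stopifnot(is(frame, "Frame"), is(qmap, "QMap"))
  if (qmap@geometry@mode != "grazing")
    stop("GISAXS cuts require a grazing-mode q-map")
  if (!identical(dim(frame@data), dim(qmap@qy)))
    stop("frame and q-map shapes differ")
  d <- dim(frame@data)
  pixQz <- if (d[1] > 1) min(abs(diff(qmap@qz[, 1]))) else 0
  pixQy <- if (d[2] > 1) min(abs(diff(qmap@qy[1, ]))) else 0
  if (is.null(roiWidth))
    roiWidth <- if (direction == "horizontal") pixQz else pixQy
  minW <- if (direction == "horizontal") pixQz else
          if (direction == "vertical") pixQy else min(pixQy, pixQz)
  if (roiWidth < minW / 2)
    stop("roiWidth below one pixel's q extent")
  ok <- !frame@mask
  if (direction == "horizontal") {
    inRoi <- abs(qmap@qz - at) <= roiWidth / 2
    group <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
    coord <- qmap@qy
  } else if (direction == "vertical") {
    inRoi <- abs(qmap@qy - at) <= roiWidth / 2
    group <- matrix(rep(seq_len(d[1]), times = d[2]), d[1], d[2])
    coord <- qmap@qz
  } else {
    if (is.null(angle)) stop("arbitrary cuts need an angle")
    a <- angle * pi / 180
    t <- qmap@qy * cos(a) + (qmap@qz - at) * sin(a)
    perp <- -qmap@qy * sin(a) + (qmap@qz - at) * cos(a)
    inRoi <- abs(perp) <= roiWidth / 2
    step <- min(pixQy, pixQz)
    group <- floor(t / step)
    coord <- t
  }
  sel <- ok & inRoi
  if (!any(sel)) stop("ROI lies outside the detector")
  g <- as.vector(group)[as.vector(sel)]
  v <- as.vector(frame@data)[as.vector(sel)]
  s2 <- as.vector(frame@sigma)[as.vector(sel)]^2
  cc <- as.vector(coord)[as.vector(sel)]
  ord <- sort(unique(g))
  gi <- match(g, ord)
  n <- tabulate(gi, length(ord))
  x <- rowsum(cc, gi)[, 1] / n
  if (reduce == "mean") {
    y <- rowsum(v, gi)[, 1] / n
    sig <- sqrt(rowsum(s2, gi)[, 1]) / n
  } else {
    y <- vapply(split(v, gi), stats::median, numeric(1))
    sig <- rep(NA_real_, length(ord))
  }
  o <- order(x)
  scatterCurve(x[o], y[o], sig[o], n[o], "cut")
}

#' Statistics of a rectangular region of interest
#'
#' Computes the minimum, maximum, average and sum intensity of the unmasked
#' pixels inside a pixel-space rectangle (clipped to the image).
#'
#' @param frame a [Frame-class].
#' @param x,y top-left corner of the ROI, 0-based pixel coordinates
#'   (x = column, y = row).
#' @param width,height ROI extent in pixels.
#' @return list with `min`, `max`, `average`, `sum` and `nPix`.
#' @export
roiStats <- function(frame, x, y, width, height) {
  stopifnot(is(frame, "Frame"))
  d <- dim(frame@data)
  cols <- seq(max(0, floor(x)), min(d[2] - 1, ceiling(x + width) - 1))
  rows <- seq(max(0, floor(y)), min(d[1] - 1, ceiling(y + height) - 1))
  if (width <= 0 || height <= 0 || x >= d[2] || y >= d[1] ||
      x + width <= 0 || y + height <= 0)
    stop("ROI does not intersect the image")
  sub <- frame@data[rows + 1, cols + 1, drop = FALSE]
  subMask <- frame@mask[rows + 1, cols + 1, drop = FALSE]
  vals <- sub[!subMask]
  if (length(vals) == 0) stop("ROI is fully masked")
  list(min = min(vals), max = max(vals), average = mean(vals),
       sum = sum(vals), nPix = length(vals))
}
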