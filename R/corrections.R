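# Pre-integration corrections with first-order Poisson error propagation.
#
# Negative intensities after background subtraction are retained, not
# clipped: clipping would bias every downstream bin mean upward.

#' Subtract a (scaled) background frame
#'
#' `data' = data - scale * bg`. Under the Poisson model the propagated
#' uncertainty is `sigma' = sqrt(sigma^2 + scale^2 * sigma_bg^2)`, which for
#' raw counts equals `sqrt(data + scale^2 * bg)`. Masks are unioned. The
#' scale (exposure or transmission ratio) is supplied by the caller.
#'
#' @param frame,bg [Frame-class] objects of matching shape.
#' @param scale non-negative dimensionless factor applied to `bg`.
#' @return A corrected [Frame-class] (provenance appended).
#' @export
subtractBackground <- function(frame, bg, scale = 1) {
  stopifnot(is(frame, "Frame"), is(bg, "Frame"))
  if (!identical(dim(frame@data), dim(bg@data)))
    stop("frame and background shapes differ")
  if (!is.finite(scale) || scale < 0) stop("scale must be >= 0")
  frame@data <- frame@data - scale * bg@data
  frame@sigma <- sqrt(frame@sigma^2 + scale^2 * bg@sigma^2)
  frame@mask <- frame@mask | bg@mask
  frame@provenance <- c(frame@provenance,
                        sprintf("subtract_background(scale=%.6g)", scale))
  validObject(frame)
  frame
}

#' Normalize a frame by its monitor counts
#'
#' Divides intensities and uncertainties by the incident-flux monitor and
#' resets the monitor to 1, making frames with different incident flux
#' comparable. Normalization commutes with integration.
#'
#' @param frame a [Frame-class] with `monitor > 0`.
#' @param defaultMonitor if `TRUE`, a missing/NA monitor is treated as 1
#'   with a logged notice instead of an error.
#' @return A normalized [Frame-class].
#' @export
normalizeMonitor <- function(frame, defaultMonitor = FALSE) {
  stopifnot(is(frame, "Frame"))
  m <- frame@monitor
  if (!is.finite(m) || m <= 0) {
    if (!defaultMonitor) stop("frame has no usable monitor counts")
    logMsg("info", "missing monitor; defaulting to 1.0")
    m <- 1
  }
  frame@data <- frame@data / m
  frame@sigma <- frame@sigma / m
  frame@provenance <- c(frame@provenance,
                        sprintf("normalize_monitor(%.6g)", m))
  frame@monitor <- 1
  frame
}

#' Bin pixels in n x n blocks
#'
#' Reduces each n x n block by sum or mean over its unmasked members.
#' A bin is masked iff all members are masked; partial blocks at the right
#' and bottom edges are dropped. Sum-mode uncertainty is
#' `sqrt(sum(sigma^2))`; mean mode divides by the unmasked count.
#' Sum-mode binning conserves the total unmasked intensity exactly when the
#' shape is divisible by n.
#'
#' Note the pixel pitch grows by the factor n: rebuild the q-map with
#' `pixelSize * n` and `beamCenter` mapped as `(c + 0.5)/n - 0.5` before
#' integrating binned frames.
#'
#' @param frame a [Frame-class].
#' @param n integer block edge, >= 1.
#' @param reduce `"sum"` or `"mean"`.
#' @return A binned [Frame-class].
#' @export
binPixels <- function(frame, n, reduce = c("sum", "mean")) {
  stopifnot(is(frame, "Frame"))
  reduce <- match.arg(reduce)
  n <- as.integer(n)
  if (n < 1) stop("binning factor must be >= 1")
  d <- dim(frame@data)
  if (n > min(d)) stop("binning factor exceeds image size")
  if (n == 1) return(frame)
  nr <- d[1] %/% n; nc <- d[2] %/% n
  sub <- function(m) m[seq_len(nr * n), seq_len(nc * n), drop = FALSE]
  data <- sub(frame@data); sig <- sub(frame@sigma); mask <- sub(frame@mask)
  grp <- matrix(0L, nr * n, nc * n)
  grp[] <- (rep(seq_len(nc * n) - 1L, each = nr * n) %/% n) * nr +
    ((rep(seq_len(nr * n) - 1L, times = nc * n)) %/% n) + 1L
  ok <- !mask
  sums  <- rowsum(as.vector(data * ok), as.vector(grp))
  var2  <- rowsum(as.vector(sig^2 * ok), as.vector(grp))
  count <- rowsum(as.vector(ok * 1), as.vector(grp))
  newData <- matrix(sums, nr, nc)
  newVar <- matrix(var2, nr, nc)
  cnt <- matrix(count, nr, nc)
  newMask <- cnt == 0
  if (reduce == "mean") {
    newData <- ifelse(cnt > 0, newData / cnt, 0)
    newSigma <- ifelse(cnt > 0, sqrt(newVar) / pmax(cnt, 1), 0)
  } else {
    newSigma <- sqrt(newVar)
  }
  frame@data <- newData
  frame@sigma <- newSigma
  frame@mask <- newMask
  frame@provenance <- c(frame@provenance,
                        sprintf("bin_pixels(n=%d, reduce=%s)", n, reduce))
  validObject(frame)
  frame
}
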