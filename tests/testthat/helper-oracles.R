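# Loop-based pixel oracles, intentionally naive: one pixel at a time,
# same binning rule (half-open bins, last bin closed) as the package.

oracleBin <- function(v, breaks) {
  for (i in seq_len(length(breaks) - 1)) {
    hi <- breaks[i + 1]
    if (v >= breaks[i] && (v < hi || (i == length(breaks) - 1 && v == hi)))
      return(i)
  }
  NA_integer_
}

oracleRadial <- function(frame, qmap, breaks, chiRange = NULL) {
  d <- dim(frameData(frame))
  nb <- length(breaks) - 1
  ysum <- numeric(nb); n <- integer(nb)
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    if (frameMask(frame)[r, c]) next
    if (!is.null(chiRange)) {
      chi <- qmap@chi[r, c]
      lo <- chiRange[1] %% 360; hi <- chiRange[2] %% 360
      inChi <- if (lo <= hi) chi >= lo && chi <= hi else
        chi >= lo || chi <= hi
      if (!inChi) next
    }
    b <- oracleBin(qmap@q[r, c], breaks)
    if (is.na(b)) next
    ysum[b] <- ysum[b] + frameData(frame)[r, c]
    n[b] <- n[b] + 1L
  }
  list(y = ifelse(n > 0, ysum / n, NaN), n = n)
}

oracleAzimuthal <- function(frame, qmap, qRange, breaks) {
  d <- dim(frameData(frame))
  nb <- length(breaks) - 1
  ysum <- numeric(nb); n <- integer(nb)
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    if (frameMask(frame)[r, c]) next
    q <- qmap@q[r, c]
    if (q < qRange[1] || q > qRange[2]) next
    b <- oracleBin(qmap@chi[r, c], breaks)
    if (is.na(b)) next
    ysum[b] <- ysum[b] + frameData(frame)[r, c]
    n[b] <- n[b] + 1L
  }
  list(y = ifelse(n > 0, ysum / n, NaN), n = n)
}

# horizontal cut: per-column mean over pixels with |qz - at| <= w/2
oracleCutHorizontal <- function(frame, qmap, at, roiWidth) {
  d <- dim(frameData(frame))
  x <- numeric(); y <- numeric(); n <- integer()
  for (c in seq_len(d[2])) {
    vals <- numeric(); qys <- numeric()
    for (r in seq_len(d[1])) {
      if (frameMask(frame)[r, c]) next
      if (abs(qmap@qz[r, c] - at) > roiWidth / 2) next
      vals <- c(vals, frameData(frame)[r, c])
      qys <- c(qys, qmap@qy[r, c])
    }
    if (length(vals)) {
      x <- c(x, mean(qys)); y <- c(y, mean(vals)); n <- c(n, length(vals))
    }
  }
  o <- order(x)
  list(x = x[o], y = y[o], n = n[o])
}

oracleRoi <- function(frame, x, y, width, height) {
  d <- dim(frameData(frame))
  vals <- numeric()
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    px <- c - 1; py <- r - 1
    if (px < x || px >= x + width || py < y || py >= y + height) next
    if (frameMask(frame)[r, c]) next
    vals <- c(vals, frameData(frame)[r, c])
  }
  list(min = min(vals), max = max(vals), average = mean(vals),
       sum = sum(vals), nPix = length(vals))
}

# small random frame with a random mask, reproducible
randomFrame <- function(seed, nr = 24, nc = 26, maskFrac = 0.1) {
  set.seed(seed)
  data <- matrix(rpois(nr * nc, 50), nr, nc)
  mask <- matrix(runif(nr * nc) < maskFrac, nr, nc)
  detectorFrame(data, mask = mask)
}

smallTransGeom <- function(nr = 24, nc = 26)
  experimentGeometry(0.1, 800, c((nc - 1) / 2 + 0.3, (nr - 1) / 2 - 0.2),
                     c(1.0, 1.1))

smallGrazGeom <- function(nr = 24, nc = 26)
  experimentGeometry(0.096, 1000, c((nc - 1) / 2, nr - 2), 0.172,
                     incidence = 0.5, mode = "grazing")
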