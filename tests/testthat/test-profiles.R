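# Radial/azimuthal integration, GISAXS cuts, ROI statistics.

test_that("radial profile of a uniform image is flat and conserves counts", {
  geom <- smallTransGeom()
  fr <- detectorFrame(matrix(7.5, 24, 26))
  qm <- buildQMap(dim(fr), geom)
  breaks <- seq(0.05, max(qm@q) + 0.01, length.out = 15)
  cv <- radialProfile(fr, qm, breaks)
  expect_true(all(curveY(cv)[curveN(cv) > 0] == 7.5))
  # conservation: sum(y * nPix) equals the brute-force in-range pixel sum
  inRange <- qm@q >= breaks[1] & qm@q <= breaks[length(breaks)]
  expect_equal(sum(curveY(cv) * curveN(cv), na.rm = TRUE),
               sum(frameData(fr)[inRange]))
})

test_that("radial profile recovers a smooth planted I(q) within binning error", {
  geom <- smallTransGeom(64, 64)
  qm <- buildQMap(c(64, 64), geom)
  f <- function(q) 100 * exp(-q / 2)
  fr <- detectorFrame(matrix(f(qm@q), 64, 64))
  breaks <- seq(0.1, max(qm@q), length.out = 40)
  cv <- radialProfile(fr, qm, breaks)
  binw <- diff(breaks)[1]
  maxSlope <- max(abs(100 / 2 * exp(-breaks / 2)))
  ok <- curveN(cv) > 0
  expect_true(all(abs(curveY(cv)[ok] - f(curveX(cv)[ok])) <=
                    maxSlope * binw))
})

test_that("radial and azimuthal profiles equal the loop-based pixel oracles", {
  geom <- smallTransGeom()
  for (seed in c(101, 102)) {
    fr <- randomFrame(seed, maskFrac = 0.12)
    qm <- buildQMap(dim(fr), geom)
    breaks <- seq(0.1, max(qm@q) * 0.95, length.out = 9)
    cv <- radialProfile(fr, qm, breaks)
    orc <- oracleRadial(fr, qm, breaks)
    expect_identical(curveN(cv), as.numeric(orc$n))
    expect_equal(curveY(cv), orc$y, tolerance = 1e-13)
    # with a wrap-around chi restriction
    cvc <- radialProfile(fr, qm, breaks, chiRange = c(300, 60))
    orcc <- oracleRadial(fr, qm, breaks, chiRange = c(300, 60))
    expect_identical(curveN(cvc), as.numeric(orcc$n))
    expect_equal(curveY(cvc), orcc$y, tolerance = 1e-13)
    chiBreaks <- seq(0, 360, by = 30)
    qr <- c(0.2, max(qm@q) * 0.8)
    az <- azimuthalProfile(fr, qm, qr, chiBreaks)
    orca <- oracleAzimuthal(fr, qm, qr, chiBreaks)
    expect_identical(curveN(az), as.numeric(orca$n))
    expect_equal(curveY(az), orca$y, tolerance = 1e-13)
  }
})

test_that("empty annulus and all-masked selections are reported", {
  geom <- smallTransGeom()
  fr <- randomFrame(5)
  qm <- buildQMap(dim(fr), geom)
  expect_error(azimuthalProfile(fr, qm, c(50, 60)), "empty annulus")
  expect_warning(radialProfile(fr, qm, c(50, 60)), "all-NaN")
})

test_that("azimuthal profile of an anisotropic pattern peaks 180 deg apart", {
  geom <- synthGeometry("transmission", c(96, 96))
  ap <- anisotropicPattern(geom, c(96, 96), chi0 = 35, a = 6, b = 1,
                           seed = 3)
  qm <- buildQMap(c(96, 96), geom)
  az <- azimuthalProfile(ap$frame, qm, c(0.5, 2), seq(0, 360, by = 5))
  y <- curveY(az); x <- curveX(az)
  # two maxima separated by ~180 degrees
  half1 <- which(x < 180); half2 <- which(x >= 180)
  m1 <- x[half1][which.max(y[half1])]
  m2 <- x[half2][which.max(y[half2])]
  expect_lt(abs((m2 - m1) - 180), 15)
  expect_lt(abs(m1 - 35), 15)
  # isotropic control: flat within counting noise
  iso <- anisotropicPattern(geom, c(96, 96), a = 0, b = 1, flux = 2000,
                            seed = 4)
  azi <- azimuthalProfile(iso$frame, qm, c(0.5, 2), seq(0, 360, by = 15))
  yi <- curveY(azi)
  expect_lt((max(yi) - min(yi)) / mean(yi), 0.2)
})

test_that("radial profile of an isotropic pattern ignores chi restriction", {
  geom <- synthGeometry("transmission", c(96, 96))
  iso <- anisotropicPattern(geom, c(96, 96), a = 0, b = 1, flux = 5000,
                            seed = 9)
  qm <- buildQMap(c(96, 96), geom)
  breaks <- seq(0.3, 3, length.out = 12)
  full <- radialProfile(iso$frame, qm, breaks)
  sector <- radialProfile(iso$frame, qm, breaks, chiRange = c(10, 100))
  ok <- curveN(sector) > 20
  expect_true(all(abs(curveY(full)[ok] - curveY(sector)[ok]) /
                    curveY(full)[ok] < 0.1))
})

test_that("GISAXS cuts match the brute-force pixel selection", {
  geom <- smallGrazGeom()
  fr <- randomFrame(51, maskFrac = 0.1)
  qm <- buildQMap(dim(fr), geom)
  at <- stats::median(qm@qz); w <- diff(range(qm@qz)) / 6
  cut <- gisaxsCut(fr, qm, "horizontal", at = at, roiWidth = w)
  orc <- oracleCutHorizontal(fr, qm, at, w)
  expect_equal(curveX(cut), orc$x, tolerance = 1e-13)
  expect_equal(curveY(cut), orc$y, tolerance = 1e-13)
  expect_identical(curveN(cut), as.numeric(orc$n))
})

test_that("a one-pixel-high ROI reproduces that detector row", {
  geom <- smallGrazGeom()
  fr <- randomFrame(52, maskFrac = 0)
  qm <- buildQMap(dim(fr), geom)
  row <- 8   # 1-based matrix row
  at <- qm@qz[row, 1]
  pixQz <- abs(qm@qz[row, 1] - qm@qz[row + 1, 1])
  cut <- gisaxsCut(fr, qm, "horizontal", at = at, roiWidth = pixQz * 0.9)
  # qz varies slightly along the row; all selected pixels must be row 8
  expect_equal(sum(curveN(cut)), sum(abs(qm@qz - at) <= pixQz * 0.45))
  expect_equal(curveY(cut)[match(qm@qy[row, 3], curveX(cut))],
               frameData(fr)[row, 3])
})

test_that("vertical and arbitrary cuts run along the stated directions", {
  geom <- smallGrazGeom()
  fr <- randomFrame(53, maskFrac = 0)
  qm <- buildQMap(dim(fr), geom)
  vc <- gisaxsCut(fr, qm, "vertical", at = 0,
                  roiWidth = diff(range(qm@qy)) / 5)
  expect_true(all(diff(curveX(vc)) > 0))
  expect_equal(min(curveX(vc)), min(qm@qz), tolerance = 0.05)
  # a 90-degree arbitrary cut is the vertical cut's geometry
  ac <- gisaxsCut(fr, qm, "arbitrary", at = 0, angle = 90,
                  roiWidth = diff(range(qm@qy)) / 5)
  expect_true(all(diff(curveX(ac)) > 0))
  expect_error(gisaxsCut(fr, qm, "horizontal", at = 99, roiWidth = 0.01),
               "outside")
})

test_that("cuts locate a planted side maximum", {
  geom <- synthGeometry("grazing")
  ser <- gisaxsSeries(geom, 1, 0.55, seed = 8)
  qm <- buildQMap(c(100, 160), geom)
  cut <- gisaxsCut(ser$frames[[1]], qm, "horizontal", at = 0.25,
                   roiWidth = 0.15)
  keep <- curveX(cut) > 0.2
  xa <- curveX(cut)[keep][which.max(curveY(cut)[keep])]
  expect_lt(abs(xa - 0.55), 0.03)
})

test_that("ROI statistics match Fig.-3-style brute force and clip edges", {
  fr <- detectorFrame(matrix(2, 10, 10))
  st <- roiStats(fr, 2, 3, 5, 5)
  expect_equal(st[c("min", "max", "average", "sum")],
               list(min = 2, max = 2, average = 2, sum = 50))
  rf <- randomFrame(61)
  st2 <- roiStats(rf, 3, 5, 9, 7)
  orc <- oracleRoi(rf, 3, 5, 9, 7)
  expect_equal(st2, orc)
  # sum = average * unmasked count
  expect_equal(st2$sum, st2$average * st2$nPix)
  # clipped at the border
  stc <- roiStats(rf, 20, 20, 100, 100)
  orcc <- oracleRoi(rf, 20, 20, 100, 100)
  expect_equal(stc, orcc)
  expect_error(roiStats(rf, 400, 0, 5, 5), "intersect")
  allMask <- detectorFrame(matrix(1, 5, 5),
                           mask = rbind(matrix(TRUE, 4, 5), FALSE))
  expect_error(roiStats(allMask, 0, 0, 5, 2), "masked")
})

test_that("enlarging the mask never changes untouched bins", {
  geom <- smallTransGeom()
  fr <- randomFrame(71, maskFrac = 0.05)
  qm <- buildQMap(dim(fr), geom)
  breaks <- seq(0.1, max(qm@q) * 0.95, length.out = 10)
  base <- radialProfile(fr, qm, breaks)
  for (rep in 1:5) {
    set.seed(700 + rep)
    extra <- frameMask(fr)
    extra[sample(length(extra), 25)] <- TRUE
    fr2 <- detectorFrame(frameData(fr), mask = extra,
                         sigma = frameSigma(fr))
    cv2 <- radialProfile(fr2, qm, breaks)
    untouched <- curveN(cv2) == curveN(base)
    expect_equal(curveY(cv2)[untouched], curveY(base)[untouched])
  }
})
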