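# Peak shapes, least-squares fitting, series propagation.

test_that("peak shapes obey the FWHM and mixing-limit identities", {
  x <- seq(-3, 7, by = 0.01)
  g <- peakModel(list(gaussianPeak(2, 1, 0.8)))
  l <- peakModel(list(lorentzianPeak(2, 1, 0.8)))
  # half height at x0 +/- w/2
  expect_equal(evaluatePeakModel(g, c(0.6, 1.4)), c(1, 1), tolerance = 1e-12)
  expect_equal(evaluatePeakModel(l, c(0.6, 1.4)), c(1, 1), tolerance = 1e-12)
  expect_equal(evaluatePeakModel(g, 1), 2)
  # pseudo-Voigt limits reproduce the pure shapes at every x
  pv0 <- peakModel(list(pseudoVoigtPeak(2, 1, 0.8, eta = 0)))
  pv1 <- peakModel(list(pseudoVoigtPeak(2, 1, 0.8, eta = 1)))
  expect_equal(evaluatePeakModel(pv0, x), evaluatePeakModel(g, x),
               tolerance = 1e-14)
  expect_equal(evaluatePeakModel(pv1, x), evaluatePeakModel(l, x),
               tolerance = 1e-14)
  # peaks and background sum
  both <- peakModel(list(gaussianPeak(2, 1, 0.8), lorentzianPeak(1, 4, 2)),
                    background = list(type = "linear", coef = c(0.5, 0.1)))
  expect_equal(evaluatePeakModel(both, x),
               evaluatePeakModel(g, x) +
                 evaluatePeakModel(peakModel(list(lorentzianPeak(1, 4, 2))),
                                   x) + 0.5 + 0.1 * x,
               tolerance = 1e-14)
})

test_that("closed-form areas match numerical integration to 1e-6 relative", {
  for (shape in c("gaussian", "lorentzian", "pseudo_voigt")) {
    A <- 3.2; w <- 0.45; eta <- 0.37
    peak <- switch(shape,
                   gaussian = gaussianPeak(A, 2, w),
                   lorentzian = lorentzianPeak(A, 2, w),
                   pseudo_voigt = pseudoVoigtPeak(A, 2, w, eta))
    m <- peakModel(list(peak))
    num <- stats::integrate(function(x) evaluatePeakModel(m, x),
                            -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(num, peakArea(shape, A, w, eta), tolerance = 1e-6)
  }
})

test_that("noiseless data are recovered to 1e-6 relative from exact init", {
  x <- seq(0, 4, length.out = 120)
  true <- peakModel(list(gaussianPeak(10, 1.7, 0.5)),
                    background = list(type = "constant", coef = 1))
  y <- evaluatePeakModel(true, x)
  init <- peakModel(list(gaussianPeak(8, 1.5, 0.7)),
                    background = list(type = "constant", coef = 0.5))
  fit <- fitCurve(list(x = x, y = y), init)
  expect_true(fitConverged(fit))
  p <- fitParameters(fit)
  expect_equal(p[["p1.amplitude"]], 10, tolerance = 1e-6)
  expect_equal(p[["p1.center"]], 1.7, tolerance = 1e-6)
  expect_equal(p[["p1.fwhm"]], 0.5, tolerance = 1e-6)
  expect_equal(p[["bg.c0"]], 1, tolerance = 1e-6)
  expect_lt(fit@redchi, 1e-12)
})

test_that("initial values outside the bounds fail before optimization", {
  x <- seq(0, 4, length.out = 50)
  m <- peakModel(list(gaussianPeak(5, 2, 0.5)))
  expect_error(fitCurve(list(x = x, y = x), m,
                        lower = c(p1.amplitude = 10)), "outside")
  expect_error(fitCurve(list(x = x[1:3], y = x[1:3]), m), "fewer")
})

test_that("parameter ties are honoured and propagated to uncertainties", {
  x <- seq(0, 360, by = 3)
  true <- peakModel(list(gaussianPeak(5, 40, 25), gaussianPeak(5, 220, 25)),
                    background = list(type = "constant", coef = 2))
  set.seed(10)
  y <- evaluatePeakModel(true, x) + rnorm(length(x), 0, 0.1)
  tied <- peakModel(list(gaussianPeak(4, 35, 30), gaussianPeak(4, 215, 30)),
                    background = list(type = "constant", coef = 1),
                    ties = list(
                      list(target = "p2.amplitude", source = "p1.amplitude"),
                      list(target = "p2.center", source = "p1.center",
                           offset = 180),
                      list(target = "p2.fwhm", source = "p1.fwhm")))
  fit <- fitCurve(list(x = x, y = y), tied)
  expect_true(fitConverged(fit))
  p <- fitParameters(fit)
  expect_identical(p[["p2.center"]], p[["p1.center"]] + 180)
  expect_identical(p[["p2.amplitude"]], p[["p1.amplitude"]])
  s <- fitStderr(fit)
  expect_identical(s[["p2.center"]], s[["p1.center"]])
  expect_lt(abs(p[["p1.center"]] - 40), 1)
})

test_that("uncertainties calibrate on noisy Lorentzians (coverage check)", {
  # Poisson-noisy Lorentzian, A=1000, x0=1, w=0.2, 200 points; the fitted
  # x0 and w should sit within 3 standard errors in ~95% of replicates
  x <- seq(0.3, 1.7, length.out = 200)
  true <- peakModel(list(lorentzianPeak(1000, 1, 0.2)),
                    background = list(type = "constant", coef = 20))
  mu <- evaluatePeakModel(true, x)
  hits <- 0L; n <- 80L
  for (rep in seq_len(n)) {
    set.seed(1000 + rep)
    y <- rpois(length(x), mu)
    init <- peakModel(list(lorentzianPeak(900, 1.05, 0.25)),
                      background = list(type = "constant", coef = 10))
    fit <- fitCurve(list(x = x, y = y, sigma = sqrt(pmax(y, 1))), init)
    if (!fitConverged(fit)) next
    p <- fitParameters(fit); s <- fitStderr(fit)
    okx <- abs(p[["p1.center"]] - 1) <= 3 * s[["p1.center"]]
    okw <- abs(p[["p1.fwhm"]] - 0.2) <= 3 * s[["p1.fwhm"]]
    if (okx && okw) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.9)
})

test_that("fitting is shift and scale equivariant", {
  x <- seq(0, 4, length.out = 150)
  true <- peakModel(list(gaussianPeak(10, 1.7, 0.5)),
                    background = list(type = "constant", coef = 1))
  set.seed(3)
  y <- evaluatePeakModel(true, x) + rnorm(length(x), 0, 0.05)
  init <- peakModel(list(gaussianPeak(9, 1.6, 0.6)),
                    background = list(type = "constant", coef = 0.8))
  fit1 <- fitCurve(list(x = x, y = y), init)
  a <- 2.5; b <- -1.0
  init2 <- peakModel(list(gaussianPeak(9, 1.6 * a + b, 0.6 * a)),
                     background = list(type = "constant", coef = 0.8))
  fit2 <- fitCurve(list(x = a * x + b, y = y), init2)
  p1 <- fitParameters(fit1); p2 <- fitParameters(fit2)
  expect_equal(p2[["p1.center"]], a * p1[["p1.center"]] + b,
               tolerance = 1e-6)
  expect_equal(p2[["p1.fwhm"]], a * p1[["p1.fwhm"]], tolerance = 1e-6)
  expect_equal(p2[["p1.amplitude"]], p1[["p1.amplitude"]], tolerance = 1e-6)
})

test_that("series fits propagate, fall back, and keep row order", {
  x <- seq(0, 4, length.out = 100)
  m <- peakModel(list(gaussianPeak(9, 1.6, 0.6)),
                 background = list(type = "constant", coef = 0.5))
  mkCurve <- function(c0, seed) {
    set.seed(seed)
    true <- peakModel(list(gaussianPeak(10, c0, 0.5)),
                      background = list(type = "constant", coef = 1))
    list(x = x, y = evaluatePeakModel(true, x) + rnorm(length(x), 0, 0.05))
  }
  same <- replicate(5, mkCurve(1.7, 77), simplify = FALSE)
  res <- fitSeries(same, m)
  expect_equal(nrow(res), 5)
  expect_equal(res$frame, 1:5)
  expect_true(all(res$converged))
  expect_equal(res$p1.center, rep(res$p1.center[1], 5), tolerance = 1e-8)
  # propagate = FALSE equals independent per-frame fits
  drift <- lapply(1:6, function(k) mkCurve(1.2 + 0.1 * k, 80 + k))
  indep <- fitSeries(drift, m, propagate = FALSE)
  solo <- vapply(drift, function(cv)
    fitParameters(fitCurve(cv, m))[["p1.center"]], numeric(1))
  expect_equal(indep$p1.center, solo, tolerance = 1e-12)
  # a hopeless frame is flagged, not fatal
  broken <- drift
  broken[[3]] <- list(x = x, y = rep(NaN, length(x)))
  expect_error(res2 <- fitSeries(broken, m), NA)
  expect_equal(nrow(res2), 6)
})
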