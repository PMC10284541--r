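# Passive spectroscopy: spectra, focal spots, wavelength fits, dispersion
# assembly, central frequency.

test_that("temporalSpectrum localizes bin-aligned tones exactly", {
  fs <- 38; nT <- 152L
  tt <- seq(0, by = 1 / fs, length.out = nT)
  x <- seq(0, 1e-3, by = 1e-4)
  f0 <- 6 * fs / nT  # exactly 1.5 Hz
  phi <- matrix(rep(cos(2 * pi * f0 * tt), each = length(x)),
                nrow = length(x))
  fld <- temporalSpectrum(CurvilinearSignal(x, tt, phi), detrend = FALSE)
  expect_equal(fld@f[which.max(fld@meanSpectrum)], 1.5, tolerance = 1e-12)
  off <- fld@meanSpectrum[abs(fld@f - 1.5) > 1e-9]
  expect_lt(max(off), 1e-10 * max(fld@meanSpectrum))
})

test_that("detrending removes constant and linear content", {
  x <- seq(0, 1e-3, by = 1e-4)
  tt <- seq(0, by = 1 / 38, length.out = 64)
  phi <- outer(seq_along(x), 3 + 0.5 * tt, function(i, v) v)
  fld <- temporalSpectrum(CurvilinearSignal(x, tt, phi), detrend = TRUE)
  expect_lt(max(fld@meanSpectrum[fld@f > 0]), 1e-10)
  expect_error(temporalSpectrum(CurvilinearSignal(
    x, tt[1:8], phi[, 1:8])), "16")
})

test_that("two-tone amplitude ratios are preserved", {
  fs <- 40; nT <- 160L
  tt <- seq(0, by = 1 / fs, length.out = nT)
  x <- seq(0, 1e-3, by = 1e-4)
  f1 <- 8 * fs / nT; f2 <- 20 * fs / nT
  phi <- matrix(rep(1.0 * cos(2 * pi * f1 * tt) +
                      0.4 * cos(2 * pi * f2 * tt),
                    each = length(x)), nrow = length(x))
  fld <- temporalSpectrum(CurvilinearSignal(x, tt, phi), detrend = FALSE)
  a1 <- fld@meanSpectrum[which.min(abs(fld@f - f1))]
  a2 <- fld@meanSpectrum[which.min(abs(fld@f - f2))]
  expect_rel_equal(a2 / a1, 0.4, 1e-9)
})

test_that("the focal spot of a plane wave is an exact cosine", {
  lambda <- 2.2e-3
  fld <- planeWaveField(lambda)
  fBin <- round(6.7 * 128 / 38) * 38 / 128
  spot <- focalSpot(fld, fBin)
  expect_lt(max(abs(spot@C - cos(2 * pi * spot@r / lambda))), 1e-10)
  expect_identical(spot@C[spot@r == 0], 1)
})

test_that("focal spots are phase-only: amplitude envelopes drop out", {
  lambda <- 2.2e-3
  nPos <- 64L; dx <- 1e-4; nT <- 128L; fs <- 38
  x <- seq(0, by = dx, length.out = nPos)
  tt <- seq(0, by = 1 / fs, length.out = nT)
  fBin <- round(6.7 * nT / fs) * fs / nT
  base <- cos(outer(-2 * pi * x / lambda, 2 * pi * fBin * tt, "+"))
  env <- 0.2 + runif(nPos)
  fld1 <- temporalSpectrum(CurvilinearSignal(x, tt, base),
                           detrend = FALSE)
  fld2 <- temporalSpectrum(CurvilinearSignal(x, tt, env * base),
                           detrend = FALSE)
  s1 <- focalSpot(fld1, fBin); s2 <- focalSpot(fld2, fBin)
  expect_equal(s1@C, s2@C, tolerance = 1e-12)
})

test_that("counter-propagating waves give an even focal spot", {
  nPos <- 64L; dx <- 1e-4; nT <- 128L; fs <- 38
  x <- seq(0, by = dx, length.out = nPos)
  tt <- seq(0, by = 1 / fs, length.out = nT)
  fBin <- round(6.7 * nT / fs) * fs / nT
  lambda <- 1.7e-3
  phi <- cos(outer(-2 * pi * x / lambda, 2 * pi * fBin * tt, "+")) +
    cos(outer(2 * pi * x / lambda, 2 * pi * fBin * tt, "+"))
  fld <- temporalSpectrum(CurvilinearSignal(x, tt, phi), detrend = FALSE)
  spot <- focalSpot(fld, fBin)
  expect_equal(spot@C, rev(spot@C), tolerance = 1e-10)
})

test_that("degenerate focal-spot inputs error rather than mislead", {
  x <- seq(0, 1e-3, by = 1e-4)
  tt <- seq(0, by = 1 / 38, length.out = 64)
  fld <- temporalSpectrum(CurvilinearSignal(
    x, tt, matrix(0, length(x), length(tt))), detrend = FALSE)
  expect_error(focalSpot(fld, 3), "zero spectral amplitude")
  flat <- new(Class = "FocalSpot", r = seq(-5, 5) * 1e-4,
              C = c(rep(1, 5), 1, rep(1, 5)), fCenter = 3)
  expect_error(fitWavelength(flat), "flat")
})

test_that("fitWavelength recovers exact and truncated cosines", {
  r <- seq(-2.65e-3, 2.65e-3, by = 5.52e-5)
  r <- r - r[which.min(abs(r))]  # ensure a lag exactly at 0
  lam0 <- 1.9e-3
  spot <- new(Class = "FocalSpot", r = r, C = cos(2 * pi * r / lam0),
              fCenter = 5)
  est <- fitWavelength(spot)
  expect_rel_equal(est[["lambda"]], lam0, 1e-4)

  # aperture = lambda/4: only part of the central lobe is visible
  lamBig <- 8 * max(r)
  spotT <- new(Class = "FocalSpot", r = r, C = cos(2 * pi * r / lamBig),
               fCenter = 5)
  estT <- fitWavelength(spotT)
  expect_rel_equal(estT[["lambda"]], lamBig, 0.1)
})

test_that("dispersion of a non-dispersive field is flat", {
  tv <- travelingSignal(0.012)
  fld <- temporalSpectrum(tv$sig)
  fList <- seq_along(tv$source@amplitudes) * tv$source@fundamentalHz
  crv <- dispersionCurve(fld, fList)
  expect_true(all(crv@fitOk))
  expect_lt(diff(range(crv@v)) / mean(crv@v), 0.02)
  expect_equal(crv@v, crv@lambda * crv@f)  # exact identity
  expect_error(dispersionCurve(fld, numeric()), "empty")
})

test_that("recovered dispersion exponent of the flexural law is 1/2", {
  g <- retinalGeometry(100e-6)
  tv <- travelingSignal(function(f) vFpwLowfreq(f, g),
                        amplitudes = rep(1, 7), nPos = 256L,
                        aperture = 10.6e-3, duration = 16)
  fld <- temporalSpectrum(tv$sig)
  fList <- seq_along(tv$source@amplitudes) * tv$source@fundamentalHz
  crv <- dispersionCurve(fld, fList)
  expect_true(all(crv@fitOk))
  slope <- stats::coef(lm(log(crv@v) ~ log(crv@f * g@d)))[[2]]
  expect_gt(slope, 0.48)
  expect_lt(slope, 0.52)
})

test_that("polychromatic spots agree with monochromatic ones", {
  tv <- travelingSignal(0.012, amplitudes = c(0, 0, 1))
  fld <- temporalSpectrum(tv$sig, detrend = FALSE)
  f3 <- 3 * tv$source@fundamentalHz
  mono <- focalSpot(fld, f3)
  poly <- polychromaticFocalSpot(fld, c(f3 - 0.4, f3 + 0.4))
  expect_equal(poly@C, mono@C, tolerance = 1e-10)

  # narrowband multi-tone: polychromatic lambda near the band-center one
  tv2 <- travelingSignal(0.012, amplitudes = c(0, 0, 1, 1, 1))
  fld2 <- temporalSpectrum(tv2$sig, detrend = FALSE)
  f4 <- 4 * tv2$source@fundamentalHz
  lamPoly <- fitWavelength(polychromaticFocalSpot(
    fld2, c(3, 5) * tv2$source@fundamentalHz))[["lambda"]]
  lamMono <- fitWavelength(focalSpot(fld2, f4))[["lambda"]]
  expect_rel_equal(lamPoly, lamMono, 0.05)
  expect_error(polychromaticFocalSpot(fld2, c(17, 18)), "band")
})

test_that("central frequency comes from the autocorrelation period", {
  fs <- 500
  tt <- seq(0, 2, by = 1 / fs)
  expect_rel_equal(centralFrequency(cos(2 * pi * 7.5 * tt), dt = 1 / fs),
                   7.5, 1 / (7.5 * length(tt) / fs) + 0.02)
  expect_error(centralFrequency(rep(1, 500), dt = 1 / fs), "constant")

  # band-limited noise: estimate falls inside the synthesis band
  set.seed(8)
  n <- 1000L
  sp <- fft(rnorm(n))
  f <- (0:(n - 1)) * fs / n
  fFold <- pmin(f, fs - f)
  sp[fFold < 6 | fFold > 19] <- 0
  y <- Re(fft(sp, inverse = TRUE)) / n
  fc <- centralFrequency(y, dt = 1 / fs)
  expect_gt(fc, 6); expect_lt(fc, 19)
})
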