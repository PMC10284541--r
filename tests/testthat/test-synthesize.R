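# Synthetic-data generator: harmonic sources, traveling-mode propagation,
# movie and wall rendering, determinism and spectral purity.

acqSmall <- AcquisitionSpec(38, 8, 5.3e-3 / 96, 5.3e-3, seed = 11L)

test_that("makeSource reproduces the closed-form harmonic sum", {
  s <- makeSource(SourceSpectrum(1.5, amplitudes = 1), acqSmall)
  tt <- attr(s, "t")
  expect_equal(as.numeric(s), cos(2 * pi * 1.5 * tt), tolerance = 1e-12)

  s0 <- makeSource(SourceSpectrum(1.5, amplitudes = c(0, 0)), acqSmall)
  expect_true(all(s0 == 0))

  withPhase <- makeSource(SourceSpectrum(2, amplitudes = c(0.5, 0.25),
                                         phases = c(0.3, -0.2)), acqSmall)
  expect_equal(as.numeric(withPhase),
               0.5 * cos(2 * pi * 2 * tt + 0.3) +
                 0.25 * cos(2 * pi * 4 * tt - 0.2), tolerance = 1e-12)
})

test_that("source spectrum peaks sit exactly on the synthesized harmonics", {
  acq <- AcquisitionSpec(38, 8, 1e-4, 5.3e-3)
  src <- binAlignSource(SourceSpectrum(1.5, amplitudes = rep(1, 5)), acq)
  s <- makeSource(src, acq)
  n <- length(s)
  mag <- Mod(fft(as.numeric(s)))[seq_len(n / 2)]
  f <- (seq_len(n / 2) - 1) * 38 / n
  found <- f[mag > 0.5 * max(mag)]
  expect_equal(found, seq_len(5) * src@fundamentalHz, tolerance = 1e-9)
})

test_that("harmonics at or above Nyquist are rejected", {
  expect_error(makeSource(SourceSpectrum(10, amplitudes = c(1, 1)),
                          acqSmall), "Nyquist")
  expect_error(propagateMode(SourceSpectrum(10, amplitudes = c(1, 1)),
                             ModeSpec("symmetric", 1), 0:3 * 1e-4,
                             acqSmall), "Nyquist")
})

test_that("constant-velocity propagation is a pure traveling cosine", {
  x <- seq(0, 5e-3, by = 1e-4)
  v0 <- 0.01
  u <- propagateMode(SourceSpectrum(1.5, amplitudes = 0.7, phases = 0.4),
                     ModeSpec("antisymmetric", v0, amplitude = 2), x,
                     acqSmall)
  tt <- attr(u, "t")
  expected <- 2 * 0.7 * cos(outer(-2 * pi * 1.5 * x / v0,
                                  2 * pi * 1.5 * tt, "+") + 0.4)
  expect_equal(unname(u), unname(expected), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the dispersive flexural law gives ~2.5 mm wavelength at 10 Hz", {
  g <- retinalGeometry(100e-6)
  v10 <- vFpwLowfreq(10, g)
  expect_rel_equal(v10 / 10, 2.5e-3, 0.01)
})

test_that("reversing the direction flips the spatial phase gradient", {
  x <- seq(0, 5e-3, by = 1e-4)
  uR <- propagateMode(SourceSpectrum(1.5), ModeSpec("symmetric", 0.01),
                      x, acqSmall)
  uL <- propagateMode(SourceSpectrum(1.5),
                      ModeSpec("symmetric", 0.01, direction = -1), x,
                      acqSmall)
  # a leftward wave at x equals the rightward wave evaluated at -x
  uRneg <- propagateMode(SourceSpectrum(1.5), ModeSpec("symmetric", 0.01),
                         -x, acqSmall)
  expect_equal(unname(uL), unname(uRneg), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(propagateMode(SourceSpectrum(1.5),
                             ModeSpec("symmetric", function(f) 0 * f),
                             x, acqSmall), "positive")
})

test_that("renderMovie without fields or noise is static", {
  cl <- arcCenterline(24, 64)
  mv <- renderMovie(list(), acqSmall, cl, 24, 64)
  expect_s4_class(mv, "VesselMovie")
  mean_img <- rowMeans(mv@frames, dims = 2)
  for (j in seq_len(dim(mv@frames)[3]))
    expect_equal(mv@frames[, , j], mean_img, tolerance = 1e-14)
})

test_that("a monochromatic field puts all on-vessel energy in one bin", {
  cl <- arcCenterline(24, 64)
  acq <- AcquisitionSpec(38, 8, 5.3e-3 / 64, 5.3e-3, seed = 3L)
  src <- binAlignSource(SourceSpectrum(3, amplitudes = 1), acq)
  xg <- seq(0, 7e-3, by = 5e-5)
  u <- propagateMode(src, ModeSpec("antisymmetric", 0.01, amplitude = 0.2),
                     xg, acq)
  mv <- renderMovie(list(u), acq, cl, 24, 64)
  px <- mv@frames[round(cl[1, 1]) + 1, 32, ]  # a pixel on the vessel
  n <- length(px)
  mag <- Mod(fft(px - mean(px)))[2:(n / 2)]
  f <- (2:(n / 2) - 1) * 38 / n
  expect_rel_equal(f[which.max(mag)], src@fundamentalHz, 1e-9)
  # energy placement: off-harmonic bins are empty to round-off
  off <- mag[abs(f - src@fundamentalHz) > 1e-9]
  expect_lt(max(off), 1e-10 * max(mag))
})

test_that("rendering is deterministic for one seed and linear in fields", {
  cl <- arcCenterline(20, 48)
  acq <- AcquisitionSpec(38, 8, 1e-4, 5e-3, noiseSigma = 0.05, seed = 42L)
  xg <- seq(0, 6e-3, by = 5e-5)
  src <- binAlignSource(SourceSpectrum(1.5, amplitudes = c(1, 0.5)), acq)
  u1 <- propagateMode(src, ModeSpec("antisymmetric", 0.01,
                                    amplitude = 0.1), xg, acq)
  m1 <- renderMovie(list(u1), acq, cl, 20, 48)
  m2 <- renderMovie(list(u1), acq, cl, 20, 48)
  expect_identical(m1@frames, m2@frames)

  acq0 <- AcquisitionSpec(38, 8, 1e-4, 5e-3, noiseSigma = 0, seed = 42L)
  u2 <- propagateMode(src, ModeSpec("symmetric", 0.02, amplitude = 0.07),
                      xg, acq0)
  both <- renderMovie(list(u1, u2), acq0, cl, 20, 48)
  a <- renderMovie(list(u1), acq0, cl, 20, 48)
  b <- renderMovie(list(u2), acq0, cl, 20, 48)
  base <- renderMovie(list(), acq0, cl, 20, 48)
  expect_equal(both@frames, a@frames + b@frames - base@frames,
               tolerance = 1e-12)
})

test_that("renderMovie rejects bad geometry", {
  cl <- arcCenterline(24, 64)
  expect_error(renderMovie(list(), acqSmall, cl, 10, 64), "outside")
  expect_error(renderMovie(list(), acqSmall, cl, 24, 64,
                           vesselSigmaPx = 0), "positive")
})

test_that("renderWalls applies the axial-beam sign convention", {
  x <- seq(0, 0.04, length.out = 32)
  acq <- AcquisitionSpec(500, 2, 0.04 / 32, 0.04, seed = 5L)
  src <- binAlignSource(SourceSpectrum(1.5, amplitudes = c(0, 0, 1, 1)),
                        acq)
  uS <- propagateMode(src, ModeSpec("symmetric", 3.4, amplitude = 1e-4),
                      x, acq)
  uA <- propagateMode(src, ModeSpec("antisymmetric", 0.5,
                                    amplitude = 2e-4), x, acq)
  zero <- uS * 0
  attr(zero, "x") <- x; attr(zero, "t") <- attr(uS, "t")

  pureFlex <- renderWalls(zero, uA, acq0 <- AcquisitionSpec(
    500, 2, 0.04 / 32, 0.04, noiseSigma = 0, seed = 5L))
  expect_equal(pureFlex@uTop, pureFlex@uBottom, tolerance = 1e-15)

  pureExp <- renderWalls(uS, zero, acq0)
  expect_equal(pureExp@uTop, -pureExp@uBottom, tolerance = 1e-15)

  walls <- renderWalls(uS, uA, acq0)
  mf <- separateModes(walls)
  expect_equal(mf@symmetric, unname(uS), tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(mf@antisymmetric, unname(uA), tolerance = 1e-14,
               ignore_attr = TRUE)
})

test_that("scenario generators are reproducible end to end", {
  a <- retinalScenario(seed = 9, duration = 8, nRows = 24, nCols = 64)
  b <- retinalScenario(seed = 9, duration = 8, nRows = 24, nCols = 64)
  expect_identical(a$movie@frames, b$movie@frames)
  ca <- carotidScenario(seed = 4, duration = 1)
  cb <- carotidScenario(seed = 4, duration = 1)
  expect_identical(ca$walls@uTop, cb$walls@uTop)
  expect_identical(ca$walls@uBottom, cb$walls@uBottom)
})
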