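# Vessel segmentation and cross-section reduction.

straightVesselImage <- function(nRows = 32L, nCols = 96L, rowC = 15.5,
                                sigma = 2.5) {
  r <- matrix(0:(nRows - 1), nRows, nCols)
  0.1 + exp(-(r - rowC)^2 / (2 * sigma^2))
}

test_that("a straight vessel yields the horizontal midline", {
  img <- straightVesselImage()
  pitch <- 5e-5
  seg <- segmentVessel(img, pitch)
  inner <- seg@centerline[5:(nrow(seg@centerline) - 5), ]
  expect_true(all(abs(inner[, "row"] - 15.5) < 0.5))
  expect_equal(diff(seg@abscissa)[1], pitch, tolerance = 1e-9)
  expect_true(all(diff(seg@abscissa) > 0))
})

test_that("a blank image raises a no-vessel error", {
  expect_error(segmentVessel(matrix(0.5, 32, 32), 1e-5), "no vessel")
})

test_that("a short vessel fails the minimum-section check", {
  img <- straightVesselImage(nCols = 24L)
  expect_error(segmentVessel(img, 1e-5, minSections = 30L), "too short")
})

test_that("arc length of a curved vessel matches the analytic value", {
  nR <- 48L; nC <- 96L
  sag <- 8
  cl <- arcCenterline(nR, nC, sagPx = sag)
  img <- matrix(0.1, nR, nC)
  for (i in seq_len(nrow(cl))) {
    rows <- pmax(1, pmin(nR, round(cl[i, 1]) + (-6:6) + 1))
    img[rows, round(cl[i, 2]) + 1] <-
      pmax(img[rows, round(cl[i, 2]) + 1],
           0.1 + exp(-((rows - 1) - cl[i, 1])^2 / (2 * 2.5^2)))
  }
  pitch <- 4e-5
  seg <- segmentVessel(img, pitch)
  trueLen <- sum(sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)) * pitch
  measured <- max(seg@abscissa)
  # the segmented centerline is slightly shorter at the two ends
  expect_gt(measured, 0.93 * trueLen)
  expect_lt(measured, 1.02 * trueLen)
})

test_that("cross-section traces are constant for a static movie", {
  img <- straightVesselImage()
  frames <- array(img, dim = c(dim(img), 40))
  mv <- new("VesselMovie", frames = frames, frameRate = 38,
            pixelPitch = 5e-5)
  seg <- segmentVessel(img, 5e-5)
  sig <- sampleCrossSections(mv, seg, detrend = FALSE)
  expect_lt(max(apply(sig@phi, 1, sd)), 1e-13)
})

test_that("cross sections recover a traveling wave's phase gradient", {
  sc <- retinalScenario(seed = 21, duration = 8, nRows = 32, nCols = 96,
                        amplitudes = c(1), snr = Inf)
  seg <- segmentVessel(rowMeans(sc$movie@frames, dims = 2),
                       pixelPitch(sc$movie))
  sig <- sampleCrossSections(sc$movie, seg)
  fld <- temporalSpectrum(sig)
  f0 <- sc$source@fundamentalHz
  bin <- which.min(abs(fld@f - f0))
  phases <- Arg(fld@phiHat[, bin])
  slope <- stats::coef(lm(unwrapped ~ x, data.frame(
    unwrapped = cumsum(c(phases[1], atan2(sin(diff(phases)),
                                          cos(diff(phases))))),
    x = fld@x)))[["x"]]
  kTrue <- -2 * pi * f0 / sc$law(f0)
  expect_rel_equal(slope, kTrue, 0.02)
})

test_that("half width zero degenerates to the centerline pixel value", {
  img <- straightVesselImage()
  frames <- array(rep(img, 20) * rep(seq(1, 2, length.out = 20),
                                     each = length(img)),
                  dim = c(dim(img), 20))
  mv <- new("VesselMovie", frames = frames, frameRate = 38,
            pixelPitch = 5e-5)
  seg <- segmentVessel(img, 5e-5)
  sig <- sampleCrossSections(mv, seg, halfWidthPx = 0, detrend = FALSE)
  i <- 10L
  rc <- seg@centerline[i, ]
  # bilinear interpolation of the frame at the centerline point
  r0 <- floor(rc[1]); c0 <- floor(rc[2])
  fr <- rc[1] - r0; fc <- rc[2] - c0
  manual <- (1 - fr) * (1 - fc) * frames[r0 + 1, c0 + 1, ] +
    fr * (1 - fc) * frames[r0 + 2, c0 + 1, ] +
    (1 - fr) * fc * frames[r0 + 1, c0 + 2, ] +
    fr * fc * frames[r0 + 2, c0 + 2, ]
  expect_equal(sig@phi[i, ], as.numeric(manual), tolerance = 1e-12)
})

test_that("cross-section averaging cancels axisymmetric fluctuations", {
  # modulation that is equal and opposite on the two halves of the
  # cross-section profile: its average across the section must vanish
  nR <- 32L; nC <- 96L; nT <- 24L
  rowC <- 15.5
  r <- matrix(0:(nR - 1), nR, nC)
  base <- 0.1 + exp(-(r - rowC)^2 / (2 * 2.5^2))
  odd <- (r - rowC) * exp(-(r - rowC)^2 / (2 * 2.5^2))
  frames <- vapply(seq_len(nT),
                   function(j) base + 0.3 * sin(2 * pi * j / nT) * odd,
                   base)
  mv <- new("VesselMovie", frames = array(frames, c(nR, nC, nT)),
            frameRate = 38, pixelPitch = 5e-5)
  seg <- segmentVessel(base, 5e-5)
  sig <- sampleCrossSections(mv, seg, halfWidthPx = 6, detrend = FALSE)
  inner <- sig@phi[5:(nrow(sig@phi) - 5), ]
  expect_lt(max(apply(inner, 1, sd)) / mean(inner), 0.02)
})

test_that("wavelength estimates survive centerline reversal", {
  tv <- travelingSignal(0.012, amplitudes = 1)
  fwd <- tv$sig
  rev <- CurvilinearSignal(fwd@x, fwd@t, fwd@phi[nrow(fwd@phi):1, ])
  f0 <- tv$source@fundamentalHz
  lamF <- fitWavelength(focalSpot(temporalSpectrum(fwd), f0))[["lambda"]]
  lamR <- fitWavelength(focalSpot(temporalSpectrum(rev), f0))[["lambda"]]
  expect_rel_equal(lamR, lamF, 1e-6)
})
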