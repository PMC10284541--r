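# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs in seconds.

# A spectral field carrying one unidirectional plane wave of wavelength
# `lambda` at frequency `f`, synthesized as exact FFT phases.
planeWaveField <- function(lambda, f = 6.7, nPos = 64L, dx = 1e-4,
                           nT = 128L, fs = 38) {
  x <- seq(0, by = dx, length.out = nPos)
  tt <- seq(0, by = 1 / fs, length.out = nT)
  fBin <- round(f * nT / fs) * fs / nT           # bin-aligned
  phi <- cos(outer(-2 * pi * x / lambda, 2 * pi * fBin * tt, "+"))
  temporalSpectrum(CurvilinearSignal(x, tt, phi), detrend = FALSE)
}

# A curvilinear signal with one traveling mode (constant velocity or law)
# driven by a harmonic comb, bin-aligned, noiseless.
travelingSignal <- function(velocity, amplitudes = rep(1, 6), fs = 38,
                            duration = 16, nPos = 128L, aperture = 5.3e-3,
                            fundamental = 1.5, direction = 1) {
  acq <- AcquisitionSpec(fs, duration, aperture / nPos, aperture)
  src <- binAlignSource(SourceSpectrum(fundamental, amplitudes), acq)
  x <- seq(0, by = aperture / nPos, length.out = nPos)
  u <- propagateMode(src, ModeSpec("antisymmetric", velocity,
                                   direction = direction), x, acq)
  list(sig = CurvilinearSignal(x, attr(u, "t"), u), source = src,
       acq = acq)
}

# A rightward plane wave whose wavelength divides the aperture exactly
# (integer wavelengths in space and integer cycles in time), so its 2-D
# spectrum occupies single bins: the clean case for directional filtering.
binAlignedWave <- function(nWavelengths = 8L, nPos = 64L, nT = 128L,
                           fs = 500, cyclesPerRecord = 20L,
                           direction = 1) {
  dx <- 1e-3
  L <- nPos * dx
  lambda <- L / nWavelengths
  f <- cyclesPerRecord * fs / nT
  x <- seq(0, by = dx, length.out = nPos)
  tt <- seq(0, by = 1 / fs, length.out = nT)
  phi <- cos(outer(-direction * 2 * pi * x / lambda, 2 * pi * f * tt, "+"))
  CurvilinearSignal(x, tt, phi)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
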