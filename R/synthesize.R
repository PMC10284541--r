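## Seeded synthetic-data generator: harmonic cardiac sources propagated as
## traveling guided-wave modes, rendered either as a bright curved vessel
## in a noisy power-Doppler-like movie (retinal scale) or as two-wall
## displacement records (carotid scale). Synthesis is exact in the
## frequency domain — a superposition of traveling cosines — not a PDE
## solve, matching how the analysis treats the wave field.

.timeGrid <- function(acq) {
  nT <- round(acq@duration * acq@frameRate)
  seq(0, by = 1 / acq@frameRate, length.out = nT)
}

.harmonics <- function(spec) {
  seq_along(spec@amplitudes) * spec@fundamentalHz
}

#' Snap a source spectrum to the FFT bin grid of an acquisition
#'
#' Adjusts the fundamental so that every harmonic completes an integer
#' number of cycles over the record, making spectral peaks bin-aligned
#' (no leakage with a rectangular full-record window). Used by the default
#' scenarios; disable to study leakage robustness.
#'
#' @param spec A [SourceSpectrum-class].
#' @param acq An [AcquisitionSpec-class].
#' @return A [SourceSpectrum-class] with `fundamentalHz` moved to the
#'   nearest nonzero bin frequency.
#' @export
binAlignSource <- function(spec, acq) {
  tRec <- round(acq@duration * acq@frameRate) / acq@frameRate
  f0 <- max(1, round(spec@fundamentalHz * tRec)) / tRec
  SourceSpectrum(f0, spec@amplitudes, spec@phases)
}

#' Synthesize the source displacement time series
#'
#' Evaluates the harmonic cardiac source at the inlet (x = 0):
#' `s(t) = sum_k a_k cos(2 pi k f0 t + phi_k)`. Deterministic given the
#' spectrum; harmonics at or above the Nyquist frequency are rejected.
#'
#' @param spec A [SourceSpectrum-class].
#' @param acq An [AcquisitionSpec-class] providing the time grid.
#' @return Numeric vector `s(t)` with the sample times as attribute `"t"`.
#' @examples
#' acq <- AcquisitionSpec(38, 8, 2e-5, 5.3e-3)
#' s <- makeSource(SourceSpectrum(1.5), acq)
#' @export
makeSource <- function(spec, acq) {
  stopifnot(is(spec, "SourceSpectrum"), is(acq, "AcquisitionSpec"))
  fk <- .harmonics(spec)
  live <- spec@amplitudes != 0
  if (any(fk[live] >= acq@frameRate / 2))
    stop(sprintf(
      "harmonic at %.3g Hz is at/above the Nyquist frequency %.3g Hz",
      min(fk[live][fk[live] >= acq@frameRate / 2]), acq@frameRate / 2))
  t <- .timeGrid(acq)
  s <- numeric(length(t))
  for (k in which(live))
    s <- s + spec@amplitudes[k] * cos(2 * pi * fk[k] * t + spec@phases[k])
  attr(s, "t") <- t
  s
}

#' Propagate a harmonic source as a traveling guided mode
#'
#' Frequency-domain synthesis of the displacement field
#' `u(x, t) = sum_k a_k cos(2 pi f_k t - dir * k(f_k) x + phi_k)` with
#' wavenumber `k(f) = 2 pi f / v(f)` from the mode's velocity law. A
#' constant-velocity mode yields a pure translation of the source
#' waveform; a dispersive law (e.g. the flexural `sqrt(f d)` form) gives
#' each harmonic its own wavelength.
#'
#' @param spec A [SourceSpectrum-class].
#' @param mode A [ModeSpec-class]; its amplitude multiplies the source
#'   amplitudes and its direction sets the sign of the spatial phase
#'   gradient.
#' @param x Positions (m) at which to evaluate the field.
#' @param acq An [AcquisitionSpec-class] providing the time grid; harmonics
#'   must be below Nyquist.
#' @return Numeric matrix `u`, length(x) x length(t), with `x` and `t`
#'   attached as attributes.
#' @examples
#' acq <- AcquisitionSpec(38, 8, 2e-5, 5.3e-3)
#' u <- propagateMode(SourceSpectrum(1.5), ModeSpec("symmetric", 0.005),
#'                    x = seq(0, 5e-3, by = 1e-4), acq = acq)
#' @export
propagateMode <- function(spec, mode, x, acq) {
  stopifnot(is(spec, "SourceSpectrum"), is(mode, "ModeSpec"))
  fk <- .harmonics(spec)
  live <- spec@amplitudes != 0
  if (any(fk[live] >= acq@frameRate / 2))
    stop("harmonics at/above Nyquist; reduce the harmonic count or raise the frame rate")
  vk <- mode@velocityLaw(fk)
  if (any(!is.finite(vk[live])) || any(vk[live] <= 0))
    stop("mode velocity law must be positive and finite at all synthesized frequencies")
  t <- .timeGrid(acq)
  u <- matrix(0, nrow = length(x), ncol = length(t))
  for (k in which(live)) {
    kf <- 2 * pi * fk[k] / vk[k]
    phase <- outer(-mode@direction * kf * x, 2 * pi * fk[k] * t, "+") +
      spec@phases[k]
    u <- u + mode@amplitude * spec@amplitudes[k] * cos(phase)
  }
  attr(u, "x") <- x
  attr(u, "t") <- t
  u
}

#' Circular-arc vessel centerline
#'
#' A gently curved centerline spanning the field of view horizontally,
#' for rendering synthetic vessel movies. Returned as fractional pixel
#' coordinates (row, col), finely sampled.
#'
#' @param nRows,nCols Frame size in pixels.
#' @param sagPx Vertical sag of the arc at mid-field (pixels); 0 gives a
#'   straight horizontal vessel.
#' @param marginPx Margin kept from the left/right frame edges.
#' @param oversample Centerline points per pixel of arc length.
#' @return Matrix with columns `row`, `col`.
#' @export
arcCenterline <- function(nRows, nCols, sagPx = 0.12 * nRows,
                          marginPx = 3, oversample = 4) {
  colPx <- seq(marginPx, nCols - 1 - marginPx,
               length.out = oversample * nCols)
  xm <- (colPx - (nCols - 1) / 2) / (nCols - 1 - 2 * marginPx) * 2  # [-1, 1]
  rowPx <- (nRows - 1) / 2 + sagPx * (xm^2 - 0.5)
  cbind(row = rowPx, col = colPx)
}

## Nearest-centerline lookup: for every pixel within `reach` pixels of the
## centerline, the index of the closest centerline sample and the distance
## to it. Grid-bucketed so the cost stays linear in pixels.
.nearestCenterline <- function(center, nRows, nCols, reach) {
  n <- nrow(center)
  px <- as.matrix(expand.grid(row = 0:(nRows - 1), col = 0:(nCols - 1)))
  idx <- integer(nrow(px)); dist <- rep(Inf, nrow(px))
  # coarse pass: centerline samples snapped to pixels, then local search
  colRange <- range(center[, "col"])
  for (p in seq_len(nrow(px))) {
    c0 <- px[p, "col"]
    if (c0 < colRange[1] - reach || c0 > colRange[2] + reach) next
    cand <- which(abs(center[, "col"] - c0) <= reach + 1)
    if (!length(cand)) next
    d2 <- (center[cand, "row"] - px[p, "row"])^2 +
          (center[cand, "col"] - c0)^2
    j <- which.min(d2)
    idx[p] <- cand[j]; dist[p] <- sqrt(d2[j])
  }
  list(idx = idx, dist = dist)
}

#' Render a synthetic vessel movie
#'
#' Paints a bright vessel with a Gaussian transverse profile along a
#' centerline, adds the wave fields as intensity modulations riding on the
#' vessel (each pixel takes the field value at its nearest centerline
#' abscissa, weighted by the same transverse profile), and adds seeded
#' Gaussian noise. Emulates the structure of a power-Doppler movie: a
#' bright, slightly curved vessel on a dark background whose on-vessel
#' intensity fluctuates as waves pass.
#'
#' @param fields List of displacement/modulation matrices as returned by
#'   [propagateMode()] (positions x time, sharing one `x` attribute); may
#'   be empty.
#' @param acq An [AcquisitionSpec-class]; `noiseSigma` is the sd of the
#'   per-pixel additive Gaussian noise and `seed` fixes it.
#' @param centerline Matrix of (row, col) pixel coordinates from
#'   [arcCenterline()] (or compatible); must lie inside the frame.
#' @param nRows,nCols Frame size (pixels).
#' @param vesselSigmaPx Gaussian transverse half-width of the vessel
#'   (pixels), > 0.
#' @param brightness Peak vessel intensity above background.
#' @param background Background intensity level.
#' @return A [VesselMovie-class].
#' @examples
#' acq <- AcquisitionSpec(38, 8, 5.3e-3 / 96, 5.3e-3, noiseSigma = 0, seed = 7)
#' cl <- arcCenterline(32, 96)
#' mv <- renderMovie(list(), acq, cl, 32, 96)
#' @export
renderMovie <- function(fields, acq, centerline, nRows, nCols,
                        vesselSigmaPx = 2.5, brightness = 1,
                        background = 0.1) {
  stopifnot(is(acq, "AcquisitionSpec"))
  if (vesselSigmaPx <= 0) stop("'vesselSigmaPx' must be positive")
  if (any(centerline[, 1] < 0) || any(centerline[, 1] > nRows - 1) ||
      any(centerline[, 2] < 0) || any(centerline[, 2] > nCols - 1))
    stop("centerline lies outside the frame")
  t <- .timeGrid(acq)
  nT <- length(t)
  reach <- ceiling(4 * vesselSigmaPx)
  near <- .nearestCenterline(centerline, nRows, nCols, reach)
  w <- ifelse(is.finite(near$dist),
              exp(-near$dist^2 / (2 * vesselSigmaPx^2)), 0)
  w[w < 1e-6] <- 0
  base <- background + brightness * w              # static mean image
  frames <- matrix(base, nrow = nRows * nCols, ncol = nT)
  if (length(fields)) {
    # abscissa of each centerline sample, for mapping fields onto pixels
    steps <- sqrt(diff(centerline[, 1])^2 + diff(centerline[, 2])^2)
    arc <- c(0, cumsum(steps)) * acq@pixelPitch
    on <- which(w > 0 & near$idx > 0)
    for (u in fields) {
      xg <- attr(u, "x")
      if (is.null(xg)) stop("each field needs an 'x' attribute (see propagateMode)")
      if (ncol(u) != nT) stop("field time dimension does not match the acquisition")
      # nearest synthesis-grid index for each on-vessel pixel
      ix <- findInterval(arc[near$idx[on]], xg, all.inside = TRUE)
      ix <- ix + (abs(xg[pmin(ix + 1, length(xg))] - arc[near$idx[on]]) <
                  abs(xg[ix] - arc[near$idx[on]]))
      frames[on, ] <- frames[on, ] + w[on] * u[ix, , drop = FALSE]
    }
  }
  if (acq@noiseSigma > 0) {
    set.seed(acq@seed)
    frames <- frames + matrix(rnorm(length(frames), sd = acq@noiseSigma),
                              nrow = nrow(frames))
  }
  frames <- pmax(frames, 0)  # intensities are nonnegative
  new("VesselMovie", frames = array(frames, dim = c(nRows, nCols, nT)),
      frameRate = acq@frameRate, pixelPitch = acq@pixelPitch)
}

#' Render a two-wall displacement record
#'
#' Combines a symmetric and an antisymmetric displacement field into
#' top/bottom wall traces using the axial-beam convention: radial
#' (symmetric) expansion moves the two walls in opposite directions,
#' flexion (antisymmetric) moves them together. So
#' `uTop = uA + uS` and `uBottom = uA - uS`, plus seeded Gaussian noise.
#' [separateModes()] inverts this map exactly when the noise is zero.
#'
#' @param uSym,uAntisym Displacement matrices (positions x time) on
#'   matching grids, as from [propagateMode()]; either may be a zero
#'   matrix with the same attributes.
#' @param acq An [AcquisitionSpec-class]; noise sd and seed.
#' @param misalignmentGain Optional amplitude factor on the antisymmetric
#'   field modelling an imaging plane not aligned with the flexion plane
#'   (affects amplitude only, never wavelength). Default 1.
#' @return A [WallDisplacements-class].
#' @export
renderWalls <- function(uSym, uAntisym, acq, misalignmentGain = 1) {
  if (!identical(dim(uSym), dim(uAntisym)))
    stop("symmetric and antisymmetric fields must share one grid")
  x <- attr(uSym, "x"); t <- attr(uSym, "t")
  if (is.null(x)) x <- attr(uAntisym, "x")
  if (is.null(t)) t <- attr(uAntisym, "t")
  uA <- misalignmentGain * uAntisym
  top <- uA + uSym
  bot <- uA - uSym
  if (acq@noiseSigma > 0) {
    set.seed(acq@seed)
    top <- top + matrix(rnorm(length(top), sd = acq@noiseSigma), nrow(top))
    bot <- bot + matrix(rnorm(length(bot), sd = acq@noiseSigma), nrow(bot))
  }
  WallDisplacements(x = x, t = t, uTop = top, uBottom = bot)
}

#' Default retinal-scale scenario
#'
#' A seeded synthetic retinal acquisition: 38 Hz frame rate over a 5.3 mm
#' field of view, a ~1.5 Hz cardiac source with harmonics (bin-aligned by
#' default), and a single antisymmetric mode following the dispersive
#' flexural law `v(f) = sqrt(pi f d cT / sqrt(3))` at the reference
#' geometry. The signal-to-noise ratio is set on amplitude:
#' `noiseSigma = brightness * waveAmplitude / snr`.
#'
#' @param seed RNG seed.
#' @param nHarmonics Number of source harmonics (all below Nyquist).
#' @param amplitudes Per-harmonic amplitudes (default equal).
#' @param snr Amplitude signal-to-noise ratio of the on-vessel modulation;
#'   `Inf` disables noise.
#' @param duration Record length (s).
#' @param nRows,nCols Frame size (pixels).
#' @param geom [TubeGeometry-class] for the dispersive law.
#' @param waveAmplitude Intensity-modulation amplitude per harmonic.
#' @param binAlign Snap the fundamental to an FFT bin (default TRUE).
#' @return List with elements `movie` ([VesselMovie-class]), `acq`,
#'   `source`, `mode`, `geom`, `centerline`, and `law` (the true velocity
#'   law, for validation).
#' @examples
#' sc <- retinalScenario(seed = 1, duration = 8, nCols = 64, nRows = 24)
#' sc$movie
#' @export
retinalScenario <- function(seed = 1L, nHarmonics = 6L, amplitudes = NULL,
                            snr = 10, duration = 16, nRows = 48L,
                            nCols = 192L, geom = retinalGeometry(),
                            waveAmplitude = 0.25, binAlign = TRUE) {
  fov <- 5.3e-3
  pitch <- fov / nCols
  if (is.null(amplitudes)) amplitudes <- rep(1, nHarmonics)
  amp <- waveAmplitude
  acq <- AcquisitionSpec(frameRate = 38, duration = duration,
                         pixelPitch = pitch, fieldOfView = fov,
                         noiseSigma = if (is.finite(snr)) amp / snr else 0,
                         seed = seed)
  src <- SourceSpectrum(1.5, amplitudes = amplitudes)
  if (binAlign) src <- binAlignSource(src, acq)
  law <- function(f) vFpwLowfreq(f, geom)
  mode <- ModeSpec("antisymmetric", velocity = law, amplitude = amp)
  cl <- arcCenterline(nRows, nCols)
  arcLen <- sum(sqrt(diff(cl[, 1])^2 + diff(cl[, 2])^2)) * pitch
  xg <- seq(0, arcLen, by = pitch / 2)
  u <- propagateMode(src, mode, xg, acq)
  movie <- renderMovie(list(u), acq, cl, nRows, nCols,
                       vesselSigmaPx = 2.5, brightness = 1,
                       background = 0.1)
  list(movie = movie, acq = acq, source = src, mode = mode, geom = geom,
       centerline = cl, law = law)
}

#' Default carotid-scale scenario
#'
#' A seeded synthetic carotid acquisition: two-wall displacement traces at
#' 500 Hz over a 4 cm aperture, with a non-dispersive symmetric pulse wave
#' (default 3.4 m/s) and a slower non-dispersive antisymmetric flexural
#' wave (default 0.5 m/s), both driven by a harmonic cardiac source whose
#' band covers ~4-19 Hz. Noise is additive Gaussian on displacement with
#' amplitude SNR `snr`.
#'
#' @param seed RNG seed.
#' @param vSym,vAntisym Mode phase velocities (m/s).
#' @param snr Amplitude signal-to-noise ratio; `Inf` disables noise.
#' @param duration Record length (s); default 2 s (1000 frames at 500 Hz).
#' @param nPositions Positions across the aperture.
#' @param symAmplitude,antisymAmplitude Mode displacement amplitudes (m).
#' @param binAlign Snap the fundamental to an FFT bin (default TRUE).
#' @return List with `walls` ([WallDisplacements-class]), `acq`, `source`,
#'   `modes`, and the true velocities `vSym`, `vAntisym`.
#' @examples
#' sc <- carotidScenario(seed = 2, duration = 2)
#' sc$walls
#' @export
carotidScenario <- function(seed = 1L, vSym = 3.4, vAntisym = 0.5,
                            snr = 10, duration = 2, nPositions = 128L,
                            symAmplitude = 1e-4, antisymAmplitude = 1e-4,
                            binAlign = TRUE) {
  aperture <- 4e-2
  dx <- aperture / nPositions
  acq <- AcquisitionSpec(frameRate = 500, duration = duration,
                         pixelPitch = dx, fieldOfView = aperture,
                         noiseSigma = if (is.finite(snr))
                           max(symAmplitude, antisymAmplitude) / snr else 0,
                         seed = seed)
  # harmonics 3..12 of 1.5 Hz: band 4.5-18 Hz, matching the measured
  # 6-19 Hz central-frequency range
  amps <- c(0, 0, rep(1, 10))
  src <- SourceSpectrum(1.5, amplitudes = amps)
  if (binAlign) src <- binAlignSource(src, acq)
  x <- seq(0, by = dx, length.out = nPositions)
  mS <- ModeSpec("symmetric", velocity = vSym, amplitude = symAmplitude)
  mA <- ModeSpec("antisymmetric", velocity = vAntisym,
                 amplitude = antisymAmplitude)
  uS <- propagateMode(src, mS, x, acq)
  uA <- propagateMode(src, mA, x, acq)
  walls <- renderWalls(uS, uA, acq)
  list(walls = walls, acq = acq, source = src,
       modes = list(symmetric = mS, antisymmetric = mA),
       vSym = vSym, vAntisym = vAntisym)
}
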