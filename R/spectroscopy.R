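## Passive spectroscopy: per-position temporal spectra, phase-only
## monochromatic and polychromatic focal spots, sinusoidal wavelength
## fits, dispersion-curve assembly, and autocorrelation central
## frequency. The focal spot at frequency f is
##   C(f, r) = < cos( arg phiHat_s(f) - arg phiHat_{s+r}(f) ) >_s
## averaged over all source positions s with s and s + r in range;
## discarding the Fourier modulus normalizes the correlation and whitens
## the spectrum, so any positive amplitude envelope drops out.

#' Temporal spectrum of a curvilinear signal
#'
#' Per-position FFT over the full record (rectangular window), keeping
#' nonnegative frequencies up to Nyquist, plus the magnitude spectrum
#' averaged over positions for peak picking.
#'
#' @param sig A [CurvilinearSignal-class] with at least 16 time samples.
#' @param detrend Remove a per-position linear trend first (default TRUE).
#' @return A [SpectralField-class].
#' @examples
#' sc <- carotidScenario(seed = 1, snr = Inf)
#' fld <- temporalSpectrum(CurvilinearSignal(sc$walls@x, sc$walls@t,
#'                                           sc$walls@uTop))
#' @export
temporalSpectrum <- function(sig, detrend = TRUE) {
  stopifnot(is(sig, "CurvilinearSignal"))
  nT <- length(sig@t)
  if (nT < 16L) stop("need at least 16 time samples")
  phi <- sig@phi
  if (detrend) {
    tt <- seq_len(nT)
    phi <- t(apply(phi, 1, function(y) {
      fit <- lm.fit(cbind(1, tt), y)
      y - fit$fitted.values
    }))
  }
  ph <- t(apply(phi, 1, fft))
  nF <- floor(nT / 2) + 1L
  fs <- 1 / mean(diff(sig@t))
  f <- (seq_len(nF) - 1) * fs / nT
  ph <- ph[, seq_len(nF), drop = FALSE]
  new("SpectralField", f = f, phiHat = ph,
      meanSpectrum = colMeans(abs(ph)), x = sig@x)
}

#' Spectral peaks of the mean magnitude spectrum
#'
#' Local maxima of the position-averaged magnitude spectrum above a
#' prominence threshold, used to choose the analysis frequencies of the
#' retinal dispersion curve. Peak localization uses a 4x zero-padded,
#' Hann-windowed FFT (the window keeps rectangular-window sidelobes,
#' which padding would otherwise resolve into spurious local maxima,
#' 31 dB down); frequencies are then snapped back to the unpadded grid
#' on which focal spots are defined.
#'
#' @param sig A [CurvilinearSignal-class].
#' @param prominence Minimum peak height relative to the maximum peak
#'   (default 0.1).
#' @param fMin Ignore peaks below this frequency (Hz; default one bin).
#' @return Numeric vector of peak frequencies (Hz) on the unpadded grid.
#' @export
spectralPeaks <- function(sig, prominence = 0.1, fMin = NULL) {
  stopifnot(is(sig, "CurvilinearSignal"))
  nT <- length(sig@t)
  fs <- 1 / mean(diff(sig@t))
  pad <- 4L
  phi <- sweep(sig@phi, 1, rowMeans(sig@phi))
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nT) - 1) / (nT - 1))
  phi <- sweep(phi, 2, hann, "*")
  spec <- colMeans(abs(t(apply(cbind(phi, matrix(0, nrow(phi),
                                                 (pad - 1L) * nT)),
                               1, fft))))
  nF <- floor(pad * nT / 2) + 1L
  spec <- spec[seq_len(nF)]
  fPad <- (seq_len(nF) - 1) * fs / (pad * nT)
  if (is.null(fMin)) fMin <- fs / nT * 0.9
  isPk <- c(FALSE, diff(sign(diff(spec))) < 0, FALSE) & fPad >= fMin
  pk <- which(isPk)
  if (!length(pk)) return(numeric())
  pk <- pk[spec[pk] >= prominence * max(spec[pk])]
  fRaw <- (seq_len(floor(nT / 2) + 1L) - 1) * fs / nT
  sort(unique(fRaw[vapply(fPad[pk],
                          function(f) which.min(abs(fRaw - f)),
                          integer(1))]))
}

#' Monochromatic focal spot
#'
#' Phase-only spatial correlation of the wave field at one frequency:
#' for every spatial lag r, the cosine of the phase difference between
#' positions s and s + r, averaged over all valid s. For a single
#' unidirectional plane wave of wavelength lambda the result is exactly
#' `cos(2 pi r / lambda)`; for mixtures it is the wavelength carrier used
#' by the sinusoidal fit.
#'
#' @param field A [SpectralField-class] with at least 2 positions.
#' @param f Requested frequency (Hz); snapped to the nearest grid bin,
#'   with a warning if the snap exceeds a quarter bin.
#' @return A [FocalSpot-class] with lags spanning (-L, L).
#' @export
focalSpot <- function(field, f) {
  stopifnot(is(field, "SpectralField"))
  n <- nrow(field@phiHat)
  if (n < 2L) stop("need at least 2 positions")
  bin <- which.min(abs(field@f - f))
  df <- field@f[2] - field@f[1]
  if (abs(field@f[bin] - f) > df / 4)
    warning(sprintf("frequency %.4g Hz snapped to grid bin at %.4g Hz",
                    f, field@f[bin]))
  col <- field@phiHat[, bin]
  floorAmp <- 1e-10 * max(field@meanSpectrum, .Machine$double.xmin)
  if (mean(Mod(col)) < floorAmp)
    stop("zero spectral amplitude at the requested frequency; phases undefined")
  ph <- exp(1i * Arg(col))
  lags <- -(n - 1L):(n - 1L)
  C <- vapply(lags, function(j) {
    if (j >= 0) {
      s <- seq_len(n - j)
      mean(Re(ph[s] * Conj(ph[s + j])))
    } else {
      s <- seq_len(n + j)
      mean(Re(ph[s - j] * Conj(ph[s])))
    }
  }, numeric(1))
  dx <- field@x[2] - field@x[1]
  new(Class = "FocalSpot", r = lags * dx, C = C, fCenter = field@f[bin])
}

#' Polychromatic focal spot
#'
#' Average of the monochromatic focal spots over a frequency band,
#' weighted by the position-averaged spectral magnitude in each bin.
#' Widening the band shrinks the side lobes, concentrating the spot on
#' the central peak whose width carries the central wavelength.
#'
#' @param field A [SpectralField-class].
#' @param band Numeric length-2, band limits (Hz) within Nyquist.
#' @return A [FocalSpot-class] with `fCenter` set to the band limits.
#' @export
polychromaticFocalSpot <- function(field, band) {
  stopifnot(is(field, "SpectralField"), length(band) == 2L)
  bins <- which(field@f >= band[1] & field@f <= band[2] & field@f > 0)
  if (!length(bins)) stop("empty band: no frequency bins inside it")
  wts <- field@meanSpectrum[bins]
  live <- wts > 1e-10 * max(field@meanSpectrum)
  bins <- bins[live]; wts <- wts[live]
  if (!length(bins)) stop("no spectral energy inside the band")
  spots <- lapply(field@f[bins], function(fb) focalSpot(field, fb))
  Cm <- vapply(spots, slot, numeric(length(spots[[1]]@C)), "C")
  C <- as.numeric(Cm %*% (wts / sum(wts)))
  new(Class = "FocalSpot", r = spots[[1]]@r, C = C,
      fCenter = as.numeric(band))
}

## First negative-going zero crossings of C(r) on either side of r = 0,
## linearly interpolated; NA where C never crosses zero on that side.
.zeroCrossings <- function(r, C) {
  i0 <- which(r == 0)
  right <- NA_real_
  for (i in i0:(length(r) - 1L)) {
    if (C[i] > 0 && C[i + 1] <= 0) {
      right <- r[i] + (r[i + 1] - r[i]) * C[i] / (C[i] - C[i + 1])
      break
    }
  }
  left <- NA_real_
  for (i in i0:2) {
    if (C[i] > 0 && C[i - 1] <= 0) {
      left <- r[i] - (r[i] - r[i - 1]) * C[i] / (C[i] - C[i - 1])
      break
    }
  }
  c(left = left, right = right)
}

#' Fit the wavelength of a focal spot
#'
#' Nonlinear least squares of the model `C(r) = cos(2 pi r / lambda)` on
#' the central peak of a focal spot. The fit window runs from the first
#' negative-going zero crossing left of r = 0 to the first on the right
#' when both are visible; otherwise the full aperture is used — covering
#' the long-wavelength case where the wavelength far exceeds the aperture
#' and the fit extrapolates from the central-lobe curvature. The initial
#' wavelength is 4x the first zero-crossing lag, or 8x the aperture if no
#' crossing is visible.
#'
#' @param spot A [FocalSpot-class] with at least 8 lags.
#' @return Named numeric: `lambda` (m) and `sigma` (1-sigma from the fit
#'   covariance). Errors if the correlation is flat or the fit fails or
#'   hits its bounds.
#' @examples
#' r <- seq(-2e-3, 2e-3, by = 5e-5)
#' spot <- new(Class = "FocalSpot", r = r, C = cos(2 * pi * r / 1.4e-3),
#'             fCenter = 6.7)
#' fitWavelength(spot)
#' @export
fitWavelength <- function(spot) {
  stopifnot(is(spot, "FocalSpot"))
  r <- spot@r; C <- spot@C
  if (length(r) < 8L) stop("need at least 8 lags")
  if (sd(C) < 1e-12)
    stop("flat correlation profile; wavelength undefined")
  zc <- .zeroCrossings(r, C)
  aperture <- max(abs(r))
  win <- if (all(is.finite(zc))) r >= zc["left"] & r <= zc["right"]
         else rep(TRUE, length(r))
  lambda0 <- if (any(is.finite(zc))) 4 * mean(abs(zc), na.rm = TRUE)
             else 8 * aperture
  dr <- min(diff(sort(unique(r))))
  lo <- 2 * dr; hi <- 1000 * aperture
  dat <- data.frame(r = r[win], C = C[win])
  fit <- tryCatch(
    minpack.lm::nlsLM(C ~ cos(2 * pi * r / lambda), data = dat,
                      start = list(lambda = lambda0),
                      lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("wavelength fit failed to converge: ",
                             conditionMessage(e)))
  lambda <- coef(fit)[["lambda"]]
  if (lambda <= lo * 1.001 || lambda >= hi * 0.999)
    stop("fitted wavelength hit the window bounds")
  sigma <- tryCatch(sqrt(vcov(fit)[1, 1]), error = function(e) NA_real_)
  c(lambda = lambda, sigma = sigma)
}

#' Assemble a dispersion curve
#'
#' Runs [focalSpot()] and [fitWavelength()] at each requested frequency
#' and converts wavelength to phase velocity, `v = lambda * f` (enforced
#' exactly; uncertainty propagated as `sigma_v = f * sigma_lambda`,
#' neglecting the frequency error of bin-aligned records). Frequencies
#' whose fit fails are flagged with `fitOk = FALSE` and NA estimates,
#' never dropped silently.
#'
#' @param field A [SpectralField-class].
#' @param fList Frequencies to analyze (Hz), nonempty, within the band.
#' @return A [DispersionCurve-class].
#' @export
dispersionCurve <- function(field, fList) {
  stopifnot(is(field, "SpectralField"))
  if (!length(fList)) stop("empty frequency list")
  n <- length(fList)
  lambda <- sigma <- rep(NA_real_, n)
  ok <- logical(n)
  fUsed <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      spot <- focalSpot(field, fList[i])
      est <- fitWavelength(spot)
      list(f = spot@fCenter, est = est)
    }, error = function(e) NULL)
    fUsed[i] <- if (is.null(res)) fList[i] else res$f
    if (!is.null(res)) {
      lambda[i] <- res$est[["lambda"]]
      sigma[i] <- res$est[["sigma"]]
      ok[i] <- TRUE
    }
  }
  new("DispersionCurve", f = fUsed, lambda = lambda, lambdaSigma = sigma,
      v = lambda * fUsed, vSigma = fUsed * sigma, fitOk = ok)
}

#' Central frequency by autocorrelation
#'
#' Temporal autocorrelation of the signal (averaged over positions for a
#' matrix input); the dominant period is the lag of the first local
#' maximum after the first zero crossing, refined by 3-point parabolic
#' interpolation, and the central frequency is its reciprocal.
#'
#' @param x Numeric vector (one trace) or matrix (positions x time).
#' @param dt Sample interval (s); for a [CurvilinearSignal-class] use the
#'   method below and omit it.
#' @return Central frequency (Hz).
#' @examples
#' tt <- seq(0, 2, by = 1 / 500)
#' centralFrequency(cos(2 * pi * 7.5 * tt), dt = 1 / 500)
#' @export
centralFrequency <- function(x, dt) {
  if (is(x, "CurvilinearSignal")) {
    dt <- mean(diff(x@t))
    x <- x@phi
  }
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  nT <- ncol(m)
  if (nT < 8L) stop("record too short for autocorrelation")
  m <- sweep(m, 1, rowMeans(m))
  if (all(abs(m) < .Machine$double.eps * 100))
    stop("constant signal: no oscillation to measure")
  # mean autocorrelation over positions, via FFT with zero padding
  nPad <- 2L * nextn(nT, 2)
  ac <- rowSums(vapply(seq_len(nrow(m)), function(i) {
    sp <- fft(c(m[i, ], numeric(nPad - nT)))
    Re(fft(sp * Conj(sp), inverse = TRUE))[seq_len(nT)]
  }, numeric(nT)))
  ac <- ac / ac[1]
  # first zero crossing, then first local maximum after it
  neg <- which(ac <= 0)
  if (!length(neg)) stop("no zero crossing in the autocorrelation")
  i0 <- neg[1]
  pk <- NA_integer_
  for (i in (i0 + 1L):(nT - 1L)) {
    if (ac[i] > ac[i - 1] && ac[i] >= ac[i + 1]) { pk <- i; break }
  }
  if (is.na(pk)) stop("no local maximum after the first zero crossing")
  # parabolic refinement of the peak lag
  y1 <- ac[pk - 1]; y2 <- ac[pk]; y3 <- ac[pk + 1]
  den <- y1 - 2 * y2 + y3
  shift <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
  period <- (pk - 1 + shift) * dt
  1 / period
}
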