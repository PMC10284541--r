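#' Construct a TubeGeometry
#'
#' @param d Outer diameter (m).
#' @param h Wall thickness (m).
#' @param rho Wall density (kg/m^3). Default 1000 (soft tissue ~ water).
#' @param cL Bulk compression wave velocity (m/s). Default 1500 (water).
#' @param cT Bulk shear wave velocity (m/s).
#' @return A [TubeGeometry-class] object.
#' @examples
#' retinalGeometry()
#' TubeGeometry(d = 6e-3, h = 1e-3, cT = 2)
#' @export
TubeGeometry <- function(d, h, rho = 1000, cL = 1500, cT) {
  new("TubeGeometry", d = as.numeric(d), h = as.numeric(h),
      rho = as.numeric(rho), cL = as.numeric(cL), cT = as.numeric(cT))
}

#' Reference retinal-artery geometry
#'
#' Tube parameters representative of a retinal artery: 100 um outer
#' diameter (a 60 um variant is also of interest), 15 um wall thickness,
#' density 1000 kg/m^3, compression velocity 1500 m/s and shear velocity
#' 0.35 m/s (the value that yields a ~600 mm/s symmetric pulse wave).
#'
#' @param d Outer diameter (m); default 100e-6.
#' @return A [TubeGeometry-class] object.
#' @export
retinalGeometry <- function(d = 100e-6) {
  TubeGeometry(d = d, h = 15e-6, rho = 1000, cL = 1500, cT = 0.35)
}

#' Construct a SourceSpectrum
#'
#' @param fundamentalHz Fundamental frequency (Hz); ~1.5 Hz for a heartbeat.
#' @param amplitudes Per-harmonic relative amplitudes; harmonic `k` sits at
#'   `k * fundamentalHz`.
#' @param phases Per-harmonic phases (rad); recycled to the length of
#'   `amplitudes` (default all 0).
#' @return A [SourceSpectrum-class] object.
#' @examples
#' SourceSpectrum(1.5, amplitudes = c(1, 0.8, 0.6))
#' @export
SourceSpectrum <- function(fundamentalHz = 1.5, amplitudes = 1, phases = 0) {
  new("SourceSpectrum", fundamentalHz = as.numeric(fundamentalHz),
      amplitudes = as.numeric(amplitudes),
      phases = rep_len(as.numeric(phases), length(amplitudes)))
}

#' Construct a ModeSpec
#'
#' @param kind `"symmetric"` or `"antisymmetric"`.
#' @param velocity Either a single positive number (non-dispersive mode) or
#'   a `function(f)` returning the phase velocity (m/s) at frequency f (Hz).
#' @param amplitude Mode amplitude (m, or intensity units).
#' @param direction Propagation sign, +1 or -1.
#' @return A [ModeSpec-class] object.
#' @examples
#' ModeSpec("symmetric", velocity = 3.4, amplitude = 1e-4)
#' g <- retinalGeometry()
#' ModeSpec("antisymmetric", velocity = function(f) vFpwLowfreq(f, g),
#'          amplitude = 1)
#' @export
ModeSpec <- function(kind = c("symmetric", "antisymmetric"), velocity,
                     amplitude = 1, direction = 1) {
  kind <- match.arg(kind)
  law <- if (is.function(velocity)) velocity else {
    v0 <- as.numeric(velocity)
    if (length(v0) != 1L || !is.finite(v0) || v0 <= 0)
      stop("constant 'velocity' must be a single positive number")
    function(f) rep_len(v0, length(f))
  }
  new("ModeSpec", kind = kind, velocityLaw = law,
      amplitude = as.numeric(amplitude), direction = as.numeric(direction))
}

#' Construct an AcquisitionSpec
#'
#' @param frameRate Sampling rate (Hz).
#' @param duration Record duration (s).
#' @param pixelPitch Spatial step (m/pixel).
#' @param fieldOfView Spatial aperture (m).
#' @param noiseSigma Additive Gaussian noise sd; 0 disables noise.
#' @param seed Integer RNG seed fixing all randomness of the synthesis.
#' @return An [AcquisitionSpec-class] object.
#' @export
AcquisitionSpec <- function(frameRate, duration, pixelPitch, fieldOfView,
                            noiseSigma = 0, seed = 1L) {
  new("AcquisitionSpec", frameRate = as.numeric(frameRate),
      duration = as.numeric(duration), pixelPitch = as.numeric(pixelPitch),
      fieldOfView = as.numeric(fieldOfView),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed))
}

#' Construct a CurvilinearSignal
#'
#' @param x Abscissa grid (m), uniform step.
#' @param t Time grid (s), uniform step.
#' @param phi Matrix of signal values, length(x) x length(t).
#' @return A [CurvilinearSignal-class] object.
#' @export
CurvilinearSignal <- function(x, t, phi) {
  new("CurvilinearSignal", x = as.numeric(x), t = as.numeric(t),
      phi = as.matrix(phi))
}

#' Construct a WallDisplacements record
#'
#' @param x Curvilinear positions (m), uniform.
#' @param t Sample times (s), uniform.
#' @param uTop,uBottom Displacement matrices, length(x) x length(t) (m).
#' @return A [WallDisplacements-class] object.
#' @export
WallDisplacements <- function(x, t, uTop, uBottom) {
  bare <- function(m) matrix(as.numeric(m), nrow = nrow(m))
  new("WallDisplacements", x = as.numeric(x), t = as.numeric(t),
      uTop = bare(as.matrix(uTop)), uBottom = bare(as.matrix(uBottom)))
}
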