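#' @import methods
#' @importFrom stats fft nextn sd coef vcov lm approx fivenum quantile median
#' @importFrom utils head tail write.table read.table
NULL

## Central value objects of the pipeline. All physical quantities are SI:
## meters, seconds, Hz, m/s, kg/m^3, Pa.

#' Tube geometry and material parameters
#'
#' Parameters of a thin-walled elastic tube (a blood vessel modelled as a
#' traction-free hollow cylinder): outer diameter `d`, wall thickness `h`,
#' wall density `rho`, bulk compression wave velocity `cL` and bulk shear
#' wave velocity `cT`. These are the inputs of the Moens-Korteweg relation,
#' of the low-frequency closed forms for the L(0,1) and F(1,1) guided modes,
#' and of the full Gazis dispersion solver.
#'
#' @slot d numeric(1). Outer diameter (m).
#' @slot h numeric(1). Wall thickness (m), with `0 < h < d/2`.
#' @slot rho numeric(1). Wall density (kg/m^3).
#' @slot cL numeric(1). Bulk compression (longitudinal) wave velocity (m/s).
#' @slot cT numeric(1). Bulk shear wave velocity (m/s), with `0 < cT < cL`.
#' @seealso [TubeGeometry()], [retinalGeometry()], [dispersionNumeric()]
#' @exportClass TubeGeometry
setClass("TubeGeometry",
  representation(d = "numeric", h = "numeric", rho = "numeric",
                 cL = "numeric", cT = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("d", "h", "rho", "cL", "cT")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
    }
    if (!length(msg)) {
      if (object@h >= object@d / 2)
        msg <- c(msg, "wall thickness 'h' must be smaller than the outer radius d/2")
      if (object@cT >= object@cL)
        msg <- c(msg, "shear velocity 'cT' must be smaller than compression velocity 'cL'")
    }
    if (length(msg)) msg else TRUE
  })

#' Cardiac source spectrum
#'
#' Harmonic description of the natural wave source: a fundamental (the heart
#' rate, ~1.5 Hz) plus harmonics with per-harmonic relative amplitudes and
#' phase offsets. Harmonic k has frequency `k * fundamentalHz`.
#'
#' @slot fundamentalHz numeric(1). Fundamental frequency (Hz), > 0.
#' @slot amplitudes numeric. Relative amplitude of each harmonic
#'   (dimensionless); at least one must be nonzero unless the whole source is
#'   deliberately silent.
#' @slot phases numeric. Phase offset of each harmonic (rad), same length as
#'   `amplitudes`.
#' @seealso [SourceSpectrum()], [makeSource()], [propagateMode()]
#' @exportClass SourceSpectrum
setClass("SourceSpectrum",
  representation(fundamentalHz = "numeric", amplitudes = "numeric",
                 phases = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@fundamentalHz) != 1L || !is.finite(object@fundamentalHz) ||
        object@fundamentalHz <= 0)
      msg <- c(msg, "'fundamentalHz' must be a single positive number")
    if (!length(object@amplitudes))
      msg <- c(msg, "'amplitudes' must contain at least one harmonic")
    if (length(object@phases) != length(object@amplitudes))
      msg <- c(msg, "'phases' and 'amplitudes' must have the same length")
    if (anyNA(object@amplitudes) || anyNA(object@phases))
      msg <- c(msg, "amplitudes and phases must be finite")
    if (length(msg)) msg else TRUE
  })

#' Guided-mode synthesis specification
#'
#' One traveling wave mode to synthesize: symmetric (diameter expansion,
#' L(0,1)-type) or antisymmetric (tube flexion, F(1,1)-type), with either a
#' constant phase velocity or a dispersive velocity law `v(f)`, a
#' displacement (or intensity-modulation) amplitude and a propagation
#' direction.
#'
#' @slot kind character(1). `"symmetric"` or `"antisymmetric"`.
#' @slot velocityLaw function. `function(f)` returning the phase velocity
#'   (m/s) at frequency `f` (Hz); must be positive over the synthesis band.
#' @slot amplitude numeric(1). Amplitude of the mode (m for displacements,
#'   arbitrary units for intensity modulation).
#' @slot direction numeric(1). Propagation sign, `+1` or `-1`.
#' @seealso [ModeSpec()], [propagateMode()]
#' @exportClass ModeSpec
setClass("ModeSpec",
  representation(kind = "character", velocityLaw = "function",
                 amplitude = "numeric", direction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("symmetric", "antisymmetric"))
      msg <- c(msg, "'kind' must be \"symmetric\" or \"antisymmetric\"")
    if (!object@direction %in% c(-1, 1))
      msg <- c(msg, "'direction' must be +1 or -1")
    if (length(object@amplitude) != 1L || !is.finite(object@amplitude))
      msg <- c(msg, "'amplitude' must be a single finite number")
    if (length(msg)) msg else TRUE
  })

#' Acquisition parameters for synthetic recordings
#'
#' Sampling and noise parameters of a synthetic acquisition: frame rate,
#' record duration, pixel pitch, field of view (aperture), additive Gaussian
#' noise scale, and the seed that fixes all randomness.
#'
#' @slot frameRate numeric(1). Sampling rate (Hz).
#' @slot duration numeric(1). Record duration (s); `duration * frameRate`
#'   must give at least 16 frames.
#' @slot pixelPitch numeric(1). Spatial sampling step (m/pixel).
#' @slot fieldOfView numeric(1). Spatial aperture (m).
#' @slot noiseSigma numeric(1). Standard deviation of additive Gaussian
#'   noise (intensity or displacement units), >= 0.
#' @slot seed integer(1). RNG seed; identical seeds give bit-identical
#'   synthetic outputs.
#' @seealso [AcquisitionSpec()], [renderMovie()], [renderWalls()]
#' @exportClass AcquisitionSpec
setClass("AcquisitionSpec",
  representation(frameRate = "numeric", duration = "numeric",
                 pixelPitch = "numeric", fieldOfView = "numeric",
                 noiseSigma = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@frameRate <= 0) msg <- c(msg, "'frameRate' must be positive")
    if (round(object@duration * object@frameRate) < 16)
      msg <- c(msg, "record must contain at least 16 frames")
    if (object@pixelPitch <= 0) msg <- c(msg, "'pixelPitch' must be positive")
    if (object@fieldOfView <= 0) msg <- c(msg, "'fieldOfView' must be positive")
    if (object@noiseSigma < 0) msg <- c(msg, "'noiseSigma' must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Vessel movie
#'
#' An intensity image sequence of a vessel (e.g. a power-Doppler movie)
#' with its acquisition metadata. Frames are stored as a rows x cols x time
#' array of finite intensities.
#'
#' @slot frames numeric array, rows x cols x time, at least 2 frames.
#' @slot frameRate numeric(1). Frame rate (Hz).
#' @slot pixelPitch numeric(1). Pixel pitch (m/pixel).
#' @seealso [renderMovie()], [readVesselMovie()], [segmentVessel()]
#' @exportClass VesselMovie
setClass("VesselMovie",
  representation(frames = "array", frameRate = "numeric",
                 pixelPitch = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@frames)) != 3L)
      msg <- c(msg, "'frames' must be a 3-D array (rows x cols x time)")
    else if (dim(object@frames)[3] < 2L)
      msg <- c(msg, "movie must contain at least 2 frames")
    if (!all(is.finite(object@frames)))
      msg <- c(msg, "'frames' must be finite")
    if (object@frameRate <= 0) msg <- c(msg, "'frameRate' must be positive")
    if (object@pixelPitch <= 0) msg <- c(msg, "'pixelPitch' must be positive")
    if (length(msg)) msg else TRUE
  })

#' Vessel segmentation
#'
#' Result of gradient-based vessel segmentation on a time-averaged image:
#' the edge mask, the ordered centerline, its cumulative arc length
#' (curvilinear abscissa, in meters) and the local lumen width.
#'
#' @slot edgeMask logical matrix. Edge pixels of the selected vessel.
#' @slot centerline numeric matrix, n x 2 (row, col), ordered from one end;
#'   fractional pixel coordinates, resampled to a uniform abscissa step.
#' @slot abscissa numeric. Strictly increasing arc length (m) per
#'   centerline point.
#' @slot widthPx numeric. Local lumen width (pixels) per centerline point.
#' @slot pixelPitch numeric(1). Pixel pitch (m/pixel) used for the abscissa.
#' @seealso [segmentVessel()], [sampleCrossSections()]
#' @exportClass VesselSegmentation
setClass("VesselSegmentation",
  representation(edgeMask = "matrix", centerline = "matrix",
                 abscissa = "numeric", widthPx = "numeric",
                 pixelPitch = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@centerline) != length(object@abscissa))
      msg <- c(msg, "'centerline' and 'abscissa' lengths differ")
    if (length(object@abscissa) > 1L && any(diff(object@abscissa) <= 0))
      msg <- c(msg, "'abscissa' must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Curvilinear signal
#'
#' One time trace per curvilinear abscissa along the vessel: the matrix
#' `phi` holds the signal at position `x[i]` and time `t[j]`. This is the
#' common input of passive spectroscopy and time-of-flight estimation.
#'
#' @slot x numeric. Curvilinear abscissa grid (m), uniform step.
#' @slot t numeric. Sample times (s), uniform step.
#' @slot phi numeric matrix, length(x) x length(t), finite.
#' @seealso [sampleCrossSections()], [temporalSpectrum()], [tofMap()]
#' @exportClass CurvilinearSignal
setClass("CurvilinearSignal",
  representation(x = "numeric", t = "numeric", phi = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@phi) != length(object@x) ||
        ncol(object@phi) != length(object@t))
      msg <- c(msg, "'phi' must be length(x) x length(t)")
    if (!all(is.finite(object@phi))) msg <- c(msg, "'phi' must be finite")
    for (s in c("x", "t")) {
      g <- slot(object, s)
      if (length(g) > 2L) {
        dg <- diff(g)
        if (any(abs(dg - dg[1]) > 1e-6 * abs(dg[1]) + 1e-15))
          msg <- c(msg, sprintf("'%s' grid must be uniform", s))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Spectral field
#'
#' Per-position temporal Fourier transform of a curvilinear signal, plus
#' the magnitude spectrum averaged over positions (used for peak picking).
#' Only nonnegative frequencies up to Nyquist are kept.
#'
#' @slot f numeric. Frequency grid (Hz), uniform, starting at 0.
#' @slot phiHat complex matrix, positions x frequencies.
#' @slot meanSpectrum numeric. `colMeans(abs(phiHat))`.
#' @slot x numeric. Abscissa grid (m) inherited from the signal.
#' @seealso [temporalSpectrum()], [focalSpot()], [dispersionCurve()]
#' @exportClass SpectralField
setClass("SpectralField",
  representation(f = "numeric", phiHat = "matrix", meanSpectrum = "numeric",
                 x = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.complex(object@phiHat)) msg <- c(msg, "'phiHat' must be complex")
    if (ncol(object@phiHat) != length(object@f))
      msg <- c(msg, "ncol(phiHat) must equal length(f)")
    if (nrow(object@phiHat) != length(object@x))
      msg <- c(msg, "nrow(phiHat) must equal length(x)")
    if (length(object@f) && (object@f[1] < 0))
      msg <- c(msg, "'f' must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' Focal spot
#'
#' Normalized phase-only spatial correlation `C(r)` of the wave field at
#' one frequency (or one band) versus spatial lag `r`, symmetric about
#' `r = 0` where `C(0) = 1`. For a single plane wave of wavelength
#' `lambda`, `C(r) = cos(2*pi*r/lambda)`: the focal spot carries the
#' wavelength.
#'
#' @slot r numeric. Spatial lags (m), symmetric about 0.
#' @slot C numeric. Correlation values, `|C| <= 1` (within 1e-12).
#' @slot fCenter numeric. Frequency (length 1) or band limits (length 2)
#'   of the spot (Hz).
#' @seealso [focalSpot()], [polychromaticFocalSpot()], [fitWavelength()]
#' @exportClass FocalSpot
setClass("FocalSpot",
  representation(r = "numeric", C = "numeric", fCenter = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@r) != length(object@C))
      msg <- c(msg, "'r' and 'C' lengths differ")
    i0 <- which(object@r == 0)
    if (length(i0) != 1L || abs(object@C[i0] - 1) > 1e-12)
      msg <- c(msg, "C(0) must equal 1")
    if (any(abs(object@C) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "|C(r)| must not exceed 1")
    if (length(msg)) msg else TRUE
  })

#' Dispersion curve
#'
#' Per-frequency wavelength and phase velocity records: the central result
#' of passive spectroscopy. `v = lambda * f` is enforced exactly at
#' assembly; points whose sinusoidal fit failed are flagged via `fitOk`,
#' never silently dropped.
#'
#' @slot f numeric. Frequencies (Hz).
#' @slot lambda numeric. Fitted wavelengths (m); NA where the fit failed.
#' @slot lambdaSigma numeric. 1-sigma wavelength uncertainties (m).
#' @slot v numeric. Phase velocities `lambda * f` (m/s).
#' @slot vSigma numeric. Propagated velocity uncertainties `f * lambdaSigma`.
#' @slot fitOk logical. TRUE where the wavelength fit converged.
#' @seealso [dispersionCurve()], [writeDispersionCurve()]
#' @exportClass DispersionCurve
setClass("DispersionCurve",
  representation(f = "numeric", lambda = "numeric", lambdaSigma = "numeric",
                 v = "numeric", vSigma = "numeric", fitOk = "logical"),
  validity = function(object) {
    n <- length(object@f)
    if (any(vapply(c("lambda", "lambdaSigma", "v", "vSigma", "fitOk"),
                   function(s) length(slot(object, s)) != n, logical(1))))
      return("all slots must have the same length as 'f'")
    ok <- object@fitOk & !is.na(object@lambda)
    if (any(object@lambda[ok] <= 0))
      return("fitted wavelengths must be positive")
    if (any(abs(object@v[ok] - object@lambda[ok] * object@f[ok]) >
            1e-12 * pmax(object@v[ok], 1e-300)))
      return("v must equal lambda * f exactly")
    TRUE
  })

#' Two-wall displacement record
#'
#' Displacements of the top and bottom vessel walls along the imaging beam,
#' as position x time matrices on common uniform grids. Radial (symmetric)
#' expansion moves the walls in opposite directions; flexion (antisymmetric)
#' moves them together.
#'
#' @slot x numeric. Curvilinear positions (m), uniform.
#' @slot t numeric. Sample times (s), uniform.
#' @slot uTop,uBottom numeric matrices, length(x) x length(t) (m).
#' @seealso [renderWalls()], [separateModes()], [readWallDisplacements()]
#' @exportClass WallDisplacements
setClass("WallDisplacements",
  representation(x = "numeric", t = "numeric", uTop = "matrix",
                 uBottom = "matrix"),
  validity = function(object) {
    msg <- character()
    d <- c(length(object@x), length(object@t))
    if (!identical(dim(object@uTop), as.integer(d)) ||
        !identical(dim(object@uBottom), as.integer(d)))
      msg <- c(msg, "'uTop' and 'uBottom' must be length(x) x length(t)")
    if (length(msg)) msg else TRUE
  })

#' Separated wave-mode fields
#'
#' Symmetric and antisymmetric displacement fields obtained from a two-wall
#' record by the half-sum / half-difference map (see [separateModes()]).
#'
#' @slot symmetric,antisymmetric numeric matrices, position x time.
#' @slot convention character(1). Sign/scale convention tag.
#' @seealso [separateModes()], [classifySnapshot()]
#' @exportClass ModeFields
setClass("ModeFields",
  representation(symmetric = "matrix", antisymmetric = "matrix",
                 convention = "character"),
  validity = function(object) {
    if (!identical(dim(object@symmetric), dim(object@antisymmetric)))
      return("'symmetric' and 'antisymmetric' dimensions differ")
    TRUE
  })

#' Time-of-flight correlation map
#'
#' Pairwise time-domain cross-correlation of traces separated by spatial
#' lag `dx`, averaged over all source positions: a traveling wave appears
#' as a ridge along `dt = dx / v`.
#'
#' @slot dx numeric. Spatial lags (m), symmetric about 0.
#' @slot dt numeric. Time lags (s), symmetric about 0.
#' @slot value numeric matrix, length(dx) x length(dt).
#' @seealso [tofMap()], [tofVelocity()]
#' @exportClass ToFMap
setClass("ToFMap",
  representation(dx = "numeric", dt = "numeric", value = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@value),
                   c(length(object@dx), length(object@dt))))
      return("'value' must be length(dx) x length(dt)")
    if (!all(is.finite(object@value))) return("'value' must be finite")
    TRUE
  })

#' Theoretical dispersion curve
#'
#' Phase velocity of a guided tube mode versus frequency, from the numerical
#' solution of the Gazis characteristic equation, with per-point convergence
#' flags and residual determinant magnitudes.
#'
#' @slot f numeric. Frequency grid (Hz).
#' @slot v numeric. Phase velocity (m/s); NA where the root was lost.
#' @slot converged logical. Root-polish convergence flags.
#' @slot residual numeric. |determinant| at the returned root.
#' @slot mode character(1). `"L(0,1)"` or `"F(1,1)"`.
#' @seealso [dispersionNumeric()], [characteristicDet()]
#' @exportClass TheoryCurve
setClass("TheoryCurve",
  representation(f = "numeric", v = "numeric", converged = "logical",
                 residual = "numeric", mode = "character"),
  validity = function(object) {
    n <- length(object@f)
    if (length(object@v) != n || length(object@converged) != n ||
        length(object@residual) != n)
      return("'v', 'converged' and 'residual' must match 'f' in length")
    if (any(object@v[object@converged] <= 0, na.rm = TRUE))
      return("converged phase velocities must be positive")
    TRUE
  })
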