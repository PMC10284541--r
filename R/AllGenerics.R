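#' Accessors for flexwave objects
#'
#' Small accessor generics: `frameRate()` and `pixelPitch()` return the
#' acquisition metadata of a [VesselMovie-class]; `abscissa()` returns the
#' curvilinear arc-length grid (m) of a [VesselSegmentation-class] or
#' [CurvilinearSignal-class]; `sampleTimes()` the time grid (s);
#' `signalMatrix()` the position x time matrix.
#'
#' @param object A flexwave object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setGeneric("abscissa", function(object) standardGeneric("abscissa"))
#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname accessors
setMethod("frameRate", "VesselMovie", function(object) object@frameRate)
#' @rdname accessors
setMethod("pixelPitch", "VesselMovie", function(object) object@pixelPitch)
#' @rdname accessors
setMethod("abscissa", "VesselSegmentation", function(object) object@abscissa)
#' @rdname accessors
setMethod("abscissa", "CurvilinearSignal", function(object) object@x)
#' @rdname accessors
setMethod("sampleTimes", "CurvilinearSignal", function(object) object@t)
#' @rdname accessors
setMethod("signalMatrix", "CurvilinearSignal", function(object) object@phi)

#' Coerce a DispersionCurve to a data.frame
#'
#' @param x A [DispersionCurve-class].
#' @param row.names,optional,... Passed for interface compatibility; unused.
#' @return data.frame with columns `f_hz`, `lambda_m`, `lambda_sigma_m`,
#'   `v_m_per_s`, `v_sigma_m_per_s`, `fit_ok`.
#' @export
as.data.frame.DispersionCurve <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(f_hz = x@f, lambda_m = x@lambda, lambda_sigma_m = x@lambdaSigma,
             v_m_per_s = x@v, v_sigma_m_per_s = x@vSigma, fit_ok = x@fitOk)
}

#' Coerce a TheoryCurve to a data.frame
#'
#' @param x A [TheoryCurve-class].
#' @param row.names,optional,... Unused.
#' @return data.frame with columns `f_hz`, `v_m_per_s`, `converged`,
#'   `residual`.
#' @export
as.data.frame.TheoryCurve <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(f_hz = x@f, v_m_per_s = x@v, converged = x@converged,
             residual = x@residual)
}

setMethod("show", "TubeGeometry", function(object) {
  cat("TubeGeometry: d =", format(object@d), "m, h =", format(object@h),
      "m\n  rho =", object@rho, "kg/m^3, cL =", object@cL,
      "m/s, cT =", object@cT, "m/s\n")
})

setMethod("show", "VesselMovie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VesselMovie: %d x %d pixels, %d frames @ %.3g Hz, pitch %.3g m\n",
              d[1], d[2], d[3], object@frameRate, object@pixelPitch))
})

setMethod("show", "CurvilinearSignal", function(object) {
  cat(sprintf(
    "CurvilinearSignal: %d positions over %.3g m, %d samples @ %.3g Hz\n",
    length(object@x), diff(range(object@x)), length(object@t),
    1 / mean(diff(object@t))))
})

setMethod("show", "FocalSpot", function(object) {
  lab <- if (length(object@fCenter) == 2L)
    sprintf("band %.3g-%.3g Hz", object@fCenter[1], object@fCenter[2])
  else sprintf("f = %.3g Hz", object@fCenter)
  cat(sprintf("FocalSpot (%s): %d lags over [%.3g, %.3g] m\n", lab,
              length(object@r), min(object@r), max(object@r)))
})

setMethod("show", "DispersionCurve", function(object) {
  cat(sprintf("DispersionCurve: %d points (%d fit ok)\n", length(object@f),
              sum(object@fitOk)))
  if (length(object@f)) print(as.data.frame(object), digits = 4)
})

setMethod("show", "TheoryCurve", function(object) {
  cat(sprintf("TheoryCurve %s: %d frequencies, %d converged, v in [%.3g, %.3g] m/s\n",
              object@mode, length(object@f), sum(object@converged),
              min(object@v, na.rm = TRUE), max(object@v, na.rm = TRUE)))
})

setMethod("show", "WallDisplacements", function(object) {
  cat(sprintf("WallDisplacements: %d positions x %d samples (%.3g s @ %.3g Hz)\n",
              length(object@x), length(object@t), diff(range(object@t)),
              1 / mean(diff(object@t))))
})

setMethod("show", "ToFMap", function(object) {
  cat(sprintf("ToFMap: %d spatial x %d temporal lags\n", length(object@dx),
              length(object@dt)))
})
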