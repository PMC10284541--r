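## End-to-end analysis pipelines tying the modules together, each
## returning its estimates plus a run report (resolved parameters,
## warnings, per-stage provenance, config hash). These functions, with
## the readers/writers in io.R, are the package's operational interface.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

.runReport <- function(pipeline, params, estimates, warnings = character()) {
  list(pipeline = pipeline,
       version = as.character(utils::packageVersion("flexwave")),
       params = params,
       estimates = estimates,
       warnings = warnings,
       config_hash = rlang::hash(params))
}

#' Retinal pipeline: movie to dispersion curve
#'
#' Full analysis of a vessel movie: segmentation of the time-averaged
#' image, cross-section averaging to a curvilinear signal, spectral peak
#' picking, a passive-spectroscopy dispersion curve at the peaks, and a
#' correlation time-of-flight cross-check. Velocities are reported in
#' mm/s in the report (retinal convention) while all returned objects
#' stay SI.
#'
#' @param movie A [VesselMovie-class].
#' @param prominence Spectral peak prominence threshold (default 0.1).
#' @param fBand Optional length-2 band (Hz) restricting analysis peaks.
#' @param halfWidthPx,gradientThreshold,seedPoint Passed to the geometry
#'   stage.
#' @param outDir Optional directory: writes `dispersion.csv`,
#'   `signal.csv` and `report.json` there.
#' @return List with `curve` ([DispersionCurve-class]), `tof` (named
#'   vector from [tofVelocity()], or NULL if no ridge), `signal`,
#'   `segmentation` and `report`.
#' @examples
#' sc <- retinalScenario(seed = 1, duration = 8, nRows = 32, nCols = 96)
#' res <- runRetinaPipeline(sc$movie)
#' res$curve
#' @export
runRetinaPipeline <- function(movie, prominence = 0.1, fBand = NULL,
                              halfWidthPx = NULL, gradientThreshold = NULL,
                              seedPoint = NULL, outDir = NULL) {
  stopifnot(is(movie, "VesselMovie"))
  warns <- character()
  meanImg <- rowMeans(movie@frames, dims = 2)
  seg <- .stage("geometry/segment",
                segmentVessel(meanImg, pixelPitch(movie),
                              gradientThreshold = gradientThreshold,
                              seedPoint = seedPoint))
  sig <- .stage("geometry/cross-sections",
                sampleCrossSections(movie, seg, halfWidthPx = halfWidthPx))
  peaks <- .stage("spectroscopy/peaks",
                  spectralPeaks(sig, prominence = prominence))
  if (!is.null(fBand))
    peaks <- peaks[peaks >= fBand[1] & peaks <= fBand[2]]
  if (!length(peaks)) stop("[spectroscopy/peaks] no spectral peaks found")
  field <- .stage("spectroscopy/fft", temporalSpectrum(sig))
  curve <- .stage("spectroscopy/dispersion", dispersionCurve(field, peaks))
  tof <- tryCatch(tofVelocity(tofMap(sig)), error = function(e) {
    warns <<- c(warns, paste("tof:", conditionMessage(e)))
    NULL
  })
  params <- list(prominence = prominence, fBand = fBand,
                 halfWidthPx = halfWidthPx,
                 gradientThreshold = gradientThreshold,
                 frameRate = frameRate(movie),
                 pixelPitch = pixelPitch(movie))
  est <- list(
    dispersion = lapply(seq_along(curve@f), function(i) list(
      f_hz = curve@f[i], v_mm_per_s = curve@v[i] * 1e3,
      v_sigma_mm_per_s = curve@vSigma[i] * 1e3,
      unit = "mm/s", method = "spectroscopy", fit_ok = curve@fitOk[i])),
    tof = if (!is.null(tof)) list(v_mm_per_s = tof[["v"]] * 1e3,
                                  v_sigma_mm_per_s = tof[["sigma"]] * 1e3,
                                  unit = "mm/s", method = "tof"))
  report <- .runReport("retina", params, est, warns)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeDispersionCurve(curve, file.path(outDir, "dispersion.csv"))
    writeCurvilinearSignal(sig, file.path(outDir, "signal.csv"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(curve = curve, tof = tof, signal = sig, segmentation = seg,
       report = report)
}

#' Carotid pipeline: two-wall record to per-mode velocities
#'
#' Separates symmetric and antisymmetric wall motion, measures each
#' mode's central frequency by autocorrelation, computes monochromatic
#' and polychromatic focal spots, fits the wavelength and reports
#' `v = lambda * f` per mode, with a directional-filtered correlation
#' time-of-flight cross-check. A mode whose energy falls below
#' `noiseFloorRatio` times the other mode's is flagged as below the
#' noise floor and not fitted.
#'
#' @param walls A [WallDisplacements-class].
#' @param band Analysis band (Hz) for the polychromatic spot and
#'   central-frequency search (default `c(4, 20)`).
#' @param noiseFloorRatio Energy ratio below which a mode is declared
#'   absent (default 1e-3).
#' @param outDir Optional output directory for per-mode CSVs and the
#'   report.
#' @return List with one entry per mode (`symmetric`, `antisymmetric`),
#'   each holding `fCenter`, `lambda`, `v`, `vSigma`, `tof`, `spot`,
#'   `polySpot` (or `belowNoiseFloor = TRUE`), plus `modes`
#'   ([ModeFields-class]) and `report`.
#' @examples
#' sc <- carotidScenario(seed = 2)
#' res <- runCarotidPipeline(sc$walls)
#' res$symmetric$v; res$antisymmetric$v
#' @export
runCarotidPipeline <- function(walls, band = c(4, 20),
                               noiseFloorRatio = 1e-3, outDir = NULL) {
  stopifnot(is(walls, "WallDisplacements"))
  warns <- character()
  mf <- .stage("modes/separate", separateModes(walls))
  energies <- c(symmetric = sum(mf@symmetric^2),
                antisymmetric = sum(mf@antisymmetric^2))
  analyse <- function(u, label) {
    if (energies[label] < noiseFloorRatio * max(energies)) {
      warns <<- c(warns, sprintf("%s channel below noise floor", label))
      return(list(belowNoiseFloor = TRUE))
    }
    sig <- CurvilinearSignal(walls@x, walls@t, u)
    fc <- .stage(paste0(label, "/central-frequency"),
                 centralFrequency(sig))
    fc <- min(max(fc, band[1]), band[2])
    field <- temporalSpectrum(sig)
    # evaluate the spot on the spectral peak nearest the central
    # frequency: off-peak bins carry no wave energy, only noise phases
    pks <- spectralPeaks(sig, prominence = 0.05)
    pks <- pks[pks >= band[1] & pks <= band[2]]
    if (length(pks)) fc <- pks[which.min(abs(pks - fc))]
    spot <- .stage(paste0(label, "/focal-spot"),
                   suppressWarnings(focalSpot(field, fc)))
    est <- .stage(paste0(label, "/wavelength"), fitWavelength(spot))
    poly <- tryCatch(polychromaticFocalSpot(field, band),
                     error = function(e) NULL)
    # directional filtering (against reflected waves) is only meaningful
    # when at least one wavelength fits inside the aperture; beyond that
    # the propagation direction is spatially unresolvable and quadrant
    # zeroing distorts the field
    aperture <- diff(range(walls@x))
    useFilter <- est[["lambda"]] < aperture
    tof <- tryCatch({
      tsig <- if (useFilter) directionalFilter(sig, direction = 1) else sig
      tofVelocity(tofMap(tsig))
    }, error = function(e) {
      warns <<- c(warns, sprintf("%s tof: %s", label, conditionMessage(e)))
      NULL
    })
    list(belowNoiseFloor = FALSE, fCenter = spot@fCenter,
         lambda = est[["lambda"]], lambdaSigma = est[["sigma"]],
         v = est[["lambda"]] * spot@fCenter,
         vSigma = est[["sigma"]] * spot@fCenter,
         tof = tof, spot = spot, polySpot = poly)
  }
  sym <- analyse(mf@symmetric, "symmetric")
  ant <- analyse(mf@antisymmetric, "antisymmetric")
  params <- list(band = band, noiseFloorRatio = noiseFloorRatio)
  asEst <- function(m, label) {
    if (isTRUE(m$belowNoiseFloor)) list(below_noise_floor = TRUE)
    else list(f_hz = m$fCenter, lambda_m = m$lambda,
              v_m_per_s = m$v, v_sigma_m_per_s = m$vSigma, unit = "m/s",
              method = "spectroscopy",
              tof_v_m_per_s = if (!is.null(m$tof)) m$tof[["v"]],
              tof_method = "tof")
  }
  report <- .runReport("carotid", params,
                       list(symmetric = asEst(sym, "symmetric"),
                            antisymmetric = asEst(ant, "antisymmetric")),
                       warns)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCurvilinearSignal(CurvilinearSignal(walls@x, walls@t,
                                             mf@symmetric),
                           file.path(outDir, "mode_symmetric.csv"))
    writeCurvilinearSignal(CurvilinearSignal(walls@x, walls@t,
                                             mf@antisymmetric),
                           file.path(outDir, "mode_antisymmetric.csv"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(symmetric = sym, antisymmetric = ant, modes = mf, report = report)
}

#' Theory pipeline: geometry to dispersion curves for both modes
#'
#' Numerical Gazis dispersion curves for L(0,1) and F(1,1) at one
#' geometry, with the closed-form low-frequency asymptotes attached.
#'
#' @param geom A [TubeGeometry-class].
#' @param fGrid Ascending frequency grid (Hz).
#' @param outDir Optional output directory: per-mode CSV + geometry JSON.
#' @return List with [TheoryCurve-class] entries `L` and `F` and the
#'   asymptote functions.
#' @examples
#' res <- runTheoryCurves(retinalGeometry(60e-6), seq(1, 10, 1))
#' res$F
#' @export
runTheoryCurves <- function(geom, fGrid, outDir = NULL) {
  L <- .stage("theory/L(0,1)", dispersionNumeric("L(0,1)", geom, fGrid))
  F <- .stage("theory/F(1,1)", dispersionNumeric("F(1,1)", geom, fGrid))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeTheoryCurve(L, geom, file.path(outDir, "theory_L01.csv"))
    writeTheoryCurve(F, geom, file.path(outDir, "theory_F11.csv"))
  }
  list(L = L, F = F,
       asymptotes = list(fpw = function(f) vFpwLowfreq(f, geom),
                         fpwBeam = function(f) vFpwBeam(f, geom),
                         lpw = function() vLpwLowfreq(geom)))
}
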