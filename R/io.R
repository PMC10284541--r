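## File interfaces. All on-disk quantities are SI: movies as multi-page
## TIFF (32-bit float) with a JSON sidecar holding the acquisition
## metadata; displacement and signal matrices as CSV with the abscissa in
## the first column and the time grid in the header row; curves as plain
## CSV with unit-suffixed column names.

.sidecarPath <- function(path) sub("\\.tiff?$", ".json", path,
                                   ignore.case = TRUE)

#' Write / read a vessel movie
#'
#' `writeVesselMovie()` stores the frames as a multi-page 32-bit float
#' TIFF plus a JSON sidecar `{frame_rate_hz, pixel_pitch_m, seed,
#' scenario}`; `readVesselMovie()` reads the pair back.
#'
#' @param movie A [VesselMovie-class].
#' @param path Path of the TIFF file; the sidecar uses the same stem with
#'   a `.json` extension.
#' @param seed,scenario Optional metadata echoed into the sidecar.
#' @return `writeVesselMovie()`: the TIFF path, invisibly.
#' @export
writeVesselMovie <- function(movie, path, seed = NA, scenario = NA) {
  stopifnot(is(movie, "VesselMovie"))
  nT <- dim(movie@frames)[3]
  # TIFF samples live in [0, 1]; the intensity scale goes in the sidecar
  sc <- max(movie@frames)
  if (sc <= 0) sc <- 1
  pages <- lapply(seq_len(nT), function(i) movie@frames[, , i] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(frame_rate_hz = movie@frameRate,
               pixel_pitch_m = movie@pixelPitch,
               intensity_scale = sc,
               seed = seed, scenario = scenario)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVesselMovie
#' @return `readVesselMovie()`: a [VesselMovie-class].
#' @export
readVesselMovie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(.sidecarPath(path))
  sc <- if (!is.null(meta$intensity_scale))
    as.numeric(meta$intensity_scale) else 1
  frames <- array(unlist(pages) * sc,
                  dim = c(dim(pages[[1]]), length(pages)))
  new("VesselMovie", frames = frames,
      frameRate = as.numeric(meta$frame_rate_hz),
      pixelPitch = as.numeric(meta$pixel_pitch_m))
}

.writeXTMatrix <- function(x, t, m, path) {
  header <- paste(c("x_m", format(t, digits = 15, scientific = TRUE,
                                  trim = TRUE)), collapse = ",")
  body <- cbind(x, m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(body, con, sep = ",", row.names = FALSE, col.names = FALSE)
}

.readXTMatrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  t <- as.numeric(header[-1])
  body <- as.matrix(read.table(path, sep = ",", skip = 1L))
  list(x = body[, 1], t = t, m = unname(body[, -1, drop = FALSE]))
}

#' Write / read two-wall displacement CSV files
#'
#' One CSV per wall: first column the curvilinear position x (m), header
#' row the sample times (s), body the displacements (m).
#'
#' @param walls A [WallDisplacements-class].
#' @param topPath,bottomPath File paths for the two walls.
#' @return `writeWallDisplacements()`: invisibly, the two paths.
#' @export
writeWallDisplacements <- function(walls, topPath, bottomPath) {
  stopifnot(is(walls, "WallDisplacements"))
  .writeXTMatrix(walls@x, walls@t, walls@uTop, topPath)
  .writeXTMatrix(walls@x, walls@t, walls@uBottom, bottomPath)
  invisible(c(topPath, bottomPath))
}

#' @rdname writeWallDisplacements
#' @return `readWallDisplacements()`: a [WallDisplacements-class].
#' @export
readWallDisplacements <- function(topPath, bottomPath) {
  top <- .readXTMatrix(topPath)
  bot <- .readXTMatrix(bottomPath)
  if (!isTRUE(all.equal(top$x, bot$x)) ||
      !isTRUE(all.equal(top$t, bot$t)))
    stop("the two wall files do not share one grid")
  WallDisplacements(x = top$x, t = top$t, uTop = top$m, uBottom = bot$m)
}

#' Write a curvilinear signal as CSV
#'
#' Same layout as the wall files: x column, time header row, signal body.
#'
#' @param sig A [CurvilinearSignal-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeCurvilinearSignal <- function(sig, path) {
  stopifnot(is(sig, "CurvilinearSignal"))
  .writeXTMatrix(sig@x, sig@t, sig@phi, path)
  invisible(path)
}

#' Write a dispersion curve as CSV
#'
#' Columns: `f_hz, lambda_m, lambda_sigma_m, v_m_per_s, v_sigma_m_per_s,
#' fit_ok`.
#'
#' @param curve A [DispersionCurve-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeDispersionCurve <- function(curve, path) {
  stopifnot(is(curve, "DispersionCurve"))
  write.table(as.data.frame(curve), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a focal spot as CSV
#'
#' Columns `r_m, C`.
#'
#' @param spot A [FocalSpot-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeFocalSpot <- function(spot, path) {
  stopifnot(is(spot, "FocalSpot"))
  write.table(data.frame(r_m = spot@r, C = spot@C), path, sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a theoretical dispersion curve as CSV
#'
#' Columns `f_hz, v_m_per_s, converged, residual`, plus the closed-form
#' low-frequency asymptote columns for the two modes; the geometry is
#' echoed to a JSON file next to the CSV.
#'
#' @param curve A [TheoryCurve-class].
#' @param geom The [TubeGeometry-class] it was computed from.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeTheoryCurve <- function(curve, geom, path) {
  stopifnot(is(curve, "TheoryCurve"), is(geom, "TubeGeometry"))
  df <- as.data.frame(curve)
  df$v_asym_fpw_m_per_s <- vFpwLowfreq(df$f_hz, geom)
  df$v_asym_lpw_m_per_s <- vLpwLowfreq(geom)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(mode = curve@mode, d_m = geom@d, h_m = geom@h,
         rho_kg_m3 = geom@rho, cL_m_per_s = geom@cL, cT_m_per_s = geom@cT),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
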