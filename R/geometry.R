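## Vessel geometry extraction: Sobel edge detection on the time-averaged
## image, centerline construction from paired opposing edges, and
## reduction of the movie to one trace per cross section along the
## curvilinear abscissa.

.sobel <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(img, kx)
  gy <- EBImage::filter2(img, t(kx))
  sqrt(gx^2 + gy^2)
}

.movingAverage <- function(v, n = 5L) {
  if (length(v) < n) return(v)
  as.numeric(stats::filter(v, rep(1 / n, n), sides = 2)) ->
    out
  # keep the ends untouched where the window does not fit
  k <- (n - 1L) / 2L
  out[seq_len(k)] <- v[seq_len(k)]
  out[(length(v) - k + 1L):length(v)] <- v[(length(v) - k + 1L):length(v)]
  out
}

#' Segment a vessel on a time-averaged image
#'
#' Gradient-based segmentation: Sobel gradient magnitude, threshold
#' (Otsu's method on the normalized gradient if not given), then the edge
#' mask is restricted to the connected component containing (or nearest
#' to) the seed point, or to the largest component if no seed is given.
#' The centerline is built as the midpoints between paired opposing edges
#' scanned along the vessel's long axis, ordered from one end, smoothed
#' with a 5-point moving average, and resampled to a uniform abscissa step
#' of one pixel pitch.
#'
#' @param meanImage Numeric matrix: the time-averaged frame.
#' @param pixelPitch Pixel pitch (m/pixel) used to express the abscissa in
#'   meters.
#' @param gradientThreshold Threshold on the Sobel gradient magnitude;
#'   default: Otsu on the normalized gradient.
#' @param seedPoint Optional `c(row, col)` (0-based pixel coordinates, the
#'   package-wide convention) on or near the target vessel.
#' @param minSections Minimum number of usable cross sections (default 16).
#' @return A [VesselSegmentation-class].
#' @examples
#' sc <- retinalScenario(seed = 1, duration = 8, nRows = 32, nCols = 96)
#' seg <- segmentVessel(rowMeans(sc$movie@frames, dims = 2),
#'                      pixelPitch = pixelPitch(sc$movie))
#' @export
segmentVessel <- function(meanImage, pixelPitch, gradientThreshold = NULL,
                          seedPoint = NULL, minSections = 16L) {
  stopifnot(is.matrix(meanImage), pixelPitch > 0)
  g <- .sobel(meanImage)
  rng <- range(g)
  if (rng[2] <= rng[1])
    stop("no vessel found: flat image (zero gradient everywhere)")
  gn <- (g - rng[1]) / (rng[2] - rng[1])
  thr <- if (is.null(gradientThreshold))
    as.numeric(EBImage::otsu(EBImage::Image(gn), range = c(0, 1)))
  else (gradientThreshold - rng[1]) / (rng[2] - rng[1])
  mask <- gn > thr
  if (!any(mask)) stop("no vessel found: no gradient above threshold")
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  labm <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(labm[labm > 0])
  pick <- if (is.null(seedPoint)) which.max(sizes) else {
    idx <- which(labm > 0, arr.ind = TRUE)
    d2 <- (idx[, 1] - 1 - seedPoint[1])^2 + (idx[, 2] - 1 - seedPoint[2])^2
    labm[idx[which.min(d2), , drop = FALSE]]
  }
  # the two walls of a clean vessel can appear as two disjoint parallel
  # edge rails: adopt any comparably sized component that runs alongside
  # the picked one (>= 50 % overlap of its span along the long axis)
  edge <- labm == pick
  ptsP <- which(edge, arr.ind = TRUE)
  axP <- if (diff(range(ptsP[, 2])) >= diff(range(ptsP[, 1]))) 2L else 1L
  spanP <- range(ptsP[, axP])
  for (lbl in which(sizes >= 0.25 * sizes[pick])) {
    if (lbl == pick) next
    ptsO <- which(labm == lbl, arr.ind = TRUE)
    spanO <- range(ptsO[, axP])
    overlap <- min(spanP[2], spanO[2]) - max(spanP[1], spanO[1])
    if (overlap >= 0.5 * diff(spanP)) edge <- edge | labm == lbl
  }
  pts <- which(edge, arr.ind = TRUE) - 1  # 0-based pixel coordinates
  # scan along the longer axis of the component's bounding box
  spanRow <- diff(range(pts[, 1])); spanCol <- diff(range(pts[, 2]))
  byCol <- spanCol >= spanRow
  scanIdx <- if (byCol) pts[, 2] else pts[, 1]
  crossIdx <- if (byCol) pts[, 1] else pts[, 2]
  mids <- vapply(sort(unique(scanIdx)), function(s) {
    cc <- crossIdx[scanIdx == s]
    if (length(cc) < 2L || diff(range(cc)) < 1) return(c(NA, NA, NA))
    c(s, (min(cc) + max(cc)) / 2, diff(range(cc)))
  }, numeric(3))
  keep <- !is.na(mids[1, ])
  if (sum(keep) < minSections)
    stop(sprintf("vessel too short: %d cross sections found, need >= %d",
                 sum(keep), minSections))
  scan <- mids[1, keep]; mid <- mids[2, keep]; width <- mids[3, keep]
  ord <- order(scan)
  scan <- scan[ord]; mid <- .movingAverage(mid[ord], 5L)
  width <- width[ord]
  center <- if (byCol) cbind(row = mid, col = scan)
            else cbind(row = scan, col = mid)
  # uniform curvilinear resampling (step = one pixel pitch)
  steps <- sqrt(diff(center[, 1])^2 + diff(center[, 2])^2)
  arc <- c(0, cumsum(steps))
  su <- seq(0, arc[length(arc)], by = 1)
  rowU <- approx(arc, center[, 1], xout = su)$y
  colU <- approx(arc, center[, 2], xout = su)$y
  wU <- approx(arc, width, xout = su)$y
  new("VesselSegmentation", edgeMask = edge,
      centerline = cbind(row = rowU, col = colU),
      abscissa = su * pixelPitch, widthPx = wU,
      pixelPitch = pixelPitch)
}

#' Reduce a movie to one trace per cross section
#'
#' For every centerline point, averages the intensity along the segment
#' perpendicular to the local (smoothed) tangent, of half-length
#' `halfWidthPx` pixels, in every frame — associating one time-dependent
#' signal to each curvilinear abscissa. Averaging across the section
#' cancels contributions that are equal and opposite on the two halves of
#' the profile (axisymmetric intensity patterns), which is what makes the
#' retinal analysis blind to the symmetric mode. Sampling is bilinear via
#' one sparse matrix applied to all frames at once.
#'
#' @param movie A [VesselMovie-class].
#' @param seg A [VesselSegmentation-class] of the same movie.
#' @param halfWidthPx Cross-section half width in pixels; default half the
#'   median lumen width measured by the segmentation. `0` degenerates to
#'   the centerline pixel value itself.
#' @param detrend Remove a per-trace linear drift (default TRUE); slow
#'   acquisition drifts do not influence the wave measurements.
#' @return A [CurvilinearSignal-class].
#' @export
sampleCrossSections <- function(movie, seg, halfWidthPx = NULL,
                                detrend = TRUE) {
  stopifnot(is(movie, "VesselMovie"), is(seg, "VesselSegmentation"))
  dims <- dim(movie@frames)
  nR <- dims[1]; nC <- dims[2]; nT <- dims[3]
  cl <- seg@centerline
  n <- nrow(cl)
  if (is.null(halfWidthPx))
    halfWidthPx <- max(1, round(median(seg@widthPx, na.rm = TRUE) / 2))
  # tangents by centered differences on the (already smoothed) centerline
  tr <- c(cl[2, 1] - cl[1, 1], diff(cl[, 1], lag = 2) / 2,
          cl[n, 1] - cl[n - 1, 1])
  tc <- c(cl[2, 2] - cl[1, 2], diff(cl[, 2], lag = 2) / 2,
          cl[n, 2] - cl[n - 1, 2])
  nrm <- sqrt(tr^2 + tc^2)
  # unit normal = tangent rotated by 90 degrees
  nr <- -tc / nrm; nc <- tr / nrm
  off <- if (halfWidthPx > 0) seq(-halfWidthPx, halfWidthPx, by = 1) else 0
  m <- length(off)
  rows <- rep(cl[, 1], each = m) + rep(nr, each = m) * off
  cols <- rep(cl[, 2], each = m) + rep(nc, each = m) * off
  if (any(rows < 0) || any(rows > nR - 1) || any(cols < 0) ||
      any(cols > nC - 1))
    stop("cross section leaves the frame; reduce 'halfWidthPx'")
  # bilinear weights on the 4 neighbours (0-based pixel coords)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  r1 <- pmin(r0 + 1, nR - 1); c1 <- pmin(c0 + 1, nC - 1)
  pix <- function(r, c) r + nR * c + 1  # column-major linear index
  i <- rep(rep(seq_len(n), each = m), 4L)
  j <- c(pix(r0, c0), pix(r1, c0), pix(r0, c1), pix(r1, c1))
  wts <- c((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc) / m
  W <- Matrix::sparseMatrix(i = i, j = j, x = wts, dims = c(n, nR * nC))
  phi <- as.matrix(W %*% matrix(movie@frames, nrow = nR * nC, ncol = nT))
  if (detrend) {
    tt <- seq_len(nT)
    phi <- t(apply(phi, 1, function(y) stats::residuals(lm(y ~ tt)) + mean(y)))
  }
  CurvilinearSignal(x = seg@abscissa,
                    t = seq(0, by = 1 / movie@frameRate, length.out = nT),
                    phi = phi)
}
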