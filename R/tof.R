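## Correlation-based time-of-flight: for each spatial separation dx, the
## normalized time-domain cross-correlation between traces at x0 and
## x0 + dx, averaged over every source position x0. A traveling wave
## shows up as a ridge along dt = dx / v whose slope is the velocity.

#' Time-of-flight correlation map
#'
#' Computes `ToF(dx, dt) = < phi(x0, t) (x)_dt phi(x0 + dx, t) >_{x0}`
#' where `(x)_dt` is time correlation: each trace pair is made zero-mean
#' and unit-energy (so bright segments do not dominate), cross-correlated
#' by FFT, and the result averaged over all valid pairs at that
#' separation. The map is extended to negative `dx` by the symmetry
#' `ToF(-dx, dt) = ToF(dx, -dt)`.
#'
#' @param sig A [CurvilinearSignal-class].
#' @param maxDx Largest spatial lag (m); default half the aperture.
#' @param maxDt Largest time lag (s); default half the dominant period of
#'   the signal (from [centralFrequency()]), so the ridge of a periodic
#'   wave field cannot wrap onto the next cycle, capped at a quarter of
#'   the record.
#' @return A [ToFMap-class].
#' @examples
#' sc <- carotidScenario(seed = 1, snr = Inf)
#' mf <- separateModes(sc$walls)
#' tm <- tofMap(CurvilinearSignal(sc$walls@x, sc$walls@t, mf@symmetric))
#' @export
tofMap <- function(sig, maxDx = NULL, maxDt = NULL) {
  stopifnot(is(sig, "CurvilinearSignal"))
  dx <- sig@x[2] - sig@x[1]
  dt <- sig@t[2] - sig@t[1]
  nX <- length(sig@x); nT <- length(sig@t)
  if (is.null(maxDx)) maxDx <- (sig@x[nX] - sig@x[1]) / 2
  if (is.null(maxDt)) {
    rec <- (sig@t[nT] - sig@t[1]) / 4
    maxDt <- tryCatch(min(rec, 0.5 / centralFrequency(sig)),
                      error = function(e) rec)
  }
  nDx <- min(nX - 1L, floor(maxDx / dx))
  nDt <- min(nT - 1L, floor(maxDt / dt))
  if (nDx < 1L || nDt < 1L) stop("lags exceed the record")
  ph <- sweep(sig@phi, 1, rowMeans(sig@phi))
  en <- sqrt(rowSums(ph^2))
  if (any(en == 0)) stop("dead trace (zero energy): cannot normalize")
  ph <- ph / en
  nPad <- 2L * nextn(nT, 2)
  F <- t(apply(cbind(ph, matrix(0, nX, nPad - nT)), 1, fft))
  lagIdx <- c(nPad - (nDt:1) + 1L, 1:(nDt + 1L))  # dt = -nDt..nDt
  half <- matrix(0, nDx + 1L, 2L * nDt + 1L)
  for (j in 0:nDx) {
    s <- seq_len(nX - j)
    cc <- Re(fft(colMeans(Conj(F[s, , drop = FALSE]) *
                          F[s + j, , drop = FALSE]), inverse = TRUE)) / nPad
    half[j + 1L, ] <- cc[lagIdx]
  }
  # full map: ToF(-dx, dt) = ToF(dx, -dt)
  full <- rbind(half[(nDx + 1L):2, ncol(half):1, drop = FALSE], half)
  new("ToFMap", dx = (-nDx:nDx) * dx, dt = (-nDt:nDt) * dt, value = full)
}

#' Velocity from a time-of-flight map
#'
#' Extracts the traveling-wave ridge of a ToF map: for every time lag the
#' spatial lag of maximum correlation (3-point parabolic interpolation),
#' keeping lags whose peak correlation clears `corThreshold` and is not
#' stuck at the aperture edge; then a weighted least-squares line through
#' the origin (a wave passes dx = 0 at dt = 0 by construction), robustly
#' reweighted (bisquare) against ridge outliers. The slope is the
#' velocity; its uncertainty comes from the weighted fit residuals. For a
#' dispersive field the value is a band-average velocity.
#'
#' @param map A [ToFMap-class].
#' @param corThreshold Minimum peak correlation to accept a ridge point
#'   (default 0.25).
#' @param minLags Minimum number of accepted ridge points (default 4).
#' @return Named numeric: `v` (m/s) and `sigma`.
#' @export
tofVelocity <- function(map, corThreshold = 0.25, minLags = 4L) {
  stopifnot(is(map, "ToFMap"))
  dts <- map@dt[map@dt != 0]
  pk <- lapply(dts, function(d) {
    j <- which(map@dt == d)
    col <- map@value[, j]
    i <- which.max(col)
    if (col[i] < corThreshold) return(NULL)
    if (i == 1L || i == length(col)) return(NULL)  # stuck at aperture edge
    y1 <- col[i - 1]; y2 <- col[i]; y3 <- col[i + 1]
    den <- y1 - 2 * y2 + y3
    shift <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
    ddx <- map@dx[2] - map@dx[1]
    c(dt = d, dx = map@dx[i] + shift * ddx, w = y2)
  })
  pk <- do.call(rbind, pk)
  if (is.null(pk) || nrow(pk) < minLags)
    stop("no detectable ridge: too few time lags with correlation above threshold")
  w <- pk[, "w"]
  v <- sum(w * pk[, "dx"] * pk[, "dt"]) / sum(w * pk[, "dt"]^2)
  for (it in 1:5) {  # bisquare reweighting against outliers at large lags
    e <- pk[, "dx"] - v * pk[, "dt"]
    s <- 6 * median(abs(e)) + .Machine$double.eps
    wb <- w * ifelse(abs(e) < s, (1 - (e / s)^2)^2, 0)
    if (sum(wb * pk[, "dt"]^2) == 0) break
    v <- sum(wb * pk[, "dx"] * pk[, "dt"]) / sum(wb * pk[, "dt"]^2)
    w <- wb
  }
  e <- pk[, "dx"] - v * pk[, "dt"]
  n <- sum(w > 0)
  sigma <- if (n > 1) sqrt(sum(w * e^2) / ((n - 1) * sum(w * pk[, "dt"]^2)))
           else NA_real_
  c(v = v, sigma = sigma)
}

#' Directional filter for traveling waves
#'
#' Separates right- from left-going waves by a 2-D Fourier transform of
#' the position x time matrix: the two quadrants of the
#' (spatial frequency, temporal frequency) plane whose sign combination
#' corresponds to the rejected propagation direction are zeroed, the
#' axes (shared DC/zero-frequency bins) are kept, and the real part of
#' the inverse transform is returned. Used before time-of-flight
#' estimation to suppress reflected waves.
#'
#' @param sig A [CurvilinearSignal-class] with at least 8 positions and 8
#'   samples.
#' @param direction `+1` to keep waves traveling toward increasing x,
#'   `-1` for the opposite.
#' @return A filtered [CurvilinearSignal-class].
#' @export
directionalFilter <- function(sig, direction = 1) {
  stopifnot(is(sig, "CurvilinearSignal"), direction %in% c(-1, 1))
  nX <- length(sig@x); nT <- length(sig@t)
  if (nX < 8L || nT < 8L) stop("need at least 8 positions and 8 samples")
  S <- fft(sig@phi)
  kx <- c(0:(floor(nX / 2)), -((nX - floor(nX / 2) - 1L):1)) / nX
  ft <- c(0:(floor(nT / 2)), -((nT - floor(nT / 2) - 1L):1)) / nT
  # a wave cos(2 pi f t - k x) travelling toward +x carries its energy on
  # bins with opposite signs of spatial and temporal frequency
  sgn <- outer(sign(kx), sign(ft))
  keep <- sgn == 0 | sgn == -direction
  S[!keep] <- 0
  CurvilinearSignal(sig@x, sig@t, Re(fft(S, inverse = TRUE)) / (nX * nT))
}
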