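## Guided-wave dispersion theory for a traction-free hollow elastic
## cylinder: the characteristic determinant of the boundary-condition
## matrix, Muller root polishing, numeric dispersion curves for the
## L(0,1) and F(1,1) modes, their low-frequency closed forms, and the
## Moens-Korteweg relation.

## Bessel basis helper: value and radial derivative of B_nu(q * r) for the
## family solving f'' + f'/r + (s * q^2 - nu^2/r^2) f = 0 with s = +1
## (oscillatory: J/Y) or s = -1 (evanescent: I/K). Derivatives use the
## upward recurrences, avoiding negative orders:
##   J_nu' = nu/x J_nu - J_{nu+1};  Y alike
##   I_nu' = nu/x I_nu + I_{nu+1};  K_nu' = nu/x K_nu - K_{nu+1}
.besselBasis <- function(nu, q, r, oscillatory) {
  x <- q * r
  if (oscillatory) {
    z1 <- besselJ(x, nu); z2 <- besselY(x, nu)
    d1 <- q * (nu / x * z1 - besselJ(x, nu + 1))
    d2 <- q * (nu / x * z2 - besselY(x, nu + 1))
  } else {
    z1 <- besselI(x, nu); z2 <- besselK(x, nu)
    d1 <- q * (nu / x * z1 + besselI(x, nu + 1))
    d2 <- q * (nu / x * z2 - besselK(x, nu + 1))
  }
  list(v1 = z1, v2 = z2, d1 = d1, d2 = d2)
}

## Stress rows (divided by the shear modulus mu) acting on the radial
## function slots (f, f', g1, g1', g3, g3') at radius r. Derived from the
## Helmholtz-potential solution with the gauge H_r = -H_theta; f solves the
## Bessel equation with alpha2, g1 (order n+1) and g3 (order n) with beta2.
.stressCoef <- function(r, n, k, w, a2, b2, lamOverMu, cL) {
  list(
    srr = c(f = -lamOverMu * (w / cL)^2 - 2 * a2 + 2 * n^2 / r^2,
            fp = -2 / r, g1 = 0, g1p = 2 * k,
            g3 = -2 * n / r^2, g3p = 2 * n / r),
    srt = c(f = 2 * n / r^2, fp = -2 * n / r,
            g1 = -k * (n + 1) / r, g1p = k,
            g3 = b2 - 2 * n^2 / r^2, g3p = 2 / r),
    srz = c(f = 0, fp = -2 * k,
            g1 = (b2 - k^2) - n * (n + 1) / r^2, g1p = -n / r,
            g3 = -k * n / r, g3p = 0))
}

.modeOrder <- function(mode) {
  switch(mode, "L(0,1)" = 0L, "F(1,1)" = 1L,
         stop("mode must be \"L(0,1)\" or \"F(1,1)\""))
}

#' Characteristic determinant of the Gazis frequency equation
#'
#' Assembles the traction-free boundary-condition matrix of a hollow
#' elastic cylinder (inner radius `(d - 2h)/2`, outer radius `d/2`) for the
#' longitudinal `L(0,1)` (circumferential order n = 0) or flexural `F(1,1)`
#' (n = 1) mode at frequency `f` and trial phase velocity `vTrial`, and
#' returns its determinant. Zeros in `vTrial` at fixed `f` are points of
#' the mode's dispersion curve.
#'
#' The radial potentials are Bessel functions of first and second kind
#' (`J`/`Y` where the radial wavenumber squared is positive, modified
#' `I`/`K` where it is negative, as is the case for slow waves with phase
#' velocity far below the bulk velocities). Each matrix column is
#' normalized to unit maximum magnitude before the determinant so that the
#' huge dynamic range between compression and shear terms
#' (`cL/cT ~ 4000` at vessel parameters) does not overflow; root
#' locations are unchanged by column scaling.
#'
#' @param mode `"L(0,1)"` or `"F(1,1)"`.
#' @param f Frequency (Hz), > 0.
#' @param vTrial Trial phase velocity (m/s), > 0. Vectorized.
#' @param geom A [TubeGeometry-class].
#' @return Numeric vector of (column-normalized) determinant values; NA
#'   where the trial velocity coincides with a bulk velocity (degenerate
#'   radial wavenumber).
#' @examples
#' g <- retinalGeometry()
#' characteristicDet("F(1,1)", f = 10, vTrial = c(0.02, 0.03), geom = g)
#' @export
characteristicDet <- function(mode, f, vTrial, geom) {
  stopifnot(is(geom, "TubeGeometry"), f > 0, all(vTrial > 0))
  n <- .modeOrder(mode)
  a <- geom@d / 2
  b <- a - geom@h
  w <- 2 * pi * f
  lamOverMu <- (geom@cL^2 - 2 * geom@cT^2) / geom@cT^2
  vapply(vTrial, function(v) {
    k <- w / v
    a2 <- (w / geom@cL)^2 - k^2
    b2 <- (w / geom@cT)^2 - k^2
    if (abs(a2) < 1e-20 || abs(b2) < 1e-20) return(NA_real_)
    qa <- sqrt(abs(a2)); qb <- sqrt(abs(b2))
    oscA <- a2 > 0; oscB <- b2 > 0
    rows <- if (n == 0L) c("srr", "srz") else c("srr", "srt", "srz")
    M <- matrix(0, nrow = 2L * length(rows),
                ncol = if (n == 0L) 4L else 6L)
    for (ir in 1:2) {
      r <- c(a, b)[ir]
      bf <- .besselBasis(n, qa, r, oscA)        # compression potential
      bg1 <- .besselBasis(n + 1L, qb, r, oscB)  # coupled shear potential
      cf <- .stressCoef(r, n, k, w, a2, b2, lamOverMu, geom@cL)
      if (n > 0L) bg3 <- .besselBasis(n, qb, r, oscB)
      for (is in seq_along(rows)) {
        cc <- cf[[rows[is]]]
        row <- (ir - 1L) * length(rows) + is
        M[row, 1] <- cc["f"] * bf$v1 + cc["fp"] * bf$d1
        M[row, 2] <- cc["f"] * bf$v2 + cc["fp"] * bf$d2
        M[row, 3] <- cc["g1"] * bg1$v1 + cc["g1p"] * bg1$d1
        M[row, 4] <- cc["g1"] * bg1$v2 + cc["g1p"] * bg1$d2
        if (n > 0L) {
          M[row, 5] <- cc["g3"] * bg3$v1 + cc["g3p"] * bg3$d1
          M[row, 6] <- cc["g3"] * bg3$v2 + cc["g3p"] * bg3$d2
        }
      }
    }
    if (!all(is.finite(M)))
      stop("non-finite Bessel evaluation in characteristic matrix; ",
           "parameters out of numerical range")
    sc <- apply(abs(M), 2, max)
    if (any(sc == 0)) return(0)
    det(sweep(M, 2, sc, "/"))
  }, numeric(1))
}

#' Muller's method root finder
#'
#' Classical three-point quadratic-interpolation iteration for a root of a
#' scalar function, as used to polish roots of the guided-wave
#' characteristic equation. Converges when the step falls below
#' `tol * |x|` or `|fn(x)|` falls below `fnTol`. A degenerate (collinear)
#' parabola falls back to a secant step.
#'
#' @param fn Function of one numeric argument.
#' @param x0,x1,x2 Three distinct starting points.
#' @param tol Relative step tolerance (default 1e-12).
#' @param fnTol Absolute tolerance on `|fn|` (default 0: step criterion
#'   only).
#' @param maxIter Maximum iterations.
#' @return List with `root`, `fval`, `iter`, `converged`.
#' @examples
#' mullerRoot(function(x) x^2 - 4, 1, 2.5, 3)$root
#' @export
mullerRoot <- function(fn, x0, x1, x2, tol = 1e-12, fnTol = 0,
                       maxIter = 100L) {
  xs <- c(x0, x1, x2)
  if (anyDuplicated(xs)) stop("starting points must be distinct")
  fs <- vapply(xs, fn, numeric(1))
  for (it in seq_len(maxIter)) {
    h1 <- xs[2] - xs[1]; h2 <- xs[3] - xs[2]
    d1 <- (fs[2] - fs[1]) / h1; d2 <- (fs[3] - fs[2]) / h2
    aa <- (d2 - d1) / (h1 + h2)
    bb <- aa * h2 + d2
    disc <- bb^2 - 4 * fs[3] * aa
    step <- if (!is.finite(disc) || disc < 0 && abs(aa) < 1e-300) NA else {
      den <- if (disc >= 0) {
        s <- sqrt(disc)
        if (abs(bb + s) > abs(bb - s)) bb + s else bb - s
      } else bb  # complex pair: damp to the real axis via the linear term
      -2 * fs[3] / den
    }
    if (!is.finite(step) || abs(aa) < .Machine$double.xmin) {
      # secant fallback
      if (d2 == 0) return(list(root = xs[3], fval = fs[3], iter = it,
                               converged = abs(fs[3]) <= fnTol))
      step <- -fs[3] / d2
    }
    xn <- xs[3] + step
    fnew <- fn(xn)
    xs <- c(xs[2], xs[3], xn); fs <- c(fs[2], fs[3], fnew)
    if (abs(step) <= tol * max(abs(xn), .Machine$double.xmin) ||
        (fnTol > 0 && abs(fnew) <= fnTol))
      return(list(root = xn, fval = fnew, iter = it, converged = TRUE))
  }
  list(root = xs[3], fval = fs[3], iter = maxIter, converged = FALSE)
}

#' Low-frequency closed forms for the guided tube modes
#'
#' `vFpwLowfreq()` is the low-frequency approximation of the flexural
#' F(1,1) phase velocity, `sqrt(pi * f * d * cT / sqrt(3))`: it vanishes at
#' f = 0 and grows as the square root of the frequency-diameter product.
#' `vLpwLowfreq()` is the low-frequency longitudinal L(0,1) plateau,
#' `sqrt(3) * cT`, independent of the tube geometry.
#'
#' @param f Frequency (Hz), >= 0; vectorized.
#' @param geom A [TubeGeometry-class].
#' @return Phase velocity (m/s).
#' @examples
#' g <- retinalGeometry()
#' vFpwLowfreq(10, g) # ~0.025 m/s
#' vLpwLowfreq(g)     # ~0.61 m/s
#' @export
vFpwLowfreq <- function(f, geom) {
  stopifnot(is(geom, "TubeGeometry"), all(f >= 0))
  sqrt(pi * f * geom@d * geom@cT / sqrt(3))
}

#' @rdname vFpwLowfreq
#' @export
vLpwLowfreq <- function(geom) {
  stopifnot(is(geom, "TubeGeometry"))
  sqrt(3) * geom@cT
}

#' @details `vFpwBeam()` is the exact low-frequency limit of the F(1,1)
#' mode: the Euler-Bernoulli flexural wave of a beam with the annular
#' cross section of the tube, `v = sqrt(omega * cbar * rg)` where
#' `cbar = sqrt(3) * cT` is the bar velocity (incompressible wall) and
#' `rg = sqrt((a^2 + b^2)) / 2` the radius of gyration of the annulus
#' (outer radius `a`, inner radius `b`). The numerical Gazis solution
#' converges to this limit as f -> 0. The simpler closed form
#' `vFpwLowfreq()` shares the `sqrt(f * d)` scaling but uses a cruder
#' prefactor; see the package vignette for the distinction.
#' @rdname vFpwLowfreq
#' @export
vFpwBeam <- function(f, geom) {
  stopifnot(is(geom, "TubeGeometry"), all(f >= 0))
  a <- geom@d / 2
  b <- a - geom@h
  rg <- sqrt(a^2 + b^2) / 2
  sqrt(2 * pi * f * sqrt(3) * geom@cT * rg)
}

#' Numerical dispersion curve from the Gazis characteristic equation
#'
#' Traces the phase-velocity dispersion curve of mode `L(0,1)` or `F(1,1)`
#' over an ascending frequency grid. At the lowest frequency the root
#' search is seeded from the low-frequency closed form; at each subsequent
#' frequency it continues from the previous root (branch tracking, which
#' selects the first branch and rejects higher ones). The root is located
#' by sign-change bracketing of the characteristic determinant over a
#' velocity scan of +/- 50 % around the seed (clipped away from the bulk
#' shear velocity, where the radial wavenumber degenerates), then polished
#' with [mullerRoot()].
#'
#' @param mode `"L(0,1)"` or `"F(1,1)"`.
#' @param geom A [TubeGeometry-class].
#' @param fGrid Ascending positive frequencies (Hz).
#' @param nScan Points in the bracketing scan (default 81).
#' @param tol Relative tolerance passed to [mullerRoot()].
#' @return A [TheoryCurve-class]; points where the branch was lost carry
#'   `NA` velocity and `converged = FALSE`.
#' @examples
#' g <- retinalGeometry()
#' crv <- dispersionNumeric("F(1,1)", g, fGrid = seq(1, 10, by = 1))
#' crv
#' @export
dispersionNumeric <- function(mode, geom, fGrid, nScan = 81L, tol = 1e-10) {
  stopifnot(is(geom, "TubeGeometry"), length(fGrid) >= 1L, all(fGrid > 0),
            !is.unsorted(fGrid, strictly = TRUE))
  n <- length(fGrid)
  v <- rep(NA_real_, n); conv <- logical(n); res <- rep(NA_real_, n)
  asym <- function(f) if (mode == "L(0,1)") vLpwLowfreq(geom)
                      else vFpwBeam(f, geom)
  seed <- NA_real_; fPrev <- NA_real_
  for (i in seq_len(n)) {
    f <- fGrid[i]
    # continuation guess, rescaled by the low-frequency law so coarse
    # frequency grids do not outrun the +/- 50 % bracketing window
    guess <- if (is.na(seed)) asym(f) else seed * asym(f) / asym(fPrev)
    lo <- 0.5 * guess; hi <- 1.5 * guess
    # keep the scan on one side of the bulk shear velocity
    if (guess < geom@cT) hi <- min(hi, 0.995 * geom@cT)
    if (guess > geom@cT) lo <- max(lo, 1.005 * geom@cT)
    vs <- seq(lo, hi, length.out = nScan)
    dets <- suppressWarnings(
      tryCatch(characteristicDet(mode, f, vs, geom),
               error = function(e) rep(NA_real_, nScan)))
    ok <- which(is.finite(dets))
    sc <- ok[which(diff(sign(dets[ok])) != 0)]
    if (!length(sc)) next  # lost branch at this frequency
    # bracket closest to the continuation guess
    j <- sc[which.min(abs(vs[sc] - guess))]
    jn <- ok[which(ok > j)][1]
    vLo <- vs[j]; vHi <- vs[jn]
    fn <- function(x) characteristicDet(mode, f, x, geom)
    ans <- mullerRoot(fn, vLo, (vLo + vHi) / 2, vHi, tol = tol)
    root <- ans$root
    if (!is.finite(root) || root < vLo - (vHi - vLo) ||
        root > vHi + (vHi - vLo)) {
      # Muller wandered: fall back to bisection refinement
      root <- uniroot(fn, c(vLo, vHi), tol = tol * guess)$root
      ans <- list(fval = fn(root), converged = TRUE)
    }
    v[i] <- root; conv[i] <- ans$converged; res[i] <- abs(ans$fval)
    seed <- root; fPrev <- f
  }
  new("TheoryCurve", f = as.numeric(fGrid), v = v, converged = conv,
      residual = res, mode = mode)
}

#' Moens-Korteweg relation and its inverse
#'
#' Forward map from tube geometry and wall shear velocity to the classical
#' symmetric pulse wave velocity, `PWV = cT * sqrt(3 h / d)`, and its
#' inverse solving for the bulk shear wave velocity given a measured PWV.
#' The two are exact inverses of one another.
#'
#' @param geom A [TubeGeometry-class].
#' @return `moensKorteweg()`: PWV (m/s).
#' @examples
#' g <- retinalGeometry()
#' pwv <- moensKorteweg(g)
#' invertMoensKorteweg(pwv, g@h, g@d) # recovers g@cT
#' @export
moensKorteweg <- function(geom) {
  stopifnot(is(geom, "TubeGeometry"))
  geom@cT * sqrt(3 * geom@h / geom@d)
}

#' @rdname moensKorteweg
#' @param pwv Measured pulse wave velocity (m/s), > 0.
#' @param h Wall thickness (m), > 0.
#' @param d Outer diameter (m), > 2h.
#' @return `invertMoensKorteweg()`: bulk shear wave velocity cT (m/s).
#' @export
invertMoensKorteweg <- function(pwv, h, d) {
  stopifnot(pwv > 0, h > 0, d > 2 * h)
  pwv / sqrt(3 * h / d)
}

#' Shear modulus from density and shear wave velocity
#'
#' The elastography relation `mu = rho * cT^2`.
#'
#' @param rho Density (kg/m^3), > 0.
#' @param cT Bulk shear wave velocity (m/s), >= 0.
#' @return Shear modulus (Pa).
#' @examples
#' shearModulus(1000, 0.35) # 122.5 Pa
#' @export
shearModulus <- function(rho, cT) {
  stopifnot(all(rho > 0), all(cT >= 0))
  rho * cT^2
}
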