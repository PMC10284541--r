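## Symmetric / antisymmetric mode separation from two-wall displacement
## records. Along the imaging beam, radial expansion (the symmetric
## L(0,1)-type pulse wave) moves the two walls in opposite directions
## while flexion (the antisymmetric F(1,1)-type wave) moves them
## together, so half-sum and half-difference isolate the modes exactly.

#' Separate symmetric and antisymmetric wall motion
#'
#' The exact linear map `antisymmetric = (uTop + uBottom) / 2`,
#' `symmetric = (uTop - uBottom) / 2` — no filtering involved. The factor
#' 1/2 makes the outputs per-mode displacement amplitudes, and makes the
#' map the exact inverse of [renderWalls()] at zero noise.
#'
#' @param walls A [WallDisplacements-class].
#' @return A [ModeFields-class].
#' @examples
#' sc <- carotidScenario(seed = 1, snr = Inf)
#' mf <- separateModes(sc$walls)
#' @export
separateModes <- function(walls) {
  stopifnot(is(walls, "WallDisplacements"))
  new("ModeFields",
      antisymmetric = (walls@uTop + walls@uBottom) / 2,
      symmetric = (walls@uTop - walls@uBottom) / 2,
      convention = "half-sum/half-difference, beam-axial displacements")
}

#' Classify a displacement snapshot
#'
#' Compares the spatial L2 norms of the symmetric and antisymmetric
#' fields at one instant: the deformation is labelled
#' `"symmetric-dominant"` or `"antisymmetric-dominant"` when one norm
#' exceeds the other by more than `ratio`, `"mixed"` otherwise. During
#' the heartbeat the overpressure source is axisymmetric, so systolic
#' frames are typically symmetric-dominant while the flexural wave
#' surfaces between beats.
#'
#' @param walls A [WallDisplacements-class].
#' @param t Time (s) of the snapshot; snapped to the nearest sample.
#' @param ratio Dominance ratio threshold (default 2).
#' @return Character label.
#' @export
classifySnapshot <- function(walls, t, ratio = 2) {
  stopifnot(is(walls, "WallDisplacements"))
  if (t < min(walls@t) - 1e-12 || t > max(walls@t) + 1e-12)
    stop("snapshot time outside the record")
  j <- which.min(abs(walls@t - t))
  mf <- separateModes(walls)
  nS <- sqrt(sum(mf@symmetric[, j]^2))
  nA <- sqrt(sum(mf@antisymmetric[, j]^2))
  if (nS > ratio * nA) "symmetric-dominant"
  else if (nA > ratio * nS) "antisymmetric-dominant"
  else "mixed"
}
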