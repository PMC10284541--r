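# Guided-wave theory: Muller iteration, characteristic determinant,
# numeric dispersion, closed forms, Moens-Korteweg, shear modulus.

gRef <- retinalGeometry(100e-6)
g60 <- retinalGeometry(60e-6)

test_that("Muller's method finds simple roots fast", {
  r <- mullerRoot(function(x) x^2 - 4, 1, 2.5, 3)
  expect_lt(abs(r$root - 2), 1e-10)
  expect_true(r$converged)

  # cubic with a complex pair: the real root is found from real starts
  fn <- function(x) x^3 - 2 * x^2 + 4 * x - 8   # roots 2, +-2i
  r2 <- mullerRoot(fn, 1, 1.5, 3)
  oracle <- uniroot(fn, c(1, 3), tol = 1e-14)$root
  expect_lt(abs(r2$root - oracle), 1e-8)

  r3 <- mullerRoot(function(x) sin(x), 2.5, 3.5, 3.0)
  expect_lt(abs(r3$root - pi), 1e-10)
  expect_lte(r3$iter, 10L)

  expect_error(mullerRoot(function(x) x, 1, 1, 2), "distinct")
})

test_that("the characteristic determinant vanishes at dispersion roots", {
  for (mode in c("L(0,1)", "F(1,1)")) {
    crv <- dispersionNumeric(mode, gRef, fGrid = c(2, 5))
    expect_true(all(crv@converged))
    for (i in seq_along(crv@f)) {
      d0 <- abs(characteristicDet(mode, crv@f[i], crv@v[i], gRef))
      dOff <- abs(characteristicDet(mode, crv@f[i],
                                    crv@v[i] * c(0.9, 1.1), gRef))
      expect_lt(d0, 1e-4 * min(dOff))
    }
  }
})

test_that("determinants are finite, real, and sign-bracket the root", {
  vs <- seq(0.015, 0.045, length.out = 21)
  dets <- characteristicDet("F(1,1)", 10, vs, gRef)
  expect_true(all(is.finite(dets)))
  expect_true(any(diff(sign(dets)) != 0))
})

test_that("root locations are stable under scan refinement", {
  a <- dispersionNumeric("F(1,1)", gRef, fGrid = c(1, 5, 10), nScan = 41L)
  b <- dispersionNumeric("F(1,1)", gRef, fGrid = c(1, 5, 10), nScan = 161L)
  expect_true(all(abs(a@v / b@v - 1) < 1e-3))
})

test_that("numeric curves converge to the low-frequency limits", {
  fr <- dispersionNumeric("F(1,1)", gRef, fGrid = c(0.1, 0.4))
  expect_true(all(abs(fr@v / vFpwBeam(fr@f, gRef) - 1) < 0.05))
  # the approach to the limit tightens as f drops
  expect_lt(abs(fr@v[1] / vFpwBeam(fr@f[1], gRef) - 1),
            abs(fr@v[2] / vFpwBeam(fr@f[2], gRef) - 1) + 1e-9)

  lr <- dispersionNumeric("L(0,1)", gRef, fGrid = c(0.5, 1))
  expect_true(all(abs(lr@v / vLpwLowfreq(gRef) - 1) < 0.01))
})

test_that("F(1,1) rises with frequency while L(0,1) stays flat", {
  fGrid <- seq(1, 10, by = 1)
  fc <- dispersionNumeric("F(1,1)", gRef, fGrid)
  lc <- dispersionNumeric("L(0,1)", gRef, fGrid)
  expect_true(all(fc@converged) && all(lc@converged))
  expect_true(all(diff(fc@v) > 0))
  expect_lt(diff(range(lc@v)) / mean(lc@v), 0.01)
  expect_true(all(fc@v < lc@v))  # flexural wave is much slower
})

test_that("closed forms obey their scaling laws", {
  expect_identical(vFpwLowfreq(0, gRef), 0)
  expect_rel_equal(vFpwLowfreq(20, gRef), sqrt(2) * vFpwLowfreq(10, gRef),
                   1e-12)
  expect_rel_equal(vFpwLowfreq(5, gRef) / vFpwLowfreq(5, g60),
                   sqrt(100 / 60), 1e-12)
  expect_rel_equal(vLpwLowfreq(gRef), sqrt(3) * 0.35, 1e-12)
})

test_that("Moens-Korteweg inverts exactly and matches its unit case", {
  g <- TubeGeometry(d = 9e-5, h = 3e-5, cT = 0.35)  # 3h/d = 1
  expect_equal(moensKorteweg(g), g@cT, tolerance = 1e-15)
  pwv <- moensKorteweg(gRef)
  expect_equal(invertMoensKorteweg(pwv, gRef@h, gRef@d), gRef@cT,
               tolerance = 1e-15)
  expect_error(invertMoensKorteweg(-1, 1e-5, 1e-4))
})

test_that("inverting a 620 mm/s pulse wave brackets 0.8 m/s shear", {
  cts <- vapply(c(60e-6, 100e-6),
                function(d) invertMoensKorteweg(0.62, 15e-6, d),
                numeric(1))
  expect_gt(min(cts), 0.7); expect_lt(max(cts), 0.95)
  expect_gt(0.8, min(cts)); expect_lt(0.8, max(cts))
})

test_that("shear modulus follows mu = rho cT^2", {
  expect_identical(shearModulus(1000, 1), 1000)
  expect_equal(shearModulus(1000, 0.35), 122.5)
  expect_identical(shearModulus(1000, 0), 0)
})
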