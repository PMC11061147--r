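# BMO ellipse fitting and LC/BMO offset metrics.

circleScene <- function(r = 1, n = 8, crvt = NULL, fovea = c(-10, 0), ...) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  bmoScene(cbind(r * cos(th), r * sin(th)), fovea = fovea, crvt = crvt, ...)
}

test_that("direct ellipse fit recovers circles and rotated ellipses", {
  th <- seq(0, 2 * pi, length.out = 9)[-1]
  f <- fitBMOEllipse(cbind(cos(th), sin(th)))
  expect_equal(f$center, c(0, 0), tolerance = 1e-9)
  expect_equal(f$semiAxes, c(1, 1), tolerance = 1e-9)
  rot <- 30 * pi / 180
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  P <- t(R %*% rbind(2 * cos(th), sin(th))) + rep(c(3, -1), each = 8)
  f2 <- fitBMOEllipse(P)
  expect_equal(f2$center, c(3, -1), tolerance = 1e-6)
  expect_equal(f2$semiAxes, c(2, 1), tolerance = 1e-6)
  expect_equal(f2$tilt, 30, tolerance = 1e-6)
  expect_error(fitBMOEllipse(cbind(cos(th[1:4]), sin(th[1:4]))), "5")
  expect_error(fitBMOEllipse(cbind(1:8, 2 * (1:8))), "collinear")
})

test_that("offset metrics follow the worked examples", {
  # circular BMO, CRVT displaced nasally (toward +x): index 0.5, angle 0
  off <- computeOffset(circleScene(crvt = c(0.5, 0)))
  expect_equal(offsetIndex(off), 0.5, tolerance = 1e-9)
  expect_equal(offsetAngle(off), 0, tolerance = 1e-9)
  # axis-aligned ellipse (2,1), CRVT superior: b = 1 -> index 0.5, angle +90
  th <- seq(0, 2 * pi, length.out = 13)[-1]
  sc <- bmoScene(cbind(2 * cos(th), sin(th)), fovea = c(-10, 0),
                 crvt = c(0, 0.5))
  off2 <- computeOffset(sc)
  expect_equal(offsetIndex(off2), 0.5, tolerance = 1e-6)
  expect_equal(offsetAngle(off2), 90, tolerance = 1e-6)
  # CRVT at the center: index 0, angle undefined
  off3 <- computeOffset(circleScene(crvt = c(0, 0)))
  expect_equal(offsetIndex(off3), 0)
  expect_true(is.na(offsetAngle(off3)))
  # visible CRVT outside the margin: clipped to 1 with a warning
  expect_warning(off4 <- computeOffset(circleScene(crvt = c(1.5, 0))),
                 "clipped")
  expect_equal(offsetIndex(off4), 1)
  expect_true(off4@clipped)
})

test_that("the invisible-CRVT rule is exact", {
  sc <- circleScene(crvtVisible = FALSE, eobMeridian = -90)
  off <- handleInvisibleCRVT(sc)
  expect_identical(offsetIndex(off), 1.0)
  expect_equal(offsetAngle(off), 90)
  expect_equal(offsetAngle(handleInvisibleCRVT(
    circleScene(crvtVisible = FALSE, eobMeridian = 0))), 180)
  expect_error(handleInvisibleCRVT(circleScene(crvtVisible = FALSE)),
               "excluded")
})

test_that("PPA angle uses the temporal reference, positive superior", {
  # ppa point directly temporal (-x from center, fovea side)
  off <- computeOffset(circleScene(crvt = c(0.2, 0), ppaPoint = c(-1.2, 0)))
  expect_equal(off@ppaAngle, 0, tolerance = 1e-9)
  off2 <- computeOffset(circleScene(crvt = c(0.2, 0), ppaPoint = c(0, 1.2)))
  expect_equal(off2@ppaAngle, 90, tolerance = 1e-9)
  ms <- makeScene(sceneSpec(ppaMeridian = -30))
  expect_equal(computePPAAngle(ms$scene), -30, tolerance = 1e-6)
})

test_that("offset metrics are scale-invariant and mirror-consistent", {
  base <- sceneSpec(trueOffsetAngle = -37, trueOffsetIndex = 0.7,
                    ppaMeridian = 25)
  off <- computeOffset(makeScene(base)$scene)
  # scale all coordinates
  sc <- makeScene(base)$scene
  sc@marginPoints <- sc@marginPoints * 3.7
  sc@crvt <- sc@crvt * 3.7
  sc@fovea <- sc@fovea * 3.7
  sc@ppaPoint <- sc@ppaPoint * 3.7
  offS <- computeOffset(sc)
  expect_equal(offsetIndex(offS), offsetIndex(off), tolerance = 1e-9)
  expect_equal(offsetAngle(offS), offsetAngle(off), tolerance = 1e-9)
  expect_equal(offS@ppaAngle, off@ppaAngle, tolerance = 1e-9)
  # mirrored left-eye twin
  left <- makeScene(modifyList(base, list(laterality = "left")))
  offL <- computeOffset(left$scene)
  expect_equal(offsetAngle(offL), offsetAngle(off), tolerance = 1e-9)
  expect_equal(offsetIndex(offL), offsetIndex(off), tolerance = 1e-9)
})

test_that("interior CRVT always yields an index strictly below 1", {
  set.seed(12)
  for (i in 1:25) {
    ms <- makeScene(sceneSpec(trueOffsetAngle = runif(1, -180, 180),
                              trueOffsetIndex = runif(1, 0, 0.99),
                              bmoTilt = runif(1, -80, 80)))
    expect_lt(offsetIndex(computeOffset(ms$scene)), 1)
  }
})

test_that("BMO area uses the supplied scale", {
  ms <- makeScene(sceneSpec(bmoSemiAxes = c(100, 80), bmoTilt = 0,
                            scale = 0.011))
  off <- computeOffset(ms$scene)
  expect_equal(off@bmoArea, pi * 100 * 80 * 0.011^2, tolerance = 1e-6)
  msPx <- makeScene(sceneSpec(bmoSemiAxes = c(100, 80), scale = NA))
  expect_equal(computeOffset(msPx$scene)@bmoArea, pi * 8000, tolerance = 1e-4)
})

test_that("scene CSV writer and reader round trip", {
  ms <- makeScene(sceneSpec(trueOffsetAngle = 45, trueOffsetIndex = 0.4,
                            ppaMeridian = 10, eobMeridian = -20))
  f <- tempfile(fileext = ".csv")
  writeBMOScene(ms$scene, f)
  back <- readBMOScene(f)
  expect_equal(back@marginPoints, ms$scene@marginPoints, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back@crvt, ms$scene@crvt, tolerance = 1e-6)
  expect_equal(back@eobMeridian, -20)
  expect_equal(offsetAngle(computeOffset(back)), 45, tolerance = 1e-6)
  unlink(f)
})
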