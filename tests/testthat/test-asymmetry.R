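# Residual field, region segmentation, asymmetry classification, OPP and
# protrusion depth.

postFitField <- function(spec) {
  post <- phantomPosterior(spec)
  fit <- fitEllipsoid(post@points)
  list(post = post, fit = fit, field = residualField(post, fit))
}

test_that("a perfect ellipsoid eye has a null residual field and is group 1", {
  x <- postFitField(phantomSpec(nPoints = 1200L, bulgeAmplitude = 0,
                                depressionAmplitude = 0))
  expect_lt(max(abs(x$field@signedRatio)), 1e-6)
  res <- classifyAsymmetry(segmentRegions(x$field), x$field)
  expect_false(isAsymmetric(res))
  expect_true(is.na(oppAngle(res)))
  expect_error(computeOPP(x$field, res), "group 2")
  expect_error(computeProtrusionDepth(x$field, res), "group 2")
})

test_that("residual signs agree with the quadric evaluation", {
  x <- postFitField(phantomSpec(nPoints = 1000L, noiseSigma = 0.12, seed = 4L))
  q <- evaluateQuadric(x$fit@model, x$post@points)
  nz <- abs(x$field@signedRatio) > 1e-10
  expect_true(all(sign(x$field@signedRatio[nz]) == sign(q[nz])))
})

test_that("an injected bulge surfaces at the right place and magnitude", {
  spec <- phantomSpec(nPoints = 2000L)
  x <- postFitField(spec)
  i <- which.max(x$field@signedRatio)
  u <- x$post@points[i, ] / sqrt(sum(x$post@points[i, ]^2))
  mu <- eyetopo:::.bulgeDirections(spec)$mu
  expect_lt(acos(sum(u * mu)) * 180 / pi, 12)
  # the ellipsoid fit absorbs part of a smooth perturbation; the visible
  # maximum stays the dominant feature at a sizable fraction of A
  expect_gt(max(x$field@signedRatio), 0.4 * spec$bulgeAmplitude)
  expect_lt(max(x$field@signedRatio), 1.1 * spec$bulgeAmplitude)
})

test_that("segmentation finds one protrusion/depression pair for a phantom", {
  x <- postFitField(phantomSpec(nPoints = 1500L))
  regs <- segmentRegions(x$field)
  pol <- vapply(regs, function(r) r@polarity, "")
  expect_true(any(pol == "outward") && any(pol == "inward"))
  # dominant outward region holds nearly all outward area
  outs <- regs[pol == "outward"]
  af <- vapply(outs, function(r) r@areaFraction, 0)
  expect_gt(max(af) / sum(af), 0.7)
  # raising the floor above the signal suppresses all regions
  expect_length(segmentRegions(x$field, magnitudeFloor = 50), 0L)
})

test_that("two antipodal bulges violate singularity and stay group 1", {
  # hand-built double-bulge surface: no reciprocal depression, two outward
  # lobes on opposite sides of the pole
  spec <- phantomSpec(nPoints = 1500L, depressionAmplitude = 0.06,
                      depressionSeparation = 80)
  d <- eyetopo:::.bulgeDirections(spec)
  ell <- ellipsoidFromGeometry(c(0, 0, 0), spec$semiAxes)
  set.seed(31)
  U <- matrix(rnorm(4500), ncol = 3)
  U <- U / sqrt(rowSums(U^2))
  k <- spec$bulgeConcentration
  mult <- 1 + 0.06 * exp(k * (U %*% d$mu - 1)) +
    0.06 * exp(k * (U %*% (d$mu * c(-1, -1, 1)) - 1))
  P <- U * (drop(ellipsoidRadius(ell, U)) * drop(mult))
  lm <- eyetopo:::.phantomLandmarks(spec, ell)
  cloud <- selectPosterior(standardizeFrame(P, lm, "right"))
  fit <- fitEllipsoid(cloud@points)
  field <- residualField(cloud, fit)
  regs <- segmentRegions(field)
  outs <- Filter(function(r) r@polarity == "outward", regs)
  expect_gte(length(outs), 2L)
  af <- vapply(outs, function(r) r@areaFraction, 0)
  expect_lt(max(af) / sum(af), 0.7)
  expect_false(isAsymmetric(classifyAsymmetry(regs, field)))
})

test_that("OPP angle follows the injected bulge direction and convention", {
  # dense sampling keeps the argmax discretization well below 5 deg
  for (ang in c(0, 90, -70)) {
    x <- postFitField(phantomSpec(nPoints = 2500L, bulgeAngle = ang,
                                  seed = 100L + ang))
    res <- classifyAsymmetry(segmentRegions(x$field), x$field)
    expect_true(isAsymmetric(res))
    expect_lt(abs(wrapAngle(oppAngle(res) - ang)), 5)
  }
})

test_that("protrusion depth adds outward and inward means and grows with A", {
  x <- postFitField(phantomSpec(nPoints = 1200L))
  res <- classifyAsymmetry(segmentRegions(x$field), x$field)
  expect_true(isAsymmetric(res))
  manual <- mean(abs(x$field@signedRatio[res@outwardRegion@members])) +
    mean(abs(x$field@signedRatio[res@inwardRegion@members]))
  expect_equal(protrusionDepth(res), manual)
  xsmall <- postFitField(phantomSpec(nPoints = 1200L, bulgeAmplitude = 0.02,
                                     depressionAmplitude = 0.02))
  rsmall <- classifyAsymmetry(segmentRegions(xsmall$field), xsmall$field)
  expect_true(isAsymmetric(rsmall))
  expect_lt(protrusionDepth(rsmall), protrusionDepth(res))
})

test_that("a mirrored left eye yields the same OPP angle and depth", {
  xr <- postFitField(phantomSpec(nPoints = 1500L, seed = 55L))
  xl <- postFitField(phantomSpec(nPoints = 1500L, seed = 55L,
                                 laterality = "left"))
  rr <- classifyAsymmetry(segmentRegions(xr$field), xr$field)
  rl <- classifyAsymmetry(segmentRegions(xl$field), xl$field)
  expect_true(isAsymmetric(rr) && isAsymmetric(rl))
  expect_equal(oppAngle(rl), oppAngle(rr), tolerance = 1e-6)
  expect_equal(protrusionDepth(rl), protrusionDepth(rr), tolerance = 1e-9)
})
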