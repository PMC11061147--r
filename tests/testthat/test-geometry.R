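# Quadric representation, conversions, distances and the ellipsoid fit.

test_that("quadric evaluation has the documented sign convention", {
  s <- ellipsoidFromQuadric(c(1, 1, 1, 0, 0, 0, 0, 0, 0, -1))
  v <- evaluateQuadric(s, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  # stored gauge rescales coefficients; signs and ratios are preserved
  expect_equal(v / abs(v[1]), c(-1, 0, 3))
  expect_lt(evaluateQuadric(s, c(0.5, 0.2, -0.1)), 0)
  expect_gt(evaluateQuadric(s, c(1.5, 0, 0)), 0)
})

test_that("geometric <-> quadric round trip is the identity", {
  expect_equal(quadricToGeometric(c(1, 1, 1, 0, 0, 0, 0, 0, 0, -1))$semiAxes,
               c(1, 1, 1))
  expect_equal(quadricToGeometric(c(1 / 4, 1, 1, 0, 0, 0, 0, 0, 0, -1))$semiAxes,
               c(2, 1, 1))
  set.seed(11)
  for (i in 1:20) {
    ctr <- rnorm(3, sd = 3)
    ax <- sort(runif(3, 1, 4), decreasing = TRUE)
    R <- randomRotation()
    k <- geometricToQuadric(ctr, ax, t(R))
    g <- quadricToGeometric(k)
    expect_equal(g$center, ctr, tolerance = 1e-9)
    expect_equal(g$semiAxes, ax, tolerance = 1e-9)
    expect_equal(unname(geometricToQuadric(g$center, g$semiAxes,
                                           g$orientation)),
                 unname(k), tolerance = 1e-9)
  }
})

test_that("non-ellipsoid quadrics are rejected with eigenvalue diagnosis", {
  expect_error(ellipsoidFromQuadric(c(1, 1, -1, 0, 0, 0, 0, 0, 0, -1)),
               "eigenvalue")
  expect_error(ellipsoidFromQuadric(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)),
               "ellipsoid")
})

test_that("point-to-ellipsoid distance is exact on principal axes", {
  e <- ellipsoidFromGeometry(c(0, 0, 0), c(2, 1, 1))
  d <- distanceToEllipsoid(e, rbind(c(3, 0, 0), c(2, 0, 0), c(0, 0.5, 0)))
  expect_equal(d$distance, c(1, 0, 0.5), tolerance = 1e-9)
  expect_equal(d$foot[1, ], c(2, 0, 0), tolerance = 1e-8)
  expect_equal(d$signedRatio, c(0.5, 0, -0.5), tolerance = 1e-9)
})

test_that("distance sign always agrees with the quadric evaluation", {
  set.seed(7)
  e <- ellipsoidFromGeometry(c(1, -1, 2), c(3, 2.2, 1.5), randomRotation())
  P <- matrix(rnorm(300, sd = 2.5), ncol = 3)
  d <- distanceToEllipsoid(e, P)
  q <- evaluateQuadric(e, P)
  on <- abs(d$signedRatio) < 1e-10
  expect_true(all(sign(d$signedRatio[!on]) == sign(q[!on])))
  # foot points lie on the surface
  expect_lt(max(abs(evaluateQuadric(e, d$foot))), 1e-7)
})

test_that("exact distance matches the dense-sampling brute force", {
  set.seed(21)
  for (i in 1:6) {
    ax <- sort(runif(3, 10, 14), decreasing = TRUE)
    e <- ellipsoidFromGeometry(rnorm(3), ax, randomRotation())
    p <- ellipsoidCenter(e) + rnorm(3, sd = 6)
    d <- distanceToEllipsoid(e, p)$distance
    expect_lt(abs(d - bruteForceDistance(e, p)), 1e-4)
  }
})

test_that("noise-free clouds are recovered to machine-level accuracy", {
  P <- ellipsoidPoints(1200, center = c(1, -2, 0.5))
  fit <- fitEllipsoid(P)
  expect_true(fit@converged)
  expect_lt(max(abs(semiAxes(fit) - c(12.5, 12, 11.5))), 1e-3)
  expect_lt(max(abs(ellipsoidCenter(fit) - c(1, -2, 0.5))), 1e-3)
  expect_lt(fitRMSE(fit), 1e-6)
})

test_that("fit is equivariant under rigid motions", {
  P <- ellipsoidPoints(800, center = c(0.5, 0, -1))
  fit0 <- fitEllipsoid(P)
  set.seed(5)
  R <- randomRotation()
  t0 <- c(3, -7, 2)
  fitR <- fitEllipsoid(sweep(P %*% t(R), 2, t0, "+"))
  expect_equal(ellipsoidCenter(fitR),
               drop(R %*% ellipsoidCenter(fit0)) + t0, tolerance = 1e-6)
  expect_equal(semiAxes(fitR), semiAxes(fit0), tolerance = 1e-6)
})

test_that("rmse is scale-invariant (radius-normalized residuals)", {
  set.seed(9)
  P <- ellipsoidPoints(600) + matrix(rnorm(1800, 0, 0.1), ncol = 3)
  f1 <- fitEllipsoid(P)
  f2 <- fitEllipsoid(P * 3)
  expect_equal(fitRMSE(f1), fitRMSE(f2), tolerance = 1e-3)
})

test_that("degenerate inputs are refused", {
  expect_error(fitEllipsoid(matrix(rnorm(12), ncol = 3)), "at least 9")
  flat <- cbind(matrix(rnorm(60), ncol = 2), 0)
  expect_error(fitEllipsoid(flat), "coplanar")
})

test_that("simplex fit cost beats a coarse grid search around truth", {
  P <- ellipsoidPoints(50, center = c(0.2, -0.3, 0.1),
                       semiAxes = c(12.5, 12, 11.5))
  set.seed(3)
  P <- P + matrix(rnorm(150, 0, 0.15), ncol = 3)
  fit <- fitEllipsoid(P)
  fitCost <- sum(distanceToEllipsoid(fit@model, P)$distance^2)
  gridCost <- Inf
  for (dc in c(-1, 0, 1)) for (da in c(-1, 0, 1)) for (ea in c(-10, 0, 10)) {
    m <- ellipsoidFromGeometry(c(0.2, -0.3, 0.1) + dc * c(1, -1, 1) / 2,
                               c(12.5, 12, 11.5) + da * c(1, -1, 1) / 2,
                               t(eyetopo:::.eulerRotation(ea, ea / 2, -ea)))
    gridCost <- min(gridCost, sum(distanceToEllipsoid(m, P)$distance^2))
  }
  expect_lte(fitCost, gridCost)
})

test_that("model serializes to a complete JSON record", {
  fit <- fitEllipsoid(ellipsoidPoints(400))
  rec <- jsonlite::fromJSON(modelToJSON(fit))
  expect_named(rec, c("coefficients", "center", "semi_axes", "orientation",
                      "rmse"), ignore.order = TRUE)
  expect_equal(unlist(rec$semi_axes), semiAxes(fit), tolerance = 1e-10,
               ignore_attr = TRUE)
})
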