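# Intensity rescaling, slice-wise Canny contour extraction, frame
# standardization and the posterior cut.

test_that("intensity rescaling maps the range onto 0-256 and is idempotent", {
  set.seed(1)
  v <- voxelVolume(array(runif(8^3, 100, 612), dim = c(8, 8, 8)))
  r <- rescaleIntensities(v)
  expect_equal(range(r@intensities), c(0, 256))
  expect_equal(rescaleIntensities(r)@intensities, r@intensities)
  m <- v@intensities
  expect_equal(r@intensities, (m - min(m)) * 256 / (max(m) - min(m)))
  expect_error(rescaleIntensities(voxelVolume(array(5, dim = c(4, 4, 4)))),
               "constant")
})

test_that("phantom volume contour lies within one voxel of the true surface", {
  spec <- phantomSpec(nPoints = 500L)
  vol <- makeVolume(spec)
  pts <- extractContour(rescaleIntensities(vol))
  expect_gt(nrow(pts), 1000)
  ctr <- vol@meta$centerWorld
  U <- sweep(pts, 2, ctr)
  r <- sqrt(rowSums(U^2))
  ell <- ellipsoidFromGeometry(c(0, 0, 0), spec$semiAxes)
  rtrue <- drop(ellipsoidRadius(ell, U)) *
    drop(eyetopo:::.surfaceMultiplier(spec, U / r))
  expect_lt(max(abs(r - rtrue)), sqrt(3) * spec$voxelSpacing)
  expect_lt(stats::median(abs(r - rtrue)), spec$voxelSpacing)
})

test_that("noisy phantom volume still traces the globe boundary", {
  spec <- phantomSpec(nPoints = 500L, intensityNoise = 5, seed = 77L)
  vol <- makeVolume(spec)
  pts <- extractContour(rescaleIntensities(vol))
  ctr <- vol@meta$centerWorld
  U <- sweep(pts, 2, ctr)
  r <- sqrt(rowSums(U^2))
  ell <- ellipsoidFromGeometry(c(0, 0, 0), spec$semiAxes)
  rtrue <- drop(ellipsoidRadius(ell, U)) *
    drop(eyetopo:::.surfaceMultiplier(spec, U / r))
  expect_gt(mean(abs(r - rtrue) <= sqrt(3) * spec$voxelSpacing), 0.95)
})

test_that("blank volumes and flat gradients are refused", {
  expect_error(extractContour(voxelVolume(array(0, dim = c(10, 10, 10)))),
               "gradient")
})

test_that("frame standardization is the identity for a standard right eye", {
  ph <- makeSurface(phantomSpec(nPoints = 800L))
  cloud <- standardizeFrame(ph$points, ph$landmarks, "right")
  expect_equal(cloud@points, ph$points, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(cloud@visualAxis, c(0, 0, 1))
})

test_that("left-eye mirroring is an involution", {
  ph <- makeSurface(phantomSpec(nPoints = 600L, laterality = "left"))
  once <- standardizeFrame(ph$points, ph$landmarks, "left")
  lm2 <- list(lens = once@lensCenter, onh = once@onhCenter,
              fovea = once@fovea, bmo = once@bmoPoint)
  twice <- standardizeFrame(once@points, lm2, "left")
  expect_equal(twice@points[, 1], ph$points[, 1], tolerance = 1e-12)
})

test_that("a rotated phantom maps back to canonical landmark positions", {
  # rotation about an axis orthogonal to z is undone exactly by the minimal
  # rotation that realigns the visual axis
  R <- eyetopo:::.rotationBetween(c(0, 0, 1), .unitv <- c(0.3, -0.4, 0.866))
  ph0 <- makeSurface(phantomSpec(nPoints = 400L))
  ph <- makeSurface(phantomSpec(nPoints = 400L, rotation = R))
  cloud <- standardizeFrame(ph$points, ph$landmarks, "right")
  expect_equal(cloud@fovea, ph0$landmarks$fovea, tolerance = 1e-9)
  expect_equal(cloud@bmoPoint, ph0$landmarks$bmo, tolerance = 1e-9)
  expect_error(standardizeFrame(ph$points,
                                list(lens = c(0, 0, 0), onh = c(0, 0, 0),
                                     fovea = c(1, 1, 1), bmo = c(1, 1, 2)),
                                "right"),
               "coincide")
})

test_that("posterior cut keeps the axial fraction and matches cap area", {
  ph <- makeSurface(phantomSpec(nPoints = 4000L, bulgeAmplitude = 0,
                                depressionAmplitude = 0,
                                semiAxes = c(12, 12, 12)))
  cloud <- standardizeFrame(ph$points, ph$landmarks, "right")
  full <- selectPosterior(cloud, fraction = 1)
  expect_equal(nrow(full@points), 4000L)
  post <- selectPosterior(cloud, fraction = 2 / 3)
  # spherical cap area above z >= -R/3 is 2/3 of the sphere
  expect_equal(nrow(post@points) / 4000, 2 / 3, tolerance = 0.02)
  expect_true(all(post@points[, 3] >=
                    min(cloud@points[, 3]) + (1 / 3) * diff(range(cloud@points[, 3]))))
  expect_error(selectPosterior(cloud, fraction = 0.01), "survive")
})

test_that("volume pipeline recovers phantom axes within half a voxel", {
  spec <- phantomSpec(nPoints = 500L, bulgeAmplitude = 0,
                      depressionAmplitude = 0)
  vol <- makeVolume(spec)
  out <- analyzeEyeVolume(vol, vol@meta$landmarks, "right")
  expect_lt(max(abs(semiAxes(out$fit) - spec$semiAxes)),
            0.5 * spec$voxelSpacing)
  expect_false(isAsymmetric(out$result))
})

test_that("NIfTI round trip preserves intensities and spacing", {
  spec <- phantomSpec(nPoints = 100L, voxelSpacing = 2)
  vol <- makeVolume(spec)
  f <- tempfile(fileext = ".nii.gz")
  writeNIfTIVolume(vol, f)
  back <- readNIfTIVolume(f)
  expect_equal(back@intensities, vol@intensities, ignore_attr = TRUE)
  expect_equal(back@spacing, vol@spacing)
  unlink(f)
})

test_that("landmark CSV and point-cloud writers round trip", {
  d <- data.frame(subject_id = "S1", eye = "OD",
                  structure = c("lens", "onh", "fovea", "bmo"),
                  x_mm = 1:4, y_mm = 5:8, z_mm = 9:12)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(d, f, row.names = FALSE)
  lm <- readLandmarks(f)
  expect_equal(lm$S1$OD$fovea, c(3, 7, 11))
  p <- matrix(rnorm(30), ncol = 3)
  fp <- tempfile(fileext = ".csv")
  writePointCloud(p, fp)
  expect_equal(as.matrix(utils::read.csv(fp)), p, ignore_attr = TRUE,
               tolerance = 1e-12)
  fply <- tempfile(fileext = ".ply")
  writePointCloud(p, fply)
  expect_match(readLines(fply, n = 1), "ply")
  unlink(c(f, fp, fply))
})
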