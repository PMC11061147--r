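# Synthetic ground-truth generators: globe phantoms (surface clouds and voxel
# volumes), ONH scenes, and cohort manifests.
#
# The bulge model is a von-Mises-Fisher-shaped radial perturbation
#   r(u) = r_ell(u) * (1 + A exp(kappa (u.mu - 1)) - D exp(kappa (u.mu' - 1)))
# with the reciprocal depression mu' placed along the same meridian at a
# fixed angular separation from the bulge, emulating a smooth focal
# protrusion with an immediately adjacent depression.

#' Specify a globe phantom
#'
#' Defaults represent an emmetropic-to-moderately-myopic adult globe
#' (semi-axes 12.5/12.0/11.5 mm) with a group-2-scale focal bulge: amplitude
#' 0.06 of the local radius (the mean protrusion-depth scale reported for
#' asymmetric eyes), a reciprocal depression of equal amplitude placed 40
#' degrees up-meridian (centered on the posterior pole), and a
#' concentration giving a protrusion/depression pair wide enough to dominate
#' the posterior pole.
#'
#' @param semiAxes numeric(3), mm (default c(12.5, 12, 11.5)).
#' @param rotation 3x3 rotation applied to the phantom (default identity).
#' @param translation numeric(3) offset, mm.
#' @param bulgeAngle degrees from the nasal fovea-BMO axis, positive
#'   superior (default -70, the inferonasal mean OPP location).
#' @param bulgeInclination degrees from the posterior pole (default 40).
#' @param bulgeAmplitude dimensionless ratio A >= 0 (default 0.06).
#' @param bulgeConcentration kappa > 0; smaller is wider (default 6).
#' @param depressionAmplitude ratio (default 0.06, reciprocal to the bulge).
#' @param depressionSeparation degrees between bulge and depression centers
#'   along the meridian (default 40, placing the depression at the pole).
#' @param noiseSigma isotropic point noise, mm (default 0).
#' @param intensityNoise Gaussian intensity noise for rasterized volumes,
#'   intensity units (default 0).
#' @param nPoints surface points to sample (default 2000).
#' @param voxelSpacing mm (default 1, the scan resolution).
#' @param laterality "right" or "left".
#' @param seed integer seed (default 20240430).
#' @return a list of class "phantomSpec".
#' @export
phantomSpec <- function(semiAxes = c(12.5, 12.0, 11.5), rotation = diag(3),
                        translation = c(0, 0, 0),
                        bulgeAngle = -70, bulgeInclination = 40,
                        bulgeAmplitude = 0.06, bulgeConcentration = 6,
                        depressionAmplitude = 0.06, depressionSeparation = 40,
                        noiseSigma = 0, intensityNoise = 0, nPoints = 2000L,
                        voxelSpacing = 1, laterality = "right",
                        seed = 20240430L) {
  stopifnot(bulgeAmplitude >= 0, bulgeConcentration > 0,
            all(semiAxes > 0), laterality %in% c("right", "left"))
  structure(list(semiAxes = semiAxes, rotation = rotation,
                 translation = translation, bulgeAngle = bulgeAngle,
                 bulgeInclination = bulgeInclination,
                 bulgeAmplitude = bulgeAmplitude,
                 bulgeConcentration = bulgeConcentration,
                 depressionAmplitude = depressionAmplitude,
                 depressionSeparation = depressionSeparation,
                 noiseSigma = noiseSigma, intensityNoise = intensityNoise,
                 nPoints = as.integer(nPoints), voxelSpacing = voxelSpacing,
                 laterality = laterality, seed = as.integer(seed)),
            class = "phantomSpec")
}

# bulge/depression direction unit vectors in the standardized frame; the
# depression sits on the bulge meridian, displaced poleward by the angular
# separation (crossing the pole if the separation exceeds the inclination),
# so the pair is compact around the posterior pole and the azimuthal pull of
# the depression tail on the residual maximum cancels by symmetry
.bulgeDirections <- function(spec) {
  th <- spec$bulgeAngle * pi / 180
  phi <- spec$bulgeInclination * pi / 180
  sep <- spec$depressionSeparation * pi / 180
  mu <- c(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  phi2 <- phi - sep
  th2 <- th
  if (phi2 < 0) { phi2 <- -phi2; th2 <- th + pi }
  mu2 <- c(sin(phi2) * cos(th2), sin(phi2) * sin(th2), cos(phi2))
  list(mu = mu, mu2 = mu2)
}

# radial multiplier of the perturbed surface for unit directions U (n x 3)
.surfaceMultiplier <- function(spec, U) {
  d <- .bulgeDirections(spec)
  k <- spec$bulgeConcentration
  1 + spec$bulgeAmplitude * exp(k * (U %*% d$mu - 1)) -
    spec$depressionAmplitude * exp(k * (U %*% d$mu2 - 1))
}

# landmarks on the perturbed surface, standardized frame
.phantomLandmarks <- function(spec, ell) {
  dirF <- c(-sin(15 * pi / 180), 0, cos(15 * pi / 180))   # fovea temporal
  dirB <- c(0, 0, 1)                                       # BMO at the pole
  rF <- ellipsoidRadius(ell, dirF) * drop(.surfaceMultiplier(spec, rbind(dirF)))
  rB <- ellipsoidRadius(ell, dirB) * drop(.surfaceMultiplier(spec, rbind(dirB)))
  rA <- ellipsoidRadius(ell, -dirB)
  list(fovea = rF * dirF, bmo = rB * dirB, onh = rB * dirB,
       lens = -0.9 * rA * dirB)
}

#' Sample a phantom globe surface with ground truth
#'
#' @param spec a [phantomSpec()].
#' @return list with `points` (n x 3, mm), `landmarks` (lens/onh/fovea/bmo),
#'   `laterality`, and `truth` (the spec plus the analytic bulge direction).
#' @export
makeSurface <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  ell <- ellipsoidFromGeometry(c(0, 0, 0), spec$semiAxes)
  .withSeed(spec$seed, {
    # quasi-uniform direction coverage (Fibonacci lattice under a seeded
    # random rotation): dense contours are structured samplings of the
    # surface, not iid draws, and uniform coverage keeps the fit and the
    # residual argmax free of clump-induced wiggle
    i <- seq_len(spec$nPoints) - 0.5
    phi <- acos(1 - 2 * i / spec$nPoints)
    th <- pi * (1 + sqrt(5)) * i
    U <- cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
    Rl <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Rl) < 0) Rl[, 1] <- -Rl[, 1]
    U <- U %*% t(Rl)
    r <- ellipsoidRadius(ell, U) * drop(.surfaceMultiplier(spec, U))
    P <- U * r
    if (spec$noiseSigma > 0)
      P <- P + matrix(rnorm(length(P), 0, spec$noiseSigma), ncol = 3)
    lm <- .phantomLandmarks(spec, ell)
    P <- P %*% t(spec$rotation)
    P <- sweep(P, 2, spec$translation, "+")
    lm <- lapply(lm, function(v) drop(spec$rotation %*% v) + spec$translation)
    if (spec$laterality == "left") {
      P[, 1] <- -P[, 1]
      lm <- lapply(lm, function(v) { v[1] <- -v[1]; v })
    }
    list(points = P, landmarks = lm, laterality = spec$laterality,
         truth = list(spec = spec, oppAngle = spec$bulgeAngle,
                      amplitude = spec$bulgeAmplitude))
  })
}

#' Rasterize a phantom globe into a voxel volume
#'
#' Voxels inside the perturbed surface get intensity 200, outside 20, with
#' optional Gaussian intensity noise; voxel centers sit at
#' (index - 0.5) * spacing.
#'
#' @param spec a [phantomSpec()].
#' @param margin extra empty border, mm (default 3).
#' @return a [VoxelVolume-class]; `meta` carries the landmarks (mm, world
#'   coordinates) and the truth record.
#' @export
makeVolume <- function(spec, margin = 3) {
  stopifnot(inherits(spec, "phantomSpec"))
  sp <- spec$voxelSpacing
  rmax <- max(spec$semiAxes) * (1 + spec$bulgeAmplitude + 0.02)
  half <- rmax + margin
  n <- ceiling(2 * half / sp)
  if (n < 8) stop("grid too small to contain the phantom surface")
  ctrWorld <- n * sp / 2
  ax <- ((seq_len(n)) - 0.5) * sp - ctrWorld
  G <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  nrm <- sqrt(rowSums(G^2))
  U <- G / pmax(nrm, 1e-12)
  U[nrm < 1e-12, ] <- rep(c(0, 0, 1), each = sum(nrm < 1e-12))
  ell <- ellipsoidFromGeometry(c(0, 0, 0), spec$semiAxes)
  rsurf <- ellipsoidRadius(ell, U) * drop(.surfaceMultiplier(spec, U))
  if (max(rsurf) > half - sp)
    stop("phantom surface exceeds the voxel grid")
  inside <- nrm <= rsurf
  v <- array(ifelse(inside, 200, 20), dim = c(n, n, n))
  if (spec$intensityNoise > 0)
    v <- v + .withSeed(spec$seed + 1L,
                       array(rnorm(length(v), 0, spec$intensityNoise), dim = dim(v)))
  lm <- .phantomLandmarks(spec, ell)
  lm <- lapply(lm, function(p) drop(spec$rotation %*% p) + spec$translation)
  if (spec$laterality == "left") lm <- lapply(lm, function(p) { p[1] <- -p[1]; p })
  lm <- lapply(lm, function(p) p + ctrWorld)
  voxelVolume(v, spacing = sp,
              meta = list(landmarks = lm, truth = list(spec = spec),
                          centerWorld = rep(ctrWorld, 3)))
}

#' Specify a synthetic ONH scene
#'
#' @param bmoSemiAxes numeric(2), px (default c(95, 80)).
#' @param bmoTilt degrees (default 20).
#' @param bmoCenter numeric(2), px.
#' @param trueOffsetAngle degrees from the nasal fovea-BMO axis.
#' @param trueOffsetIndex in [0, 1].
#' @param crvtVisible logical (default TRUE).
#' @param eobMeridian degrees or NA.
#' @param ppaMeridian degrees (temporal convention) or NA.
#' @param foveaDistance px from the BMO center (default 600).
#' @param laterality "right" or "left".
#' @param scale mm per px or NA (default 0.011).
#' @param jitterSigma Gaussian jitter of margin points, px (default 0).
#' @param seed integer seed.
#' @return a list of class "sceneSpec".
#' @export
sceneSpec <- function(bmoSemiAxes = c(95, 80), bmoTilt = 20,
                      bmoCenter = c(256, 256), trueOffsetAngle = 60,
                      trueOffsetIndex = 0.6, crvtVisible = TRUE,
                      eobMeridian = NA_real_, ppaMeridian = NA_real_,
                      foveaDistance = 600, laterality = "right",
                      scale = 0.011, jitterSigma = 0, seed = 20240430L) {
  stopifnot(trueOffsetIndex >= 0, trueOffsetIndex <= 1)
  structure(list(bmoSemiAxes = bmoSemiAxes, bmoTilt = bmoTilt,
                 bmoCenter = bmoCenter, trueOffsetAngle = trueOffsetAngle,
                 trueOffsetIndex = trueOffsetIndex, crvtVisible = crvtVisible,
                 eobMeridian = eobMeridian, ppaMeridian = ppaMeridian,
                 foveaDistance = foveaDistance, laterality = laterality,
                 scale = scale, jitterSigma = jitterSigma,
                 seed = as.integer(seed)),
            class = "sceneSpec")
}

#' Generate a BMO scene with known offset truth
#'
#' Places 24 margin points on the specified ellipse (matching the 24 radial
#' scans the margins are marked on), the fovea along the nasal axis, and the
#' CRVT at the requested (angle, index) by inverting the offset definition.
#'
#' @param spec a [sceneSpec()].
#' @param nMargin margin points (default 24).
#' @return list with `scene` (a [BMOScene-class]) and `truth`.
#' @export
makeScene <- function(spec, nMargin = 24L) {
  stopifnot(inherits(spec, "sceneSpec"))
  th <- spec$bmoTilt * pi / 180
  e1 <- c(cos(th), sin(th)); e2 <- c(-sin(th), cos(th))
  tt <- seq(0, 2 * pi, length.out = nMargin + 1L)[-(nMargin + 1L)]
  M <- t(vapply(tt, function(a)
    spec$bmoCenter + spec$bmoSemiAxes[1] * cos(a) * e1 +
      spec$bmoSemiAxes[2] * sin(a) * e2, numeric(2)))
  if (spec$jitterSigma > 0)
    M <- M + .withSeed(spec$seed, matrix(rnorm(length(M), 0, spec$jitterSigma),
                                         ncol = 2))
  nasal <- c(1, 0)                         # right-eye frame: nasal +x
  fovea <- spec$bmoCenter - spec$foveaDistance * nasal
  ang <- spec$trueOffsetAngle * pi / 180
  d <- c(cos(ang), sin(ang))               # angle from nasal, CCW = superior
  b <- .rayEllipseDistance(spec$bmoSemiAxes, spec$bmoTilt, d)
  crvt <- spec$bmoCenter + spec$trueOffsetIndex * b * d
  ppa <- if (is.finite(spec$ppaMeridian)) {
    pa <- spec$ppaMeridian * pi / 180
    dp <- c(-cos(pa), sin(pa))             # temporal reference, +superior
    spec$bmoCenter + 1.3 * .rayEllipseDistance(spec$bmoSemiAxes,
                                               spec$bmoTilt, dp) * dp
  } else c(NA_real_, NA_real_)
  sc <- bmoScene(M, fovea = fovea,
                 crvt = if (spec$crvtVisible) crvt else NULL,
                 crvtVisible = spec$crvtVisible, laterality = "right",
                 eobMeridian = spec$eobMeridian, ppaPoint = ppa,
                 scale = spec$scale)
  if (spec$laterality == "left") {
    sc@marginPoints[, 1] <- -sc@marginPoints[, 1]
    sc@fovea[1] <- -sc@fovea[1]
    if (all(is.finite(sc@crvt))) sc@crvt[1] <- -sc@crvt[1]
    if (all(is.finite(sc@ppaPoint))) sc@ppaPoint[1] <- -sc@ppaPoint[1]
    sc@laterality <- "left"
  }
  list(scene = sc, truth = list(offsetAngle = spec$trueOffsetAngle,
                                offsetIndex = spec$trueOffsetIndex,
                                ppaAngle = spec$ppaMeridian))
}

#' Generate a synthetic cohort manifest with coupled eye metrics
#'
#' Per-subject demographics follow the cohort moments (age ~ N(55, 16.2^2)
#' years, axial length ~ N(25.6, 1.9^2) mm); each eye is asymmetric (group 2)
#' with probability `asymmetricFraction`.  For group-2 eyes the OPP angle is
#' drawn from the group-2 distribution (N(-68.1, 51.2^2), wrapped) and the
#' LC/BMO offset angle is linearly opposed,
#' offset = wrap(-0.716 * opp + 12.6 + N(0, couplingNoiseDeg^2)),
#' while the offset index couples positively to the protrusion depth.
#' Exclusion flags reproduce the study's exclusion flow.
#'
#' @param nSubjects enrolled subjects (default 96).
#' @param asymmetricFraction probability an eye is group 2 (default 0.465).
#' @param couplingNoiseDeg angular coupling noise, degrees (default 30).
#' @param exclusionCounts named integer vector in exclusion order:
#'   withdrew, metal_fb, poor_mri, poor_oct, crvt_bifurcation (defaults
#'   3, 1, 4, 2, 1).
#' @param seed integer seed.
#' @return list with `manifest` (data.frame, one row per eye) and `truth`.
#' @export
makeCohort <- function(nSubjects = 96L, asymmetricFraction = 0.465,
                       couplingNoiseDeg = 30,
                       exclusionCounts = c(withdrew = 3L, metal_fb = 1L,
                                           poor_mri = 4L, poor_oct = 2L,
                                           crvt_bifurcation = 1L),
                       seed = 20240430L) {
  if (asymmetricFraction < 0 || asymmetricFraction > 1)
    stop("asymmetricFraction must lie in [0, 1]")
  if (sum(exclusionCounts) > nSubjects)
    stop("more exclusions than subjects")
  .withSeed(seed, {
    subj <- sprintf("S%03d", seq_len(nSubjects))
    age <- pmax(18, rnorm(nSubjects, 55.0, 16.2))
    sexF <- rbinom(nSubjects, 1, 0.49) == 1
    flagNames <- c("withdrew", "metal_fb", "poor_mri", "poor_oct",
                   "crvt_bifurcation")
    flags <- matrix(FALSE, nSubjects, length(flagNames),
                    dimnames = list(NULL, flagNames))
    excl <- sample(nSubjects, sum(exclusionCounts))
    k <- 0L
    for (f in names(exclusionCounts)) {
      cnt <- exclusionCounts[[f]]
      if (cnt > 0) flags[excl[k + seq_len(cnt)], f] <- TRUE
      k <- k + cnt
    }
    rows <- list()
    for (i in seq_len(nSubjects)) {
      for (eye in c("OD", "OS")) {
        grp2 <- runif(1) < asymmetricFraction
        if (grp2) {
          opp <- wrapAngle(rnorm(1, -68.1, 51.2))
          depth <- max(0.01, rnorm(1, 0.06, 0.01))
          off <- wrapAngle(-0.716 * opp + 12.6 + rnorm(1, 0, couplingNoiseDeg))
          oidx <- min(1, max(0, 0.68 + 3 * (depth - 0.06) + rnorm(1, 0, 0.15)))
          rmse <- max(0.005, rnorm(1, 0.025, 0.010))
        } else {
          opp <- NA_real_
          depth <- NA_real_
          off <- wrapAngle(rnorm(1, 10.3, 74.1))
          oidx <- min(1, max(0, rnorm(1, 0.54, 0.29)))
          rmse <- max(0.004, rnorm(1, 0.017, 0.005))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subj[i], eye = eye, age = age[i],
          sex = if (sexF[i]) "F" else "M",
          axial_length = rnorm(1, 25.6, 1.9),
          iop = pmax(8, rnorm(1, 15.3, 4.2)),
          glaucoma = runif(1) < 122 / 170,
          withdrew = flags[i, "withdrew"], metal_fb = flags[i, "metal_fb"],
          poor_mri = flags[i, "poor_mri"], poor_oct = flags[i, "poor_oct"],
          crvt_bifurcation = flags[i, "crvt_bifurcation"],
          group = if (grp2) 2L else 1L, opp_angle = opp,
          protrusion_depth = depth, rmse = rmse, offset_angle = off,
          offset_index = oidx, bmo_area = max(0.5, rnorm(1, 3.3, 1.8)),
          ppa_angle = wrapAngle(rnorm(1, 0, 70)),
          stringsAsFactors = FALSE)
      }
    }
    manifest <- do.call(rbind, rows)
    list(manifest = manifest,
         truth = list(nSubjects = nSubjects,
                      excludedSubjects = subj[sort(excl)],
                      asymmetricFraction = asymmetricFraction,
                      couplingNoiseDeg = couplingNoiseDeg))
  })
}
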