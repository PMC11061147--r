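# Signed residual field, suprathreshold region growing, asymmetry
# classification, OPP angle and protrusion depth.
#
# Conventions: the posterior polar plane is the xy-plane of the standardized
# frame; all angles are measured from the nasal side of the fovea-BMO axis,
# positive toward superior (+y), wrapped to (-180, 180].  The posterior-pole
# area (the denominator of every area fraction) is the polar cap within
# poleCapDeg of the +z direction as seen from the fitted ellipsoid center.

.knnIndex <- function(P, k = 8L) {
  n <- nrow(P)
  k <- min(k, n - 1L)
  D <- as.matrix(stats::dist(P))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) idx[i, ] <- order(D[i, ])[2:(k + 1L)]
  attr(idx, "kdist") <- vapply(seq_len(n), function(i) D[i, idx[i, k]], 0)
  idx
}

# nasal unit 2-vector: from the projected fovea toward the projected BMO
.nasalAxis <- function(field) {
  v <- (field@cloud@bmoPoint - field@cloud@fovea)[1:2]
  .unit(v)
}

#' Build the signed residual field over a posterior cloud
#'
#' Each contour point receives its radius-normalized signed distance to the
#' fitted ellipsoid (positive outside); Voronoi-like area weights are derived
#' from the local 8-neighbor spacing (squared distance to the k-th neighbor),
#' compensating the non-uniform slice-wise sampling of the contour.
#'
#' @param cloud the posterior [EyePointCloud-class] used for the fit.
#' @param fit the [EllipsoidFit-class] obtained from the same cloud.
#' @param k neighbors for the surface adjacency graph (default 8).
#' @return a [ResidualField-class].
#' @export
residualField <- function(cloud, fit, k = 8L) {
  P <- cloud@points
  ratio <- distanceToEllipsoid(fit@model, P)$signedRatio
  knn <- .knnIndex(P, k)
  w <- attr(knn, "kdist")^2
  ctr <- fit@model@center
  fDir <- .unit((cloud@fovea - ctr)[1:2])
  bDir <- .unit((cloud@bmoPoint - ctr)[1:2])
  new("ResidualField", cloud = cloud, fit = fit, signedRatio = ratio,
      areaWeight = w, foveaDir = fDir, bmoDir = bDir, knn = knn)
}

# indices of points in the posterior polar cap: within `capDeg` of the
# posterior pole direction (+z) as seen from the fitted ellipsoid center
.poleCap <- function(field, capDeg = 35) {
  v <- sweep(field@cloud@points, 2, field@fit@model@center)
  cosIncl <- v[, 3] / sqrt(rowSums(v^2))
  which(cosIncl >= cos(capDeg * pi / 180))
}

#' Segment suprathreshold protrusion/depression regions
#'
#' Points whose absolute signed ratio reaches `magnitudeFloor` times the fit
#' RMSE are grouped by polarity into connected components of the k-nearest-
#' neighbor surface graph.  Area fractions are expressed relative to the
#' posterior-pole surface area.
#'
#' @param field a [ResidualField-class].
#' @param magnitudeFloor threshold as a multiple of the fit RMSE (default 1).
#' @param poleCapDeg half-angle of the posterior-pole cap used as the area
#'   denominator, degrees from the posterior pole (default 35, the central
#'   posterior region).
#' @param minRegionPoints smallest connected component kept as a region
#'   (default 5); isolated suprathreshold specks are sampling noise, not
#'   anatomy.
#' @return list of [ProtrusionRegion-class], sorted by decreasing area.
#' @export
segmentRegions <- function(field, magnitudeFloor = 1.0, poleCapDeg = 35,
                           minRegionPoints = 5L) {
  ratio <- field@signedRatio
  thr <- magnitudeFloor * field@fit@rmse
  supra <- abs(ratio) >= thr & thr > 0
  if (!any(supra)) return(list())
  cap <- .poleCap(field, poleCapDeg)
  wCap <- sum(field@areaWeight[cap])
  nasal <- .nasalAxis(field)
  ctr2 <- field@fit@model@center[1:2]
  P <- field@cloud@points
  knn <- field@knn
  lab <- integer(length(ratio))
  comp <- 0L
  for (i in which(supra)) {
    if (lab[i]) next
    comp <- comp + 1L
    pol <- ratio[i] > 0
    queue <- i; lab[i] <- comp
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      nb <- knn[cur, ]
      nb <- nb[supra[nb] & !lab[nb] & ((ratio[nb] > 0) == pol)]
      lab[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  sizes <- tabulate(lab, comp)
  regions <- lapply(which(sizes >= minRegionPoints), function(cid) {
    members <- which(lab == cid)
    mCap <- intersect(members, cap)
    af <- min(1, max(sum(field@areaWeight[mCap]) / wCap, 1e-12))
    cen <- colSums(P[members, 1:2, drop = FALSE] * field@areaWeight[members]) /
      sum(field@areaWeight[members])
    new("ProtrusionRegion",
        polarity = if (ratio[members[1]] > 0) "outward" else "inward",
        members = as.integer(members), areaFraction = af,
        meanRatio = mean(abs(ratio[members])),
        centroidAngle = .signedAngle2(nasal, cen - ctr2))
  })
  regions[order(vapply(regions, function(r) r@areaFraction, 0),
                decreasing = TRUE)]
}

# are two member sets within `hops` steps of each other on the kNN graph?
.regionsAdjacent <- function(knn, a, b, hops = 2L) {
  reach <- a
  for (h in seq_len(hops)) {
    reach <- unique(c(reach, as.integer(knn[reach, ])))
    if (any(reach %in% b)) return(TRUE)
  }
  FALSE
}

#' Classify eyeball asymmetry from segmented regions
#'
#' Group 2 (asymmetric) requires: (i) a single dominant outward protrusion
#' (the largest outward component holds at least `dominanceFraction` of the
#' total suprathreshold outward area), (ii) an inward depression immediately
#' adjacent to it (within `adjacencyHops` steps on the surface graph), and
#' (iii) the protrusion/depression pair jointly covering more than
#' `pairAreaThreshold` of the posterior-pole area (set
#' `areaRule = "depression"` for the alternative reading in which the
#' depression alone must exceed the threshold).
#'
#' @param regions output of [segmentRegions()].
#' @param field the [ResidualField-class] the regions came from.
#' @param dominanceFraction default 0.7.
#' @param pairAreaThreshold default 0.5.
#' @param adjacencyHops default 3: the threshold-at-RMSE rule leaves a
#'   subthreshold band at the protrusion-depression zero crossing about two
#'   points wide at typical sampling densities, which three hops bridge.
#' @param areaRule "pair" (default) or "depression".
#' @return an [AsymmetryResult-class]; OPP angle and protrusion depth are
#'   filled for asymmetric eyes.
#' @export
classifyAsymmetry <- function(regions, field, dominanceFraction = 0.7,
                              pairAreaThreshold = 0.5, adjacencyHops = 3L,
                              areaRule = c("pair", "depression")) {
  areaRule <- match.arg(areaRule)
  group1 <- function() new("AsymmetryResult", isAsymmetric = FALSE,
                           oppAngle = NA_real_, protrusionDepth = NA_real_,
                           rmse = field@fit@rmse, outwardRegion = NULL,
                           inwardRegion = NULL)
  outs <- Filter(function(r) r@polarity == "outward", regions)
  ins <- Filter(function(r) r@polarity == "inward", regions)
  if (!length(outs) || !length(ins)) return(group1())
  totOut <- sum(vapply(outs, function(r) r@areaFraction, 0))
  dom <- outs[[1]]
  if (dom@areaFraction < dominanceFraction * totOut) return(group1())
  adj <- Filter(function(r) .regionsAdjacent(field@knn, dom@members,
                                             r@members, adjacencyHops), ins)
  if (!length(adj)) return(group1())
  dep <- adj[[1]]                      # largest adjacent depression
  pairArea <- if (areaRule == "pair") dom@areaFraction + dep@areaFraction
              else dep@areaFraction
  if (pairArea <= pairAreaThreshold) return(group1())
  res <- new("AsymmetryResult", isAsymmetric = TRUE, oppAngle = 0,
             protrusionDepth = 0, rmse = field@fit@rmse,
             outwardRegion = dom, inwardRegion = dep)
  res@oppAngle <- computeOPP(field, res)
  res@protrusionDepth <- computeProtrusionDepth(field, res)
  validObject(res)
  res
}

#' Outermost protruded point (OPP) angle
#'
#' The OPP is the point of maximal signed ratio within the dominant outward
#' region; its projection onto the posterior polar plane gives the angle from
#' the nasal fovea-BMO axis (positive superior).  Near-exact ties are broken
#' by the larger area-weighted neighborhood mean.
#'
#' @param field a [ResidualField-class].
#' @param result an asymmetric [AsymmetryResult-class].
#' @return angle in degrees, (-180, 180].
#' @export
computeOPP <- function(field, result) {
  if (!result@isAsymmetric)
    stop("OPP is defined only for asymmetric (group 2) eyes")
  members <- result@outwardRegion@members
  r <- field@signedRatio[members]
  cand <- members[r >= max(r) - 1e-12]
  if (length(cand) > 1L) {
    nbMean <- vapply(cand, function(i) {
      nb <- c(i, field@knn[i, ])
      sum(field@signedRatio[nb] * field@areaWeight[nb]) / sum(field@areaWeight[nb])
    }, 0)
    cand <- cand[which.max(nbMean)]
  }
  opp <- field@cloud@points[cand[1], 1:2]
  .signedAngle2(.nasalAxis(field), opp - field@fit@model@center[1:2])
}

#' Protrusion depth of the dominant protrusion/depression pair
#'
#' Mean absolute radius-normalized deviation over the dominant outward region
#' plus the same over its paired inward depression (each a ratio relative to
#' the ellipsoid radius in the point's direction).
#'
#' @param field a [ResidualField-class].
#' @param result an asymmetric [AsymmetryResult-class].
#' @return dimensionless depth >= 0.
#' @export
computeProtrusionDepth <- function(field, result) {
  if (!result@isAsymmetric)
    stop("protrusion depth is defined only for asymmetric (group 2) eyes")
  mean(abs(field@signedRatio[result@outwardRegion@members])) +
    mean(abs(field@signedRatio[result@inwardRegion@members]))
}

#' Run the full asymmetry analysis for one posterior cloud
#'
#' Convenience wrapper: fit (unless supplied), residual field, segmentation,
#' classification.
#'
#' @param cloud posterior [EyePointCloud-class].
#' @param fit optional precomputed [EllipsoidFit-class].
#' @param ... passed to [classifyAsymmetry()].
#' @param magnitudeFloor passed to [segmentRegions()].
#' @return an [AsymmetryResult-class].
#' @export
analyzeAsymmetry <- function(cloud, fit = NULL, magnitudeFloor = 1.0,
                             poleCapDeg = 35, ...) {
  if (is.null(fit)) fit <- fitEllipsoid(cloud@points)
  field <- residualField(cloud, fit)
  classifyAsymmetry(segmentRegions(field, magnitudeFloor, poleCapDeg),
                    field, ...)
}
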