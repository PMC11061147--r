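#' @import methods
#' @importFrom stats coef cor cor.test chisq.test t.test rnorm runif rbinom
#'   qnorm pnorm sd var median setNames quantile binomial optim lm
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Ellipsoid as a normalized quadric with derived geometry
#'
#' An implicit second-order surface \eqn{ax^2+by^2+cz^2+dx+ey+fz+gxy+hyz+izx+j=0}
#' restricted to real ellipsoids.  The coefficient vector is stored in a fixed
#' gauge: the quadratic-form matrix has trace 3 and the polynomial is negative
#' at the center, so the 10-tuple is unique.  The geometric description
#' (center, semi-axes sorted descending, rotation with principal directions as
#' rows) is derived once and kept in sync by the constructors.
#'
#' @slot coefficients named numeric(10): a, b, c, d, e, f, g, h, i, j.
#' @slot center numeric(3), mm.
#' @slot semiAxes numeric(3), mm, sorted descending.
#' @slot orientation 3x3 rotation matrix, rows are the principal directions
#'   matching \code{semiAxes}; determinant +1.
#'
#' @seealso [ellipsoidFromGeometry()], [ellipsoidFromQuadric()]
#' @export
setClass("EllipsoidModel",
  representation(coefficients = "numeric", center = "numeric",
                 semiAxes = "numeric", orientation = "matrix"))

setValidity("EllipsoidModel", function(object) {
  msg <- character()
  k <- object@coefficients
  if (length(k) != 10L) msg <- c(msg, "coefficients must have length 10")
  A <- .quadraticForm(k)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) msg <- c(msg, "quadratic form is not positive definite")
  if (abs(sum(diag(A)) - 3) > 1e-6) msg <- c(msg, "coefficient gauge violated (trace != 3)")
  if (any(object@semiAxes <= 0)) msg <- c(msg, "semiAxes must be positive")
  if (is.unsorted(rev(object@semiAxes))) msg <- c(msg, "semiAxes must be sorted descending")
  R <- object@orientation
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) msg <- c(msg, "orientation not orthonormal")
  if (det(R) < 0) msg <- c(msg, "orientation must have determinant +1")
  if (length(msg)) msg else TRUE
})

#' Result of an optimal ellipsoid fit
#'
#' @slot model the fitted [EllipsoidModel-class].
#' @slot rmse dimensionless root-mean-square of the radius-normalized signed
#'   residuals (Euclidean distance divided by the center-to-surface radius in
#'   the point's direction).
#' @slot nPoints number of points used.
#' @slot converged did the simplex optimizer report convergence.
#' @slot nRestarts number of jittered restarts consumed.
#' @export
setClass("EllipsoidFit",
  representation(model = "EllipsoidModel", rmse = "numeric",
                 nPoints = "integer", converged = "logical",
                 nRestarts = "integer"))

setValidity("EllipsoidFit", function(object) {
  if (object@rmse < 0) "rmse must be >= 0" else TRUE
})

#' Posterior eye contour points in the standardized eye frame
#'
#' Points are in mm.  After [standardizeFrame()] the visual axis (lens center
#' to optic nerve head) is +z with the posterior pole at large z, superior is
#' +y, and left eyes are mirrored so nasal is +x for every eye (right-eye
#' orientation).
#'
#' @slot points n x 3 matrix, mm.
#' @slot laterality "right" or "left" (of the source eye).
#' @slot lensCenter,onhCenter,fovea,bmoPoint numeric(3) landmarks, mm.
#' @slot visualAxis unit numeric(3); +z after standardization.
#' @slot standardized logical flag.
#' @export
setClass("EyePointCloud",
  representation(points = "matrix", laterality = "character",
                 lensCenter = "numeric", onhCenter = "numeric",
                 fovea = "numeric", bmoPoint = "numeric",
                 visualAxis = "numeric", standardized = "logical"))

setValidity("EyePointCloud", function(object) {
  msg <- character()
  if (ncol(object@points) != 3L) msg <- c(msg, "points must be n x 3")
  if (!object@laterality %in% c("right", "left"))
    msg <- c(msg, "laterality must be 'right' or 'left'")
  if (abs(sqrt(sum(object@visualAxis^2)) - 1) > 1e-6)
    msg <- c(msg, "visualAxis must be a unit vector")
  if (length(msg)) msg else TRUE
})

#' Voxelized scan volume
#'
#' @slot intensities 3D numeric array.
#' @slot spacing numeric(3) voxel spacing, mm.
#' @slot axisLabels character(3) anatomical orientation tags.
#' @slot meta list for provenance (phantom truth, landmarks, ...).
#' @export
setClass("VoxelVolume",
  representation(intensities = "array", spacing = "numeric",
                 axisLabels = "character", meta = "list"))

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@intensities)) != 3L) msg <- c(msg, "intensities must be 3D")
  if (any(dim(object@intensities) < 1L)) msg <- c(msg, "grid must be non-empty")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values")
  if (length(msg)) msg else TRUE
})

#' Signed radial residual field over the posterior contour
#'
#' One signed, radius-normalized residual per retained contour point
#' (positive = outside the fitted ellipsoid), together with area weights and
#' the projected fovea/BMO directions in the posterior polar plane.
#'
#' @slot cloud the posterior [EyePointCloud-class].
#' @slot fit the [EllipsoidFit-class] obtained from the same cloud.
#' @slot signedRatio numeric(n) signed distance ratios.
#' @slot areaWeight numeric(n) Voronoi-like surface-area weights.
#' @slot foveaDir,bmoDir unit numeric(2) projections onto the posterior polar
#'   plane (relative to the projected ellipsoid center).
#' @slot knn n x k matrix of nearest-neighbor indices (surface adjacency
#'   graph used for region growing and adjacency tests).
#' @export
setClass("ResidualField",
  representation(cloud = "EyePointCloud", fit = "EllipsoidFit",
                 signedRatio = "numeric", areaWeight = "numeric",
                 foveaDir = "numeric", bmoDir = "numeric", knn = "matrix"))

setValidity("ResidualField", function(object) {
  if (length(object@signedRatio) != nrow(object@cloud@points))
    "one residual per contour point required" else TRUE
})

#' A connected suprathreshold protrusion or depression region
#'
#' @slot polarity "outward" or "inward".
#' @slot members integer indices into the residual field.
#' @slot areaFraction fraction of the posterior-pole surface area.
#' @slot meanRatio mean absolute signed ratio over members.
#' @slot centroidAngle degrees from the nasal fovea-BMO axis, positive superior.
#' @export
setClass("ProtrusionRegion",
  representation(polarity = "character", members = "integer",
                 areaFraction = "numeric", meanRatio = "numeric",
                 centroidAngle = "numeric"))

setValidity("ProtrusionRegion", function(object) {
  msg <- character()
  if (!object@polarity %in% c("outward", "inward"))
    msg <- c(msg, "polarity must be 'outward' or 'inward'")
  if (object@areaFraction <= 0 || object@areaFraction > 1)
    msg <- c(msg, "areaFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

setClassUnion("ProtrusionRegionOrNULL", c("ProtrusionRegion", "NULL"))

#' Eyeball asymmetry classification result
#'
#' Group 2 (asymmetric) requires a single dominant outward protrusion with an
#' immediately adjacent reciprocal inward depression whose joint area exceeds
#' half the posterior pole.  The outermost protruded point (OPP) angle and the
#' protrusion depth are defined only for asymmetric eyes.
#'
#' @slot isAsymmetric logical (TRUE = group 2).
#' @slot oppAngle degrees in (-180, 180], 0 = nasal side of the fovea-BMO
#'   axis, positive = superior; NA for group 1.
#' @slot protrusionDepth dimensionless; NA for group 1.
#' @slot rmse fit RMSE carried over.
#' @slot outwardRegion,inwardRegion the dominant pair, or NULL for group 1.
#' @export
setClass("AsymmetryResult",
  representation(isAsymmetric = "logical", oppAngle = "numeric",
                 protrusionDepth = "numeric", rmse = "numeric",
                 outwardRegion = "ProtrusionRegionOrNULL",
                 inwardRegion = "ProtrusionRegionOrNULL"))

setValidity("AsymmetryResult", function(object) {
  msg <- character()
  if (object@isAsymmetric) {
    if (is.na(object@oppAngle) || is.na(object@protrusionDepth))
      msg <- c(msg, "asymmetric eyes must carry oppAngle and protrusionDepth")
    if (!is.na(object@protrusionDepth) && object@protrusionDepth < 0)
      msg <- c(msg, "protrusionDepth must be >= 0")
  } else {
    if (!is.na(object@oppAngle) || !is.na(object@protrusionDepth))
      msg <- c(msg, "group-1 eyes must not carry oppAngle or protrusionDepth")
  }
  if (length(msg)) msg else TRUE
})

#' 2D optic-nerve-head scene around the Bruch's membrane opening
#'
#' Coordinates are image pixels in a mathematical frame (+x nasal after
#' mirroring, +y superior).  Landmarks are consumed as human-marked inputs,
#' never detected.
#'
#' @slot marginPoints n x 2 matrix of BMO margin points (>= 5).
#' @slot crvt numeric(2) central retinal vascular trunk position, or NA.
#' @slot crvtVisible logical.
#' @slot fovea numeric(2).
#' @slot laterality "right" or "left".
#' @slot eobMeridian degrees (longest externally oblique border), or NA.
#' @slot ppaPoint numeric(2) maximal beta-zone PPA width meridian point, or NA.
#' @slot scale mm per pixel, or NA.
#' @export
setClass("BMOScene",
  representation(marginPoints = "matrix", crvt = "numeric",
                 crvtVisible = "logical", fovea = "numeric",
                 laterality = "character", eobMeridian = "numeric",
                 ppaPoint = "numeric", scale = "numeric"))

setValidity("BMOScene", function(object) {
  msg <- character()
  if (nrow(object@marginPoints) < 5L)
    msg <- c(msg, "at least 5 BMO margin points required (ellipse has 5 dof)")
  if (ncol(object@marginPoints) != 2L) msg <- c(msg, "marginPoints must be n x 2")
  if (!object@laterality %in% c("right", "left"))
    msg <- c(msg, "laterality must be 'right' or 'left'")
  if (length(msg)) msg else TRUE
})

#' LC/BMO offset metrics
#'
#' @slot offsetAngle degrees in (-180, 180], 0 = nasal fovea-BMO axis,
#'   positive superior; NA when the CRVT coincides with the BMO center.
#' @slot offsetIndex a/b in [0, 1].
#' @slot bmoCenter numeric(2).
#' @slot bmoSemiAxes numeric(2), px.
#' @slot bmoTilt degrees.
#' @slot bmoArea mm^2 when a scale was supplied, else px^2.
#' @slot ppaAngle degrees from the temporal horizontal midline, or NA.
#' @slot clipped TRUE when a visible CRVT fell outside the fitted ellipse and
#'   the index was clipped to 1.
#' @export
setClass("OffsetResult",
  representation(offsetAngle = "numeric", offsetIndex = "numeric",
                 bmoCenter = "numeric", bmoSemiAxes = "numeric",
                 bmoTilt = "numeric", bmoArea = "numeric",
                 ppaAngle = "numeric", clipped = "logical"))

setValidity("OffsetResult", function(object) {
  if (!is.na(object@offsetIndex) &&
      (object@offsetIndex < 0 || object@offsetIndex > 1))
    "offsetIndex must lie in [0, 1]" else TRUE
})
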