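# Quadric <-> geometric representation of ellipsoids.
#
# Coefficient order throughout: (a, b, c, d, e, f, g, h, i, j) in
#   a x^2 + b y^2 + c z^2 + d x + e y + f z + g xy + h yz + i zx + j = 0.
# Gauge: trace of the quadratic form fixed at 3, polynomial negative at the
# center.  This removes the one-parameter scale freedom and makes the interior
# sign (negative inside / positive outside) unambiguous.

.coefNames <- c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j")

.quadraticForm <- function(k) {
  matrix(c(k[1], k[7] / 2, k[9] / 2,
           k[7] / 2, k[2], k[8] / 2,
           k[9] / 2, k[8] / 2, k[3]), 3, 3, byrow = TRUE)
}

# Normalize a raw coefficient vector into the package gauge; returns NULL on
# non-ellipsoid input together with an attribute-free diagnosis via `details`.
.normalizeQuadric <- function(k, details = FALSE) {
  A <- .quadraticForm(k)
  if (sum(diag(A)) < 0) { k <- -k; A <- -A }
  eg <- eigen(A, symmetric = TRUE)
  if (any(eg$values <= 0)) {
    if (details) return(list(ok = FALSE, eigenvalues = eg$values))
    return(NULL)
  }
  s <- 3 / sum(eg$values)
  k <- k * s
  A <- A * s
  bvec <- k[4:6]
  center <- drop(-solve(A, bvec) / 2)
  kappa <- drop(center %*% A %*% center) - k[10]
  if (kappa <= 0) {
    if (details) return(list(ok = FALSE, eigenvalues = eg$values * s, kappa = kappa))
    return(NULL)
  }
  lam <- eg$values * s
  ord <- order(lam)                      # ascending eigenvalue = descending axis
  semi <- sqrt(kappa / lam[ord])
  R <- t(eg$vectors[, ord, drop = FALSE])
  if (det(R) < 0) R[3, ] <- -R[3, ]
  # canonical row signs for reproducibility
  for (r in 1:2) {
    piv <- which.max(abs(R[r, ]))
    if (R[r, piv] < 0) { R[r, ] <- -R[r, ]; R[3, ] <- -R[3, ] }
  }
  list(ok = TRUE, coefficients = setNames(k, .coefNames), center = center,
       semiAxes = semi, orientation = R, kappa = kappa)
}

#' Build an ellipsoid model from quadric coefficients
#'
#' @param coefficients numeric(10) in the order a, b, c, d, e, f, g, h, i, j
#'   of \eqn{ax^2+by^2+cz^2+dx+ey+fz+gxy+hyz+izx+j=0}.  Any overall scale is
#'   accepted; the stored vector is renormalized to the package gauge.
#' @return an [EllipsoidModel-class].
#' @examples
#' ellipsoidFromQuadric(c(1, 1, 1, 0, 0, 0, 0, 0, 0, -1))  # unit sphere
#' @export
ellipsoidFromQuadric <- function(coefficients) {
  stopifnot(length(coefficients) == 10L, all(is.finite(coefficients)))
  g <- .normalizeQuadric(coefficients, details = TRUE)
  if (!isTRUE(g$ok)) {
    stop("coefficients do not describe a real ellipsoid (eigenvalue signs: ",
         paste(sprintf("%+d", sign(g$eigenvalues)), collapse = ", "), ")")
  }
  new("EllipsoidModel", coefficients = g$coefficients, center = g$center,
      semiAxes = g$semiAxes, orientation = g$orientation)
}

#' Build an ellipsoid model from center, semi-axes and orientation
#'
#' @param center numeric(3), mm.
#' @param semiAxes numeric(3) positive semi-axis lengths, mm (any order).
#' @param orientation 3x3 rotation matrix whose rows are the principal
#'   directions matching \code{semiAxes}; defaults to the identity.
#' @return an [EllipsoidModel-class].
#' @examples
#' ellipsoidFromGeometry(c(0, 0, 0), c(12.5, 12, 11.5))
#' @export
ellipsoidFromGeometry <- function(center, semiAxes, orientation = diag(3)) {
  stopifnot(length(center) == 3L, length(semiAxes) == 3L, all(semiAxes > 0))
  ellipsoidFromQuadric(geometricToQuadric(center, semiAxes, orientation))
}

#' Convert between quadric coefficients and geometric parameters
#'
#' `quadricToGeometric()` eigendecomposes the quadratic form; the round trip
#' geometric -> quadric -> geometric is the identity to near machine precision.
#'
#' @param coefficients numeric(10) quadric coefficients.
#' @return `quadricToGeometric()`: a list with `center`, `semiAxes` (sorted
#'   descending, mm) and `orientation` (rows = principal directions).
#' @examples
#' quadricToGeometric(c(1/4, 1, 1, 0, 0, 0, 0, 0, 0, -1))$semiAxes  # 2 1 1
#' @export
quadricToGeometric <- function(coefficients) {
  m <- ellipsoidFromQuadric(coefficients)
  list(center = m@center, semiAxes = m@semiAxes, orientation = m@orientation)
}

#' @rdname quadricToGeometric
#' @inheritParams ellipsoidFromGeometry
#' @return `geometricToQuadric()`: a named numeric(10) in the package gauge.
#' @export
geometricToQuadric <- function(center, semiAxes, orientation = diag(3)) {
  stopifnot(length(center) == 3L, length(semiAxes) == 3L, all(semiAxes > 0))
  R <- orientation
  A <- crossprod(R * (1 / semiAxes^2), R)   # t(R) %*% diag(1/s^2) %*% R
  bvec <- drop(-2 * A %*% center)
  j0 <- drop(center %*% A %*% center) - 1
  k <- c(A[1, 1], A[2, 2], A[3, 3], bvec, 2 * A[1, 2], 2 * A[2, 3], 2 * A[1, 3], j0)
  s <- 3 / sum(diag(A))
  setNames(k * s, .coefNames)
}

#' Evaluate the quadric polynomial at points
#'
#' Negative inside the ellipsoid, zero on the surface, positive outside
#' (guaranteed by the stored gauge).
#'
#' @param model an [EllipsoidModel-class].
#' @param points numeric(3) or an n x 3 matrix, mm.
#' @return numeric vector of polynomial values.
#' @examples
#' s <- ellipsoidFromQuadric(c(1, 1, 1, 0, 0, 0, 0, 0, 0, -1))
#' evaluateQuadric(s, rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
#' @export
evaluateQuadric <- function(model, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  k <- model@coefficients
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  k[1] * x^2 + k[2] * y^2 + k[3] * z^2 + k[4] * x + k[5] * y + k[6] * z +
    k[7] * x * y + k[8] * y * z + k[9] * z * x + k[10]
}

#' Center-to-surface radius of an ellipsoid along given directions
#'
#' @param model an [EllipsoidModel-class].
#' @param directions numeric(3) or n x 3 matrix of directions (need not be
#'   unit length).
#' @return numeric vector of radii, mm.
#' @export
ellipsoidRadius <- function(model, directions) {
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3)
  U <- directions / sqrt(rowSums(directions^2))
  V <- U %*% t(model@orientation)        # principal-frame components
  1 / sqrt(rowSums(sweep(V, 2, model@semiAxes, "/")^2))
}

#' Serialize an ellipsoid fit to a JSON record
#'
#' @param fit an [EllipsoidFit-class] or [EllipsoidModel-class].
#' @return a JSON string with coefficients, center, semiAxes, orientation and
#'   (for fits) rmse.
#' @export
modelToJSON <- function(fit) {
  m <- if (is(fit, "EllipsoidFit")) fit@model else fit
  rec <- list(coefficients = as.list(m@coefficients),
              center = m@center, semi_axes = m@semiAxes,
              orientation = m@orientation)
  if (is(fit, "EllipsoidFit")) rec$rmse <- fit@rmse
  jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE)
}
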