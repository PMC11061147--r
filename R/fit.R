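# Optimal ellipsoid fit: Nelder-Mead minimisation of the sum of squared exact
# Euclidean point-to-surface distances, seeded by an algebraic least-squares
# quadric.  The simplex works on 9 free coefficients (a, b, d, e, f, g, h, i,
# j) with c = 3 - a - b enforcing the trace gauge, so the scale freedom of the
# quadric never enters the search.  Excursions outside ellipsoid space are
# penalized by 1e6 times the summed magnitude of offending eigenvalues, which
# keeps the simplex inside the positive-definite cone.

.thetaToCoef <- function(theta) {
  c(theta[1], theta[2], 3 - theta[1] - theta[2], theta[3:9])
}

.coefToTheta <- function(k) k[-3]

.algebraicSeed <- function(P) {
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  D <- cbind(x^2, y^2, z^2, x, y, z, x * y, y * z, z * x, 1)
  v <- svd(D, nu = 0)$v[, 10]
  g <- .normalizeQuadric(v)
  if (!is.null(g)) return(g$coefficients)
  # algebraic quadric is not an ellipsoid: fall back to a least-squares sphere
  rhs <- -(x^2 + y^2 + z^2)
  beta <- qr.coef(qr(cbind(x, y, z, 1)), rhs)
  g <- .normalizeQuadric(c(1, 1, 1, beta[1:3], 0, 0, 0, beta[4]))
  g$coefficients
}

# Squared distances without constructing (and validity-checking) an S4 model;
# this sits in the optimizer's inner loop.
.sumSqDistance <- function(g, P) {
  Y <- sweep(P, 2, g$center) %*% t(g$orientation)
  sol <- .footParameter(g$semiAxes, Y)
  D <- outer(sol$t, g$semiAxes^2, "+")
  Yf <- sweep(sol$Y, 2, g$semiAxes^2, "*") / D
  sum((sol$Y - Yf)^2)
}

.fitCost <- function(theta, P) {
  k <- .thetaToCoef(theta)
  g <- .normalizeQuadric(k, details = TRUE)
  if (!isTRUE(g$ok)) {
    pen <- sum(pmax(0, -g$eigenvalues))
    if (!is.null(g$kappa)) pen <- pen + max(0, -g$kappa)
    return(1e4 + 1e6 * pen)
  }
  d2 <- tryCatch(.sumSqDistance(g, P), error = function(e) NULL)
  if (is.null(d2)) return(1e4)
  d2
}

#' Fit the optimal ellipsoid to a 3D point cloud
#'
#' Minimizes the sum of squared exact Euclidean distances between the points
#' and the ellipsoid surface with the Nelder-Mead simplex, initialized from an
#' algebraic least-squares quadric fit.  If the optimizer fails to converge or
#' leaves ellipsoid space, up to `maxRestarts` restarts with +/-5% jitter on
#' the seed coefficients are attempted; the best valid solution wins.
#'
#' @param points n x 3 matrix of contour points, mm; at least 9 non-coplanar
#'   points are required (10 coefficients minus the scale gauge).
#' @param maxRestarts maximum number of jittered restarts (default 5).
#' @param seed integer seed for the restart jitter (default 20240430).
#' @param reltol relative tolerance on the cost spread across the simplex.
#'   The default 1e-8 sits just above the numerical noise floor of the exact
#'   distance evaluations; tightening it further makes the simplex chase
#'   round-off.
#' @param maxit cap on cost-function evaluations per (re)start.
#' @return an [EllipsoidFit-class]; its `rmse` is the root mean square of the
#'   radius-normalized signed residuals (dimensionless), matching the scale on
#'   which protrusion depth is expressed.
#' @examples
#' truth <- ellipsoidFromGeometry(c(1, -2, 0.5), c(12.5, 12, 11.5))
#' u <- matrix(rnorm(600), ncol = 3)
#' u <- u / sqrt(rowSums(u^2))
#' p <- sweep(u * ellipsoidRadius(truth, u), 2, ellipsoidCenter(truth), "+")
#' fit <- fitEllipsoid(p)
#' semiAxes(fit)
#' @export
fitEllipsoid <- function(points, maxRestarts = 5L, seed = 20240430L,
                         reltol = 1e-8, maxit = 4000L) {
  if (is.null(dim(points))) stop("points must be an n x 3 matrix")
  P <- as.matrix(points)
  if (nrow(P) < 9L)
    stop("at least 9 points are required to determine an ellipsoid")
  sv <- svd(sweep(P, 2, colMeans(P)), nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * sv[1])
    stop("degenerate input: points are (near-)coplanar")

  seedCoef <- .algebraicSeed(P)
  best <- NULL
  nUsed <- 0L
  for (attempt in 0:maxRestarts) {
    theta0 <- .coefToTheta(seedCoef)
    if (attempt > 0L) {
      theta0 <- .withSeed(seed + attempt,
                          theta0 * (1 + runif(9, -0.05, 0.05)))
      nUsed <- attempt
    }
    # tight initial simplex around the algebraic seed: the seed is close, so
    # a ~1% step converges far faster than a blind 10% simplex
    # absolute cost floor: a cost this small means residual ratios ~1e-7 of
    # the radius, i.e. an exact-interpolation fit; scale-aware so rmse stays
    # scale-invariant
    r2 <- mean(rowSums(sweep(P, 2, colMeans(P))^2))
    opt <- .nelderMead(function(th) .fitCost(th, P), theta0,
                       step = pmax(abs(theta0), 0.05) * 0.01,
                       reltol = reltol, stol = 1e-6,
                       abstol = 1e-14 * nrow(P) * r2, maxeval = maxit)
    g <- .normalizeQuadric(.thetaToCoef(opt$par))
    valid <- !is.null(g)
    if (valid && (is.null(best) || opt$value < best$value)) {
      best <- list(value = opt$value, g = g, converged = opt$converged)
    }
    if (!is.null(best) && best$converged) break
  }
  if (is.null(best))
    stop("optimizer failed to find an ellipsoid after ", maxRestarts,
         " restarts (penalized non-ellipsoid quadrics)")
  m <- new("EllipsoidModel", coefficients = best$g$coefficients,
           center = best$g$center, semiAxes = best$g$semiAxes,
           orientation = best$g$orientation)
  ratio <- distanceToEllipsoid(m, P)$signedRatio
  new("EllipsoidFit", model = m, rmse = sqrt(mean(ratio^2)),
      nPoints = nrow(P), converged = best$converged, nRestarts = nUsed)
}
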