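# Exact Euclidean point-to-ellipsoid distance.
#
# In the principal frame the foot point of p = (y1,y2,y3) on the ellipsoid
# sum (x_j/s_j)^2 = 1 satisfies x_j = s_j^2 y_j / (s_j^2 + t) for the unique
# root t of F(t) = sum (s_j y_j)^2 / (s_j^2 + t)^2 - 1 = 0 on
# (-min(s)^2, Inf): t > 0 outside, t < 0 inside.  F is strictly decreasing on
# the bracket, so a bisection-safeguarded Newton iteration is globally
# convergent.  The solver is vectorized across points.

.footParameter <- function(s, Y, tol = 1e-10, maxit = 200L) {
  s2 <- s^2
  smin2 <- min(s2)
  # measure-zero degeneracy: points exactly on a principal plane of the
  # smallest axis; nudge off the plane (error << tol in the distance)
  eps <- 1e-12 * s
  for (j in 1:3) {
    zi <- abs(Y[, j]) < eps[j]
    Y[zi, j] <- eps[j]
  }
  Z <- t.default(Y)                               # 3 x n: s2 recycles by row
  num <- s2 * Z^2                                 # (s_j y_j)^2
  g <- .colSums(Z^2 / s2, 3L, ncol(Z))
  outside <- g > 1
  ynorm <- sqrt(.colSums(Z^2, 3L, ncol(Z)))
  lo <- ifelse(outside, 0, -smin2 * (1 - 1e-9))
  hi <- ifelse(outside, max(s) * ynorm + smin2, 0)
  tpar <- (lo + hi) / 2
  on <- abs(g - 1) < 1e-14                        # already on the surface
  tpar[on] <- 0
  lo[on] <- 0; hi[on] <- 0
  conv <- FALSE
  for (it in seq_len(maxit)) {
    D <- rep(tpar, each = 3L) + s2
    Fv <- .colSums(num / D^2, 3L, length(tpar)) - 1
    pos <- Fv > 0
    lo[pos] <- tpar[pos]
    hi[!pos] <- tpar[!pos]
    if (all(abs(Fv) < 1e-13 | (hi - lo) < tol * 1e-3)) { conv <- TRUE; break }
    Fp <- -2 * .colSums(num / D^3, 3L, length(tpar))
    tn <- tpar - Fv / Fp
    bad <- !is.finite(tn) | tn <= lo | tn >= hi
    tn[bad] <- (lo[bad] + hi[bad]) / 2
    tpar <- tn
  }
  if (!conv) {
    D <- rep(tpar, each = 3L) + s2
    Fv <- .colSums(num / D^2, 3L, length(tpar)) - 1
    worst <- which(!(abs(Fv) < 1e-13 | (hi - lo) < tol * 1e-3))
    if (length(worst))
      stop("point-to-ellipsoid distance did not converge for point(s) ",
           paste(utils::head(worst, 3L), collapse = ", "))
  }
  list(t = tpar, Y = Y)
}

#' Exact Euclidean distance from points to an ellipsoid surface
#'
#' Computes, for each point, the minimal Euclidean distance to the surface,
#' the foot point realizing it, and the signed radius-normalized ratio
#' (distance divided by the center-to-surface radius in the point's direction,
#' positive outside).  The root is found by a bisection-safeguarded Newton
#' iteration in the principal frame (tolerance 1e-10 mm).
#'
#' @param model an [EllipsoidModel-class].
#' @param points numeric(3) or n x 3 matrix, mm.
#' @return a list with `distance` (mm, >= 0), `foot` (n x 3, on the surface)
#'   and `signedRatio` (dimensionless; sign matches [evaluateQuadric()]).
#' @examples
#' e <- ellipsoidFromGeometry(c(0, 0, 0), c(2, 1, 1))
#' distanceToEllipsoid(e, c(3, 0, 0))
#' @export
distanceToEllipsoid <- function(model, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  s <- model@semiAxes
  R <- model@orientation
  Y <- sweep(points, 2, model@center) %*% t(R)
  ynorm <- sqrt(rowSums(Y^2))
  central <- ynorm < 1e-12 * min(s)
  # points numerically at the center: nearest surface point is the smallest
  # axis tip; the direction for the ratio is taken along that axis
  Y[central, ] <- 0
  Y[central, 3] <- 1e-11 * min(s)
  sol <- .footParameter(s, Y)
  D <- outer(sol$t, s^2, "+")
  Yf <- sweep(sol$Y, 2, s^2, "*") / D
  dist <- sqrt(rowSums((sol$Y - Yf)^2))
  foot <- sweep(Yf %*% R, 2, model@center, "+")
  radius <- ellipsoidRadius(model, sol$Y %*% R)
  sgn <- sign(sol$t)
  ratio <- sgn * dist / radius
  list(distance = dist, foot = foot, signedRatio = ratio)
}
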