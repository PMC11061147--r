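# Small shared helpers: circular arithmetic and seeded evaluation.

#' Wrap angles to (-180, 180] degrees
#'
#' All angular quantities in the package (OPP angle, LC/BMO offset angle, PPA
#' angle, EOB meridian) live on this branch; wraparound is handled here so the
#' convention is applied uniformly.
#'
#' @param x angles in degrees.
#' @return angles wrapped to (-180, 180].
#' @examples
#' wrapAngle(c(-180, 270, 90))
#' @export
wrapAngle <- function(x) {
  w <- x %% 360
  w[!is.na(w) & w > 180] <- w[!is.na(w) & w > 180] - 360
  w
}

# Signed angle (degrees) from 2-vector `ref` to each row of `v` (n x 2),
# positive counterclockwise (toward +y when ref is +x).
.signedAngle2 <- function(ref, v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 2)
  deg <- atan2(ref[1] * v[, 2] - ref[2] * v[, 1],
               ref[1] * v[, 1] + ref[2] * v[, 2]) * 180 / pi
  wrapAngle(deg)
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# Rotation matrix from intrinsic z-y-x Euler angles (degrees).
.eulerRotation <- function(yaw, pitch, roll) {
  cz <- cos(yaw * pi / 180); sz <- sin(yaw * pi / 180)
  cy <- cos(pitch * pi / 180); sy <- sin(pitch * pi / 180)
  cx <- cos(roll * pi / 180); sx <- sin(roll * pi / 180)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Minimal rotation taking unit vector `a` onto unit vector `b` (Rodrigues).
.rotationBetween <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth > 1 - 1e-12) return(diag(3))
  if (cth < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to a
    e <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- .unit(e - sum(e * a) * a)
    return(2 * outer(axis, axis) - diag(3))
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K / (1 + cth)
}
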