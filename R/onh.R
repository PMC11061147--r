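# LC/BMO offset metrics from a 2D optic-nerve-head scene.
#
# Scene coordinates are treated mathematically: after mirroring left eyes,
# nasal is +x-ward and superior +y-ward.  The offset angle uses the nasal
# fovea-BMO axis as 0 degrees with positive values toward superior (for the
# nasal reference this is counterclockwise); the PPA angle uses the temporal
# horizontal midline as 0 degrees, again positive toward superior (for the
# temporal reference, clockwise).  Both conventions are therefore intrinsic
# and independent of image handedness.

#' Construct a BMO scene
#'
#' @param marginPoints n x 2 matrix of BMO margin points (>= 5), image px.
#' @param fovea numeric(2) fovea position, px.
#' @param crvt numeric(2) CRVT position, or NULL/NA when not visible.
#' @param crvtVisible logical; defaults to TRUE when `crvt` is given.
#' @param laterality "right" or "left".
#' @param eobMeridian longest externally-oblique-border meridian, degrees in
#'   the nasal-axis convention, or NA.
#' @param ppaPoint numeric(2) meridian point of maximal beta-zone PPA width,
#'   or NA.
#' @param scale mm per px, or NA (areas then reported in px^2).
#' @return a [BMOScene-class].
#' @export
bmoScene <- function(marginPoints, fovea, crvt = NULL,
                     crvtVisible = !is.null(crvt) && all(is.finite(crvt)),
                     laterality = "right", eobMeridian = NA_real_,
                     ppaPoint = c(NA_real_, NA_real_), scale = NA_real_) {
  if (is.null(crvt)) crvt <- c(NA_real_, NA_real_)
  new("BMOScene", marginPoints = as.matrix(marginPoints),
      crvt = as.numeric(crvt), crvtVisible = isTRUE(crvtVisible),
      fovea = as.numeric(fovea), laterality = laterality,
      eobMeridian = as.numeric(eobMeridian),
      ppaPoint = as.numeric(ppaPoint), scale = as.numeric(scale))
}

#' Direct least-squares ellipse fit to BMO margin points
#'
#' Fitzgibbon's ellipse-constrained conic fit (numerically stable
#' Halir-Flusser block formulation): always returns an ellipse when the
#' points admit one.
#'
#' @param marginPoints n x 2 matrix, n >= 5 and not collinear.
#' @return list with `center` (2), `semiAxes` (major, minor), `tilt`
#'   (degrees of the major axis, (-90, 90]).
#' @export
fitBMOEllipse <- function(marginPoints) {
  P <- as.matrix(marginPoints)
  if (nrow(P) < 5L)
    stop("an ellipse has 5 degrees of freedom; at least 5 points required")
  x <- P[, 1] - mean(P[, 1]); y <- P[, 2] - mean(P[, 2])
  sv <- svd(cbind(x, y), nu = 0, nv = 0)$d
  if (sv[2] < 1e-10 * sv[1]) stop("margin points are (near-)collinear")
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  ok <- which(Re(4 * eg$vectors[1, ] * eg$vectors[3, ] - eg$vectors[2, ]^2) > 0 &
              abs(Im(eg$values)) < 1e-8)
  if (!length(ok)) stop("degenerate conic: no ellipse solution")
  a1 <- Re(eg$vectors[, ok[1]])
  conic <- c(a1, drop(Tm %*% a1))      # A, B, C, D, E, F (centered coords)
  A <- conic[1]; B <- conic[2]; C <- conic[3]
  Dc <- conic[4]; E <- conic[5]; Fc <- conic[6]
  AQ <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ctr <- drop(solve(2 * AQ, -c(Dc, E)))
  # conic value at the center; centered form is (x-c)' AQ (x-c) = -Q(c)
  Qc <- A * ctr[1]^2 + B * ctr[1] * ctr[2] + C * ctr[2]^2 +
    Dc * ctr[1] + E * ctr[2] + Fc
  kappa <- -Qc
  eg2 <- eigen(AQ, symmetric = TRUE)
  if (all(eg2$values < 0)) { eg2$values <- -eg2$values; kappa <- -kappa }
  if (any(eg2$values <= 0) || kappa <= 0) stop("degenerate conic: not an ellipse")
  ord <- order(eg2$values)               # ascending eigenvalue = major axis
  semi <- sqrt(kappa / eg2$values[ord])  # descending semi-axes
  major <- eg2$vectors[, ord[1]]
  tilt <- atan2(major[2], major[1]) * 180 / pi
  if (tilt <= -90) tilt <- tilt + 180
  if (tilt > 90) tilt <- tilt - 180
  list(center = ctr + c(mean(P[, 1]), mean(P[, 2])),
       semiAxes = semi, tilt = tilt)
}

# distance from the ellipse center to the margin along unit direction d
.rayEllipseDistance <- function(semiAxes, tilt, d) {
  th <- tilt * pi / 180
  e1 <- c(cos(th), sin(th)); e2 <- c(-sin(th), cos(th))
  1 / sqrt((sum(d * e1) / semiAxes[1])^2 + (sum(d * e2) / semiAxes[2])^2)
}

.mirrorScene <- function(scene) {
  scene@marginPoints[, 1] <- -scene@marginPoints[, 1]
  scene@fovea[1] <- -scene@fovea[1]
  if (all(is.finite(scene@crvt))) scene@crvt[1] <- -scene@crvt[1]
  if (all(is.finite(scene@ppaPoint))) scene@ppaPoint[1] <- -scene@ppaPoint[1]
  # the EOB meridian is intrinsic (nasal-referenced) and unchanged by mirroring
  scene@laterality <- "right"
  scene
}

#' Compute the LC/BMO offset metrics for a scene
#'
#' Fits the BMO margin ellipse, then measures the CRVT deviation from the BMO
#' center: `a` = CRVT-to-center distance, `b` = center-to-margin distance
#' along the same ray (ray-conic intersection), offset index = a/b, and the
#' angular deviation from the nasal fovea-BMO axis (positive superior).  For
#' an invisible CRVT the rule of [handleInvisibleCRVT()] applies.
#'
#' @param scene a [BMOScene-class]; left eyes are mirrored internally.
#' @return an [OffsetResult-class].
#' @export
computeOffset <- function(scene) {
  if (!scene@crvtVisible) return(handleInvisibleCRVT(scene))
  if (scene@laterality == "left") scene <- .mirrorScene(scene)
  ell <- fitBMOEllipse(scene@marginPoints)
  nasal <- .unit(ell$center - scene@fovea)
  v <- scene@crvt - ell$center
  a <- sqrt(sum(v^2))
  scaleRef <- sqrt(prod(ell$semiAxes))
  if (a < 1e-9 * scaleRef) {
    idx <- 0; ang <- NA_real_; clipped <- FALSE
  } else {
    d <- v / a
    b <- .rayEllipseDistance(ell$semiAxes, ell$tilt, d)
    idx <- a / b
    clipped <- FALSE
    if (idx > 1) {
      warning("visible CRVT lies outside the fitted BMO ellipse; ",
              "offset index clipped to 1")
      idx <- 1
      clipped <- TRUE
    }
    ang <- .signedAngle2(nasal, d)
  }
  new("OffsetResult", offsetAngle = ang, offsetIndex = idx,
      bmoCenter = ell$center, bmoSemiAxes = ell$semiAxes, bmoTilt = ell$tilt,
      bmoArea = .bmoArea(ell, scene@scale), ppaAngle = .ppaAngle(scene, ell),
      clipped = clipped)
}

.bmoArea <- function(ell, scale) {
  if (is.finite(scale)) pi * prod(ell$semiAxes) * scale^2
  else pi * prod(ell$semiAxes)
}

.ppaAngle <- function(scene, ell) {
  if (!all(is.finite(scene@ppaPoint))) return(NA_real_)
  nasal <- .unit(ell$center - scene@fovea)
  temporal <- -nasal
  v <- scene@ppaPoint - ell$center
  # positive toward superior: clockwise relative to the temporal reference
  -.signedAngle2(temporal, v)
}

#' Offset metrics when the CRVT is invisible (outside the BMO)
#'
#' The offset index is defined as 1.0 and the angular deviation as the
#' direction opposite to the longest externally oblique border meridian.
#'
#' @param scene a [BMOScene-class] with `crvtVisible = FALSE` and an
#'   `eobMeridian`.
#' @return an [OffsetResult-class].
#' @export
handleInvisibleCRVT <- function(scene) {
  if (!is.finite(scene@eobMeridian))
    stop("invisible CRVT without an EOB meridian: eye must be excluded upstream")
  if (scene@laterality == "left") scene <- .mirrorScene(scene)
  ell <- fitBMOEllipse(scene@marginPoints)
  new("OffsetResult", offsetAngle = wrapAngle(scene@eobMeridian + 180),
      offsetIndex = 1.0, bmoCenter = ell$center, bmoSemiAxes = ell$semiAxes,
      bmoTilt = ell$tilt, bmoArea = .bmoArea(ell, scene@scale),
      ppaAngle = .ppaAngle(scene, ell), clipped = FALSE)
}

#' Angular location of the maximal beta-zone PPA width
#'
#' Signed angle of the PPA meridian point from the temporal horizontal
#' midline (0 degrees temporal, positive superior).
#'
#' @param scene a [BMOScene-class] with a `ppaPoint`.
#' @return degrees in (-180, 180], or NA when no PPA point is present.
#' @export
computePPAAngle <- function(scene) {
  if (!all(is.finite(scene@ppaPoint))) return(NA_real_)
  if (scene@laterality == "left") scene <- .mirrorScene(scene)
  .ppaAngle(scene, fitBMOEllipse(scene@marginPoints))
}

#' Read / write a BMO scene CSV
#'
#' Format: comment header lines `#key=value` for laterality, scale and
#' crvt_visible, then CSV columns role,x_px,y_px with roles bmo_margin, crvt,
#' fovea, ppa and eob (for eob, x_px holds the meridian in degrees).
#'
#' @param path CSV path.
#' @return a [BMOScene-class].
#' @export
readBMOScene <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    p <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    kv[[trimws(p[1])]] <- trimws(p[2])
  }
  d <- utils::read.csv(text = paste(grep("^#", lines, value = TRUE,
                                         invert = TRUE), collapse = "\n"))
  margin <- as.matrix(d[d$role == "bmo_margin", c("x_px", "y_px")])
  getPt <- function(role) {
    r <- d[d$role == role, c("x_px", "y_px")]
    if (nrow(r)) as.numeric(r[1, ]) else c(NA_real_, NA_real_)
  }
  eob <- d[d$role == "eob", "x_px"]
  bmoScene(margin, fovea = getPt("fovea"), crvt = getPt("crvt"),
           crvtVisible = identical(tolower(kv$crvt_visible %||% "true"), "true"),
           laterality = kv$laterality %||% "right",
           eobMeridian = if (length(eob)) eob[1] else NA_real_,
           ppaPoint = getPt("ppa"),
           scale = as.numeric(kv$scale %||% NA))
}

#' @rdname readBMOScene
#' @param scene a [BMOScene-class] to write.
#' @export
writeBMOScene <- function(scene, path) {
  hdr <- c(paste0("#laterality=", scene@laterality),
           paste0("#scale=", scene@scale),
           paste0("#crvt_visible=", tolower(scene@crvtVisible)))
  rows <- data.frame(role = "bmo_margin",
                     x_px = scene@marginPoints[, 1],
                     y_px = scene@marginPoints[, 2])
  rows <- rbind(rows, data.frame(role = "fovea", x_px = scene@fovea[1],
                                 y_px = scene@fovea[2]))
  if (all(is.finite(scene@crvt)))
    rows <- rbind(rows, data.frame(role = "crvt", x_px = scene@crvt[1],
                                   y_px = scene@crvt[2]))
  if (is.finite(scene@eobMeridian))
    rows <- rbind(rows, data.frame(role = "eob", x_px = scene@eobMeridian,
                                   y_px = NA))
  if (all(is.finite(scene@ppaPoint)))
    rows <- rbind(rows, data.frame(role = "ppa", x_px = scene@ppaPoint[1],
                                   y_px = scene@ppaPoint[2]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
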