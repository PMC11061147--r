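# Standardized eye frame: visual axis (lens -> optic nerve head) along +z
# with the posterior pole at large z, superior approximately +y (the minimal
# rotation preserves the scanner's vertical), and left eyes mirrored in x so
# nasal is +x for every eye (right-eye orientation).

#' Standardize a contour cloud into the canonical eye frame
#'
#' Rotates the cloud so the lens-to-ONH axis becomes +z (posterior pole at
#' large z) and mirrors left eyes in x (nasal = +x for all eyes).  The fovea
#' and BMO landmarks are kept as marked (they define the angular reference
#' axis); a warning is raised if either lies more than 2 mm off the contour.
#'
#' @param points n x 3 matrix of contour points, mm.
#' @param landmarks named list with numeric(3) entries `lens`, `onh`, `fovea`
#'   and `bmo` (mm, same frame as `points`).
#' @param laterality "right" or "left".
#' @return an [EyePointCloud-class] in the standardized frame.
#' @export
standardizeFrame <- function(points, landmarks, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  stopifnot(is.matrix(points), ncol(points) == 3L)
  need <- c("lens", "onh", "fovea", "bmo")
  if (!all(need %in% names(landmarks)))
    stop("landmarks must provide: ", paste(need, collapse = ", "))
  axis <- landmarks$onh - landmarks$lens
  if (sqrt(sum(axis^2)) < 1e-9)
    stop("lens and ONH landmarks coincide; visual axis undefined")
  R <- .rotationBetween(axis, c(0, 0, 1))
  P <- points %*% t(R)
  lm <- lapply(landmarks[need], function(v) drop(R %*% v))
  if (laterality == "left") {
    P[, 1] <- -P[, 1]
    lm <- lapply(lm, function(v) { v[1] <- -v[1]; v })
  }
  # landmarks are kept as marked; they should lie on or near the contour
  # (slice-wise extraction leaves a gap at the polar tangent, so the
  # diagnostic allows a few millimetres there)
  checkNear <- function(v, what) {
    d <- sqrt(min(rowSums(sweep(P, 2, v)^2)))
    if (d > 5)
      warning(what, " landmark lies ", round(d, 1),
              " mm from the nearest contour point")
    v
  }
  fovea <- checkNear(lm$fovea, "fovea")
  bmo <- checkNear(lm$bmo, "BMO")
  new("EyePointCloud", points = P, laterality = laterality,
      lensCenter = lm$lens, onhCenter = lm$onh, fovea = fovea,
      bmoPoint = bmo, visualAxis = c(0, 0, 1), standardized = TRUE)
}

#' Keep the posterior part of a standardized cloud
#'
#' Cuts along the visual axis: points with
#' z >= z_min + (1 - fraction) * (z_max - z_min) are retained, removing the
#' anterior 1/3 for the default fraction of 2/3.
#'
#' @param cloud a standardized [EyePointCloud-class].
#' @param fraction axial fraction to keep from the posterior side (default 2/3).
#' @param minPoints minimum surviving points for a fit to proceed (default 500).
#' @return the trimmed [EyePointCloud-class].
#' @export
selectPosterior <- function(cloud, fraction = 2 / 3, minPoints = 500L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!cloud@standardized) stop("cloud must be standardized first")
  z <- cloud@points[, 3]
  zcut <- min(z) + (1 - fraction) * (max(z) - min(z))
  keep <- z >= zcut
  if (sum(keep) < minPoints)
    stop("only ", sum(keep), " points survive the posterior cut (need >= ",
         minPoints, ")")
  cloud@points <- cloud@points[keep, , drop = FALSE]
  cloud
}

#' Read a landmark CSV
#'
#' Expected columns: subject_id, eye, structure (lens/onh/fovea/bmo), x_mm,
#' y_mm, z_mm.
#'
#' @param path CSV path.
#' @return nested list: `[[subject_id]][[eye]]` -> named list of numeric(3).
#' @export
readLandmarks <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "eye", "structure", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(d)))
    stop("landmark file must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (r in seq_len(nrow(d))) {
    s <- as.character(d$subject_id[r]); e <- as.character(d$eye[r])
    out[[s]][[e]][[d$structure[r]]] <- c(d$x_mm[r], d$y_mm[r], d$z_mm[r])
  }
  out
}

#' Write a point cloud to CSV or PLY
#'
#' @param points n x 3 matrix, mm.
#' @param path output path; format chosen by extension (.csv or .ply).
#' @return the path, invisibly.
#' @export
writePointCloud <- function(points, path) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(points)),
                 "property float x", "property float y", "property float z",
                 "end_header"), con)
    utils::write.table(format(points, trim = TRUE, digits = 8), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(data.frame(x_mm = points[, 1], y_mm = points[, 2],
                                z_mm = points[, 3]),
                     path, row.names = FALSE)
  }
  invisible(path)
}
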