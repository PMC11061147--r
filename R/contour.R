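# Globe contour extraction: intensity rescale + slice-wise Canny edges.
#
# The Canny detector is applied per axial slice (third array index), matching
# per-slice tracing of the scan stack: Gaussian blur, Sobel gradients,
# non-maximum suppression along the quantized gradient direction, hysteresis
# thresholding seeded at the strong threshold, then the largest connected
# edge component of each slice is taken as the globe boundary.

#' Construct a voxel volume
#'
#' @param intensities 3D numeric array.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param axisLabels anatomical tags for the three axes; the standard frame
#'   assumes x nasal/temporal, y superior, z along the scanner axis.
#' @param meta free-form provenance list.
#' @return a [VoxelVolume-class].
#' @export
voxelVolume <- function(intensities, spacing = c(1, 1, 1),
                        axisLabels = c("x", "y", "z"), meta = list()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VoxelVolume", intensities = intensities, spacing = as.numeric(spacing),
      axisLabels = axisLabels, meta = meta)
}

#' Read a NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a [VoxelVolume-class] with spacing taken from the header.
#' @export
readNIfTIVolume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  voxelVolume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp)
}

#' Write a volume to NIfTI
#'
#' @param volume a [VoxelVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeNIfTIVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@intensities)
  RNifti::pixdim(img) <- volume@spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Rescale volume intensities to the linear 0-256 range
#'
#' Minimum maps to 0, maximum to 256, linear in between (idempotent on
#' already-rescaled input).
#'
#' @param volume a [VoxelVolume-class].
#' @return the rescaled [VoxelVolume-class].
#' @export
rescaleIntensities <- function(volume) {
  v <- volume@intensities
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps)
    stop("constant-intensity volume cannot be rescaled")
  volume@intensities <- (v - rng[1]) * (256 / diff(rng))
  volume
}

# ---- slice-wise Canny ------------------------------------------------------

.sobel <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- EBImage::filter2(m, kx, boundary = "replicate")
  gy <- EBImage::filter2(m, t(kx), boundary = "replicate")
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

.shiftMat <- function(m, di, dj) {
  n <- matrix(0, nrow(m), ncol(m))
  si <- seq_len(nrow(m)); sj <- seq_len(ncol(m))
  ti <- si + di; tj <- sj + dj
  ok_i <- ti >= 1 & ti <= nrow(m); ok_j <- tj >= 1 & tj <= ncol(m)
  n[si[ok_i], sj[ok_j]] <- m[ti[ok_i], tj[ok_j]]
  n
}

# Non-maximum suppression with gradient direction quantized to 0/45/90/135.
.nonMaxSuppress <- function(g) {
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4  # 0:horiz .. 3:diag2
  offs <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  keep <- matrix(FALSE, nrow(g$mag), ncol(g$mag))
  for (s in 0:3) {
    o <- offs[[s + 1L]]
    n1 <- .shiftMat(g$mag, o[1], o[2])
    n2 <- .shiftMat(g$mag, -o[1], -o[2])
    keep <- keep | (sector == s & g$mag >= n1 & g$mag >= n2)
  }
  keep
}

# One-slice Canny; thresholds are absolute gradient magnitudes.
.cannySlice <- function(m, lowAbs, highAbs, sigma) {
  sm <- if (sigma > 0) EBImage::gblur(m, sigma = sigma, boundary = "replicate") else m
  g <- .sobel(sm)
  nms <- .nonMaxSuppress(g) & g$mag >= lowAbs
  if (!any(nms)) return(NULL)
  strong <- nms & g$mag >= highAbs
  if (!any(strong)) return(NULL)
  # hysteresis + component selection: label candidate pixels (diagonal links
  # bridged by a 3x3 dilation), keep components seeded by a strong pixel
  lab <- EBImage::bwlabel(EBImage::dilate(nms * 1, EBImage::makeBrush(3, "box")))
  lab[!nms] <- 0
  keepLabs <- setdiff(unique(lab[strong]), 0)
  if (!length(keepLabs)) return(NULL)
  counts <- tabulate(lab[lab > 0])
  best <- keepLabs[which.max(counts[keepLabs])]
  ij <- which(lab == best, arr.ind = TRUE)
  # sub-pixel refinement: parabolic interpolation of the gradient magnitude
  # along the quantized gradient direction (removes most of the half-voxel
  # quantization that would otherwise dominate the residual field)
  ang <- atan2(g$gy, g$gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- matrix(findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4,
                   nrow(m), ncol(m))
  offs <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  nr <- nrow(m); nc <- ncol(m)
  shift <- matrix(0, nrow(ij), 2)
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    o <- offs[[sector[i, j] + 1L]]
    i1 <- i + o[1]; j1 <- j + o[2]; i2 <- i - o[1]; j2 <- j - o[2]
    if (i1 < 1 || i1 > nr || j1 < 1 || j1 > nc ||
        i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
    mp <- g$mag[i1, j1]; mm <- g$mag[i2, j2]; m0 <- g$mag[i, j]
    den <- mm - 2 * m0 + mp
    if (abs(den) > 1e-12) {
      dlt <- 0.5 * (mm - mp) / den
      dlt <- max(min(dlt, 0.5), -0.5)
      shift[r, ] <- dlt * o
    }
  }
  ij + shift
}

#' Extract the globe contour from a rescaled volume
#'
#' Runs the Canny detector on every axial slice and collects the largest
#' connected edge component per slice (the globe boundary) into a 3D point
#' cloud in mm (voxel centers at (index - 0.5) * spacing).
#'
#' @param volume a rescaled [VoxelVolume-class] (see [rescaleIntensities()]).
#' @param lowThresh,highThresh hysteresis thresholds as fractions of the
#'   maximum gradient magnitude over the volume (defaults 0.1 and 0.3).
#' @param sigma Gaussian blur in voxels before the gradient (default 1).
#' @return n x 3 matrix of contour points, mm.
#' @export
extractContour <- function(volume, lowThresh = 0.1, highThresh = 0.3,
                           sigma = 1.0) {
  v <- volume@intensities
  nz <- dim(v)[3]
  # global gradient ceiling so thresholds are comparable across slices
  gmax <- 0
  smooth <- vector("list", nz)
  for (k in seq_len(nz)) {
    m <- v[, , k]
    sm <- if (sigma > 0) EBImage::gblur(m, sigma = sigma, boundary = "replicate") else m
    smooth[[k]] <- sm
    g <- .sobel(sm)
    gmax <- max(gmax, max(g$mag))
  }
  if (gmax < .Machine$double.eps) stop("volume has no intensity gradients")
  lowAbs <- lowThresh * gmax
  highAbs <- highThresh * gmax
  pts <- vector("list", nz)
  hit <- logical(nz)
  for (k in seq_len(nz)) {
    ij <- .cannySlice(smooth[[k]], lowAbs, highAbs, sigma = 0)
    if (!is.null(ij) && nrow(ij) > 0) {
      hit[k] <- TRUE
      pts[[k]] <- cbind(ij, k)
    }
  }
  span <- which(hit)
  if (!length(span)) stop("no globe contour found on any slice")
  inSpan <- seq(min(span), max(span))
  if (mean(!hit[inSpan]) > 0.20)
    stop("no closed contour found on more than 20% of slices spanning the globe")
  P <- do.call(rbind, pts[span])
  sweep(P - 0.5, 2, volume@spacing, "*")
}
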