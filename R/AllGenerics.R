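#' @rdname EllipsoidModel-class
#' @param object an S4 object from this package
#' @export
setGeneric("quadricCoefficients", function(object) standardGeneric("quadricCoefficients"))

#' @rdname EllipsoidModel-class
#' @export
setGeneric("ellipsoidCenter", function(object) standardGeneric("ellipsoidCenter"))

#' @rdname EllipsoidModel-class
#' @export
setGeneric("semiAxes", function(object) standardGeneric("semiAxes"))

#' @rdname EllipsoidModel-class
#' @export
setGeneric("orientation", function(object) standardGeneric("orientation"))

#' @rdname EllipsoidFit-class
#' @export
setGeneric("fitRMSE", function(object) standardGeneric("fitRMSE"))

#' @rdname EyePointCloud-class
#' @export
setGeneric("cloudPoints", function(object) standardGeneric("cloudPoints"))

#' @rdname EyePointCloud-class
#' @export
setGeneric("laterality", function(object) standardGeneric("laterality"))

#' @rdname AsymmetryResult-class
#' @export
setGeneric("isAsymmetric", function(object) standardGeneric("isAsymmetric"))

#' @rdname AsymmetryResult-class
#' @export
setGeneric("oppAngle", function(object) standardGeneric("oppAngle"))

#' @rdname AsymmetryResult-class
#' @export
setGeneric("protrusionDepth", function(object) standardGeneric("protrusionDepth"))

#' @rdname OffsetResult-class
#' @export
setGeneric("offsetAngle", function(object) standardGeneric("offsetAngle"))

#' @rdname OffsetResult-class
#' @export
setGeneric("offsetIndex", function(object) standardGeneric("offsetIndex"))

setMethod("quadricCoefficients", "EllipsoidModel", function(object) object@coefficients)
setMethod("quadricCoefficients", "EllipsoidFit", function(object) object@model@coefficients)
setMethod("ellipsoidCenter", "EllipsoidModel", function(object) object@center)
setMethod("ellipsoidCenter", "EllipsoidFit", function(object) object@model@center)
setMethod("semiAxes", "EllipsoidModel", function(object) object@semiAxes)
setMethod("semiAxes", "EllipsoidFit", function(object) object@model@semiAxes)
setMethod("orientation", "EllipsoidModel", function(object) object@orientation)
setMethod("orientation", "EllipsoidFit", function(object) object@model@orientation)
setMethod("fitRMSE", "EllipsoidFit", function(object) object@rmse)
setMethod("fitRMSE", "AsymmetryResult", function(object) object@rmse)
setMethod("cloudPoints", "EyePointCloud", function(object) object@points)
setMethod("laterality", "EyePointCloud", function(object) object@laterality)
setMethod("laterality", "BMOScene", function(object) object@laterality)
setMethod("isAsymmetric", "AsymmetryResult", function(object) object@isAsymmetric)
setMethod("oppAngle", "AsymmetryResult", function(object) object@oppAngle)
setMethod("protrusionDepth", "AsymmetryResult", function(object) object@protrusionDepth)
setMethod("offsetAngle", "OffsetResult", function(object) object@offsetAngle)
setMethod("offsetIndex", "OffsetResult", function(object) object@offsetIndex)

setMethod("show", "EllipsoidModel", function(object) {
  cat("EllipsoidModel\n")
  cat("  center   :", paste(sprintf("%.3f", object@center), collapse = ", "), "mm\n")
  cat("  semiAxes :", paste(sprintf("%.3f", object@semiAxes), collapse = ", "), "mm\n")
})

setMethod("show", "EllipsoidFit", function(object) {
  cat("EllipsoidFit on", object@nPoints, "points\n")
  show(object@model)
  cat(sprintf("  rmse     : %.5f (radius-normalized)\n", object@rmse))
  cat("  converged:", object@converged,
      sprintf("(%d restart%s)\n", object@nRestarts,
              if (object@nRestarts == 1L) "" else "s"))
})

setMethod("show", "EyePointCloud", function(object) {
  cat("EyePointCloud:", nrow(object@points), "points,", object@laterality, "eye",
      if (object@standardized) "(standardized frame)" else "(native frame)", "\n")
})

setMethod("show", "VoxelVolume", function(object) {
  cat("VoxelVolume", paste(dim(object@intensities), collapse = " x "),
      "voxels @", paste(object@spacing, collapse = " x "), "mm\n")
})

setMethod("show", "AsymmetryResult", function(object) {
  if (object@isAsymmetric) {
    cat(sprintf("AsymmetryResult: group 2 (asymmetric); OPP %+.1f deg, depth %.4f, rmse %.4f\n",
                object@oppAngle, object@protrusionDepth, object@rmse))
  } else {
    cat(sprintf("AsymmetryResult: group 1 (no asymmetry); rmse %.4f\n", object@rmse))
  }
})

setMethod("show", "BMOScene", function(object) {
  cat("BMOScene:", nrow(object@marginPoints), "margin points,",
      object@laterality, "eye, CRVT",
      if (object@crvtVisible) "visible" else "invisible", "\n")
})

setMethod("show", "OffsetResult", function(object) {
  cat(sprintf("OffsetResult: angle %+.1f deg, index %.3f\n",
              object@offsetAngle, object@offsetIndex))
})

setMethod("show", "ResidualField", function(object) {
  cat("ResidualField:", length(object@signedRatio), "residuals, range",
      sprintf("[%.4f, %.4f]\n", min(object@signedRatio), max(object@signedRatio)))
})
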