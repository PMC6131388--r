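#' Voxel or pixel spacing in mm
#' @param x a volume, image or arch object
#' @return numeric spacing vector (mm per voxel/pixel)
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' World origin in mm
#' @param x a volume, image or arch object
#' @return numeric world coordinate of the first voxel/pixel
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Grid dimensions
#' @param x a volume, image or arch object
#' @return integer vector of grid sizes
#' @export
setGeneric("dims", function(x) standardGeneric("dims"))

#' @describeIn spacing spacing of a 3D volume
#' @export
setMethod("spacing", "Volume3D", function(x) x@spacing)
#' @describeIn spacing spacing of a 2D image
#' @export
setMethod("spacing", "Image2D", function(x) x@spacing)
#' @describeIn spacing spacing of an arch image
#' @export
setMethod("spacing", "ArchImage", function(x) x@spacing)
#' @describeIn spacing spacing of an average arch
#' @export
setMethod("spacing", "AverageArch", function(x) x@spacing)

#' @describeIn origin origin of a 3D volume
#' @export
setMethod("origin", "Volume3D", function(x) x@origin)
#' @describeIn origin origin of a 2D image
#' @export
setMethod("origin", "Image2D", function(x) x@origin)
#' @describeIn origin origin of an arch image
#' @export
setMethod("origin", "ArchImage", function(x) x@origin)
#' @describeIn origin origin of an average arch
#' @export
setMethod("origin", "AverageArch", function(x) x@origin)

#' @describeIn dims dimensions of a 3D volume
#' @export
setMethod("dims", "Volume3D", function(x) dim(x@data))
#' @describeIn dims dimensions of a 2D image
#' @export
setMethod("dims", "Image2D", function(x) dim(x@data))
#' @describeIn dims dimensions of an arch image
#' @export
setMethod("dims", "ArchImage", function(x) dim(x@mask))

#' Extract the raw data grid
#' @param x a volume or image object
#' @return the underlying array or matrix
#' @export
setGeneric("gridData", function(x) standardGeneric("gridData"))

#' @describeIn gridData array of a 3D volume
#' @export
setMethod("gridData", "Volume3D", function(x) x@data)
#' @describeIn gridData matrix of a 2D image
#' @export
setMethod("gridData", "Image2D", function(x) x@data)
#' @describeIn gridData mask matrix of an arch image
#' @export
setMethod("gridData", "ArchImage", function(x) x@mask)

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              class(object), d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm; intensity range [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryVolume3D", function(object) {
  d <- dim(object@data)
  cat(sprintf("BinaryVolume3D: %d x %d x %d voxels, %d foreground (%.1f mm^3 each)\n",
              d[1], d[2], d[3], sum(object@data), prod(object@spacing)))
})

setMethod("show", "Image2D", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d pixels (%s x %s), spacing (%.3g, %.3g) mm\n",
              class(object), d[1], d[2], object@axes[1], object@axes[2],
              object@spacing[1], object@spacing[2]))
})

setMethod("show", "LandmarkSet", function(object) {
  cat("LandmarkSet with 10 points (world mm):\n")
  print(round(object@points, 3))
})

setMethod("show", "ArchImage", function(object) {
  d <- dim(object@mask)
  cat(sprintf("ArchImage: %d x %d px, area %.2f mm^2, reference (%.2f, %.2f) mm\n",
              d[1], d[2], archArea(object), object@reference[1], object@reference[2]))
})

setMethod("show", "AverageArch", function(object) {
  cat(sprintf("AverageArch of %d subjects: t* = %.2f, mean individual area %.2f mm^2, average mask area %.2f mm^2\n",
              object@nSubjects, object@threshold,
              object@meanIndividualArea, object@maskArea))
})

setMethod("show", "SmoothingSpline", function(object) {
  cat(sprintf("SmoothingSpline: %d cubic pieces on [%.3g, %.3g]\n",
              nrow(object@coef), min(object@breaks), max(object@breaks)))
})

setMethod("show", "TroughModel", function(object) {
  cat("TroughModel (center / buccal / lingual smoothing-spline curves)\n")
  cat(sprintf("  canine midpoint (%.2f, %.2f) mm; canine arc positions %.2f / %.2f mm\n",
              object@canineMid[1], object@canineMid[2],
              object@canineS[1], object@canineS[2]))
})

setMethod("show", "ThicknessProfile", function(object) {
  cat(sprintf("ThicknessProfile: %d samples over %.1f mm; anterior min %.2f mm, posterior min %.2f mm\n",
              length(object@s), max(object@s), object@anteriorMin, object@posteriorMin))
})

setMethod("show", "TransitionResult", function(object) {
  cat(sprintf("Transition: %.2f mm lateral, %.2f mm posterior to the canine midpoint; slope %.2f deg\n",
              object@lateral, object@posterior, object@slope))
})

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport:\n")
  cat(sprintf("  threshold t* = %.2f; mean individual area %.2f mm^2; average area %.2f mm^2\n",
              object@threshold, object@meanIndividualArea, object@averageArea))
  cat(sprintf("  minimum thickness: anterior %.2f mm, posterior %.2f mm\n",
              object@anteriorMin, object@posteriorMin))
  cat(sprintf("  transition: %.2f mm lateral, %.2f mm posterior, slope %.2f deg\n",
              object@transitionLateral, object@transitionPosterior,
              object@transitionSlope))
  cat(sprintf("  %d stored spline curves\n", length(object@splines)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d x %d x %d @ (%.2g, %.2g, %.2g) mm; a = %.1f, b = %.1f, ramus angle %.1f deg, band %.1f mm\n",
              object@dim[1], object@dim[2], object@dim[3],
              object@spacing[1], object@spacing[2], object@spacing[3],
              object@archDepth, object@archHalfWidth, object@ramusAngle,
              object@bandWidth))
  cat(sprintf("  confounders: soft=%s vertebra=%s cranium=%s; noise sd %.3g, bias %.3g, seed %d\n",
              object@includeSoftTissue, object@includeVertebra,
              object@includeCranium, object@noiseSd, object@biasAmplitude,
              object@seed))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf("PipelineConfig: vertebra x%.2f, mask x%.2f, condyle ellipse %.0f x %.0f mm, tooth %.0f mm, %d previous slices, grid %.2g, spline p %.3g, thickness step %.2g mm\n",
              object@vertebraMagnification, object@maskMagnification,
              object@condyleEllipse[1], object@condyleEllipse[2],
              object@toothLength, object@kPrevSlices,
              object@thresholdGridStep, object@splineSmooth,
              object@thicknessStep))
})
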