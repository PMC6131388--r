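
## Axes convention used throughout: array index i -> X = subject left (+) /
## right (-), j -> Y = anterior (+) / posterior (-), k -> Z = superior (+) /
## inferior (-).  World coordinate of 0-based voxel (i,j,k) is
## origin + c(i,j,k) * spacing, in mm.

#' 3D scalar volume with voxel spacing and world origin
#'
#' Container for a 3D grayscale grid (arbitrary intensity units) together with
#' its per-axis voxel spacing in mm and the world position of the first voxel.
#' Array axes follow the package convention: the first index runs along X
#' (subject left positive), the second along Y (anterior positive), the third
#' along Z (superior positive).
#'
#' @slot data numeric 3D array of intensities.
#' @slot spacing numeric(3), mm per voxel along X, Y, Z; all positive.
#' @slot origin numeric(3), world mm coordinate of voxel (0,0,0).
#' @export
setClass("Volume3D", representation(
  data = "array", spacing = "numeric", origin = "numeric"
))

setValidity("Volume3D", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (any(dim(d) < 2L)) return("each axis needs at least 2 voxels")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers")
  TRUE
})

#' Binary 3D volume
#'
#' A [Volume3D-class] whose grid is logical (a segmentation mask).
#' @export
setClass("BinaryVolume3D", contains = "Volume3D")

setValidity("BinaryVolume3D", function(object) {
  if (!is.logical(object@data)) return("mask data must be logical")
  TRUE
})

#' 2D image with pixel spacing and origin
#'
#' A 2D scalar image, typically a projection of a [Volume3D-class]. The two
#' matrix axes carry the two retained world axes of the projection; `spacing`
#' and `origin` are in mm.
#'
#' @slot data numeric matrix.
#' @slot spacing numeric(2) mm per pixel.
#' @slot origin numeric(2) world mm of pixel (0,0).
#' @slot axes character(2) naming the world axes of the rows/columns
#'   (e.g. c("X","Y") for an axial image).
#' @export
setClass("Image2D", representation(
  data = "matrix", spacing = "numeric", origin = "numeric", axes = "character"
))

setValidity("Image2D", function(object) {
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    return("spacing must be 2 positive numbers")
  if (length(object@origin) != 2L) return("origin must have length 2")
  if (length(object@axes) != 2L) return("axes must have length 2")
  TRUE
})

#' Binary 2D image
#' @export
setClass("BinaryImage2D", contains = "Image2D")

setValidity("BinaryImage2D", function(object) {
  if (!is.logical(object@data)) return("mask data must be logical")
  TRUE
})

## The ten operator-selected points, in a fixed order.
.LANDMARK_NAMES <- c(
  "frankfort_orbit", "frankfort_meatus",
  "coronal_right", "coronal_left",
  "occlusal_anterior", "occlusal_posterior",
  "condyle_a", "condyle_b",
  "canine_right", "canine_left"
)

#' Set of the ten named operator landmarks
#'
#' Holds the ten points that drive preprocessing: the two Frankfort-plane
#' points (inferior orbital margin, superior meatus margin), the two coronal
#' ramus points, the two sagittal occlusal points, the two condyle-top points,
#' and the distal contact points of the right and left mandibular canines.
#' Stored as a 10 x 3 matrix of world mm, rows named.
#'
#' @slot points numeric 10 x 3 matrix, rownames the landmark names, columns
#'   X, Y, Z in mm.
#' @export
setClass("LandmarkSet", representation(points = "matrix"))

setValidity("LandmarkSet", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3L) return("points must be an n x 3 numeric matrix")
  if (!identical(sort(rownames(p)), sort(.LANDMARK_NAMES)))
    return(sprintf("landmark names must be exactly: %s",
                   paste(.LANDMARK_NAMES, collapse = ", ")))
  if (any(!is.finite(p))) return("landmark coordinates must be finite")
  if (p["canine_right", 1] >= p["canine_left", 1])
    return("canine_right must have smaller X than canine_left (X = left positive)")
  TRUE
})

#' Per-subject 2D arch image
#'
#' Binary axial maximum-intensity projection of the segmented mandible, with
#' pixel spacing, world origin, the canine-midpoint reference used for cohort
#' superimposition, and the two canine contact points, all in axial (X, Y) mm.
#'
#' @slot mask logical matrix (X along rows, Y along columns).
#' @slot spacing numeric(2) mm.
#' @slot origin numeric(2) mm of pixel (0,0).
#' @slot reference numeric(2), canine midpoint in mm.
#' @slot canines numeric 2 x 2 matrix (rows right/left canine, columns X, Y).
#' @export
setClass("ArchImage", representation(
  mask = "matrix", spacing = "numeric", origin = "numeric",
  reference = "numeric", canines = "matrix"
))

setValidity("ArchImage", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    return("spacing must be 2 positive numbers")
  if (length(object@reference) != 2L) return("reference must have length 2")
  lo <- object@origin - object@spacing / 2
  hi <- object@origin + (dim(object@mask) - 0.5) * object@spacing
  if (any(object@reference < lo) || any(object@reference > hi))
    return("reference must lie inside the image bounds")
  TRUE
})

#' Cohort average arch
#'
#' Per-pixel frequency map (fraction of subjects foreground), the number of
#' subjects, the area-matched threshold, the resulting binary average mask,
#' and the areas used in threshold selection. The canvas is positioned so the
#' common canine-midpoint reference is at world (0, 0).
#'
#' @slot freq numeric matrix in [0,1].
#' @slot spacing numeric(2) mm.
#' @slot origin numeric(2) mm.
#' @slot nSubjects integer.
#' @slot threshold numeric, chosen t*.
#' @slot mask logical matrix, freq >= t*.
#' @slot meanIndividualArea numeric, mean subject arch area in mm^2.
#' @slot maskArea numeric, area of the thresholded average mask in mm^2.
#' @slot canines numeric 2 x 2, cohort-mean canine points (mm).
#' @export
setClass("AverageArch", representation(
  freq = "matrix", spacing = "numeric", origin = "numeric",
  nSubjects = "integer", threshold = "numeric", mask = "matrix",
  meanIndividualArea = "numeric", maskArea = "numeric", canines = "matrix"
))

setValidity("AverageArch", function(object) {
  if (min(object@freq) < 0 || max(object@freq) > 1)
    return("frequency values must lie in [0,1]")
  if (object@nSubjects < 1L) return("nSubjects must be >= 1")
  TRUE
})

#' Piecewise-cubic smoothing spline (one coordinate)
#'
#' Natural cubic smoothing spline in piecewise-polynomial form: ordered breaks
#' and four ascending-power coefficients per piece, so that on piece i with
#' local coordinate dx = t - breaks[i] the value is
#' c1 + c2*dx + c3*dx^2 + c4*dx^3.
#'
#' @slot breaks numeric, strictly increasing knots.
#' @slot coef numeric (length(breaks)-1) x 4 matrix, ascending powers.
#' @export
setClass("SmoothingSpline", representation(breaks = "numeric", coef = "matrix"))

setValidity("SmoothingSpline", function(object) {
  if (length(object@breaks) < 2L) return("need at least 2 breaks")
  if (any(diff(object@breaks) <= 0)) return("breaks must be strictly increasing")
  if (nrow(object@coef) != length(object@breaks) - 1L || ncol(object@coef) != 4L)
    return("coef must be (pieces x 4)")
  TRUE
})

#' Planar fitted curve (parameter -> 2D point)
#'
#' Two [SmoothingSpline-class] components over a shared parameter (arc length
#' along the trough center, mm), mapping parameter to (X, Y) mm.
#' @export
setClass("FittedCurve", representation(x = "SmoothingSpline", y = "SmoothingSpline"))

#' Panoramic focal trough model
#'
#' The three fitted curves of the focal trough (center, buccal = outer,
#' lingual = inner boundary) over the signed center arc-length parameter
#' (0 at the anterior midline, negative toward the subject right, positive
#' toward the left), plus the canine midpoint and the canines' arc positions.
#'
#' @slot center,buccal,lingual [FittedCurve-class] objects sharing the
#'   center arc-length parameter.
#' @slot canineMid numeric(2) mm.
#' @slot canineS numeric(2), signed arc positions of the right and left canine.
#' @export
setClass("TroughModel", representation(
  center = "FittedCurve", buccal = "FittedCurve", lingual = "FittedCurve",
  canineMid = "numeric", canineS = "numeric"
))

#' Focal-trough thickness profile
#'
#' Thickness of the trough (buccal-to-lingual distance along the center
#' normal) against arc length from the anterior midline. The trough is
#' mirror-symmetric by construction, so one side suffices.
#'
#' @slot s numeric, arc-length samples (mm) from the anterior midline.
#' @slot thickness numeric, trough thickness (mm) at each sample.
#' @slot canineS numeric, arc position of the canine contact point.
#' @slot anteriorMin numeric, minimum thickness from midline to canine (mm).
#' @slot posteriorMin numeric, minimum thickness posterior to the canine (mm).
#' @export
setClass("ThicknessProfile", representation(
  s = "numeric", thickness = "numeric", canineS = "numeric",
  anteriorMin = "numeric", posteriorMin = "numeric"
))

setValidity("ThicknessProfile", function(object) {
  if (length(object@s) != length(object@thickness))
    return("s and thickness must have equal length")
  if (any(object@thickness <= 0)) return("thickness must be positive")
  TRUE
})

#' Dental-arch-to-ramus transition
#'
#' Location (offsets from the canine midpoint) and slope of the point where
#' the trough center stops curving and straightens into the ascending ramus.
#'
#' @slot lateral numeric, |X offset| from the canine midpoint (mm).
#' @slot posterior numeric, posterior offset from the canine midpoint (mm).
#' @slot slope numeric, angle of the center tangent to the midsagittal axis
#'   at the transition, degrees.
#' @export
setClass("TransitionResult", representation(
  lateral = "numeric", posterior = "numeric", slope = "numeric"
))

setValidity("TransitionResult", function(object) {
  if (object@lateral < 0 || object@posterior < 0) return("offsets must be >= 0")
  if (object@slope <= 0 || object@slope >= 90)
    return("slope must lie strictly between 0 and 90 degrees")
  TRUE
})

#' Cohort analysis report
#'
#' All cohort-level outputs of the pipeline: chosen threshold, areas,
#' regional minimum thicknesses, transition geometry, and the breaks +
#' cubic coefficients of every fitted spline. Serializes losslessly to JSON.
#'
#' @slot threshold numeric, area-matched frequency threshold t*.
#' @slot meanIndividualArea numeric, mean individual arch area (mm^2).
#' @slot averageArea numeric, thresholded average-mask area (mm^2).
#' @slot anteriorMin,posteriorMin numeric, regional minimum thickness (mm).
#' @slot transitionLateral,transitionPosterior numeric, mm offsets.
#' @slot transitionSlope numeric, degrees.
#' @slot splines list of named curves; each entry a list with `breaks` and a
#'   pieces x 4 `coef` matrix.
#' @export
setClass("AnalysisReport", representation(
  threshold = "numeric", meanIndividualArea = "numeric", averageArea = "numeric",
  anteriorMin = "numeric", posteriorMin = "numeric",
  transitionLateral = "numeric", transitionPosterior = "numeric",
  transitionSlope = "numeric", splines = "list"
))

#' Synthetic phantom specification
#'
#' Parameters of the skull-like phantom: grid geometry, the parabolic dental
#' arch (x = +/- b*sqrt(y'/a), anterior half-depth `archDepth` = a, half-width
#' `archHalfWidth` = b), the straight rami joined tangentially at
#' `ramusAngle` degrees from the midsagittal axis, band width, vertical
#' extents, tissue intensities, optional confounders, noise and bias field.
#'
#' @slot dim integer(3) grid size.
#' @slot spacing numeric(3) mm.
#' @slot archDepth numeric, a (mm).
#' @slot archHalfWidth numeric, b (mm).
#' @slot ramusAngle numeric, tangent angle of the ramus to the midsagittal
#'   axis, degrees in (0, 90).
#' @slot bandWidth numeric, full width of the arch band (mm).
#' @slot ramusLength numeric, straight ramus length in the axial plane (mm).
#' @slot apexY numeric, world Y of the anterior arch apex (mm).
#' @slot occlusalZ numeric, world Z of the occlusal plane (mm).
#' @slot bodyDepth numeric, vertical extent of the mandibular body below the
#'   occlusal plane (mm).
#' @slot ramusTopZ numeric, world Z of the ramus top (condyle neck) (mm).
#' @slot condyleRadius numeric, condylar knob radius (mm).
#' @slot canineX numeric, |X| of the canine contact points on the arch (mm).
#' @slot boneIntensity,softIntensity,backgroundIntensity numeric, ordered
#'   bone > soft > background.
#' @slot includeSoftTissue,includeVertebra,includeCranium logical confounder
#'   switches.
#' @slot vertebraRadius,vertebraY numeric, posterior cylinder geometry (mm).
#' @slot craniumZ numeric, inferior face of the cranial slab (mm).
#' @slot noiseSd numeric, additive Gaussian noise s.d.
#' @slot biasAmplitude numeric, amplitude of the smooth multiplicative bias
#'   field (0 = none).
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec", representation(
  dim = "integer", spacing = "numeric",
  archDepth = "numeric", archHalfWidth = "numeric", ramusAngle = "numeric",
  bandWidth = "numeric", ramusLength = "numeric",
  apexY = "numeric", occlusalZ = "numeric", bodyDepth = "numeric",
  ramusTopZ = "numeric", condyleRadius = "numeric", canineX = "numeric",
  boneIntensity = "numeric", softIntensity = "numeric",
  backgroundIntensity = "numeric",
  includeSoftTissue = "logical", includeVertebra = "logical",
  includeCranium = "logical",
  vertebraRadius = "numeric", vertebraY = "numeric", craniumZ = "numeric",
  noiseSd = "numeric", biasAmplitude = "numeric", seed = "integer"
))

setValidity("PhantomSpec", function(object) {
  if (object@archDepth <= 0 || object@archHalfWidth <= 0 || object@bandWidth <= 0)
    return("arch depth, half-width and band width must be positive")
  if (object@ramusAngle <= 0 || object@ramusAngle >= 90)
    return("ramusAngle must lie strictly between 0 and 90 degrees")
  if (!(object@boneIntensity > object@softIntensity &&
        object@softIntensity > object@backgroundIntensity))
    return("intensities must satisfy bone > soft > background")
  if (object@noiseSd < 0 || object@biasAmplitude < 0)
    return("noiseSd and biasAmplitude must be >= 0")
  TRUE
})

#' Phantom ground truth
#'
#' Analytic truth of a generated phantom: the sampled arch centerline in the
#' axial plane, the half-width along it, the true landmark set, the true
#' transition (offsets from the canine midpoint and the tangent angle), and
#' the rendered true mandible mask.
#'
#' @slot centerline numeric n x 2 (X, Y mm), ordered right end to left end.
#' @slot arcLength numeric n, signed arc length (0 at the midline apex).
#' @slot halfWidth numeric n, half band width at each centerline sample (mm).
#' @slot landmarks [LandmarkSet-class].
#' @slot transition [TransitionResult-class], analytic truth.
#' @slot mask [BinaryVolume3D-class], the true mandible.
#' @export
setClass("PhantomGroundTruth", representation(
  centerline = "matrix", arcLength = "numeric", halfWidth = "numeric",
  landmarks = "LandmarkSet", transition = "TransitionResult",
  mask = "BinaryVolume3D"
))

#' Pipeline configuration
#'
#' The tunable constants of the processing chain. Defaults are the published
#' procedure's values: 1.5x vertebra magnification, 1.2x propagated-mask
#' magnification, a 15 x 21 mm condylar ellipse, 20 mm average tooth length,
#' 3 previous slices in the cumulative binarization, a 0.01 threshold grid.
#'
#' @slot vertebraMagnification numeric > 1.
#' @slot maskMagnification numeric > 1.
#' @slot condyleEllipse numeric(2), anteroposterior (Y) and superoinferior
#'   (Z) full axes of the condylar removal ellipse, mm.
#' @slot toothLength numeric, mm.
#' @slot kPrevSlices integer >= 1.
#' @slot thresholdGridStep numeric in (0, 1].
#' @slot splineSmooth numeric in (0, 1], smoothing parameter p.
#' @slot thicknessStep numeric, arc-length sampling step for the thickness
#'   profile, mm.
#' @export
setClass("PipelineConfig", representation(
  vertebraMagnification = "numeric", maskMagnification = "numeric",
  condyleEllipse = "numeric", toothLength = "numeric", kPrevSlices = "integer",
  thresholdGridStep = "numeric", splineSmooth = "numeric",
  thicknessStep = "numeric"
))

setValidity("PipelineConfig", function(object) {
  if (object@vertebraMagnification <= 1 || object@maskMagnification <= 1)
    return("magnifications must be > 1")
  if (length(object@condyleEllipse) != 2L || any(object@condyleEllipse <= 0))
    return("condyleEllipse must be 2 positive axes (mm)")
  if (object@kPrevSlices < 1L) return("kPrevSlices must be >= 1")
  if (object@thresholdGridStep <= 0 || object@thresholdGridStep > 1)
    return("thresholdGridStep must lie in (0, 1]")
  if (object@splineSmooth <= 0 || object@splineSmooth > 1)
    return("splineSmooth must lie in (0, 1]")
  if (object@thicknessStep <= 0) return("thicknessStep must be positive")
  TRUE
})
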