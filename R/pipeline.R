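## Subject- and cohort-level orchestration of the processing chain, with a
## run manifest (config snapshot, stage content hashes, warnings) so reruns
## are verifiably reproducible.

## md5 of an R object via its serialization
.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

## rotate all landmarks with the same sagittal-plane rotation that
## reorientToFrankfort applies to the volume
.reorientLandmarks <- function(landmarks, orbit, meatus) {
  d <- meatus[2:3] - orbit[2:3]
  phi <- atan2(d[2], d[1])
  if (phi > pi / 2) phi <- phi - pi
  if (phi <= -pi / 2) phi <- phi + pi
  if (phi == 0) return(landmarks)
  ctr <- (orbit[2:3] + meatus[2:3]) / 2
  cph <- cos(-phi); sph <- sin(-phi)
  p <- landmarks@points
  dy <- p[, 2] - ctr[1]; dz <- p[, 3] - ctr[2]
  p[, 2] <- ctr[1] + cph * dy - sph * dz
  p[, 3] <- ctr[2] + sph * dy + cph * dz
  landmarks@points <- p
  landmarks
}

#' Run the subject-level pipeline
#'
#' Executes the full subject chain: intensity normalization, Frankfort
#' reorientation, removal of the midfacial region (coronal view), anterior
#' facial region (sagittal view), cervical vertebrae and condylar caps,
#' cumulative binarization up to the condylar stopping plane, and the axial
#' arch-image projection. Stage failures are rethrown with the stage name
#' and subject id.
#'
#' @param volume a [Volume3D-class] or a volume file path.
#' @param landmarks a [LandmarkSet-class] or a landmark JSON path.
#' @param config a [PipelineConfig-class].
#' @param subjectId identifier used in messages (default "subject").
#' @param outDir optional directory; when given, the segmentation mask and
#'   arch image are persisted there.
#' @return list with `arch` ([ArchImage-class]), `mask`
#'   ([BinaryVolume3D-class]), `stopZ`, `occlusalZ`, `manifest` (list)
#' @export
runSubject <- function(volume, landmarks, config = pipelineConfig(),
                       subjectId = "subject", outDir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] stage '%s': %s", subjectId, name,
                   conditionMessage(e)), call. = FALSE))
  }
  inputs <- list()
  if (is.character(volume)) {
    inputs$volumePath <- volume
    volume <- stage("load_volume", loadVolume(volume))
  }
  if (is.character(landmarks)) {
    inputs$landmarkPath <- landmarks
    landmarks <- stage("load_landmarks", loadLandmarks(landmarks, volume))
  }
  stopifnot(is(volume, "Volume3D"), is(landmarks, "LandmarkSet"))

  vol <- stage("normalize", normalizeIntensity(volume))
  orbit <- landmark(landmarks, "frankfort_orbit")
  meatus <- landmark(landmarks, "frankfort_meatus")
  vol <- stage("reorient", reorientToFrankfort(vol, orbit, meatus))
  lm <- .reorientLandmarks(landmarks, orbit, meatus)

  cr <- landmark(lm, "coronal_right"); cl <- landmark(lm, "coronal_left")
  vol <- stage("remove_midface",
               removeSuperiorHalfplane(vol, "Y", cr[c(1, 3)], cl[c(1, 3)]))
  oa <- landmark(lm, "occlusal_anterior"); op <- landmark(lm, "occlusal_posterior")
  vol <- stage("remove_anterior_face",
               removeSuperiorHalfplane(vol, "X", oa[c(2, 3)], op[c(2, 3)]))
  occlusalZ <- oa[3]
  vol <- stage("remove_vertebrae",
               removeCervicalVertebrae(vol, occlusalZ, config))
  ca <- landmark(lm, "condyle_a"); cb <- landmark(lm, "condyle_b")
  cc <- stage("remove_condyle_caps", removeCondyleCaps(vol, ca, cb, config))
  vol <- cc$volume; stopZ <- cc$stopZ

  mask <- stage("cumulative_binarize",
                cumulativeBinarize(vol, occlusalZ - config@toothLength,
                                   stopZ, config))
  canines <- rbind(landmark(lm, "canine_right"), landmark(lm, "canine_left"))
  arch <- stage("build_arch_image",
                buildArchImage(mask,
                               dentalBand = c(occlusalZ - config@toothLength,
                                              occlusalZ),
                               ramusBand = c(occlusalZ, stopZ),
                               canines = canines))
  manifest <- list(
    subject = subjectId,
    config = .configToList(config),
    inputs = inputs,
    stopZ = stopZ, occlusalZ = as.numeric(occlusalZ),
    hashes = list(volume = .hashObject(volume@data),
                  landmarks = .hashObject(landmarks@points),
                  mask = .hashObject(mask@data),
                  arch = .hashObject(arch@mask)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    saveVolume(volume3D(mask@data * 1, mask@spacing, mask@origin),
               file.path(outDir, paste0(subjectId, "_mask.nii.gz")))
    saveArchImage(arch, file.path(outDir, paste0(subjectId, "_arch.png")))
  }
  list(arch = arch, mask = mask, stopZ = stopZ,
       occlusalZ = as.numeric(occlusalZ), manifest = manifest)
}

#' Run the cohort-level pipeline
#'
#' Superimposes the subjects' arch images on the canine midpoint, selects
#' the area-matched threshold, extracts the average-arch centerline, fits
#' the focal trough, computes the thickness profile with its regional
#' minima, and locates the arch-to-ramus transition.
#'
#' @param arches list of [ArchImage-class] (>= 1), or paths readable by
#'   [loadArchImage()].
#' @param config a [PipelineConfig-class].
#' @param individualAreas optional per-subject areas (mm^2) overriding the
#'   areas of `arches`.
#' @return list with `average` ([AverageArch-class]), `centerline`,
#'   `trough` ([TroughModel-class]), `profile` ([ThicknessProfile-class]),
#'   `transition` ([TransitionResult-class]), `report`
#'   ([AnalysisReport-class]), `manifest`
#' @export
runCohort <- function(arches, config = pipelineConfig(),
                      individualAreas = NULL) {
  if (length(arches) && is.character(arches[[1]]))
    arches <- lapply(arches, loadArchImage)
  avg <- superimposeArches(arches)
  avg <- areaMatchedThreshold(avg, individualAreas, config)
  cline <- archCenterline(avg)
  trough <- fitTrough(avg, cline, avg@canines, config)
  profile <- thicknessProfile(trough, config)
  transition <- locateTransition(trough)
  report <- new("AnalysisReport",
                threshold = avg@threshold,
                meanIndividualArea = avg@meanIndividualArea,
                averageArea = avg@maskArea,
                anteriorMin = profile@anteriorMin,
                posteriorMin = profile@posteriorMin,
                transitionLateral = transition@lateral,
                transitionPosterior = transition@posterior,
                transitionSlope = transition@slope,
                splines = list(
                  center_x = .splineToList(trough@center@x),
                  center_y = .splineToList(trough@center@y),
                  buccal_x = .splineToList(trough@buccal@x),
                  buccal_y = .splineToList(trough@buccal@y),
                  lingual_x = .splineToList(trough@lingual@x),
                  lingual_y = .splineToList(trough@lingual@y)))
  manifest <- list(
    nSubjects = length(arches),
    config = .configToList(config),
    threshold = avg@threshold,
    hashes = list(frequency = .hashObject(avg@freq),
                  mask = .hashObject(avg@mask),
                  report = .hashObject(report)))
  list(average = avg, centerline = cline, trough = trough,
       profile = profile, transition = transition, report = report,
       manifest = manifest)
}

.configToList <- function(config) {
  list(vertebraMagnification = config@vertebraMagnification,
       maskMagnification = config@maskMagnification,
       condyleEllipse = config@condyleEllipse,
       toothLength = config@toothLength,
       kPrevSlices = config@kPrevSlices,
       thresholdGridStep = config@thresholdGridStep,
       splineSmooth = config@splineSmooth,
       thicknessStep = config@thicknessStep)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [PipelineConfig-class] field names; absent keys keep the
#' published defaults.
#'
#' @param path YAML file path
#' @return a [PipelineConfig-class]
#' @export
readPipelineConfig <- function(path) {
  obj <- yaml::read_yaml(path)
  base <- .configToList(pipelineConfig())
  unknown <- setdiff(names(obj), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(obj)] <- obj
  do.call(pipelineConfig, base)
}

#' Write a pipeline configuration to YAML
#' @param config a [PipelineConfig-class]
#' @param path destination path
#' @return `path`, invisibly
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(.configToList(config), path)
  invisible(path)
}
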