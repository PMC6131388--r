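## File formats.  All readers normalize into the package axes convention
## (X = left+, Y = anterior+, Z = superior+; world mm at the API boundary):
## NIfTI-1 read/write (RNifti), MetaImage .mha/.mhd read/write (plain-text
## header + raw little-endian payload), DICOM series read (converted through
## SimpleITK via the system `python`), JSON landmark and report files, and
## PNG + JSON-sidecar arch images.

#' Load a 3D volume from disk
#'
#' Reads a NIfTI-1 file (`.nii`, `.nii.gz`), a MetaImage file (`.mha`,
#' `.mhd`), or a DICOM series directory, and reorients the grid into the
#' package axes convention (X = subject left positive, Y = anterior
#' positive, Z = superior positive) using the stored orientation. Only
#' axis-aligned orientations (permutations/flips) are supported.
#'
#' @param path file or DICOM directory path
#' @return a [Volume3D-class]
#' @export
loadVolume <- function(path) {
  if (dir.exists(path)) return(.loadDicomSeries(path))
  if (!file.exists(path)) stop("format error: no such file: ", path)
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return(.loadNifti(path))
  if (grepl("\\.(mha|mhd)$", low)) return(.loadMetaImage(path))
  stop("format error: unrecognized volume format: ", path)
}

#' Save a 3D volume
#'
#' Writes NIfTI-1 (`.nii`, `.nii.gz`) or MetaImage (`.mha`, `.mhd` +
#' `.raw`), chosen by extension, embedding spacing and origin so that
#' [loadVolume()] round-trips the world geometry exactly.
#'
#' @param vol a [Volume3D-class]
#' @param path destination path
#' @return `path`, invisibly
#' @export
saveVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume3D"))
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) .saveNifti(vol, path)
  else if (grepl("\\.(mha|mhd)$", low)) .saveMetaImage(vol, path)
  else stop("format error: unrecognized volume extension: ", path)
  invisible(path)
}

.saveNifti <- function(vol, path) {
  d <- vol@data
  storage.mode(d) <- "double"
  img <- RNifti::asNifti(d)
  RNifti::pixdim(img) <- vol@spacing
  ## our convention is LAS; NIfTI world is RAS, so negate X
  m <- rbind(c(-vol@spacing[1], 0, 0, -vol@origin[1]),
             c(0, vol@spacing[2], 0, vol@origin[2]),
             c(0, 0, vol@spacing[3], vol@origin[3]),
             c(0, 0, 0, 1))
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
}

.loadNifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("format error: ", conditionMessage(e)))
  data <- as.array(img)
  if (length(dim(data)) > 3L) {
    if (prod(dim(data)[-(1:3)]) != 1L) stop("format error: not a 3D volume")
    dim(data) <- dim(data)[1:3]
  }
  M <- RNifti::xform(img)
  .normalizeOrientation(data, M)
}

## data: 3D array; M: 4x4 voxel(0-based)->RAS affine.  Reorders axes and
## flips so that i,j,k run along +X(left), +Y(anterior), +Z(superior).
.normalizeOrientation <- function(data, M) {
  L <- diag(c(-1, 1, 1, 1)) %*% M   # RAS -> LAS world
  A <- L[1:3, 1:3]
  perm <- integer(3); sgn <- numeric(3)
  for (worldAx in 1:3) {
    j <- which.max(abs(A[worldAx, ]))
    if (abs(A[worldAx, j]) < 1e-9 ||
        max(abs(A[worldAx, -j])) > 1e-6 * abs(A[worldAx, j]))
      stop("format error: oblique orientation not supported")
    perm[worldAx] <- j
    sgn[worldAx] <- sign(A[worldAx, j])
  }
  if (anyDuplicated(perm)) stop("format error: degenerate orientation")
  out <- aperm(data, perm)
  dm <- dim(out)
  corner <- numeric(3)  # old 0-based index of the new (0,0,0) voxel
  for (worldAx in 1:3) {
    if (sgn[worldAx] < 0) {
      idx <- lapply(dm, seq_len)
      idx[[worldAx]] <- rev(idx[[worldAx]])
      out <- do.call(`[`, c(list(out), idx, list(drop = FALSE)))
      corner[perm[worldAx]] <- dm[worldAx] - 1
    }
  }
  sp <- abs(A[cbind(1:3, perm)])
  orig <- as.numeric(L[1:3, 1:3] %*% corner + L[1:3, 4])
  volume3D(out, spacing = sp, origin = orig)
}

## ---- MetaImage ----

.metaTypes <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                MET_SHORT = "integer", MET_USHORT = "integer",
                MET_INT = "integer", MET_UINT = "integer",
                MET_FLOAT = "double", MET_DOUBLE = "double")
.metaSizes <- c(MET_UCHAR = 1, MET_CHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
                MET_INT = 4, MET_UINT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)

.saveMetaImage <- function(vol, path) {
  mhd <- grepl("\\.mhd$", tolower(path))
  rawName <- if (mhd) sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
             else "LOCAL"
  hdr <- c(
    "ObjectType = Image", "NDims = 3", "BinaryData = True",
    "BinaryDataByteOrderMSB = False", "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(vol@origin, collapse = " ")),
    "CenterOfRotation = 0 0 0", "AnatomicalOrientation = ???",
    paste("ElementSpacing =", paste(vol@spacing, collapse = " ")),
    paste("DimSize =", paste(dim(vol@data), collapse = " ")),
    "ElementType = MET_DOUBLE",
    paste("ElementDataFile =", rawName))
  payload <- as.numeric(vol@data)
  if (mhd) {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), rawName), "wb")
    writeBin(payload, con, size = 8, endian = "little")
    close(con)
  } else {
    con <- file(path, "wb")
    writeLines(hdr, con, sep = "\n")
    writeBin(payload, con, size = 8, endian = "little")
    close(con)
  }
}

.loadMetaImage <- function(path) {
  rawAll <- readBin(path, "raw", file.info(path)$size)
  ## header = everything up to and including the ElementDataFile line
  txtEnd <- length(rawAll)
  marker <- charToRaw("ElementDataFile")
  pos <- NULL
  limit <- min(length(rawAll), 65536L)
  for (i in seq_len(limit - length(marker) + 1L)) {
    if (rawAll[i] == marker[1] &&
        identical(rawAll[i:(i + length(marker) - 1L)], marker)) { pos <- i; break }
  }
  if (is.null(pos)) stop("format error: no ElementDataFile key in ", path)
  nlAfter <- pos + which(rawAll[pos:limit] == as.raw(10))[1] - 1L
  if (is.na(nlAfter)) nlAfter <- length(rawAll)
  hdrTxt <- strsplit(rawToChar(rawAll[1:nlAfter]), "\n", fixed = TRUE)[[1]]
  kv <- list()
  for (line in hdrTxt) {
    parts <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(parts) >= 2)
      kv[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  need <- c("DimSize", "ElementSpacing", "ElementType", "ElementDataFile")
  for (k in need) if (is.null(kv[[k]]))
    stop("metadata error: MetaImage header missing ", k)
  dm <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]])
  off <- if (!is.null(kv$Offset)) as.numeric(strsplit(kv$Offset, "\\s+")[[1]])
         else rep(0, 3)
  if (!is.null(kv$TransformMatrix)) {
    tm <- as.numeric(strsplit(kv$TransformMatrix, "\\s+")[[1]])
    if (max(abs(tm - c(1, 0, 0, 0, 1, 0, 0, 0, 1))) > 1e-9)
      stop("format error: non-identity MetaImage TransformMatrix not supported")
  }
  et <- kv$ElementType
  if (!et %in% names(.metaTypes)) stop("format error: ElementType ", et)
  n <- prod(dm)
  if (identical(kv$ElementDataFile, "LOCAL")) {
    con <- rawConnection(rawAll[(nlAfter + 1L):length(rawAll)])
  } else {
    con <- file(file.path(dirname(path), kv$ElementDataFile), "rb")
  }
  on.exit(close(con))
  vals <- readBin(con, .metaTypes[[et]], n = n, size = .metaSizes[[et]],
                  endian = "little",
                  signed = !(et %in% c("MET_UCHAR", "MET_USHORT")))
  if (length(vals) != n) stop("format error: truncated MetaImage payload")
  volume3D(array(as.numeric(vals), dm), spacing = sp, origin = off)
}

## ---- DICOM (via SimpleITK through the system python) ----

.loadDicomSeries <- function(path) {
  files <- list.files(path)
  if (!length(files)) stop("format error: empty DICOM directory: ", path)
  py <- Sys.which("python")
  if (py == "") stop("format error: DICOM reading requires `python` with SimpleITK on PATH")
  out <- tempfile(fileext = ".nii.gz")
  code <- paste(
    "import sys, SimpleITK as sitk",
    "r = sitk.ImageSeriesReader()",
    "ids = r.GetGDCMSeriesIDs(sys.argv[1])",
    "assert ids, 'no DICOM series found'",
    "r.SetFileNames(r.GetGDCMSeriesFileNames(sys.argv[1], ids[0]))",
    "sitk.WriteImage(r.Execute(), sys.argv[2])",
    sep = "; ")
  st <- system2(py, c("-c", shQuote(code), shQuote(path), shQuote(out)),
                stdout = TRUE, stderr = TRUE)
  if (!file.exists(out))
    stop("format error: DICOM conversion failed: ",
         paste(st, collapse = " "))
  .loadNifti(out)
}

## ---- landmarks ----

#' Load a landmark file
#'
#' Reads a flat JSON object `{name: [x, y, z], ...}` of world-mm
#' coordinates with exactly the ten landmark names (see [landmarkNames()]).
#' If `volume` is given, every point must lie inside its bounds.
#'
#' @param path JSON file path
#' @param volume optional [Volume3D-class] for the bounds check
#' @return a [LandmarkSet-class]
#' @export
loadLandmarks <- function(path, volume = NULL) {
  if (!file.exists(path)) stop("schema error: no such file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("schema error: ", conditionMessage(e)))
  missing <- setdiff(.LANDMARK_NAMES, names(obj))
  if (length(missing))
    stop("schema error: missing landmark key(s): ",
         paste(missing, collapse = ", "))
  lm <- landmarkSet(obj[.LANDMARK_NAMES])
  if (!is.null(volume)) {
    lo <- volume@origin - volume@spacing / 2
    hi <- volume@origin + (dim(volume@data) - 0.5) * volume@spacing
    bad <- apply(lm@points, 1, function(p) any(p < lo) || any(p > hi))
    if (any(bad))
      stop("bounds error: landmark(s) outside the volume: ",
           paste(rownames(lm@points)[bad], collapse = ", "))
  }
  lm
}

#' Save a landmark set to JSON
#' @param landmarks a [LandmarkSet-class]
#' @param path destination path
#' @return `path`, invisibly
#' @export
saveLandmarks <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  obj <- lapply(seq_len(nrow(landmarks@points)),
                function(i) as.numeric(landmarks@points[i, ]))
  names(obj) <- rownames(landmarks@points)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

## ---- analysis report ----

#' Save an analysis report to JSON
#'
#' Lossless serialization of all report fields, including the breaks and
#' four cubic coefficients of every stored spline piece.
#'
#' @param report an [AnalysisReport-class]
#' @param path destination path
#' @return `path`, invisibly
#' @export
saveReport <- function(report, path) {
  stopifnot(is(report, "AnalysisReport"))
  obj <- list(
    threshold = report@threshold,
    mean_individual_area_mm2 = report@meanIndividualArea,
    average_area_mm2 = report@averageArea,
    anterior_min_mm = report@anteriorMin,
    posterior_min_mm = report@posteriorMin,
    transition = list(lateral_mm = report@transitionLateral,
                      posterior_mm = report@transitionPosterior,
                      slope_deg = report@transitionSlope),
    splines = lapply(report@splines, function(s)
      list(breaks = s$breaks, coef = s$coef)))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("I/O error: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Load an analysis report from JSON
#' @param path JSON file path
#' @return an [AnalysisReport-class]
#' @export
loadReport <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                  error = function(e) stop("parse error: ", conditionMessage(e)))
  splines <- lapply(obj$splines, function(s) {
    co <- s$coef
    if (is.null(dim(co))) co <- matrix(co, ncol = 4)
    list(breaks = as.numeric(s$breaks), coef = co)
  })
  if (is.null(splines)) splines <- list()
  new("AnalysisReport",
      threshold = obj$threshold,
      meanIndividualArea = obj$mean_individual_area_mm2,
      averageArea = obj$average_area_mm2,
      anteriorMin = obj$anterior_min_mm,
      posteriorMin = obj$posterior_min_mm,
      transitionLateral = obj$transition$lateral_mm,
      transitionPosterior = obj$transition$posterior_mm,
      transitionSlope = obj$transition$slope_deg,
      splines = splines)
}

## ---- arch images (PNG mask + JSON sidecar) ----

#' Save an arch image as PNG plus JSON sidecar
#'
#' The binary mask is written as a grayscale PNG; pixel spacing, origin,
#' reference point and canine points go into `<path>.json`.
#'
#' @param arch an [ArchImage-class]
#' @param path PNG destination path
#' @return `path`, invisibly
#' @export
saveArchImage <- function(arch, path) {
  stopifnot(is(arch, "ArchImage"))
  png::writePNG(t(arch@mask * 1)[rev(seq_len(ncol(arch@mask))), , drop = FALSE],
                path)
  side <- list(spacing = arch@spacing, origin = arch@origin,
               reference = arch@reference, canines = arch@canines)
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Load an arch image written by [saveArchImage()]
#' @param path PNG path (the `.json` sidecar must sit next to it)
#' @return an [ArchImage-class]
#' @export
loadArchImage <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  mask <- t(img[rev(seq_len(nrow(img))), , drop = FALSE]) > 0.5
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  canines <- side$canines
  if (is.null(dim(canines))) canines <- matrix(canines, 2, 2)
  new("ArchImage", mask = mask, spacing = as.numeric(side$spacing),
      origin = as.numeric(side$origin),
      reference = as.numeric(side$reference), canines = canines)
}
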