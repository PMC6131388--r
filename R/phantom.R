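## Synthetic skull phantom: a U-shaped mandibular arch band (parabolic
## anterior segment joined C1 to straight rami at a known tangent angle)
## extruded in Z, condylar knobs at the ramus tops, optional soft-tissue,
## vertebral and cranial confounders, a smooth multiplicative bias field and
## Gaussian noise.  Every phantom carries its analytic ground truth, so each
## pipeline stage can be scored without patient data.

#' Phantom specification with realistic adult defaults
#'
#' The default geometry emulates an adult mandible inside a 154 mm
#' field of view: a parabolic arch of 25 mm anterior half-depth and 30 mm
#' half-width, straight rami leaving the parabola at a 40 degree tangent to
#' the midsagittal axis, a 12 mm wide bone band, 20 mm tooth/body depth,
#' rami ascending 35 mm above the occlusal plane to 7 mm condylar knobs.
#' Default intensities (bone 0.85, soft tissue 0.15, background 0.05),
#' a 10% multiplicative bias field and noise s.d. 0.02 give a CBCT-like
#' contrast with realistic shading.
#'
#' @param dim integer(3) grid size (default 128^3).
#' @param spacing numeric(3) mm (default 1.2 mm isotropic).
#' @param archDepth parabola anterior half-depth a, mm.
#' @param archHalfWidth parabola half-width b, mm.
#' @param ramusAngle ramus tangent angle to the midsagittal axis, degrees.
#' @param bandWidth full arch band width, mm.
#' @param ramusLength straight ramus length in the axial plane, mm.
#' @param apexY world Y of the anterior apex, mm.
#' @param occlusalZ world Z of the occlusal plane, mm.
#' @param bodyDepth mandibular body depth below the occlusal plane, mm.
#' @param ramusTopZ world Z of the ramus top, mm.
#' @param condyleRadius condylar knob radius, mm (0 disables the knobs).
#' @param canineX |X| of the canine contact points, mm.
#' @param boneIntensity,softIntensity,backgroundIntensity tissue intensities.
#' @param includeSoftTissue,includeVertebra,includeCranium confounder flags.
#' @param vertebraRadius,vertebraY posterior vertebra cylinder radius and
#'   center Y, mm.
#' @param craniumZ inferior face of the cranial slab, mm.
#' @param noiseSd additive Gaussian noise s.d.
#' @param biasAmplitude amplitude of the multiplicative bias field.
#' @param seed RNG seed.
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(dim = c(128L, 128L, 128L), spacing = c(1.2, 1.2, 1.2),
                        archDepth = 25, archHalfWidth = 30, ramusAngle = 40,
                        bandWidth = 12, ramusLength = 40,
                        apexY = 35, occlusalZ = 0, bodyDepth = 20,
                        ramusTopZ = 35, condyleRadius = 7, canineX = 10,
                        boneIntensity = 0.85, softIntensity = 0.15,
                        backgroundIntensity = 0.05,
                        includeSoftTissue = TRUE, includeVertebra = TRUE,
                        includeCranium = TRUE,
                        vertebraRadius = 10, vertebraY = -45, craniumZ = 55,
                        noiseSd = 0.02, biasAmplitude = 0.1, seed = 1L) {
  new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
      archDepth = archDepth, archHalfWidth = archHalfWidth,
      ramusAngle = ramusAngle, bandWidth = bandWidth,
      ramusLength = ramusLength, apexY = apexY, occlusalZ = occlusalZ,
      bodyDepth = bodyDepth, ramusTopZ = ramusTopZ,
      condyleRadius = condyleRadius, canineX = canineX,
      boneIntensity = boneIntensity, softIntensity = softIntensity,
      backgroundIntensity = backgroundIntensity,
      includeSoftTissue = includeSoftTissue,
      includeVertebra = includeVertebra, includeCranium = includeCranium,
      vertebraRadius = vertebraRadius, vertebraY = vertebraY,
      craniumZ = craniumZ, noiseSd = noiseSd, biasAmplitude = biasAmplitude,
      seed = as.integer(seed))
}

## analytic centerline of the arch in the axial plane.
## Returns the ordered polyline (right ramus end -> apex -> left ramus end),
## the signed arc length (0 at the apex, negative on the right), and the
## closed-form joint: x_t = b^2 / (2 a tan(theta)).
.phantomCenterline <- function(spec, step = 0.4) {
  a <- spec@archDepth; b <- spec@archHalfWidth
  th <- spec@ramusAngle * pi / 180
  xt <- b^2 / (2 * a * tan(th))
  if (spec@bandWidth / 2 >= b^2 / (2 * a))
    stop("band self-intersection: bandWidth too large for the arch curvature")
  yPar <- function(x) spec@apexY - a * x^2 / b^2
  ## left half: parabola from apex to joint, then straight ramus
  xs <- seq(0, xt, by = step / 2)
  par <- cbind(xs, yPar(xs))
  dirR <- c(sin(th), -cos(th))
  tEnd <- spec@ramusLength
  ts <- seq(0, tEnd, by = step)[-1]
  ram <- cbind(par[nrow(par), 1] + ts * dirR[1],
               par[nrow(par), 2] + ts * dirR[2])
  left <- rbind(par, ram)
  arcL <- .polylineArc(left)
  ## resample evenly, then mirror
  sL <- seq(0, max(arcL), by = step)
  left <- .polylineAt(left, arcL, sL)
  right <- left[nrow(left):1, , drop = FALSE]
  right[, 1] <- -right[, 1]
  poly <- rbind(right[-nrow(right), , drop = FALSE], left)
  s <- c(-rev(sL)[-length(sL)], sL)
  sJoint <- sL[which.min(abs(left[, 1] - xt))]
  list(poly = poly, s = s, joint = c(xt, yPar(xt)), sJoint = sJoint,
       end = left[nrow(left), ])
}

## per-pixel distance to the centerline and arc position of the nearest
## sample, on the axial grid of the spec (chunked to bound memory)
.centerlineFields <- function(spec, cl) {
  nx <- spec@dim[1]; ny <- spec@dim[2]
  ox <- -(spec@dim - 1) * spec@spacing / 2
  gx <- ox[1] + (seq_len(nx) - 1) * spec@spacing[1]
  gy <- ox[2] + (seq_len(ny) - 1) * spec@spacing[2]
  px <- rep(gx, times = ny)
  py <- rep(gy, each = nx)
  best <- rep(Inf, nx * ny)
  bestS <- rep(0, nx * ny)
  pts <- cl$poly; s <- cl$s
  chunk <- 64L
  for (i0 in seq(1, nrow(pts), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nrow(pts))
    d2 <- outer(px, pts[i0:i1, 1], `-`)^2 + outer(py, pts[i0:i1, 2], `-`)^2
    mi <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_len(nrow(d2)), mi)]
    upd <- dmin < best
    best[upd] <- dmin[upd]
    bestS[upd] <- s[i0:i1][mi[upd]]
  }
  list(dist = matrix(sqrt(best), nx, ny), sNear = matrix(bestS, nx, ny))
}

#' Generate a synthetic phantom volume with ground truth
#'
#' Renders the arch band, rami and condylar knobs plus the requested
#' confounders at the spec's intensities, applies the multiplicative bias
#' field and Gaussian noise (seeded), and returns the volume together with
#' its analytic ground truth: sampled centerline, half-width, true landmark
#' set, true transition, and the clean mandible mask.
#'
#' @param spec a [PhantomSpec-class]
#' @return list with elements `volume` ([Volume3D-class]) and `truth`
#'   ([PhantomGroundTruth-class])
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  cl <- .phantomCenterline(spec)
  fld <- .centerlineFields(spec, cl)
  nx <- spec@dim[1]; ny <- spec@dim[2]; nz <- spec@dim[3]
  sp <- spec@spacing
  orig <- -(spec@dim - 1) * sp / 2
  gz <- orig[3] + (seq_len(nz) - 1) * sp[3]
  w2 <- spec@bandWidth / 2
  inBand <- fld$dist <= w2
  isRamus <- abs(fld$sNear) >= cl$sJoint

  mand <- array(FALSE, spec@dim)
  kBody <- which(gz >= spec@occlusalZ - spec@bodyDepth & gz <= spec@occlusalZ)
  kRamus <- which(gz > spec@occlusalZ & gz <= spec@ramusTopZ)
  if (length(kBody)) mand[, , kBody] <- inBand
  if (length(kRamus)) mand[, , kRamus] <- inBand & isRamus
  ## condylar knobs
  if (spec@condyleRadius > 0) {
    gx <- orig[1] + (seq_len(nx) - 1) * sp[1]
    gy <- orig[2] + (seq_len(ny) - 1) * sp[2]
    endL <- cl$end
    for (sgn in c(-1, 1)) {
      cx <- sgn * endL[1]; cy <- endL[2]; cz <- spec@ramusTopZ
      kz <- which(abs(gz - cz) <= spec@condyleRadius)
      for (kk in kz) {
        r2 <- spec@condyleRadius^2 - (gz[kk] - cz)^2
        disk <- outer((gx - cx)^2, (gy - cy)^2, `+`) <= r2
        mand[, , kk] <- mand[, , kk] | disk
      }
    }
  }

  img <- array(spec@backgroundIntensity, spec@dim)
  gx <- orig[1] + (seq_len(nx) - 1) * sp[1]
  gy <- orig[2] + (seq_len(ny) - 1) * sp[2]
  if (spec@includeSoftTissue) {
    ell <- outer((gx / 55)^2, (gy / 50)^2, `+`) <= 1
    kSoft <- which(gz >= spec@occlusalZ - spec@bodyDepth - 10 &
                     gz <= spec@occlusalZ + 50)
    for (kk in kSoft) img[, , kk][ell] <- spec@softIntensity
  }
  img[mand] <- spec@boneIntensity
  if (spec@includeVertebra) {
    cyl <- outer((gx - 0)^2, (gy - spec@vertebraY)^2, `+`) <=
      spec@vertebraRadius^2
    kV <- which(gz >= spec@occlusalZ - spec@bodyDepth - 10 &
                  gz <= spec@occlusalZ + 50)
    for (kk in kV) img[, , kk][cyl] <- spec@boneIntensity
  }
  if (spec@includeCranium) {
    kC <- which(gz >= spec@craniumZ & gz <= spec@craniumZ + 15)
    if (length(kC)) img[, , kC] <- spec@boneIntensity
  }

  if (spec@biasAmplitude > 0) {
    xh <- gx / max(abs(gx)); yh <- gy / max(abs(gy)); zh <- gz / max(abs(gz))
    B <- array(rep(0.6 * xh, times = ny * nz), spec@dim) +
      array(rep(rep(0.25 * yh, each = nx), times = nz), spec@dim) +
      array(rep(-0.15 * zh, each = nx * ny), spec@dim) +
      array(rep(0.4 * outer(xh, yh), times = nz), spec@dim)
    img <- img * (1 + spec@biasAmplitude * pmin(pmax(B, -1), 1))
  }
  if (spec@noiseSd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(spec@seed)
    img <- img + array(stats::rnorm(length(img), 0, spec@noiseSd), spec@dim)
  }

  vol <- volume3D(img, spacing = sp, origin = orig)
  truth <- .phantomTruth(spec, cl, mand, sp, orig)
  list(volume = vol, truth = truth)
}

## assemble the ground-truth object (landmarks, analytic transition, mask)
.phantomTruth <- function(spec, cl, mand, sp, orig) {
  a <- spec@archDepth; b <- spec@archHalfWidth
  yC <- spec@apexY - a * spec@canineX^2 / b^2
  zCut <- spec@ramusTopZ + spec@condyleRadius + 4
  condZ <- spec@ramusTopZ + spec@condyleRadius
  endL <- cl$end
  yAnt <- spec@apexY + spec@bandWidth / 2 + 1
  mSlope <- 2.2
  lm <- landmarkSet(list(
    frankfort_orbit = c(0, 50, 60), frankfort_meatus = c(0, -40, 60),
    coronal_right = c(-55, 0, zCut), coronal_left = c(55, 0, zCut),
    occlusal_anterior = c(0, yAnt, spec@occlusalZ),
    occlusal_posterior = c(0, yAnt - 30, spec@occlusalZ + mSlope * 30),
    condyle_a = c(-endL[1], endL[2], condZ),
    condyle_b = c(endL[1], endL[2], condZ),
    canine_right = c(-spec@canineX, yC, spec@occlusalZ),
    canine_left = c(spec@canineX, yC, spec@occlusalZ)
  ))
  trans <- new("TransitionResult",
               lateral = cl$joint[1],
               posterior = yC - cl$joint[2],
               slope = spec@ramusAngle)
  new("PhantomGroundTruth",
      centerline = cl$poly, arcLength = cl$s,
      halfWidth = rep(spec@bandWidth / 2, nrow(cl$poly)),
      landmarks = lm, transition = trans,
      mask = binaryVolume3D(mand, spacing = sp, origin = orig))
}

#' Generate a cohort of phantoms with parameter variability
#'
#' Draws `n` phantom specs with the shape parameters (arch depth, arch
#' half-width, ramus angle, band width, ramus length) perturbed by
#' independent Gaussians with relative s.d. `variability` around the base
#' spec, truncated to validity (at most 100 redraws per subject), each with
#' a sub-seed derived from `seed`.
#'
#' @param baseSpec a [PhantomSpec-class]
#' @param n number of subjects (>= 1)
#' @param variability relative s.d. of the varied parameters (e.g. 0.05);
#'   0 reproduces the base spec for every subject.
#' @param seed integer seed driving both the parameter draws and each
#'   phantom's noise.
#' @return list of `n` lists with elements `volume` and `truth`
#' @export
generateCohort <- function(baseSpec, n, variability = 0.05, seed = 1L) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()), add = TRUE)
  out <- vector("list", n)
  ## one derived sub-seed drives every phantom's noise (so zero
  ## variability reproduces identical volumes); parameter draws come from
  ## a single stream seeded once
  subSeed <- as.integer((seed * 1009 + 1) %% .Machine$integer.max)
  set.seed(seed)
  for (i in seq_len(n)) {
    spec <- NULL
    for (try in seq_len(100)) {
      cand <- baseSpec
      if (variability > 0) {
        cand@archDepth <- baseSpec@archDepth * (1 + stats::rnorm(1, 0, variability))
        cand@archHalfWidth <- baseSpec@archHalfWidth * (1 + stats::rnorm(1, 0, variability))
        cand@ramusAngle <- baseSpec@ramusAngle * (1 + stats::rnorm(1, 0, variability))
        cand@bandWidth <- baseSpec@bandWidth * (1 + stats::rnorm(1, 0, variability))
        cand@ramusLength <- baseSpec@ramusLength * (1 + stats::rnorm(1, 0, variability))
      }
      cand@seed <- subSeed
      ok <- tryCatch({
        validObject(cand)
        if (cand@bandWidth / 2 >= cand@archHalfWidth^2 / (2 * cand@archDepth))
          stop("self-intersection")
        TRUE
      }, error = function(e) FALSE)
      if (ok) { spec <- cand; break }
    }
    if (is.null(spec))
      stop("could not draw a valid spec for subject ", i, " in 100 tries")
    rngState <- get(".Random.seed", envir = globalenv())
    out[[i]] <- generatePhantom(spec)
    assign(".Random.seed", rngState, envir = globalenv())
  }
  out
}
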