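# Synthetic dynamic thorax phantom: the ground-truth oracle for every
# detector. Region boundaries are continuous mm positions rendered through
# Gaussian-CDF edge transitions, so the blurred piecewise-constant profile
# has its steepest declines/inclines and its lung-rib inflection exactly at
# the exported truth positions (up to pixel sampling).

#' Construct a phantom specification
#'
#' Defaults emulate a tangential-field thorax phantom at EPID resolution:
#' a 128 x 224 frame at 0.5 mm pixels, jaws at 16.3 and 96.3 mm (80 mm field),
#' 5 mm exposed lung, a 5 mm rib strip, 20 mm of skin-air flash, a gentle
#' quadratic chest wall bow and 2% Gaussian noise.
#'
#' @param nRows,nCols image size in pixels.
#' @param rowSpacingMm,colSpacingMm pixel size in mm.
#' @param medialEdgeMm,lateralEdgeMm jaw positions in mm.
#' @param exposedLungMm lung exposed between medial border and junction.
#' @param ribThicknessMm rib strip width in mm.
#' @param flashWidthMm skin-air flash width before the lateral border.
#' @param intensities named vector (blocked, rib, breast, lung, flash).
#' @param mlcCorner,mlcIntensity emulate MLC corner shielding: the medial
#'   blocked region is rendered at \code{mlcIntensity}, weakening the medial
#'   gradient below the skin-air drop (the narrow-field failure mode).
#' @param curvatureAmplitudeMm quadratic bow of the chest wall across rows.
#' @param noiseSigma noise SD as a fraction of the intensity range.
#' @param noiseModel \code{"gaussian"} (dose-integrated cine frames) or
#'   \code{"poisson"}.
#' @param edgeSoftnessMm Gaussian penumbra scale of all edges (default 0.5).
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(nRows = 128L, nCols = 224L, rowSpacingMm = 0.5,
                        colSpacingMm = 0.5, medialEdgeMm = 16.3,
                        lateralEdgeMm = 96.3, exposedLungMm = 5,
                        ribThicknessMm = 5, flashWidthMm = 20,
                        intensities = c(blocked = 1.0, rib = 0.75,
                                        breast = 0.6, lung = 0.35,
                                        flash = 0.1),
                        mlcCorner = FALSE, mlcIntensity = 0.55,
                        curvatureAmplitudeMm = 1, noiseSigma = 0.02,
                        noiseModel = "gaussian", edgeSoftnessMm = 0.5) {
  new("PhantomSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      rowSpacingMm = rowSpacingMm, colSpacingMm = colSpacingMm,
      medialEdgeMm = medialEdgeMm, lateralEdgeMm = lateralEdgeMm,
      exposedLungMm = exposedLungMm, ribThicknessMm = ribThicknessMm,
      flashWidthMm = flashWidthMm, intensities = intensities,
      mlcCorner = mlcCorner, mlcIntensity = mlcIntensity,
      curvatureAmplitudeMm = curvatureAmplitudeMm, noiseSigma = noiseSigma,
      noiseModel = noiseModel, edgeSoftnessMm = edgeSoftnessMm)
}

# Evaluate an expression under a temporary RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Per-row anatomy positions (mm) for a spec + rigid displacement.
.phantom_geometry <- function(spec, displacementMm = 0) {
  r <- seq_len(spec@nRows)
  center <- round((spec@nRows + 1) / 2)
  curv <- spec@curvatureAmplitudeMm *
    ((r - center) / ((spec@nRows - 1) / 2))^2
  shift <- curv + displacementMm
  m <- spec@medialEdgeMm
  l <- spec@lateralEdgeMm
  junction <- m + spec@exposedLungMm + shift
  rib_end <- junction + spec@ribThicknessMm
  skin <- (l - spec@flashWidthMm) + shift
  if (any(junction < m))
    stop("displacement pushes the lung-rib junction medial of the field edge")
  if (any(skin > l - 2))
    stop("displacement pushes the skin-air flash outside the field")
  data.frame(row = r, medialMm = m, lateralMm = l, junctionMm = junction,
             peakMm = junction + spec@ribThicknessMm / 2,
             ribEndMm = rib_end, skinMm = skin,
             cwpMedialMm = junction - m, cwpLateralMm = l - junction,
             displacementMm = displacementMm)
}

#' Render one synthetic phantom frame with ground truth
#'
#' The noiseless frame is the analytically blurred piecewise-constant
#' anatomy (Gaussian-CDF transitions of scale \code{edgeSoftnessMm} at each
#' region boundary); noise is added afterwards and pixels are clamped at 0
#' and quantized to the 1e-4 grid used by 16-bit DICOM storage. Geometry is
#' independent of the seed, so two seeds give identical truth and different
#' noise.
#'
#' @param spec a [PhantomSpec-class].
#' @param seed integer RNG seed for the noise (NULL draws from the current
#'   RNG stream).
#' @param displacementMm rigid chest wall displacement in mm applied to the
#'   junction and all anatomy lateral of it (jaws fixed).
#' @param frameIndex,beamId,fractionId,acquisitionTime frame metadata.
#' @return list with elements \code{frame} (an [EpidFrame-class]) and
#'   \code{truth}, a data.frame of per-row ground truth with columns
#'   \code{row}, \code{medialMm}, \code{lateralMm}, \code{junctionMm},
#'   \code{peakMm}, \code{ribEndMm}, \code{skinMm}, \code{cwpMedialMm},
#'   \code{cwpLateralMm}, \code{displacementMm}.
#' @examples
#' ph <- renderPhantom(phantomSpec(exposedLungMm = 10), seed = 7)
#' ph$truth$cwpMedialMm[64]   # 10 mm plus the (zero at center) curvature
#' @export
renderPhantom <- function(spec, seed = NULL, displacementMm = 0,
                          frameIndex = 1L, beamId = "beam1",
                          fractionId = "fx1", acquisitionTime = "") {
  stopifnot(is(spec, "PhantomSpec"))
  geo <- .phantom_geometry(spec, displacementMm)
  lev <- spec@intensities
  b_med <- if (spec@mlcCorner) spec@mlcIntensity else unname(lev["blocked"])
  sig <- spec@edgeSoftnessMm
  x <- (seq_len(spec@nCols) - 0.5) * spec@colSpacingMm

  px <- matrix(0, spec@nRows, spec@nCols)
  for (r in seq_len(spec@nRows)) {
    px[r, ] <- b_med +
      (lev["lung"] - b_med) * stats::pnorm((x - geo$medialMm[r]) / sig) +
      (lev["rib"] - lev["lung"]) * stats::pnorm((x - geo$junctionMm[r]) / sig) +
      (lev["breast"] - lev["rib"]) * stats::pnorm((x - geo$ribEndMm[r]) / sig) +
      (lev["flash"] - lev["breast"]) * stats::pnorm((x - geo$skinMm[r]) / sig) +
      (lev["blocked"] - lev["flash"]) * stats::pnorm((x - geo$lateralMm[r]) / sig)
  }

  if (spec@noiseSigma > 0) {
    rng <- diff(range(lev))
    px <- .with_seed(seed, {
      if (spec@noiseModel == "gaussian") {
        px + matrix(stats::rnorm(length(px), 0, spec@noiseSigma * rng),
                    nrow(px))
      } else {
        k <- 1 / spec@noiseSigma^2   # counts per unit intensity
        matrix(stats::rpois(length(px), pmax(px, 0) * k) / k, nrow(px))
      }
    })
  }
  px <- round(pmax(px, 0) / 1e-4) * 1e-4

  frame <- epidFrame(px, spec@rowSpacingMm, spec@colSpacingMm,
                     frameIndex = frameIndex, beamId = beamId,
                     fractionId = fractionId, fieldLabel = "lateral",
                     source = "EPID", acquisitionTime = acquisitionTime)
  list(frame = frame, truth = geo)
}

#' Construct a cine trajectory
#'
#' @param displacementsMm numeric vector of per-frame rigid chest wall
#'   displacements in mm; the first element must be 0 (the first frame is
#'   the motion reference).
#' @return a [TrajectorySpec-class].
#' @seealso [trajectoryStep()], [trajectoryDrift()]
#' @export
trajectorySpec <- function(displacementsMm) {
  new("TrajectorySpec", nFrames = length(displacementsMm),
      displacementsMm = as.numeric(displacementsMm))
}

#' @rdname trajectorySpec
#' @param nFrames number of cine frames.
#' @param stepMm step amplitude in mm.
#' @param atFrame first frame at the stepped position.
#' @export
trajectoryStep <- function(nFrames, stepMm, atFrame) {
  stopifnot(atFrame >= 2L, atFrame <= nFrames)
  trajectorySpec(c(rep(0, atFrame - 1L), rep(stepMm, nFrames - atFrame + 1L)))
}

#' @rdname trajectorySpec
#' @param totalMm final drift amplitude in mm (linear from 0).
#' @export
trajectoryDrift <- function(nFrames, totalMm) {
  trajectorySpec(seq(0, totalMm, length.out = nFrames))
}

#' Render a cine series with programmed motion
#'
#' Frame \code{i} is the phantom displaced by \code{displacementsMm[i]};
#' noise is drawn sequentially from one seeded stream so the series is
#' reproducible as a whole.
#'
#' @param spec a [PhantomSpec-class].
#' @param traj a [TrajectorySpec-class].
#' @param seed integer RNG seed.
#' @param beamId,fractionId series metadata.
#' @return list with elements \code{series} (a [BeamSeries-class]) and
#'   \code{truth}, the row-wise ground truth of all frames with a leading
#'   \code{frame} column.
#' @examples
#' rc <- renderCine(phantomSpec(), trajectoryStep(10, 2, 5), seed = 1)
#' length(rc$series)
#' @export
renderCine <- function(spec, traj, seed = 1L, beamId = "beam1",
                       fractionId = "fx1") {
  stopifnot(is(spec, "PhantomSpec"), is(traj, "TrajectorySpec"))
  .with_seed(seed, {
    out <- vector("list", traj@nFrames)
    for (i in seq_len(traj@nFrames)) {
      out[[i]] <- renderPhantom(
        spec, seed = NULL, displacementMm = traj@displacementsMm[i],
        frameIndex = i, beamId = beamId, fractionId = fractionId,
        acquisitionTime = sprintf("12%02d%02d.%03d",
                                  (i - 1L) %/% 60L, (i - 1L) %% 60L, 0L))
    }
    truth <- do.call(rbind, lapply(seq_along(out), function(i)
      cbind(frame = i, out[[i]]$truth)))
    list(series = beamSeries(lapply(out, `[[`, "frame")), truth = truth)
  })
}
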