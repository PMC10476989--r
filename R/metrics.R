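# Intrafraction motion, MV DRR reference measurement and setup error.
#
# Sign convention throughout: positive = deeper breath hold (chest wall
# displaced posteriorly, more lung exposed). With a medial reference edge
# the chest wall distance grows with a deeper breath; with a lateral
# reference it shrinks, so lateral-referenced raw differences are negated.
# This makes medial- and lateral-referenced results interchangeable.

.edge_sign <- function(referenceEdge) if (referenceEdge == "medial") 1 else -1

.cwp_algorithm <- function(algorithm) {
  switch(algorithm,
         inflection = inflectionCwp,
         peak = peakCwp,
         canny = cannyCwp,
         stop("unknown algorithm: ", algorithm))
}

#' Intrafraction motion of one beam
#'
#' Measures the chest wall position in every cine frame and reports each
#' subsequent frame's shift against the first analyzable frame, plus the
#' signed shift of greatest magnitude (ties broken toward the earlier
#' frame). Frames the detector rejects are skipped with a warning, not
#' interpolated. With fewer than two analyzable frames an empty result is
#' returned and no tolerance flag is raised.
#'
#' @param series a [BeamSeries-class].
#' @param algorithm \code{"inflection"} (default), \code{"peak"} or
#'   \code{"canny"}.
#' @param referenceEdge \code{"lateral"} (default, robust to superior-
#'   inferior motion under MLC shielding) or \code{"medial"}.
#' @param toleranceMm motion tolerance in mm (default 3).
#' @param roi optional [RoiSpec-class]; defaults to [makeRoi()] of the first
#'   frame.
#' @param ... further arguments to the per-frame detector (e.g.
#'   \code{params} for Canny).
#' @return a [MotionResult-class].
#' @examples
#' rc <- renderCine(phantomSpec(exposedLungMm = 10), trajectoryStep(6, 2, 4),
#'                  seed = 1)
#' intrafractionMotion(rc$series)
#' @export
intrafractionMotion <- function(series, algorithm = "inflection",
                                referenceEdge = c("lateral", "medial"),
                                toleranceMm = 3, roi = NULL, ...) {
  stopifnot(is(series, "BeamSeries"), toleranceMm > 0)
  referenceEdge <- match.arg(referenceEdge)
  fun <- .cwp_algorithm(algorithm)
  frs <- frames(series)
  if (is.null(roi)) roi <- makeRoi(frs[[1]])
  beam <- beamId(frs[[1]])

  cwp <- rep(NA_real_, length(frs))
  for (i in seq_along(frs)) {
    m <- tryCatch(fun(frs[[i]], roi, referenceEdge = referenceEdge, ...),
                  error = function(e) {
                    warning("frame ", frameIndex(frs[[i]]), " of beam '",
                            beam, "' excluded: ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    if (!is.null(m)) cwp[i] <- medianMm(m)
  }
  ok <- which(is.finite(cwp))
  if (!length(ok)) stop("all frames of beam '", beam, "' were rejected")
  if (length(ok) < 2L)
    return(new("MotionResult", beamId = beam, frameIndices = integer(0),
               perFrameShiftMm = numeric(0), maxShiftMm = NA_real_,
               withinTolerance = NA, toleranceMm = toleranceMm))

  shifts <- .edge_sign(referenceEdge) * (cwp[ok] - cwp[ok[1]])
  max_shift <- shifts[which.max(abs(shifts))]   # leftmost tie = earlier frame
  new("MotionResult", beamId = beam,
      frameIndices = vapply(frs[ok], frameIndex, integer(1)),
      perFrameShiftMm = shifts, maxShiftMm = max_shift,
      withinTolerance = abs(max_shift) <= toleranceMm,
      toleranceMm = toleranceMm)
}

#' MV window weight of a CT number
#'
#' Piecewise-constant re-weighting that turns a planning-CT projection into
#' an MV-like DRR: CT numbers in [-1000, 100] get weight 0.5, CT numbers in
#' (100, 1000] get weight 2.0 (the boundary value 100 belongs to the lower
#' interval). Values outside [-1000, 1000] are clamped to the nearest bound.
#'
#' @param ctNumber numeric vector/array of CT numbers (HU-like).
#' @return numeric weights, same shape as the input.
#' @examples
#' mvWindowWeight(c(-1000, 100, 500))   # 0.5 0.5 2.0
#' @export
mvWindowWeight <- function(ctNumber) {
  ct <- pmin(pmax(ctNumber, -1000), 1000)
  w <- ifelse(ct <= 100, 0.5, 2.0)
  if (is.array(ctNumber)) dim(w) <- dim(ctNumber)
  w
}

#' Chest wall position on an MV DRR
#'
#' Runs the inflection-point pipeline on the DRR's region of interest (31
#' rows at ~1 mm pixels for the standard 15 mm half-span). The per-row
#' spread is typically larger than on EPID frames because rib curvature and
#' overlap vary the junction across rows.
#'
#' @param drr an [EpidFrame-class] with \code{source = "MV_DRR"} (a warning
#'   is issued otherwise).
#' @param roi a [RoiSpec-class]; defaults to [makeRoi()] of the DRR.
#' @param referenceEdge \code{"lateral"} (default) or \code{"medial"}.
#' @param ... further arguments to [inflectionCwp()].
#' @return a [CwpMeasurement-class].
#' @export
drrCwp <- function(drr, roi = NULL, referenceEdge = c("lateral", "medial"),
                   ...) {
  stopifnot(is(drr, "EpidFrame"))
  referenceEdge <- match.arg(referenceEdge)
  if (!identical(drr@source, "MV_DRR"))
    warning("drrCwp() called on a frame whose source is not MV_DRR")
  if (is.null(roi)) roi <- makeRoi(drr)
  inflectionCwp(drr, roi, referenceEdge = referenceEdge, ...)
}

#' Setup error of one fraction
#'
#' Signed difference between the chest wall position of the first treatment
#' EPID frame and of the planning MV DRR, oriented so that positive means a
#' deeper breath hold at treatment than at simulation. Both measurements
#' must use the same reference edge; they may have different pixel sizes
#' since the subtraction happens in mm at the common reporting plane.
#'
#' @param drrMeas [CwpMeasurement-class] of the planning DRR.
#' @param firstEpidMeas [CwpMeasurement-class] of the first EPID frame.
#' @param toleranceMm setup tolerance in mm (default 5).
#' @param fractionId fraction identifier for the result.
#' @return a [SetupResult-class].
#' @examples
#' ph <- renderPhantom(phantomSpec(exposedLungMm = 10), seed = 1)
#' m <- inflectionCwp(ph$frame, makeRoi(ph$frame), "lateral")
#' setupError(m, m)   # identical measurements: 0 mm
#' @export
setupError <- function(drrMeas, firstEpidMeas, toleranceMm = 5,
                       fractionId = "fx1") {
  stopifnot(is(drrMeas, "CwpMeasurement"), is(firstEpidMeas, "CwpMeasurement"),
            toleranceMm > 0)
  if (!identical(referenceEdge(drrMeas), referenceEdge(firstEpidMeas)))
    stop("mismatched reference edges: DRR uses '", referenceEdge(drrMeas),
         "', EPID uses '", referenceEdge(firstEpidMeas), "'")
  err <- .edge_sign(referenceEdge(drrMeas)) *
    (medianMm(firstEpidMeas) - medianMm(drrMeas))
  new("SetupResult", fractionId = fractionId, setupErrorMm = err,
      withinTolerance = abs(err) <= toleranceMm, toleranceMm = toleranceMm)
}
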