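#' Construct an EpidFrame
#'
#' Low-level constructor; most frames come from [readRTImage()] or the
#' synthetic generator. A frame supplied in the \code{"transmission_up"}
#' convention (denser anatomy darker) is inverted about its intensity range
#' so that the stored frame is always \code{"attenuation_up"}.
#'
#' @param pixels numeric matrix, rows superior to inferior, columns medial to
#'   lateral.
#' @param rowSpacingMm,colSpacingMm pixel size in mm.
#' @param frameIndex integer ordinal within the cine acquisition.
#' @param beamId,fractionId identifiers.
#' @param fieldLabel \code{"medial"} or \code{"lateral"}.
#' @param source \code{"EPID"} or \code{"MV_DRR"}.
#' @param intensityConvention convention of \code{pixels} as supplied.
#' @param planeVerified logical, see [EpidFrame-class].
#' @param acquisitionTime DICOM TM string or \code{""}.
#' @return an [EpidFrame-class] object.
#' @examples
#' f <- epidFrame(matrix(runif(64 * 64), 64), 0.5, 0.5)
#' rowSpacingMm(f)
#' @export
epidFrame <- function(pixels, rowSpacingMm, colSpacingMm,
                      frameIndex = 1L, beamId = "beam1",
                      fractionId = "fx1", fieldLabel = "lateral",
                      source = "EPID",
                      intensityConvention = "attenuation_up",
                      planeVerified = TRUE, acquisitionTime = "") {
  if (identical(intensityConvention, "transmission_up")) {
    pixels <- max(pixels) + min(pixels) - pixels
    intensityConvention <- "attenuation_up"
  }
  new("EpidFrame", pixels = pixels,
      rowSpacingMm = as.numeric(rowSpacingMm),
      colSpacingMm = as.numeric(colSpacingMm),
      frameIndex = as.integer(frameIndex), beamId = beamId,
      fractionId = fractionId, fieldLabel = fieldLabel, source = source,
      intensityConvention = intensityConvention,
      planeVerified = planeVerified, acquisitionTime = acquisitionTime)
}

#' Construct a BeamSeries
#'
#' @param frames list of [EpidFrame-class] objects (ordered).
#' @param referenceFrame optional reference [EpidFrame-class] (e.g. MV DRR).
#' @return a [BeamSeries-class] object.
#' @export
beamSeries <- function(frames, referenceFrame = NULL) {
  new("BeamSeries", frames = frames, referenceFrame = referenceFrame)
}

#' @rdname EpidFrame-class
#' @export
setMethod("pixels", "EpidFrame", function(x) x@pixels)
#' @rdname EpidFrame-class
#' @export
setMethod("rowSpacingMm", "EpidFrame", function(x) x@rowSpacingMm)
#' @rdname EpidFrame-class
#' @export
setMethod("colSpacingMm", "EpidFrame", function(x) x@colSpacingMm)
#' @rdname EpidFrame-class
#' @export
setMethod("frameIndex", "EpidFrame", function(x) x@frameIndex)
#' @rdname EpidFrame-class
#' @export
setMethod("beamId", "EpidFrame", function(x) x@beamId)
#' @rdname EpidFrame-class
#' @export
setMethod("fieldLabel", "EpidFrame", function(x) x@fieldLabel)
#' @rdname EpidFrame-class
#' @export
setMethod("imageSource", "EpidFrame", function(x) x@source)
#' @rdname EpidFrame-class
#' @export
setMethod("planeVerified", "EpidFrame", function(x) x@planeVerified)
#' @rdname EpidFrame-class
#' @export
setMethod("dim", "EpidFrame", function(x) dim(x@pixels))

#' @rdname BeamSeries-class
#' @export
setMethod("frames", "BeamSeries", function(x) x@frames)
#' @rdname BeamSeries-class
#' @export
setMethod("referenceFrame", "BeamSeries", function(x) x@referenceFrame)
#' @rdname BeamSeries-class
#' @export
setMethod("length", "BeamSeries", function(x) length(x@frames))
#' @rdname BeamSeries-class
#' @param i frame position
#' @export
setMethod("[[", "BeamSeries", function(x, i) x@frames[[i]])

#' @rdname RoiSpec-class
#' @export
setMethod("roiRows", "RoiSpec", function(x) {
  half <- (x@nRows - 1L) %/% 2L
  seq.int(x@centerRow - half, x@centerRow + half)
})
#' @rdname RoiSpec-class
#' @export
setMethod("nRows", "RoiSpec", function(x) x@nRows)

#' @rdname FieldBorders-class
#' @export
setMethod("medialCol", "FieldBorders", function(x) x@medialCol)
#' @rdname FieldBorders-class
#' @export
setMethod("lateralCol", "FieldBorders", function(x) x@lateralCol)
#' @rdname FieldBorders-class
#' @export
setMethod("fieldWidthMm", "FieldBorders", function(x) x@fieldWidthMm)
#' @rdname FieldBorders-class
#' @export
setMethod("fallbackUsed", "FieldBorders", function(x) x@fallbackUsed)

#' @rdname CwpMeasurement-class
#' @export
setMethod("perRow", "CwpMeasurement", function(x) x@perRow)
#' @rdname CwpMeasurement-class
#' @export
setMethod("medianMm", "CwpMeasurement", function(x) x@medianMm)
#' @rdname CwpMeasurement-class
#' @export
setMethod("sdMm", "CwpMeasurement", function(x) x@sdMm)
#' @rdname CwpMeasurement-class
#' @export
setMethod("referenceEdge", "CwpMeasurement", function(x) x@referenceEdge)
#' @rdname CwpMeasurement-class
#' @export
setMethod("nValidRows", "CwpMeasurement", function(x) x@nValidRows)
#' @rdname CwpMeasurement-class
#' @export
setMethod("measurementFlags", "CwpMeasurement", function(x) x@flags)

#' @rdname MotionResult-class
#' @export
setMethod("perFrameShiftMm", "MotionResult", function(x) x@perFrameShiftMm)
#' @rdname MotionResult-class
#' @export
setMethod("maxShiftMm", "MotionResult", function(x) x@maxShiftMm)
#' @rdname MotionResult-class
#' @export
setMethod("withinTolerance", "MotionResult", function(x) x@withinTolerance)
#' @rdname MotionResult-class
#' @export
setMethod("beamId", "MotionResult", function(x) x@beamId)

#' @rdname SetupResult-class
#' @export
setMethod("setupErrorMm", "SetupResult", function(x) x@setupErrorMm)
#' @rdname SetupResult-class
#' @export
setMethod("withinTolerance", "SetupResult", function(x) x@withinTolerance)

#' @rdname CtPhantom-class
#' @export
setMethod("groundTruth", "CtPhantom", function(x) x@truth)

setMethod("show", "EpidFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "EpidFrame [%s] %d x %d px, %.3f x %.3f mm/px, beam '%s' (%s field), frame %d%s\n",
    object@source, d[1], d[2], object@rowSpacingMm, object@colSpacingMm,
    object@beamId, object@fieldLabel, object@frameIndex,
    if (object@planeVerified) "" else " [plane unverified]"))
})

setMethod("show", "BeamSeries", function(object) {
  cat(sprintf("BeamSeries: %d frame(s) of beam '%s' (%s field), reference %s\n",
              length(object@frames), object@frames[[1]]@beamId,
              object@frames[[1]]@fieldLabel,
              if (is.null(object@referenceFrame)) "absent" else "present"))
})

setMethod("show", "CwpMeasurement", function(object) {
  cat(sprintf(
    "CwpMeasurement [%s, %s edge]: median %.2f mm, sd %.2f mm over %d row(s)%s\n",
    object@algorithm, object@referenceEdge, object@medianMm, object@sdMm,
    object@nValidRows,
    if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ", "), "]")
    else ""))
})

setMethod("show", "MotionResult", function(object) {
  if (!length(object@perFrameShiftMm)) {
    cat(sprintf("MotionResult beam '%s': not evaluated (<2 analyzable frames)\n",
                object@beamId))
  } else {
    cat(sprintf(
      "MotionResult beam '%s': max shift %+0.2f mm over %d frame(s), %s %.1f mm tolerance\n",
      object@beamId, object@maxShiftMm, length(object@perFrameShiftMm),
      if (isTRUE(object@withinTolerance)) "within" else "OUTSIDE",
      object@toleranceMm))
  }
})

setMethod("show", "SetupResult", function(object) {
  cat(sprintf("SetupResult fraction '%s': %+0.2f mm, %s %.1f mm tolerance\n",
              object@fractionId, object@setupErrorMm,
              if (isTRUE(object@withinTolerance)) "within" else "OUTSIDE",
              object@toleranceMm))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d x %d px @ %.3g/%.3g mm, field [%.1f, %.1f] mm, exposed lung %.2f mm, rib %.1f mm%s\n",
    object@nRows, object@nCols, object@rowSpacingMm, object@colSpacingMm,
    object@medialEdgeMm, object@lateralEdgeMm, object@exposedLungMm,
    object@ribThicknessMm, if (object@mlcCorner) " [MLC corner]" else ""))
})

setMethod("show", "CtPhantom", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CtPhantom: %d x %d x %d voxels @ %s mm, aperture [%s, %s] mm\n",
              d[1], d[2], d[3],
              paste(signif(object@voxelSizeMm, 3), collapse = " x "),
              format(object@medialEdgeMm), format(object@lateralEdgeMm)))
})
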