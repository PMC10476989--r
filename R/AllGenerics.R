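# Accessor generics. Slot access from user code should go through these.

#' @rdname EpidFrame-class
#' @param object,x an object of the documented class
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname EpidFrame-class
#' @export
setGeneric("rowSpacingMm", function(x) standardGeneric("rowSpacingMm"))
#' @rdname EpidFrame-class
#' @export
setGeneric("colSpacingMm", function(x) standardGeneric("colSpacingMm"))
#' @rdname EpidFrame-class
#' @export
setGeneric("frameIndex", function(x) standardGeneric("frameIndex"))
#' @rdname EpidFrame-class
#' @export
setGeneric("beamId", function(x) standardGeneric("beamId"))
#' @rdname EpidFrame-class
#' @export
setGeneric("fieldLabel", function(x) standardGeneric("fieldLabel"))
#' @rdname EpidFrame-class
#' @export
setGeneric("imageSource", function(x) standardGeneric("imageSource"))
#' @rdname EpidFrame-class
#' @export
setGeneric("planeVerified", function(x) standardGeneric("planeVerified"))

#' @rdname BeamSeries-class
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname BeamSeries-class
#' @export
setGeneric("referenceFrame", function(x) standardGeneric("referenceFrame"))

#' @rdname RoiSpec-class
#' @export
setGeneric("roiRows", function(x) standardGeneric("roiRows"))
#' @rdname RoiSpec-class
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname FieldBorders-class
#' @export
setGeneric("medialCol", function(x) standardGeneric("medialCol"))
#' @rdname FieldBorders-class
#' @export
setGeneric("lateralCol", function(x) standardGeneric("lateralCol"))
#' @rdname FieldBorders-class
#' @export
setGeneric("fieldWidthMm", function(x) standardGeneric("fieldWidthMm"))
#' @rdname FieldBorders-class
#' @export
setGeneric("fallbackUsed", function(x) standardGeneric("fallbackUsed"))

#' @rdname CwpMeasurement-class
#' @export
setGeneric("perRow", function(x) standardGeneric("perRow"))
#' @rdname CwpMeasurement-class
#' @export
setGeneric("medianMm", function(x) standardGeneric("medianMm"))
#' @rdname CwpMeasurement-class
#' @export
setGeneric("sdMm", function(x) standardGeneric("sdMm"))
#' @rdname CwpMeasurement-class
#' @export
setGeneric("referenceEdge", function(x) standardGeneric("referenceEdge"))
#' @rdname CwpMeasurement-class
#' @export
setGeneric("nValidRows", function(x) standardGeneric("nValidRows"))
#' @rdname CwpMeasurement-class
#' @export
setGeneric("measurementFlags", function(x) standardGeneric("measurementFlags"))

#' @rdname MotionResult-class
#' @export
setGeneric("perFrameShiftMm", function(x) standardGeneric("perFrameShiftMm"))
#' @rdname MotionResult-class
#' @export
setGeneric("maxShiftMm", function(x) standardGeneric("maxShiftMm"))
#' @rdname MotionResult-class
#' @export
setGeneric("withinTolerance", function(x) standardGeneric("withinTolerance"))

#' @rdname SetupResult-class
#' @export
setGeneric("setupErrorMm", function(x) standardGeneric("setupErrorMm"))

#' @rdname CtPhantom-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
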