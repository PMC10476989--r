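#' @import methods
NULL

setClassUnion("EpidFrameOrNULL", "NULL")

#' Calibrated portal image frame
#'
#' An \code{EpidFrame} holds one EPID cine frame or one (MV-windowed) DRR as a
#' numeric pixel matrix together with the geometry needed to express
#' measurements in millimetres. Rows run superior to inferior and columns run
#' medial to lateral; the canonical intensity convention is
#' \code{"attenuation_up"}, i.e. denser anatomy (rib, blocked field) is
#' brighter than lung or the skin-air flash.
#'
#' @slot pixels numeric matrix of intensities (rows x columns), at least
#'   64 x 64, finite.
#' @slot rowSpacingMm,colSpacingMm physical pixel size in mm at the reporting
#'   plane (isocenter when SAD/SID metadata permitted rescaling).
#' @slot frameIndex integer ordinal of the frame within its cine acquisition.
#' @slot beamId,fractionId character identifiers of beam and fraction.
#' @slot fieldLabel \code{"medial"} or \code{"lateral"} tangential field.
#' @slot source \code{"EPID"} or \code{"MV_DRR"}.
#' @slot intensityConvention always \code{"attenuation_up"} after
#'   construction; transmission-style input is inverted on read.
#' @slot planeVerified logical; \code{FALSE} when pixel spacing could not be
#'   rescaled to the isocenter plane (missing SAD/SID metadata).
#' @slot acquisitionTime character DICOM TM string, possibly empty.
#'
#' @seealso [epidFrame()], [readRTImage()], [renderPhantom()]
#' @export
setClass("EpidFrame",
  representation(
    pixels = "matrix",
    rowSpacingMm = "numeric",
    colSpacingMm = "numeric",
    frameIndex = "integer",
    beamId = "character",
    fractionId = "character",
    fieldLabel = "character",
    source = "character",
    intensityConvention = "character",
    planeVerified = "logical",
    acquisitionTime = "character"
  )
)

setValidity("EpidFrame", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 64L || ncol(p) < 64L)
    return("pixels must be at least 64 x 64")
  if (!all(is.finite(p))) return("pixels must be finite")
  if (length(object@rowSpacingMm) != 1L || object@rowSpacingMm <= 0)
    return("rowSpacingMm must be a single positive number")
  if (length(object@colSpacingMm) != 1L || object@colSpacingMm <= 0)
    return("colSpacingMm must be a single positive number")
  if (!object@fieldLabel %in% c("medial", "lateral"))
    return("fieldLabel must be 'medial' or 'lateral'")
  if (!object@source %in% c("EPID", "MV_DRR"))
    return("source must be 'EPID' or 'MV_DRR'")
  if (!identical(object@intensityConvention, "attenuation_up"))
    return("frames must be normalized to the attenuation_up convention")
  TRUE
})

#' Ordered cine series of one beam
#'
#' @slot frames list of [EpidFrame-class] objects with strictly increasing
#'   \code{frameIndex}, all sharing beam id, field label, shape and spacing.
#' @slot referenceFrame optional [EpidFrame-class] (the MV DRR used for setup
#'   error) or \code{NULL}.
#'
#' @seealso [beamSeries()], [readCineSeries()], [intrafractionMotion()]
#' @export
setClass("BeamSeries",
  representation(frames = "list", referenceFrame = "ANY")
)

setValidity("BeamSeries", function(object) {
  fr <- object@frames
  if (length(fr) < 1L) return("a BeamSeries needs at least one frame")
  if (!all(vapply(fr, is, logical(1), "EpidFrame")))
    return("all frames must be EpidFrame objects")
  ids <- vapply(fr, function(f) f@beamId, character(1))
  if (length(unique(ids)) != 1L) return("frames mix beam identifiers")
  lab <- vapply(fr, function(f) f@fieldLabel, character(1))
  if (length(unique(lab)) != 1L) return("frames mix field labels")
  dims <- vapply(fr, function(f) dim(f@pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("frames mix image shapes")
  idx <- vapply(fr, function(f) f@frameIndex, integer(1))
  if (any(diff(idx) <= 0L)) return("frameIndex must be strictly increasing")
  rf <- object@referenceFrame
  if (!is.null(rf) && !is(rf, "EpidFrame"))
    return("referenceFrame must be an EpidFrame or NULL")
  TRUE
})

#' Region-of-interest specification
#'
#' A fixed-height band of image rows centered on the image midline. The row
#' count is derived from the physical half-span and the row spacing:
#' \code{nRows = 2 * round(halfSpanMm / rowSpacingMm) + 1}, which yields the
#' conventional 61 rows at ~0.5 mm EPID pixels and 31 rows at ~1 mm DRR
#' pixels for a 15 mm half-span.
#'
#' @slot centerRow integer center row index.
#' @slot nRows odd integer number of rows.
#' @slot halfSpanMm numeric physical half-height in mm.
#'
#' @seealso [makeRoi()]
#' @export
setClass("RoiSpec",
  representation(centerRow = "integer", nRows = "integer",
                 halfSpanMm = "numeric")
)

setValidity("RoiSpec", function(object) {
  if (object@nRows < 1L || object@nRows %% 2L == 0L)
    return("nRows must be odd and >= 1")
  if (object@halfSpanMm < 0) return("halfSpanMm must be >= 0")
  TRUE
})

#' One image row's intensity trace
#'
#' @slot intensities numeric vector along columns (medial to lateral).
#' @slot rowIndex integer source row.
#' @slot colSpacingMm numeric column spacing in mm.
#'
#' @seealso [rowProfile()], [detectBorders()]
#' @export
setClass("RowProfile",
  representation(intensities = "numeric", rowIndex = "integer",
                 colSpacingMm = "numeric")
)

setValidity("RowProfile", function(object) {
  if (!all(is.finite(object@intensities))) return("intensities must be finite")
  if (length(object@intensities) < 8L) return("profile too short")
  if (object@colSpacingMm <= 0) return("colSpacingMm must be positive")
  TRUE
})

#' Detected radiation-field borders of one profile
#'
#' @slot medialCol,lateralCol integer column indices of the medial (steepest
#'   intensity decline) and lateral (steepest incline) field borders.
#' @slot fieldWidthMm numeric \code{(lateralCol - medialCol) * colSpacingMm}.
#' @slot fallbackUsed logical; \code{TRUE} when the narrow-field fallback
#'   re-assigned the medial border to the second-steepest decline.
#'
#' @seealso [detectBorders()]
#' @export
setClass("FieldBorders",
  representation(medialCol = "integer", lateralCol = "integer",
                 fieldWidthMm = "numeric", fallbackUsed = "logical")
)

setValidity("FieldBorders", function(object) {
  if (object@medialCol >= object@lateralCol)
    return("medialCol must be left of lateralCol")
  if (object@fieldWidthMm <= 0) return("fieldWidthMm must be positive")
  TRUE
})

#' Canny filter parameters
#'
#' Hysteresis thresholds apply to the gradient magnitude normalized to its
#' image maximum. Defaults are the phantom calibration (sigma 2, thresholds
#' 0.01/0.02); the patient-optimized setting is sigma 4 with a single
#' threshold parameter of 0.006 (interpreted as the high threshold with
#' low = high / 2, mirroring the phantom pair's ratio).
#'
#' @slot sigma Gaussian smoothing scale in pixels.
#' @slot lowThreshold,highThreshold hysteresis thresholds in (0, 1].
#'
#' @seealso [cannyParams()], [cannyCwp()]
#' @export
setClass("CannyParams",
  representation(sigma = "numeric", lowThreshold = "numeric",
                 highThreshold = "numeric")
)

setValidity("CannyParams", function(object) {
  if (object@sigma <= 0) return("sigma must be positive")
  lo <- object@lowThreshold; hi <- object@highThreshold
  if (!(lo > 0 && lo < hi && hi <= 1))
    return("thresholds must satisfy 0 < low < high <= 1")
  TRUE
})

#' Per-frame chest wall position measurement
#'
#' @slot perRow data.frame with one row per analyzable ROI row: \code{row},
#'   \code{medialCol}, \code{lateralCol}, \code{featureCol} (detected chest
#'   wall column), \code{peakCol} (in-breast peak; NA for Canny),
#'   \code{distanceMm}, \code{fallback}, \code{broadPeak}.
#' @slot medianMm,sdMm median and sample standard deviation (n-1; 0 when a
#'   single row survives) of the per-row distances.
#' @slot referenceEdge \code{"medial"} or \code{"lateral"}.
#' @slot algorithm \code{"canny"}, \code{"peak"} or \code{"inflection"}.
#' @slot nValidRows integer number of rows that produced a distance.
#' @slot flags character vector of quality flags (e.g. \code{"broad peak"}).
#'
#' @seealso [peakCwp()], [inflectionCwp()], [cannyCwp()], [drrCwp()]
#' @export
setClass("CwpMeasurement",
  representation(
    perRow = "data.frame",
    medianMm = "numeric",
    sdMm = "numeric",
    referenceEdge = "character",
    algorithm = "character",
    nValidRows = "integer",
    flags = "character"
  )
)

setValidity("CwpMeasurement", function(object) {
  if (!object@referenceEdge %in% c("medial", "lateral"))
    return("referenceEdge must be 'medial' or 'lateral'")
  if (!object@algorithm %in% c("canny", "peak", "inflection"))
    return("algorithm must be 'canny', 'peak' or 'inflection'")
  if (object@nValidRows >= 1L &&
      !(is.finite(object@medianMm) && is.finite(object@sdMm)))
    return("median/sd must be finite when any row is valid")
  TRUE
})

#' Intrafraction motion result for one beam
#'
#' Shifts are signed with the convention that positive means a deeper breath
#' hold (chest wall displaced posteriorly, more lung exposed) than in the
#' first cine frame, regardless of the reference edge used.
#'
#' @slot beamId character.
#' @slot frameIndices integer indices of the analyzable frames.
#' @slot perFrameShiftMm numeric shifts versus the first analyzable frame
#'   (first element 0 by construction); length 0 when fewer than two frames
#'   could be analyzed.
#' @slot maxShiftMm signed shift of greatest magnitude (ties broken toward
#'   the earlier frame); NA when no motion could be evaluated.
#' @slot withinTolerance logical; NA when not evaluated.
#' @slot toleranceMm numeric tolerance (default 3 mm).
#'
#' @seealso [intrafractionMotion()]
#' @export
setClass("MotionResult",
  representation(beamId = "character", frameIndices = "integer",
                 perFrameShiftMm = "numeric", maxShiftMm = "numeric",
                 withinTolerance = "logical", toleranceMm = "numeric")
)

setValidity("MotionResult", function(object) {
  if (object@toleranceMm <= 0) return("toleranceMm must be positive")
  s <- object@perFrameShiftMm
  if (length(s) && abs(s[1]) > 1e-12)
    return("first per-frame shift must be 0 by construction")
  if (length(s) && is.finite(object@maxShiftMm) &&
      abs(abs(object@maxShiftMm) - max(abs(s))) > 1e-9)
    return("|maxShiftMm| must equal max(|perFrameShiftMm|)")
  TRUE
})

#' Setup error result for one fraction
#'
#' Positive values mean a deeper breath hold at treatment than at simulation
#' (more lung exposed in the first EPID frame than in the planning DRR).
#'
#' @slot fractionId character.
#' @slot setupErrorMm signed setup error in mm.
#' @slot withinTolerance logical.
#' @slot toleranceMm numeric tolerance (default 5 mm).
#'
#' @seealso [setupError()]
#' @export
setClass("SetupResult",
  representation(fractionId = "character", setupErrorMm = "numeric",
                 withinTolerance = "logical", toleranceMm = "numeric")
)

setValidity("SetupResult", function(object) {
  if (object@toleranceMm <= 0) return("toleranceMm must be positive")
  if (!is.finite(object@setupErrorMm)) return("setupErrorMm must be finite")
  TRUE
})

#' Synthetic thorax phantom specification
#'
#' Parameterizes a 2-D tangential-field phantom frame: a bright blocked
#' region outside the jaws, exposed lung from the medial border to the
#' lung-rib junction, a rib strip, breast/mediastinal tissue, and the
#' skin-air flash before the lateral border. Region boundaries are continuous
#' (sub-pixel) mm positions rendered through Gaussian-CDF edge transitions of
#' scale \code{edgeSoftnessMm}, so the exported ground truth is exact.
#'
#' @slot nRows,nCols image size in pixels.
#' @slot rowSpacingMm,colSpacingMm pixel size in mm.
#' @slot medialEdgeMm,lateralEdgeMm jaw positions in mm from the medial image
#'   edge (pixel k spans \code{[(k-1), k] * colSpacingMm}).
#' @slot exposedLungMm distance from the medial border to the lung-rib
#'   junction at the ROI center row.
#' @slot ribThicknessMm rib strip width (default 5 mm; the ground-truth rib
#'   peak sits at junction + ribThickness/2).
#' @slot flashWidthMm width of the skin-air flash before the lateral border.
#' @slot intensities named numeric vector (blocked, rib, breast, lung, flash)
#'   on a 0-1 attenuation scale.
#' @slot mlcCorner logical; emulate MLC corner shielding that weakens the
#'   medial gradient (the narrow-field failure scenario).
#' @slot mlcIntensity blocked-region intensity on the medial side when
#'   \code{mlcCorner} is \code{TRUE}.
#' @slot curvatureAmplitudeMm quadratic chest wall bow across rows in mm.
#' @slot noiseSigma Gaussian noise standard deviation as a fraction of the
#'   intensity range (applied after blurring).
#' @slot noiseModel \code{"gaussian"} (default) or \code{"poisson"}.
#' @slot edgeSoftnessMm Gaussian penumbra scale of all edges in mm.
#'
#' @seealso [phantomSpec()], [renderPhantom()], [renderCine()]
#' @export
setClass("PhantomSpec",
  representation(
    nRows = "integer", nCols = "integer",
    rowSpacingMm = "numeric", colSpacingMm = "numeric",
    medialEdgeMm = "numeric", lateralEdgeMm = "numeric",
    exposedLungMm = "numeric", ribThicknessMm = "numeric",
    flashWidthMm = "numeric", intensities = "numeric",
    mlcCorner = "logical", mlcIntensity = "numeric",
    curvatureAmplitudeMm = "numeric", noiseSigma = "numeric",
    noiseModel = "character", edgeSoftnessMm = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  need <- c("blocked", "rib", "breast", "lung", "flash")
  if (!all(need %in% names(object@intensities)))
    return(paste("intensities must name", paste(need, collapse = ", ")))
  if (object@exposedLungMm < 0) return("exposedLungMm must be >= 0")
  if (object@ribThicknessMm <= 0) return("ribThicknessMm must be positive")
  if (object@medialEdgeMm >= object@lateralEdgeMm)
    return("medialEdgeMm must be left of lateralEdgeMm")
  if (object@lateralEdgeMm >= object@nCols * object@colSpacingMm)
    return("lateral jaw falls outside the image")
  if (object@edgeSoftnessMm <= 0) return("edgeSoftnessMm must be positive")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (!object@noiseModel %in% c("gaussian", "poisson"))
    return("noiseModel must be 'gaussian' or 'poisson'")
  skin <- object@lateralEdgeMm - object@flashWidthMm
  body <- object@medialEdgeMm + object@exposedLungMm + object@ribThicknessMm
  if (skin <= body)
    return("regions overlap: skin must lie lateral of the rib strip")
  TRUE
})

#' Programmed cine trajectory
#'
#' Per-frame rigid chest wall displacement in mm, applied to the lung-rib
#' junction and all anatomy lateral of it while the field stays fixed.
#' Positive displacements move the chest wall laterally (deeper breath, more
#' lung exposed).
#'
#' @slot nFrames integer number of cine frames.
#' @slot displacementsMm numeric per-frame displacement; first element 0.
#'
#' @seealso [trajectorySpec()], [renderCine()]
#' @export
setClass("TrajectorySpec",
  representation(nFrames = "integer", displacementsMm = "numeric")
)

setValidity("TrajectorySpec", function(object) {
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (length(object@displacementsMm) != object@nFrames)
    return("displacementsMm must have one value per frame")
  if (abs(object@displacementsMm[1]) > 1e-12)
    return("first-frame displacement must be 0")
  TRUE
})

#' Voxel CT phantom for DRR projection
#'
#' @slot voxels 3-D numeric array of CT numbers in [-1000, 1000], dimensions
#'   (image rows, image columns, depth along the ray).
#' @slot voxelSizeMm numeric length-3 voxel size (row, column, depth) in mm.
#' @slot projectionAxis character; only \code{"depth"} (parallel rays along
#'   the third array dimension) is supported.
#' @slot medialEdgeMm,lateralEdgeMm field aperture in mm (NA for an open,
#'   aperture-free projection).
#' @slot truth data.frame of per-image-row ground truth (see
#'   [renderPhantom()] for columns) or an empty data.frame.
#'
#' @seealso [ctPhantom()], [projectDrr()]
#' @export
setClass("CtPhantom",
  representation(voxels = "array", voxelSizeMm = "numeric",
                 projectionAxis = "character", medialEdgeMm = "numeric",
                 lateralEdgeMm = "numeric", truth = "data.frame")
)

setValidity("CtPhantom", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3-D array")
  if (length(object@voxels) &&
      (min(object@voxels) < -1000 || max(object@voxels) > 1000))
    return("CT numbers must lie in [-1000, 1000]")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    return("voxelSizeMm must be 3 positive numbers")
  if (!identical(object@projectionAxis, "depth"))
    return("projectionAxis must be 'depth'")
  TRUE
})
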