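# Per-row chest wall detectors and ROI aggregation.
#
# All three detectors share the same scaffolding: per ROI row the field
# borders are found on the row profile, a per-row chest wall column is
# detected, and its distance from the reference edge is recorded; the frame
# measurement is the median of the per-row distances with the sample
# standard deviation as uncertainty. Rows are processed independently (no
# cross-row smoothing) so the SD is an honest per-row spread statistic.

#' Aggregate per-row distances into a frame measurement
#'
#' @param distances numeric vector of per-row distances (>= 1 value).
#' @return list with elements \code{median} (sample median) and \code{sd}
#'   (sample standard deviation, n-1 denominator; 0 for a single value).
#' @examples
#' aggregateRows(c(2, 2, 2))       # median 2, sd 0
#' aggregateRows(c(1, 2, 100))     # median 2: robust to an outlier row
#' @export
aggregateRows <- function(distances) {
  if (!length(distances)) stop("no distances to aggregate")
  if (!all(is.finite(distances))) stop("distances must be finite")
  list(median = stats::median(distances),
       sd = if (length(distances) > 1L) stats::sd(distances) else 0)
}

# Parabolic vertex offset from three samples around a discrete extremum;
# clamped to half a pixel, 0 when the parabola degenerates.
.parabolic_offset <- function(y_m1, y_0, y_p1) {
  den <- y_m1 - 2 * y_0 + y_p1
  if (!is.finite(den) || abs(den) < 1e-12) return(0)
  max(-0.5, min(0.5, 0.5 * (y_m1 - y_p1) / den))
}

# Leftmost argmax plus plateau width (columns tied with the maximum).
.argmax_plateau <- function(y) {
  pk <- which.max(y)
  run <- 0L
  while (pk + run + 1L <= length(y) &&
         abs(y[pk + run + 1L] - y[pk]) <= 1e-12) run <- run + 1L
  list(peak = pk, plateau = run + 1L)
}

# Shared per-row driver. feature_fun(y_smooth, borders, seg_cols, row)
# returns list(featureCol, peakCol, broadPeak) or NULL to drop the row.
.cwp_frame <- function(frame, roi, referenceEdge, algorithm, feature_fun,
                       minFieldWidthMm = 55, marginMm = 2, smoothWindow = 3L,
                       fallback = TRUE) {
  stopifnot(is(frame, "EpidFrame"), is(roi, "RoiSpec"))
  referenceEdge <- match.arg(referenceEdge, c("medial", "lateral"))
  sp <- frame@colSpacingMm
  rows <- roiRows(roi)
  rec <- vector("list", length(rows))
  n_border_fail <- 0L

  for (k in seq_along(rows)) {
    r <- rows[k]
    prof <- rowProfile(frame, r)
    borders <- tryCatch(
      detectBorders(prof, minFieldWidthMm = minFieldWidthMm,
                    smoothWindow = smoothWindow, fallback = fallback),
      error = function(e) NULL)
    if (is.null(borders)) { n_border_fail <- n_border_fail + 1L; next }
    seg <- tryCatch(cropInfield(prof, borders, marginMm = marginMm),
                    error = function(e) NULL)
    if (is.null(seg)) { n_border_fail <- n_border_fail + 1L; next }
    y <- .smooth_ma(prof@intensities, smoothWindow)
    feat <- feature_fun(y, borders, seg, r)
    if (is.null(feat)) next
    fcol <- if (is.null(feat$featureSub)) feat$featureCol else feat$featureSub
    dist_mm <- if (referenceEdge == "medial")
      (fcol - borders@medialCol) * sp
    else (borders@lateralCol - fcol) * sp
    if (!is.finite(dist_mm) || dist_mm <= 0) next
    rec[[k]] <- data.frame(
      row = r, medialCol = borders@medialCol, lateralCol = borders@lateralCol,
      featureCol = feat$featureCol,
      peakCol = if (is.null(feat$peakCol)) NA_integer_ else feat$peakCol,
      distanceMm = dist_mm, fallback = borders@fallbackUsed,
      broadPeak = isTRUE(feat$broadPeak))
  }

  if (n_border_fail > length(rows) / 2)
    stop("frame rejected: border detection failed on ", n_border_fail,
         " of ", length(rows), " ROI rows")
  per_row <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  if (is.null(per_row) || nrow(per_row) == 0L)
    stop("frame rejected: no ROI row produced a chest wall position")

  agg <- aggregateRows(per_row$distanceMm)
  flags <- character(0)
  if (any(per_row$broadPeak)) flags <- c(flags, "broad peak")
  if (any(per_row$fallback)) flags <- c(flags, "narrow-field fallback")
  new("CwpMeasurement", perRow = per_row, medianMm = agg$median,
      sdMm = agg$sd, referenceEdge = referenceEdge, algorithm = algorithm,
      nValidRows = nrow(per_row), flags = flags)
}

#' Peak-intensity chest wall position
#'
#' Per ROI row, the chest wall is the column of peak intensity within the
#' open field (the in-breast/rib maximum), excluding a penumbra margin next
#' to both field borders. Plateau ties resolve to the leftmost column; a
#' plateau wider than 2 mm flags the row as "broad peak".
#'
#' @param frame an [EpidFrame-class].
#' @param roi a [RoiSpec-class] (see [makeRoi()]).
#' @param referenceEdge \code{"medial"} or \code{"lateral"}: edge from which
#'   the distance is reported.
#' @param minFieldWidthMm,marginMm,smoothWindow,fallback border-detection
#'   settings, see [detectBorders()] and [cropInfield()].
#' @param subpixel refine the detected column by a parabolic fit through its
#'   two neighbours (off by default: locations are reported at pixel
#'   resolution).
#' @return a [CwpMeasurement-class].
#' @examples
#' ph <- renderPhantom(phantomSpec(exposedLungMm = 5), seed = 1)
#' peakCwp(ph$frame, makeRoi(ph$frame))
#' @export
peakCwp <- function(frame, roi, referenceEdge = c("medial", "lateral"),
                    minFieldWidthMm = 55, marginMm = 2, smoothWindow = 3L,
                    fallback = TRUE, subpixel = FALSE) {
  referenceEdge <- match.arg(referenceEdge)
  sp <- frame@colSpacingMm
  fun <- function(y, borders, seg, row) {
    ap <- .argmax_plateau(y[seg])
    pk <- seg[ap$peak]
    sub <- if (subpixel && pk > 1L && pk < length(y))
      pk + .parabolic_offset(y[pk - 1L], y[pk], y[pk + 1L]) else NULL
    list(featureCol = pk, featureSub = sub, peakCol = pk,
         broadPeak = ap$plateau * sp > 2)
  }
  .cwp_frame(frame, roi, referenceEdge, "peak", fun,
             minFieldWidthMm = minFieldWidthMm, marginMm = marginMm,
             smoothWindow = smoothWindow, fallback = fallback)
}

#' Inflection-point chest wall position
#'
#' Per ROI row, the in-field peak is located as in [peakCwp()]; the profile
#' is then cropped to the \code{cropMm} window leading up to the peak (sized
#' to the rib thickness, observed up to 5 mm) and the chest wall is the
#' maximum of the first derivative of that window: the upward inflection at
#' the lung-rib junction, an anatomical landmark that precedes the rib peak.
#'
#' @inheritParams peakCwp
#' @param cropMm window length in mm ending at the peak (default 5).
#' @return a [CwpMeasurement-class]; per-row inflection columns are strictly
#'   left of (or at most equal to) the per-row peak columns.
#' @examples
#' ph <- renderPhantom(phantomSpec(exposedLungMm = 5), seed = 1)
#' m <- inflectionCwp(ph$frame, makeRoi(ph$frame))
#' medianMm(m)   # ~5 mm from the medial border
#' @export
inflectionCwp <- function(frame, roi, referenceEdge = c("medial", "lateral"),
                          cropMm = 5, minFieldWidthMm = 55, marginMm = 2,
                          smoothWindow = 3L, fallback = TRUE,
                          subpixel = FALSE) {
  referenceEdge <- match.arg(referenceEdge)
  sp <- frame@colSpacingMm
  crop_cols <- as.integer(round(cropMm / sp))
  fun <- function(y, borders, seg, row) {
    ap <- .argmax_plateau(y[seg])
    pk <- seg[ap$peak]
    w0 <- max(2L, pk - crop_cols)
    if (pk - w0 + 1L < 3L) return(NULL)          # window shorter than 3 samples
    g <- .cdiff(y)
    interior <- (w0 + 1L):(pk - 1L)
    infl <- interior[which.max(g[interior])]
    sub <- if (subpixel && infl > 2L && infl < length(y) - 1L)
      infl + .parabolic_offset(g[infl - 1L], g[infl], g[infl + 1L]) else NULL
    list(featureCol = infl, featureSub = sub, peakCol = pk,
         broadPeak = ap$plateau * sp > 2)
  }
  .cwp_frame(frame, roi, referenceEdge, "inflection", fun,
             minFieldWidthMm = minFieldWidthMm, marginMm = marginMm,
             smoothWindow = smoothWindow, fallback = fallback)
}

#' Canny-outline chest wall position
#'
#' The frame is reduced to a single-pixel-wide Canny edge map; per ROI row
#' the chest wall is the first edge pixel encountered moving from the medial
#' border toward the lateral border, excluding pixels within
#' \code{borderExclusionMm} of either border (those belong to the field
#' edges). Edge features are distinguished purely by relative position, so
#' noise edges inside the lung can still be misidentified as chest wall;
#' this is the algorithm's documented failure mode.
#'
#' @inheritParams peakCwp
#' @param params a [CannyParams-class]; defaults to the phantom calibration
#'   (sigma 2, thresholds 0.01/0.02). For patient-like noise use
#'   \code{cannyParams(sigma = 4, threshold = 0.006)}.
#' @param borderExclusionMm exclusion zone around the field borders (default
#'   2 mm).
#' @return a [CwpMeasurement-class].
#' @export
cannyCwp <- function(frame, roi, referenceEdge = c("medial", "lateral"),
                     params = cannyParams(), borderExclusionMm = 2,
                     minFieldWidthMm = 55, marginMm = 2, smoothWindow = 3L,
                     fallback = TRUE) {
  referenceEdge <- match.arg(referenceEdge)
  edges <- cannyEdges(frame, params)
  if (!any(edges)) stop("frame rejected: no Canny edges detected")
  sp <- frame@colSpacingMm
  excl <- as.integer(round(borderExclusionMm / sp))
  fun <- function(y, borders, seg, row) {
    lo <- borders@medialCol + excl + 1L
    hi <- borders@lateralCol - excl - 1L
    if (hi < lo) return(NULL)
    hit <- which(edges[row, lo:hi])
    if (!length(hit)) return(NULL)
    list(featureCol = lo + hit[1L] - 1L, peakCol = NULL, broadPeak = FALSE)
  }
  .cwp_frame(frame, roi, referenceEdge, "canny", fun,
             minFieldWidthMm = minFieldWidthMm, marginMm = marginMm,
             smoothWindow = smoothWindow, fallback = fallback)
}
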