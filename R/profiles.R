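# Row-profile extraction and field-border detection.

#' Build the measurement region of interest
#'
#' The ROI is a band of rows centered (by default) halfway between the
#' superior and inferior image borders, spanning \code{halfSpanMm} above and
#' below the center. The row count follows from the physical span and the
#' row spacing: 61 rows at ~0.5 mm EPID pixels, 31 at ~1 mm DRR pixels.
#'
#' @param frame an [EpidFrame-class].
#' @param halfSpanMm physical half-height in mm (default 15).
#' @param centerRow center row index; defaults to the image vertical center.
#' @return a [RoiSpec-class].
#' @examples
#' ph <- renderPhantom(phantomSpec(), seed = 1)
#' nRows(makeRoi(ph$frame))   # 61 at 0.5 mm rows
#' @export
makeRoi <- function(frame, halfSpanMm = 15, centerRow = NULL) {
  stopifnot(is(frame, "EpidFrame"), halfSpanMm >= 0)
  nr <- nrow(frame@pixels)
  if (is.null(centerRow)) centerRow <- as.integer(round((nr + 1) / 2))
  half <- as.integer(round(halfSpanMm / frame@rowSpacingMm))
  n <- 2L * half + 1L
  if (centerRow - half < 1L || centerRow + half > nr)
    stop("ROI exceeds the image: ", n, " rows around row ", centerRow,
         " do not fit in ", nr, " rows")
  new("RoiSpec", centerRow = as.integer(centerRow), nRows = n,
      halfSpanMm = as.numeric(halfSpanMm))
}

#' Extract one row's intensity profile
#'
#' @param frame an [EpidFrame-class].
#' @param row row index.
#' @return a [RowProfile-class].
#' @export
rowProfile <- function(frame, row) {
  stopifnot(is(frame, "EpidFrame"), row >= 1L, row <= nrow(frame@pixels))
  new("RowProfile", intensities = as.numeric(frame@pixels[row, ]),
      rowIndex = as.integer(row), colSpacingMm = frame@colSpacingMm)
}

# Odd-window moving average with replicated ends; window 1 = identity.
.smooth_ma <- function(y, window) {
  if (window <= 1L) return(y)
  if (window %% 2L == 0L) stop("smoothing window must be odd")
  r <- (window - 1L) %/% 2L
  ypad <- c(rep(y[1], r), y, rep(y[length(y)], r))
  as.numeric(stats::filter(ypad, rep(1 / window, window), sides = 2))[
    (r + 1L):(r + length(y))]
}

# Centered first differences; NA at both ends (never selectable).
.cdiff <- function(y) {
  n <- length(y)
  g <- rep(NA_real_, n)
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / 2
  g
}

# Local minima of g (distinct intensity declines), ranked steepest first.
.decline_candidates <- function(g) {
  n <- length(g)
  i <- 3:(n - 2)
  ok <- !is.na(g[i]) & g[i] < 0 & g[i] <= g[i - 1] & g[i] <= g[i + 1]
  cand <- i[ok]
  cand[order(g[cand], cand)]   # steepest first, leftmost on ties
}

#' Detect the medial and lateral field borders of a profile
#'
#' The medial border is the column of the steepest intensity decline (bright
#' blocked region dropping into dark lung) and the lateral border is the
#' steepest incline to its right (skin-air flash rising into the blocked
#' region), both measured on centered first differences of the (optionally
#' smoothed) profile. If the resulting field width falls below
#' \code{minFieldWidthMm}, the skin-air interface has likely out-gradiented a
#' weak medial edge (MLC corner shielding with a rib close to the leaf); the
#' medial border is then re-assigned to the second-steepest distinct decline
#' and \code{fallbackUsed} is set.
#'
#' @param profile a [RowProfile-class].
#' @param minFieldWidthMm narrow-field threshold in mm (default 55; derived
#'   clinically as the narrowest credible tangential field minus a 5 mm
#'   margin).
#' @param smoothWindow odd moving-average window in samples applied before
#'   differencing (default 3; 1 disables smoothing).
#' @param fallback set \code{FALSE} to disable the narrow-field fallback (the
#'   raw, possibly wrong, borders are then returned).
#' @return a [FieldBorders-class].
#' @examples
#' y <- c(rep(1, 40), rep(0.2, 160), rep(1, 56))
#' p <- new("RowProfile", intensities = y, rowIndex = 1L, colSpacingMm = 0.5)
#' detectBorders(p)   # medial 40, lateral 200, width 80 mm
#' @export
detectBorders <- function(profile, minFieldWidthMm = 55, smoothWindow = 3L,
                          fallback = TRUE) {
  stopifnot(is(profile, "RowProfile"))
  sp <- profile@colSpacingMm
  y <- .smooth_ma(profile@intensities, smoothWindow)
  g <- .cdiff(y)
  n <- length(g)

  pick_lateral <- function(med) {
    right <- g[(med + 1L):(n - 1L)]
    if (!length(right) || all(is.na(right)) || max(right, na.rm = TRUE) <= 0)
      return(NA_integer_)
    med + which.max(right)
  }

  if (all(is.na(g) | g >= 0)) stop("no field found: no intensity decline")
  med <- which.min(g)                     # leftmost on ties
  lat <- pick_lateral(med)
  if (is.na(lat)) stop("no field found: no incline right of the medial candidate")
  width <- (lat - med) * sp
  used_fallback <- FALSE

  if (width < minFieldWidthMm && fallback) {
    cand <- .decline_candidates(g)
    cand <- cand[cand != med]
    if (!length(cand)) stop("field too narrow: no alternative medial border")
    med2 <- cand[1L]
    lat2 <- pick_lateral(med2)
    if (is.na(lat2) || (lat2 - med2) * sp < minFieldWidthMm)
      stop("field too narrow: width below ", minFieldWidthMm,
           " mm even after fallback")
    med <- med2; lat <- lat2
    width <- (lat - med) * sp
    used_fallback <- TRUE
  }
  if (width <= 0) stop("no field found: non-positive width")
  new("FieldBorders", medialCol = as.integer(med), lateralCol = as.integer(lat),
      fieldWidthMm = width, fallbackUsed = used_fallback)
}

#' Crop a profile to its open-field segment
#'
#' Returns the sub-trace between the field borders with a margin excluding
#' the penumbra, as the half-open interval
#' \code{(medialCol + margin, lateralCol - margin]}; its length in columns is
#' the field width minus twice the margin.
#'
#' @param profile a [RowProfile-class].
#' @param borders a [FieldBorders-class] for this profile.
#' @param marginMm penumbra exclusion margin in mm (default 2).
#' @return integer vector of column indices of the in-field segment.
#' @export
cropInfield <- function(profile, borders, marginMm = 2) {
  stopifnot(is(profile, "RowProfile"), is(borders, "FieldBorders"),
            marginMm >= 0)
  m <- as.integer(round(marginMm / profile@colSpacingMm))
  lo <- borders@medialCol + m
  hi <- borders@lateralCol - m
  if (hi <= lo) stop("empty in-field segment: margin too large for the field")
  seq.int(lo + 1L, hi)
}
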