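# Canny edge detection: Gaussian smoothing, Sobel gradients, non-maximum
# suppression and hysteresis thresholding on the gradient magnitude
# normalized to its image maximum. Pure matrix code; frames are small
# (~128 x 224) so no compiled code is warranted.

.gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Shift a matrix by (dr, dc) with replicated borders.
.mshift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Separable convolution with replicate padding; kernels may differ per axis.
.conv_sep <- function(m, kcol, krow = kcol) {
  r <- (length(kcol) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(kcol)) out <- out + kcol[j] * .mshift(m, 0L, j - r - 1L)
  r <- (length(krow) - 1L) %/% 2L
  res <- matrix(0, nrow(m), ncol(m))
  for (j in seq_along(krow)) res <- res + krow[j] * .mshift(out, j - r - 1L, 0L)
  res
}

#' Canny edge map of a frame
#'
#' @param frame an [EpidFrame-class] or a numeric matrix.
#' @param params a [CannyParams-class] (see [cannyParams()]).
#' @return logical matrix of single-pixel-wide edges.
#' @seealso [cannyCwp()]
#' @export
cannyEdges <- function(frame, params = cannyParams()) {
  stopifnot(is(params, "CannyParams"))
  m <- if (is(frame, "EpidFrame")) frame@pixels else frame
  s <- .conv_sep(m, .gauss_kernel(params@sigma))

  gx <- .mshift(s, 0L, -1L) - .mshift(s, 0L, 1L) +
    0.5 * (.mshift(s, -1L, -1L) - .mshift(s, -1L, 1L) +
           .mshift(s, 1L, -1L) - .mshift(s, 1L, 1L))
  gy <- .mshift(s, -1L, 0L) - .mshift(s, 1L, 0L) +
    0.5 * (.mshift(s, -1L, -1L) - .mshift(s, 1L, -1L) +
           .mshift(s, -1L, 1L) - .mshift(s, 1L, 1L))
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx <= 0) return(matrix(FALSE, nrow(m), ncol(m)))
  mag <- mag / mx

  # Non-maximum suppression along the quantized gradient direction.
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- matrix(0L, nrow(m), ncol(m))
  sector[(ang >= 22.5 & ang < 67.5)] <- 1L
  sector[(ang >= 67.5 & ang < 112.5)] <- 2L
  sector[(ang >= 112.5 & ang < 157.5)] <- 3L
  offs <- list(`0` = c(0L, 1L), `1` = c(1L, 1L), `2` = c(1L, 0L),
               `3` = c(1L, -1L))
  keep <- matrix(FALSE, nrow(m), ncol(m))
  for (sct in 0:3) {
    o <- offs[[as.character(sct)]]
    n1 <- .mshift(mag, o[1], o[2])
    n2 <- .mshift(mag, -o[1], -o[2])
    keep <- keep | (sector == sct & mag >= n1 & mag >= n2)
  }
  thin <- mag * keep

  strong <- thin >= params@highThreshold
  weak <- thin >= params@lowThreshold
  # Hysteresis: grow strong edges through 8-connected weak pixels.
  vis <- strong
  repeat {
    nb <- .mshift(vis, 1L, 0L) | .mshift(vis, -1L, 0L) |
      .mshift(vis, 0L, 1L) | .mshift(vis, 0L, -1L) |
      .mshift(vis, 1L, 1L) | .mshift(vis, 1L, -1L) |
      .mshift(vis, -1L, 1L) | .mshift(vis, -1L, -1L)
    grown <- weak & nb & !vis
    if (!any(grown)) break
    vis <- vis | grown
  }
  vis
}

#' @rdname CannyParams-class
#' @param sigma Gaussian smoothing scale in pixels.
#' @param threshold optional single threshold parameter; interpreted as the
#'   high hysteresis threshold with low = threshold / 2 (the patient-style
#'   single-parameter setting, e.g. 0.006 with sigma 4).
#' @param low,high explicit hysteresis thresholds on the normalized gradient
#'   magnitude; defaults 0.01/0.02 with sigma 2 (the phantom calibration).
#' @return a [CannyParams-class].
#' @examples
#' cannyParams()                          # phantom calibration
#' cannyParams(sigma = 4, threshold = 0.006)  # patient-optimized setting
#' @export
cannyParams <- function(sigma = 2, low = 0.01, high = 0.02, threshold = NULL) {
  if (!is.null(threshold)) {
    high <- threshold
    low <- threshold / 2
  }
  new("CannyParams", sigma = as.numeric(sigma), lowThreshold = as.numeric(low),
      highThreshold = as.numeric(high))
}
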