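# Voxel CT phantom and parallel-ray DRR projection.

#' Build a voxel CT phantom matching a 2-D phantom specification
#'
#' Extrudes the tangential-field anatomy into depth: in the lung zone a ray
#' crosses \code{chestWallMm} of soft tissue then lung; in the rib zone it
#' additionally crosses a \code{ribDepthMm} rib slab; in the breast zone it
#' crosses \code{breastDepthMm} of soft tissue only (the tangential beam
#' skims the breast); lateral of the skin it sees air. CT numbers: air
#' -1000, lung -750, soft tissue 40, rib 700. Columns are sampled at
#' \code{colVoxelMm} (finer than the 1 mm DRR pixel) so region boundaries
#' are resolved at sub-pixel scale before projection.
#'
#' @param spec a [PhantomSpec-class]; supplies the field aperture, exposed
#'   lung, rib thickness, flash width and chest wall curvature. Its pixel
#'   grid is ignored: the CT uses its own sampling.
#' @param displacementMm rigid chest wall displacement in mm (for programmed
#'   setup offsets).
#' @param nRows number of image rows (1 mm each).
#' @param depthMm ray length in mm (1 mm voxels).
#' @param chestWallMm,ribDepthMm,breastDepthMm depth composition in mm.
#' @param rowVoxelMm,colVoxelMm voxel size in the image plane.
#' @return a [CtPhantom-class] whose \code{truth} slot carries the per-row
#'   ground truth (same columns as [renderPhantom()]).
#' @examples
#' ct <- ctPhantom(phantomSpec())
#' dim(groundTruth(ct))
#' @export
ctPhantom <- function(spec, displacementMm = 0, nRows = 64L, depthMm = 150,
                      chestWallMm = 20, ribDepthMm = 10, breastDepthMm = 60,
                      rowVoxelMm = 1, colVoxelMm = 0.5) {
  stopifnot(is(spec, "PhantomSpec"))
  width_mm <- spec@nCols * spec@colSpacingMm
  ncol_vox <- as.integer(round(width_mm / colVoxelMm))
  ndepth <- as.integer(round(depthMm))

  drr_spec <- spec
  drr_spec@nRows <- as.integer(nRows)
  drr_spec@rowSpacingMm <- rowVoxelMm
  geo <- .phantom_geometry(drr_spec, displacementMm)

  ct_air <- -1000; ct_lung <- -750; ct_tissue <- 40; ct_rib <- 700
  d <- seq_len(ndepth)
  depth_patterns <- rbind(
    lung = ifelse(d <= chestWallMm, ct_tissue, ct_lung),
    rib = ifelse(d <= chestWallMm, ct_tissue,
                 ifelse(d <= chestWallMm + ribDepthMm, ct_rib, ct_lung)),
    breast = ifelse(d <= breastDepthMm, ct_tissue, ct_air),
    air = rep(ct_air, ndepth))

  x <- (seq_len(ncol_vox) - 0.5) * colVoxelMm
  vox <- array(ct_air, dim = c(nRows, ncol_vox, ndepth))
  for (r in seq_len(nRows)) {
    zone <- ifelse(x < geo$junctionMm[r], 1L,
                   ifelse(x < geo$ribEndMm[r], 2L,
                          ifelse(x < geo$skinMm[r], 3L, 4L)))
    vox[r, , ] <- depth_patterns[zone, ]
  }
  new("CtPhantom", voxels = vox,
      voxelSizeMm = c(rowVoxelMm, colVoxelMm, 1),
      projectionAxis = "depth", medialEdgeMm = spec@medialEdgeMm,
      lateralEdgeMm = spec@lateralEdgeMm, truth = geo)
}

#' Project a CT phantom to a (MV-windowed) DRR
#'
#' Parallel-ray sum along the depth axis of \code{w(CT) * (CT + 1000)},
#' with \code{w} the MV window weight ([mvWindowWeight()]) or identity 1 for
#' a kV-style DRR. The projection is normalized to its maximum, lightly
#' blurred (detector/source blur), composited with the field aperture
#' (blocked regions bright, matching the attenuation_up convention of portal
#' images) and the columns are averaged down to approximately the row
#' spacing, giving the coarser ~1 mm DRR pixels.
#'
#' @param ct a [CtPhantom-class].
#' @param weighting \code{"mv_window"} or \code{"kv_identity"}.
#' @param blurMm Gaussian detector blur in mm (default 0.6).
#' @param infieldScale in-field intensity scale relative to the blocked
#'   level (default 0.85, keeping the medial border the steepest decline).
#' @param apertureSoftnessMm jaw penumbra scale in mm (default 0.6, the same
#'   detector blur: the computed aperture is sharp before detector blur).
#' @param beamId,fractionId frame metadata.
#' @return an [EpidFrame-class] with \code{source = "MV_DRR"}.
#' @examples
#' drr <- projectDrr(ctPhantom(phantomSpec()))
#' imageSource(drr)
#' @export
projectDrr <- function(ct, weighting = c("mv_window", "kv_identity"),
                       blurMm = 0.6, infieldScale = 0.85,
                       apertureSoftnessMm = 0.6, beamId = "drr",
                       fractionId = "fx1") {
  stopifnot(is(ct, "CtPhantom"))
  weighting <- match.arg(weighting)
  dims <- dim(ct@voxels)
  if (any(dims < 1L)) stop("degenerate projection axis: empty volume")

  w <- if (weighting == "mv_window") mvWindowWeight(ct@voxels) else 1
  contrib <- w * (ct@voxels + 1000)
  flat <- contrib
  dim(flat) <- c(dims[1] * dims[2], dims[3])
  p <- matrix(rowSums(flat) * ct@voxelSizeMm[3], dims[1], dims[2])

  mx <- max(p)
  if (mx > 0) p <- p / mx
  if (blurMm > 0)
    p <- .conv_sep(p, .gauss_kernel(blurMm / ct@voxelSizeMm[2]),
                   .gauss_kernel(blurMm / ct@voxelSizeMm[1]))

  if (is.finite(ct@medialEdgeMm) && is.finite(ct@lateralEdgeMm)) {
    x <- (seq_len(dims[2]) - 0.5) * ct@voxelSizeMm[2]
    wf <- stats::pnorm((x - ct@medialEdgeMm) / apertureSoftnessMm) *
      stats::pnorm((ct@lateralEdgeMm - x) / apertureSoftnessMm)
    p <- sweep(p, 2, wf * infieldScale, `*`) +
      matrix(rep(1 - wf, each = dims[1]), dims[1], dims[2])
  }

  f <- max(1L, as.integer(round(ct@voxelSizeMm[1] / ct@voxelSizeMm[2])))
  if (f > 1L) {
    ncol_out <- dims[2] %/% f
    p <- p[, seq_len(ncol_out * f), drop = FALSE]
    dim(p) <- c(dims[1], f, ncol_out)
    p <- apply(p, c(1, 3), mean)
  }
  p <- round(pmax(p, 0) / 1e-4) * 1e-4

  epidFrame(p, ct@voxelSizeMm[1], ct@voxelSizeMm[2] * f,
            frameIndex = 1L, beamId = beamId, fractionId = fractionId,
            fieldLabel = "lateral", source = "MV_DRR")
}
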