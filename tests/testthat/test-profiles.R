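# ROI construction, border detection (incl. narrow-field fallback) and
# in-field cropping.

test_that("ROI row count follows from physical span and row spacing", {
  ph05 <- renderPhantom(phantomSpec(), seed = 1)                 # 0.5 mm rows
  expect_identical(nRows(makeRoi(ph05$frame, 15)), 61L)
  drr <- projectDrr(ctPhantom(phantomSpec()))                    # 1 mm rows
  expect_identical(nRows(makeRoi(drr, 15)), 31L)
  expect_identical(nRows(makeRoi(ph05$frame, 0)), 1L)
  expect_error(makeRoi(ph05$frame, 100), "ROI exceeds")
  expect_identical(length(roiRows(makeRoi(ph05$frame, 15))), 61L)
})

test_that("borders of a constructed step profile sit at the known columns", {
  p <- step_profile(drop_at = 40L, rise_at = 200L, spacing = 0.5)
  b <- detectBorders(p, smoothWindow = 1L)
  expect_identical(medialCol(b), 40L)
  expect_identical(lateralCol(b), 200L)
  expect_equal(fieldWidthMm(b), 80)
  expect_false(fallbackUsed(b))
  # light smoothing must not move ideal step edges by more than a column
  b3 <- detectBorders(p, smoothWindow = 3L)
  expect_lte(abs(medialCol(b3) - 40L), 1L)
  expect_lte(abs(lateralCol(b3) - 200L), 1L)
})

test_that("border detection matches the exhaustive pair-scan oracle", {
  set.seed(42)
  for (k in 1:200) {
    y <- runif(64)
    p <- new("RowProfile", intensities = y, rowIndex = 1L, colSpacingMm = 0.5)
    for (w in c(1L, 3L)) {
      oracle <- bf_borders(y, window = w)
      got <- tryCatch(
        detectBorders(p, minFieldWidthMm = 0, smoothWindow = w),
        error = function(e) NULL)
      if (is.null(got)) {
        expect_true(is.na(oracle$medial) || is.na(oracle$lateral))
      } else {
        expect_identical(medialCol(got), oracle$medial)
        expect_identical(lateralCol(got), oracle$lateral)
      }
    }
  }
})

test_that("border detection is translation-equivariant and scale-invariant", {
  set.seed(7)
  base <- pixels(renderPhantom(phantomSpec(), seed = 3)$frame)[64, ]
  p0 <- new("RowProfile", intensities = base, rowIndex = 1L, colSpacingMm = 0.5)
  b0 <- detectBorders(p0)
  for (k in c(-12L, -3L, 5L, 20L)) {
    shifted <- if (k >= 0) c(rep(base[1], k), base[1:(length(base) - k)])
               else c(base[(1 - k):length(base)], rep(base[length(base)], -k))
    bk <- detectBorders(new("RowProfile", intensities = shifted,
                            rowIndex = 1L, colSpacingMm = 0.5))
    expect_identical(medialCol(bk), medialCol(b0) + k)
    expect_identical(lateralCol(bk), lateralCol(b0) + k)
  }
  for (s in c(0.25, 3, 1700)) {
    bs <- detectBorders(new("RowProfile", intensities = s * base,
                            rowIndex = 1L, colSpacingMm = 0.5))
    expect_identical(medialCol(bs), medialCol(b0))
    expect_identical(lateralCol(bs), lateralCol(b0))
  }
})

test_that("detected borders match the generator's jaw truth within 1 column", {
  for (spec in list(phantomSpec(), phantomSpec(exposedLungMm = 1),
                    phantomSpec(curvatureAmplitudeMm = 2),
                    phantomSpec(noiseSigma = 0))) {
    ph <- renderPhantom(spec, seed = 21)
    tr <- ph$truth
    for (r in c(34, 64, 94)) {
      b <- detectBorders(rowProfile(ph$frame, r))
      med_true <- tr$medialMm[r] / 0.5 + 0.5   # continuous mm -> column units
      lat_true <- tr$lateralMm[r] / 0.5 + 0.5
      expect_lte(abs(medialCol(b) - med_true), 1)
      expect_lte(abs(lateralCol(b) - lat_true), 1)
    }
  }
})

test_that("weak medial gradients misdetect without the fallback and recover with it", {
  ph <- renderPhantom(phantomSpec(exposedLungMm = 3, mlcCorner = TRUE), seed = 4)
  tr <- ph$truth[ph$truth$row == 64, ]
  p <- rowProfile(ph$frame, 64)

  raw <- detectBorders(p, fallback = FALSE)
  skin_col <- tr$skinMm / 0.5 + 0.5
  expect_lte(abs(medialCol(raw) - skin_col), 2)       # medial picked at skin-air
  expect_lt(fieldWidthMm(raw), 55)

  fixed <- detectBorders(p)
  expect_true(fallbackUsed(fixed))
  expect_lte(abs(medialCol(fixed) - tr$medialMm / 0.5 - 0.5), 1)
  expect_gte(fieldWidthMm(fixed), 55)
})

test_that("in-field cropping arithmetic and error paths", {
  p <- step_profile(drop_at = 40L, rise_at = 200L, spacing = 0.5)
  b <- detectBorders(p, smoothWindow = 1L)
  seg <- cropInfield(p, b, marginMm = 2)   # width 80 mm minus 2 x 2 mm
  expect_identical(length(seg), 152L)
  expect_gt(seg[1], medialCol(b))
  expect_lte(seg[length(seg)], lateralCol(b))

  open <- cropInfield(p, b, marginMm = 0)
  expect_identical(length(open), lateralCol(b) - medialCol(b))
  expect_error(cropInfield(p, b, marginMm = 41), "margin")
})
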