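# Intrafraction motion, setup error, tolerances and sign conventions.

test_that("MV window weights follow the two-level step with clamping", {
  expect_equal(mvWindowWeight(c(-1000, 100, 500)), c(0.5, 0.5, 2.0))
  expect_equal(mvWindowWeight(-1001), 0.5)       # clamped
  expect_equal(mvWindowWeight(1500), 2.0)        # clamped
  ct <- seq(-1200, 1200, by = 7)
  expect_true(all(diff(mvWindowWeight(ct)) >= 0))  # monotone non-decreasing
})

test_that("a static series yields zero shifts and a single frame no result", {
  rc <- renderCine(phantomSpec(exposedLungMm = 10),
                   trajectorySpec(rep(0, 5)), seed = 1)
  mo <- intrafractionMotion(rc$series)
  expect_equal(perFrameShiftMm(mo)[1], 0)
  expect_lte(max(abs(perFrameShiftMm(mo))), 0.5)
  expect_true(withinTolerance(mo))

  one <- beamSeries(frames(rc$series)[1])
  mo1 <- intrafractionMotion(one)
  expect_identical(length(perFrameShiftMm(mo1)), 0L)
  expect_true(is.na(maxShiftMm(mo1)))
  expect_true(is.na(withinTolerance(mo1)))
})

test_that("programmed steps and drifts are recovered with correct flagging", {
  spec <- phantomSpec(exposedLungMm = 10)
  rc <- renderCine(spec, trajectoryStep(10, 2, 5), seed = 2)
  mo <- intrafractionMotion(rc$series)
  expect_lte(abs(maxShiftMm(mo) - 2), 0.5)       # within one column
  expect_true(withinTolerance(mo))

  drift <- renderCine(spec, trajectoryDrift(10, 4), seed = 3)
  mod <- intrafractionMotion(drift$series)
  expect_lte(abs(maxShiftMm(mod) - 4), 0.5)
  expect_false(withinTolerance(mod))             # exceeds the 3 mm tolerance

  neg <- renderCine(spec, trajectoryStep(8, -3.5, 4), seed = 4)
  mon <- intrafractionMotion(neg$series)
  expect_lt(maxShiftMm(mon), 0)                  # signed, not absolute
  expect_false(withinTolerance(mon))
})

test_that("rejected frames are skipped with a warning, not interpolated", {
  rc <- renderCine(phantomSpec(exposedLungMm = 10),
                   trajectoryStep(6, 2, 4), seed = 5)
  frs <- frames(rc$series)
  bad <- frs[[2]]
  bad@pixels[] <- 0.5
  s <- beamSeries(frs[c(1, 3:6)] |> append(list(bad), after = 1))
  expect_warning(mo <- intrafractionMotion(s), "excluded")
  expect_identical(length(perFrameShiftMm(mo)), 5L)
  expect_lte(abs(maxShiftMm(mo) - 2), 0.5)
})

test_that("setup error is signed, antisymmetric and tolerance-flagged", {
  spec <- phantomSpec(exposedLungMm = 15)
  ct <- ctPhantom(spec)
  drr <- projectDrr(ct)
  dm <- drrCwp(drr, makeRoi(drr), "lateral")

  same <- setupError(dm, dm)
  expect_equal(setupErrorMm(same), 0)
  expect_true(withinTolerance(same))

  ph3 <- renderPhantom(spec, seed = 6, displacementMm = 3)
  em <- inflectionCwp(ph3$frame, makeRoi(ph3$frame), "lateral")
  se <- setupError(dm, em)
  expect_lte(abs(setupErrorMm(se) - 3), 1)       # programmed +3 mm offset
  expect_true(withinTolerance(se))
  expect_equal(setupErrorMm(setupError(em, dm)), -setupErrorMm(se))

  ph6 <- renderPhantom(spec, seed = 7, displacementMm = -6)
  em6 <- inflectionCwp(ph6$frame, makeRoi(ph6$frame), "lateral")
  se6 <- setupError(dm, em6)
  expect_lte(abs(setupErrorMm(se6) + 6), 1)
  expect_false(withinTolerance(se6))             # exceeds the 5 mm tolerance

  med <- inflectionCwp(ph3$frame, makeRoi(ph3$frame), "medial")
  expect_error(setupError(dm, med), "reference edges")
})

test_that("medial- and lateral-referenced shifts agree after sign normalization", {
  spec <- phantomSpec(exposedLungMm = 10)
  base <- renderPhantom(spec, seed = 8)
  disp <- renderPhantom(spec, seed = 9, displacementMm = 2.5)
  roi <- makeRoi(base$frame)
  shift_for <- function(edge) {
    a <- medianMm(inflectionCwp(base$frame, roi, edge))
    b <- medianMm(inflectionCwp(disp$frame, roi, edge))
    sgn <- if (edge == "medial") 1 else -1
    sgn * (b - a)
  }
  s_med <- shift_for("medial")
  s_lat <- shift_for("lateral")
  expect_equal(s_med, s_lat)                     # identical after normalization
  expect_lte(abs(s_med - 2.5), 0.5)
})

test_that("a piecewise-constant trajectory is recovered frame by frame", {
  set.seed(12)
  spec <- phantomSpec(exposedLungMm = 12)
  for (k in 1:5) {
    d <- c(0, round(runif(5, -4, 4), 2))
    rc <- renderCine(spec, trajectorySpec(d), seed = 100 + k)
    mo <- intrafractionMotion(rc$series)
    expect_lte(max(abs(perFrameShiftMm(mo) - d)), 0.5)   # within one column
  }
})
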