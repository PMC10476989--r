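# The three chest wall detectors and the median/SD aggregation.

test_that("aggregation uses sample median and n-1 standard deviation", {
  expect_equal(aggregateRows(c(2, 2, 2)), list(median = 2, sd = 0))
  expect_equal(aggregateRows(c(1, 2, 100))$median, 2)   # robust to one outlier
  expect_equal(aggregateRows(5)$sd, 0)
  expect_error(aggregateRows(numeric(0)), "no distances")
  set.seed(31)
  for (k in 1:50) {
    x <- rnorm(sample(1:40, 1))
    a <- aggregateRows(x)
    expect_equal(a$median, bf_median(x))
    expect_equal(a$sd, bf_sd(x))
  }
})

test_that("stepped exposed lung moves the median CWP by 1, 3 and 5 mm", {
  roi <- NULL
  med_peak <- med_infl <- numeric(4)
  for (i in seq_along(c(1, 2, 5, 10))) {
    ph <- renderPhantom(phantomSpec(exposedLungMm = c(1, 2, 5, 10)[i]),
                        seed = 13)
    if (is.null(roi)) roi <- makeRoi(ph$frame)
    med_peak[i] <- medianMm(peakCwp(ph$frame, roi, "medial"))
    med_infl[i] <- medianMm(inflectionCwp(ph$frame, roi, "medial"))
  }
  expect_lte(max(abs(diff(med_infl) - c(1, 3, 5))), 0.5)   # within 1 column
  expect_lte(max(abs(diff(med_peak) - c(1, 3, 5))), 0.5)
})

test_that("per-row inflection precedes the peak by at most the rib width", {
  for (spec in list(phantomSpec(), phantomSpec(exposedLungMm = 2),
                    phantomSpec(ribThicknessMm = 3, noiseSigma = 0.01))) {
    ph <- renderPhantom(spec, seed = 17)
    roi <- makeRoi(ph$frame)
    m <- inflectionCwp(ph$frame, roi, "medial")
    pr <- perRow(m)
    expect_true(all(pr$featureCol <= pr$peakCol))
    gap_mm <- (pr$peakCol - pr$featureCol) * 0.5
    expect_true(all(gap_mm >= 0))
    expect_true(all(gap_mm <= spec@ribThicknessMm + 0.5))   # + 1 pixel
  }
})

test_that("noiseless junction is localized within one column", {
  ph <- renderPhantom(quiet_phantom(exposedLungMm = 7), seed = 1)
  roi <- makeRoi(ph$frame)
  m <- inflectionCwp(ph$frame, roi, "medial")
  expect_lt(abs(medianMm(m) - truthCwp(ph$truth, roi, "medial")), 0.5)
  pr <- perRow(m)
  tr <- ph$truth
  jc <- tr$junctionMm[match(pr$row, tr$row)] / 0.5 + 0.5
  expect_true(all(abs(pr$featureCol - jc) <= 1))
})

test_that("peak and inflection columns equal their brute-force oracles", {
  ph <- renderPhantom(phantomSpec(), seed = 23)
  roi <- makeRoi(ph$frame)
  pk <- perRow(peakCwp(ph$frame, roi, "medial"))
  fl <- perRow(inflectionCwp(ph$frame, roi, "medial"))
  for (i in seq_len(nrow(pk))) {
    prof <- rowProfile(ph$frame, pk$row[i])
    y <- bf_smooth(prof@intensities, 3L)
    b <- detectBorders(prof)
    seg <- cropInfield(prof, b, 2)
    peak_bf <- seg[bf_argmax(y[seg])]
    expect_identical(pk$featureCol[i], peak_bf)
    expect_identical(fl$featureCol[i], bf_inflection(y, peak_bf, 10L))
  }
})

test_that("parabolic sub-pixel refinement tightens noiseless localization", {
  spec <- quiet_phantom(exposedLungMm = 7)
  ph <- renderPhantom(spec, seed = 1)
  roi <- makeRoi(ph$frame)
  truth <- truthCwp(ph$truth, roi, "medial")
  e_int <- abs(medianMm(inflectionCwp(ph$frame, roi, "medial")) - truth)
  e_sub <- abs(medianMm(inflectionCwp(ph$frame, roi, "medial",
                                      subpixel = TRUE)) - truth)
  expect_lte(e_sub, e_int + 1e-9)
  expect_lt(e_sub, 0.25)                  # beats half the quantization limit
})

test_that("a flat in-field plateau is flagged as a broad peak", {
  px <- matrix(1, 128, 224)
  px[, 41:200] <- 0.5                      # constant open field, no rib
  f <- epidFrame(px, 0.5, 0.5)
  m <- peakCwp(f, makeRoi(f), "medial", smoothWindow = 1L)
  expect_true("broad peak" %in% measurementFlags(m))
  # plateau ties resolve leftmost: the first in-field column after the margin
  expect_true(all(perRow(m)$featureCol == perRow(m)$featureCol[1]))
})

test_that("Canny finds the lung-rib edge on a clean phantom and rejects blanks", {
  ph <- renderPhantom(quiet_phantom(exposedLungMm = 8), seed = 1)
  roi <- makeRoi(ph$frame)
  m <- cannyCwp(ph$frame, roi, "medial")
  pr <- perRow(m)
  jc <- ph$truth$junctionMm[match(pr$row, ph$truth$row)] / 0.5 + 0.5
  expect_gte(nValidRows(m), 55L)
  expect_true(all(abs(pr$featureCol - jc) <= 2))

  blank <- epidFrame(matrix(0.7, 128, 224), 0.5, 0.5)
  expect_error(cannyCwp(blank, roi), "rejected")
})

test_that("Canny parameter conventions and validity", {
  p <- cannyParams()                       # phantom calibration
  expect_equal(c(p@sigma, p@lowThreshold, p@highThreshold), c(2, 0.01, 0.02))
  p2 <- cannyParams(sigma = 4, threshold = 0.006)   # patient setting
  expect_equal(c(p2@sigma, p2@lowThreshold, p2@highThreshold),
               c(4, 0.003, 0.006))
  expect_error(cannyParams(low = 0.05, high = 0.02), "thresholds")
  expect_error(cannyParams(sigma = -1), "sigma")
})

test_that("all three detectors are invariant to global intensity scaling", {
  ph <- renderPhantom(phantomSpec(), seed = 29)
  roi <- makeRoi(ph$frame)
  scaled <- epidFrame(pixels(ph$frame) * 37.5, 0.5, 0.5)
  for (fun in list(peakCwp, inflectionCwp, cannyCwp)) {
    expect_equal(medianMm(fun(scaled, roi, "medial")),
                 medianMm(fun(ph$frame, roi, "medial")))
  }
})

test_that("frames whose rows mostly defeat border detection are rejected", {
  ph <- renderPhantom(phantomSpec(), seed = 3)
  px <- pixels(ph$frame)
  px[seq(2, 128, by = 2), ] <- 0.4         # flatten every other row
  broken <- epidFrame(px, 0.5, 0.5)
  expect_error(peakCwp(broken, makeRoi(broken), "medial"), "rejected")
})
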