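# Synthetic phantom generator: determinism, geometry truth and cine motion.

test_that("rendering is deterministic given a seed, with seed-free geometry", {
  spec <- phantomSpec()
  a <- renderPhantom(spec, seed = 5)
  b <- renderPhantom(spec, seed = 5)
  c <- renderPhantom(spec, seed = 6)
  expect_identical(pixels(a$frame), pixels(b$frame))
  expect_false(identical(pixels(a$frame), pixels(c$frame)))
  expect_identical(a$truth, c$truth)     # noise never moves the truth
})

test_that("stepped exposures shift the ground-truth junction by exactly 1/3/5 mm", {
  js <- vapply(c(1, 2, 5, 10), function(lung) {
    tr <- renderPhantom(phantomSpec(exposedLungMm = lung), seed = 1)$truth
    tr$junctionMm[tr$row == 64]
  }, numeric(1))
  expect_equal(diff(js), c(1, 3, 5))
})

test_that("the noiseless midline profile has the documented landmark structure", {
  ph <- renderPhantom(quiet_phantom(exposedLungMm = 8), seed = 1)
  tr <- ph$truth[ph$truth$row == 64, ]
  y <- pixels(ph$frame)[64, ]
  g <- diff(y)
  to_col <- function(mm) mm / 0.5 + 0.5
  expect_lte(abs(which.min(g) - to_col(tr$medialMm)), 1)       # steepest drop
  expect_lte(abs(which.max(g) - to_col(tr$lateralMm)), 1)      # steepest rise
  infield <- 50:150
  # the rib top is a near-flat blurred plateau: allow its width in ties
  expect_lte(abs(infield[which.max(y[infield])] - to_col(tr$peakMm)), 1.5)
  rise <- 40:110                                               # in-field only
  expect_lte(abs(rise[which.max(diff(y)[rise])] - to_col(tr$junctionMm)), 1.5)
})

test_that("region intensities land in attenuation_up order on the image", {
  ph <- renderPhantom(quiet_phantom(), seed = 1)
  y <- pixels(ph$frame)[64, ]
  tr <- ph$truth[ph$truth$row == 64, ]
  at <- function(mm) y[round(mm / 0.5 + 0.5)]
  expect_gt(at(5), at(tr$junctionMm - 2))                   # blocked > lung
  expect_gt(at(tr$peakMm), at(tr$peakMm + 6))               # rib > breast
  expect_gt(at(tr$peakMm + 6), at(tr$junctionMm - 2))       # breast > lung
  expect_gt(at(tr$junctionMm - 2), at(tr$skinMm + 4))       # lung > flash
})

test_that("cine trajectories displace the truth rigidly with frame 1 fixed", {
  traj <- trajectoryStep(10, 2, 5)
  expect_equal(traj@displacementsMm, c(rep(0, 4), rep(2, 6)))
  rc <- renderCine(phantomSpec(exposedLungMm = 10), traj, seed = 3)
  tr <- rc$truth
  d64 <- tr$junctionMm[tr$row == 64]
  expect_equal(d64 - d64[1], traj@displacementsMm)
  skin64 <- tr$skinMm[tr$row == 64]
  expect_equal(skin64 - skin64[1], traj@displacementsMm)    # rigid shift

  flat <- renderCine(phantomSpec(), trajectorySpec(rep(0, 3)), seed = 2)
  expect_equal(flat$truth$junctionMm[flat$truth$frame == 1],
               flat$truth$junctionMm[flat$truth$frame == 3])
})

test_that("displacements that break the field geometry are rejected", {
  expect_error(renderPhantom(phantomSpec(exposedLungMm = 2),
                             displacementMm = -4), "medial")
  expect_error(renderPhantom(phantomSpec(), displacementMm = 19), "flash")
  expect_error(trajectorySpec(c(1, 0)), "first-frame")
  expect_error(trajectoryStep(5, 2, 1))
})

test_that("the Poisson noise option produces seeded count-like noise", {
  spec <- phantomSpec(noiseModel = "poisson", noiseSigma = 0.02)
  a <- renderPhantom(spec, seed = 8)
  b <- renderPhantom(spec, seed = 8)
  expect_identical(pixels(a$frame), pixels(b$frame))
  clean <- renderPhantom(quiet_phantom(), seed = 8)
  resid <- pixels(a$frame) - pixels(clean$frame)
  # Poisson variance grows with signal: blocked (bright) noisier than flash
  expect_gt(sd(resid[, 205:220]), sd(resid[, 162:185]))
})

test_that("an invalid region layout is rejected at construction", {
  expect_error(phantomSpec(exposedLungMm = 60), "overlap")
  expect_error(phantomSpec(medialEdgeMm = 100), "medialEdgeMm")
})
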