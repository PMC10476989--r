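# DICOM RT Image round trip, geometry rescaling and cine series assembly.

test_that("DICOM round trip preserves pixels, geometry and metadata exactly", {
  ph <- renderPhantom(phantomSpec(), seed = 11, frameIndex = 3L,
                      beamId = "medA", fractionId = "fx7",
                      acquisitionTime = "120101.000")
  f <- tempfile(fileext = ".dcm")
  writeRTImage(ph$frame, f)
  rt <- readRTImage(f)

  expect_identical(pixels(rt), pixels(ph$frame))
  expect_identical(rowSpacingMm(rt), 0.5)
  expect_identical(colSpacingMm(rt), 0.5)
  expect_identical(frameIndex(rt), 3L)
  expect_identical(beamId(rt), "medA")
  expect_identical(fieldLabel(rt), "lateral")
  expect_identical(imageSource(rt), "EPID")
  expect_true(planeVerified(rt))

  # canonical orientation is a fixed point: re-reading changes nothing
  f2 <- tempfile(fileext = ".dcm")
  writeRTImage(rt, f2)
  expect_identical(pixels(readRTImage(f2)), pixels(rt))
})

test_that("detector-plane spacing is rescaled to isocenter by SAD/SID", {
  ph <- renderPhantom(phantomSpec(), seed = 2)
  f <- tempfile(fileext = ".dcm")
  # frame at 0.5 mm isocenter spacing, imaged at SID 1500 -> 0.75 mm stored
  writeRTImage(ph$frame, f, sadMm = 1000, sidMm = 1500)
  env <- epidCWP:::.parse_dicom(readBin(f, "raw", file.size(f)))
  expect_equal(epidCWP:::.dcm_ds_val(env, "30020011"), c(0.75, 0.75))
  rt <- readRTImage(f)
  expect_equal(rowSpacingMm(rt), 0.5)
  expect_true(planeVerified(rt))
})

test_that("written files parse identically under an independent DICOM reader", {
  ph <- renderPhantom(phantomSpec(), seed = 5)
  f <- tempfile(fileext = ".dcm")
  writeRTImage(ph$frame, f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import pydicom, numpy as np;",
    "d = pydicom.dcmread('", f, "');",
    "a = d.pixel_array.astype('int64');",
    "print(d.Rows, d.Columns, float(d.RescaleSlope), int(a.sum()), a[63, 5])"
  ))), stdout = TRUE)
  got <- strsplit(trimws(out[length(out)]), " ")[[1]]
  stored <- round(pixels(ph$frame) / 1e-4)
  expect_equal(as.numeric(got),
               c(128, 224, 1e-4, sum(stored), stored[64, 6]))
})

test_that("transmission-style input is inverted to attenuation_up on read", {
  ph <- renderPhantom(phantomSpec(noiseSigma = 0), seed = 1)
  f <- tempfile(fileext = ".dcm")
  px <- pixels(ph$frame)
  inv <- epidFrame(max(px) + min(px) - px, 0.5, 0.5)  # transmission-looking
  writeRTImage(inv, f)
  rt <- readRTImage(f, invert = TRUE)
  # rib region must again be brighter than lung after inversion
  expect_equal(pixels(rt), pixels(ph$frame))
})

test_that("reader rejects files without pixel data or spacing", {
  # a DICOM with header but no PixelData element
  noimg <- tempfile(fileext = ".dcm")
  meta <- c(epidCWP:::.dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  body <- c(epidCWP:::.dcm_elem(0x0008, 0x0060, "CS", "RTPLAN"))
  writeBin(c(as.raw(rep(0L, 128)), charToRaw("DICM"),
             epidCWP:::.dcm_elem(0x0002, 0x0000, "UL", epidCWP:::.u32le(length(meta))),
             meta, body), noimg)
  expect_error(readRTImage(noimg), "no pixel data")
  expect_error(readRTImage(tempfile()), "cannot read")

  # pixels present but no spacing element
  ph <- renderPhantom(phantomSpec(), seed = 1)
  f <- tempfile(fileext = ".dcm")
  writeRTImage(ph$frame, f)
  bytes <- readBin(f, "raw", file.size(f))
  tag <- c(epidCWP:::.u16le(0x3002), epidCWP:::.u16le(0x0011))
  hit <- which(bytes == tag[1])
  pos <- hit[vapply(hit, function(i) all(bytes[i:(i + 3)] == tag), logical(1))][1]
  bytes[pos:(pos + 3)] <- c(epidCWP:::.u16le(0x3002), epidCWP:::.u16le(0x0099))
  nospacing <- tempfile(fileext = ".dcm")
  writeBin(bytes, nospacing)
  expect_error(readRTImage(nospacing), "spacing")
})

test_that("cine series sort by acquisition time and reject mixed beams", {
  spec <- phantomSpec()
  dir <- tempfile(); dir.create(dir)
  paths <- character(4)
  for (i in 1:4) {
    ph <- renderPhantom(spec, seed = i, frameIndex = i,
                        acquisitionTime = sprintf("1200%02d.000", 10 - i))
    paths[i] <- file.path(dir, sprintf("f%d.dcm", i))
    writeRTImage(ph$frame, paths[i])
  }
  # later acquisition times were given to earlier instances: time wins
  bs <- suppressWarnings(readCineSeries(paths))
  expect_s4_class(bs, "BeamSeries")
  expect_identical(length(bs), 4L)
  times <- vapply(frames(bs), function(f) f@acquisitionTime, character(1))
  expect_identical(times, sort(times))

  single <- readCineSeries(paths[1])
  expect_identical(length(single), 1L)

  other <- renderPhantom(spec, seed = 9, beamId = "otherBeam")
  pother <- file.path(dir, "other.dcm")
  writeRTImage(other$frame, pother)
  expect_error(readCineSeries(c(paths, pother)), "beam identifiers")

  small <- renderPhantom(phantomSpec(nRows = 96L), seed = 1)
  psmall <- file.path(dir, "small.dcm")
  writeRTImage(small$frame, psmall)
  expect_error(readCineSeries(c(paths[1], psmall)), "shapes")
})
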