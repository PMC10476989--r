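# Batch course analysis, algorithm comparison and synthetic scenarios.
# Every summary number in the reports is recomputable from the per-frame
# CSV: motion and setup tables are derived from the frames table, not from
# hidden state.

#' Ground-truth chest wall position over a ROI
#'
#' Median of the per-row true chest wall distance (junction to reference
#' edge) over the rows of a ROI; the synthetic counterpart of a frame's
#' \code{medianMm}.
#'
#' @param truth ground-truth data.frame from [renderPhantom()] /
#'   [groundTruth()].
#' @param roi a [RoiSpec-class].
#' @param referenceEdge \code{"medial"} or \code{"lateral"}.
#' @return median true distance in mm.
#' @export
truthCwp <- function(truth, roi, referenceEdge = c("medial", "lateral")) {
  referenceEdge <- match.arg(referenceEdge)
  rows <- roiRows(roi)
  col <- if (referenceEdge == "medial") "cwpMedialMm" else "cwpLateralMm"
  stats::median(truth[[col]][match(rows, truth$row)])
}

#' Built-in synthetic scenarios
#'
#' \describe{
#'   \item{phantom-steps}{four single-frame beams with exposed lung 1, 2, 5
#'     and 10 mm (the stepped-MLC phantom experiment).}
#'   \item{motion-demo}{two 10-frame cine beams (a +2 mm step at frame 5 and
#'     a drift to +4 mm, which exceeds the 3 mm tolerance) plus a planning
#'     DRR for setup error.}
#'   \item{with-exclusions}{one 10-frame beam whose 7th frame is a flat
#'     (unanalyzable) image, exercising the exclusions report.}
#'   \item{narrow-field}{one frame with MLC corner shielding where the
#'     skin-air drop out-gradients the medial border (fallback scenario).}
#' }
#'
#' @param name scenario name.
#' @param seed integer RNG seed.
#' @return list with elements \code{beams} (list of
#'   \code{list(series, truth)}), \code{drr} (an [EpidFrame-class] or NULL)
#'   and \code{drrTruth} (data.frame or NULL).
#' @export
buildScenario <- function(name = c("phantom-steps", "motion-demo",
                                   "with-exclusions", "narrow-field"),
                          seed = 1L) {
  name <- match.arg(name)
  base <- phantomSpec(exposedLungMm = 10)
  switch(name,
    "phantom-steps" = {
      beams <- lapply(seq_along(c(1, 2, 5, 10)), function(i) {
        lung <- c(1, 2, 5, 10)[i]
        ph <- renderPhantom(phantomSpec(exposedLungMm = lung),
                            seed = seed + i, beamId = sprintf("step%02dmm", lung))
        list(series = beamSeries(list(ph$frame)), truth = ph$truth)
      })
      list(beams = beams, drr = NULL, drrTruth = NULL)
    },
    "motion-demo" = {
      b1 <- renderCine(base, trajectoryStep(10, 2, 5), seed = seed,
                       beamId = "beam-step")
      b2 <- renderCine(base, trajectoryDrift(10, 4), seed = seed + 1,
                       beamId = "beam-drift")
      ct <- ctPhantom(base)
      list(beams = list(b1, b2), drr = projectDrr(ct),
           drrTruth = groundTruth(ct))
    },
    "with-exclusions" = {
      b <- renderCine(base, trajectorySpec(rep(0, 10)), seed = seed,
                      beamId = "beam-excl")
      flat <- b$series@frames[[7]]
      flat@pixels[] <- 0.5
      b$series@frames[[7]] <- flat
      list(beams = list(b), drr = NULL, drrTruth = NULL)
    },
    "narrow-field" = {
      ph <- renderPhantom(phantomSpec(exposedLungMm = 3, mlcCorner = TRUE),
                          seed = seed, beamId = "beam-mlc")
      list(beams = list(list(series = beamSeries(list(ph$frame)),
                             truth = ph$truth)),
           drr = NULL, drrTruth = NULL)
    })
}

.frame_table <- function(beams, drr, algorithm, referenceEdge, halfSpanMm,
                         ...) {
  fun <- .cwp_algorithm(algorithm)
  rows <- list()
  add <- function(fractionId, beam, idx, meas, status) {
    rows[[length(rows) + 1L]] <<- data.frame(
      fraction = fractionId, beam = beam, frame = idx, algorithm = algorithm,
      reference_edge = referenceEdge,
      median_mm = if (is.null(meas)) NA_real_ else medianMm(meas),
      sd_mm = if (is.null(meas)) NA_real_ else sdMm(meas),
      n_valid_rows = if (is.null(meas)) 0L else nValidRows(meas),
      status = status)
  }
  for (b in beams) {
    frs <- frames(b$series)
    roi <- makeRoi(frs[[1]], halfSpanMm = halfSpanMm)
    for (f in frs) {
      meas <- tryCatch(fun(f, roi, referenceEdge = referenceEdge, ...),
                       error = function(e) conditionMessage(e))
      if (is.character(meas)) {
        add(f@fractionId, beamId(f), frameIndex(f), NULL,
            paste0("excluded: ", meas))
      } else {
        add(f@fractionId, beamId(f), frameIndex(f), meas, "ok")
      }
    }
  }
  if (!is.null(drr)) {
    roi <- makeRoi(drr, halfSpanMm = halfSpanMm)
    meas <- tryCatch(
      drrCwp(drr, roi, referenceEdge = referenceEdge),
      error = function(e) conditionMessage(e))
    if (is.character(meas)) {
      add(drr@fractionId, beamId(drr), 0L, NULL, paste0("excluded: ", meas))
    } else {
      add(drr@fractionId, beamId(drr), 0L, meas, "reference")
    }
  }
  tab <- do.call(rbind, rows)
  sgn <- .edge_sign(referenceEdge)
  tab$shift_mm <- NA_real_
  for (b in unique(tab$beam)) {
    sel <- which(tab$beam == b & tab$status == "ok")
    if (length(sel) >= 1L)
      tab$shift_mm[sel] <- sgn * (tab$median_mm[sel] - tab$median_mm[sel[1]])
  }
  tab
}

#' Analyze a treatment course and write reports
#'
#' Runs one detection algorithm over every cine frame of every beam, derives
#' per-beam intrafraction motion and (when a planning DRR is available)
#' per-fraction setup error, and writes CSV reports: \code{frames.csv}
#' (per-frame medians, SDs and shifts), \code{motion.csv},
#' \code{setup.csv}, \code{exclusions.csv}, \code{out_of_tolerance.csv} and
#' \code{summary.csv}. All summary numbers are recomputable from
#' \code{frames.csv}.
#'
#' @param input either a scenario name (see [buildScenario()]) or a list
#'   with \code{cineDirs} (character vector; each directory holds the DICOM
#'   frames of one beam, or a list of per-beam file vectors) and optionally
#'   \code{drrPath} (a DICOM MV DRR).
#' @param outputDir directory for the CSV reports (created if needed).
#' @param algorithm \code{"inflection"} (default), \code{"peak"} or
#'   \code{"canny"}.
#' @param referenceEdge \code{"lateral"} (default) or \code{"medial"}.
#' @param motionToleranceMm,setupToleranceMm clinical tolerances (3 / 5 mm).
#' @param halfSpanMm ROI half-height in mm (default 15).
#' @param seed integer seed used when \code{input} is a scenario name.
#' @param writeFigures write a per-beam motion boxplot and a setup-error
#'   histogram as PNGs (default FALSE so headless runs stay file-only).
#' @param ... further arguments to the detector.
#' @return invisibly, a list of the report data.frames.
#' @examples
#' out <- runCourse("phantom-steps", tempfile(), referenceEdge = "medial")
#' out$frames$median_mm
#' @export
runCourse <- function(input, outputDir, algorithm = "inflection",
                      referenceEdge = c("lateral", "medial"),
                      motionToleranceMm = 3, setupToleranceMm = 5,
                      halfSpanMm = 15, seed = 1L, writeFigures = FALSE,
                      ...) {
  referenceEdge <- match.arg(referenceEdge)
  stopifnot(motionToleranceMm > 0, setupToleranceMm > 0)

  if (is.character(input) && length(input) == 1L) {
    sc <- buildScenario(input, seed = seed)
    beams <- sc$beams
    drr <- sc$drr
  } else if (is.list(input)) {
    dirs <- input$cineDirs
    if (is.null(dirs)) stop("input list needs a 'cineDirs' element")
    if (is.character(dirs))
      dirs <- lapply(dirs, function(d) {
        if (!dir.exists(d)) stop("cine directory not found: ", d)
        sort(list.files(d, pattern = "\\.dcm$", full.names = TRUE))
      })
    beams <- lapply(dirs, function(p) list(series = readCineSeries(p)))
    drr <- if (!is.null(input$drrPath)) readRTImage(input$drrPath) else NULL
  } else stop("input must be a scenario name or a list")

  tab <- .frame_table(beams, drr, algorithm, referenceEdge, halfSpanMm, ...)

  ok <- tab[tab$status == "ok", , drop = FALSE]
  motion <- do.call(rbind, lapply(unique(ok$beam), function(b) {
    s <- ok[ok$beam == b, , drop = FALSE]
    if (nrow(s) < 2L)
      return(data.frame(beam = b, n_frames = nrow(s),
                        max_shift_mm = NA_real_, within_tolerance = NA,
                        tolerance_mm = motionToleranceMm))
    mx <- s$shift_mm[which.max(abs(s$shift_mm))]
    data.frame(beam = b, n_frames = nrow(s), max_shift_mm = mx,
               within_tolerance = abs(mx) <= motionToleranceMm,
               tolerance_mm = motionToleranceMm)
  }))

  setup <- NULL
  ref <- tab[tab$status == "reference", , drop = FALSE]
  if (nrow(ref) == 1L && is.finite(ref$median_mm)) {
    sgn <- .edge_sign(referenceEdge)
    setup <- do.call(rbind, lapply(unique(ok$fraction), function(fx) {
      first <- ok[ok$fraction == fx, , drop = FALSE][1L, ]
      err <- sgn * (first$median_mm - ref$median_mm)
      data.frame(fraction = fx, setup_error_mm = err,
                 within_tolerance = abs(err) <= setupToleranceMm,
                 tolerance_mm = setupToleranceMm)
    }))
  }

  excl <- tab[grepl("^excluded", tab$status),
              c("beam", "frame", "status"), drop = FALSE]
  names(excl)[3] <- "reason"

  oot <- rbind(
    if (nrow(motion))
      data.frame(type = "motion", id = motion$beam,
                 value_mm = motion$max_shift_mm)[
        !is.na(motion$within_tolerance) & !motion$within_tolerance, ],
    if (!is.null(setup))
      data.frame(type = "setup", id = setup$fraction,
                 value_mm = setup$setup_error_mm)[!setup$within_tolerance, ])
  if (is.null(oot))
    oot <- data.frame(type = character(0), id = character(0),
                      value_mm = numeric(0))

  summary_df <- data.frame(
    metric = c("n_beams", "n_frames", "n_excluded", "mean_max_motion_mm",
               "max_abs_motion_mm", "pct_beams_within_motion_tolerance",
               "mean_setup_error_mm", "pct_fractions_within_setup_tolerance"),
    value = c(nrow(motion), nrow(tab[tab$frame > 0, ]), nrow(excl),
              mean(motion$max_shift_mm, na.rm = TRUE),
              if (all(is.na(motion$max_shift_mm))) NA_real_
              else max(abs(motion$max_shift_mm), na.rm = TRUE),
              100 * mean(motion$within_tolerance, na.rm = TRUE),
              if (is.null(setup)) NA_real_ else mean(setup$setup_error_mm),
              if (is.null(setup)) NA_real_
              else 100 * mean(setup$within_tolerance)))

  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(outputDir, f),
                                         row.names = FALSE)
  wr(tab, "frames.csv")
  wr(motion, "motion.csv")
  if (!is.null(setup)) wr(setup, "setup.csv")
  wr(excl, "exclusions.csv")
  wr(oot, "out_of_tolerance.csv")
  wr(summary_df, "summary.csv")

  if (writeFigures) {
    grDevices::png(file.path(outputDir, "motion_boxplot.png"), 600, 400)
    graphics::boxplot(split(motion$max_shift_mm, motion$beam),
                      ylab = "max shift (mm)", main = "Max motion per beam")
    graphics::abline(h = c(-1, 1) * motionToleranceMm, col = "red")
    grDevices::dev.off()
    if (!is.null(setup)) {
      grDevices::png(file.path(outputDir, "setup_histogram.png"), 600, 400)
      graphics::hist(setup$setup_error_mm, xlab = "setup error (mm)",
                     main = "Setup errors")
      graphics::abline(v = c(-1, 1) * setupToleranceMm, col = "red")
      grDevices::dev.off()
    }
  }
  invisible(list(frames = tab, motion = motion, setup = setup,
                 exclusions = excl, out_of_tolerance = oot,
                 summary = summary_df))
}

#' Compare the three detection algorithms against synthetic ground truth
#'
#' Renders one frame per spec, measures it with each algorithm and reports
#' per algorithm the mean absolute error, the standard deviation of the
#' error and the maximum absolute error versus the generator's junction
#' truth (the synthetic stand-in for manual measurement).
#'
#' @param specs list of [PhantomSpec-class] objects (scenarios).
#' @param seed integer RNG seed.
#' @param algorithms subset of \code{c("canny", "peak", "inflection")}.
#' @param referenceEdge \code{"medial"} or \code{"lateral"}.
#' @param halfSpanMm ROI half-height in mm.
#' @param perFrameCsv optional path: write the per-frame errors as CSV so
#'   the table can be recomputed independently.
#' @param ... further arguments to the detectors.
#' @return list with \code{table} (per-algorithm summary data.frame) and
#'   \code{perFrame} (per-frame errors).
#' @export
compareAlgorithms <- function(specs, seed = 1L,
                              algorithms = c("canny", "peak", "inflection"),
                              referenceEdge = c("medial", "lateral"),
                              halfSpanMm = 15, perFrameCsv = NULL, ...) {
  referenceEdge <- match.arg(referenceEdge)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  per <- list()
  for (i in seq_along(specs)) {
    ph <- renderPhantom(specs[[i]], seed = seed + i)
    roi <- makeRoi(ph$frame, halfSpanMm = halfSpanMm)
    truth <- truthCwp(ph$truth, roi, referenceEdge)
    for (alg in algorithms) {
      meas <- .cwp_algorithm(alg)(ph$frame, roi,
                                  referenceEdge = referenceEdge, ...)
      per[[length(per) + 1L]] <- data.frame(
        scenario = i, algorithm = alg, median_mm = medianMm(meas),
        truth_mm = truth, error_mm = medianMm(meas) - truth)
    }
  }
  per <- do.call(rbind, per)
  tab <- do.call(rbind, lapply(algorithms, function(alg) {
    e <- per$error_mm[per$algorithm == alg]
    data.frame(algorithm = alg, mean_abs_error_mm = mean(abs(e)),
               sd_error_mm = if (length(e) > 1L) stats::sd(e) else 0,
               max_abs_error_mm = max(abs(e)), n = length(e))
  }))
  if (!is.null(perFrameCsv))
    utils::write.csv(per, perFrameCsv, row.names = FALSE)
  list(table = tab, perFrame = per)
}

#' Write a synthetic scenario to disk as DICOM plus truth sidecars
#'
#' Each frame is written with [writeRTImage()] together with a JSON sidecar
#' (same basename, \code{.truth.json}) holding its per-row ground truth, so
#' the files round-trip through [readCineSeries()] as an external dataset
#' would.
#'
#' @param name scenario name (see [buildScenario()]).
#' @param dir output directory.
#' @param seed integer RNG seed.
#' @return invisibly, a data.frame manifest (beam, frame, path).
#' @export
simulateScenario <- function(name, dir, seed = 1L) {
  sc <- buildScenario(name, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  for (b in sc$beams) {
    frs <- frames(b$series)
    bid <- beamId(frs[[1]])
    bdir <- file.path(dir, bid)
    dir.create(bdir, showWarnings = FALSE)
    for (f in frs) {
      base <- file.path(bdir, sprintf("frame%03d", frameIndex(f)))
      writeRTImage(f, paste0(base, ".dcm"))
      tr <- b$truth
      if ("frame" %in% names(tr)) tr <- tr[tr$frame == frameIndex(f), ]
      jsonlite::write_json(tr, paste0(base, ".truth.json"), digits = NA)
      manifest[[length(manifest) + 1L]] <- data.frame(
        beam = bid, frame = frameIndex(f), path = paste0(base, ".dcm"))
    }
  }
  if (!is.null(sc$drr)) {
    writeRTImage(sc$drr, file.path(dir, "drr.dcm"))
    jsonlite::write_json(sc$drrTruth, file.path(dir, "drr.truth.json"),
                         digits = NA)
  }
  invisible(do.call(rbind, manifest))
}
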