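# Minimal DICOM RT Image I/O (explicit VR little endian only).
#
# Only the tags this tool needs are written/parsed; unknown elements are
# skipped on read. Pixel data are 16-bit unsigned with a fixed rescale slope
# of 1e-4 (intercept 0), so intensities on the generator's 0-1 attenuation
# scale round-trip exactly once quantized to that grid.

.DICOM_SLOPE <- 1e-4
.dicom_uid_counter <- new.env(parent = emptyenv())
.dicom_uid_counter$n <- 0L
.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.KNOWN_VRS <- c(.LONG_VRS, "AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL",
                "FD", "IS", "LO", "LT", "PN", "SH", "SL", "SS", "ST", "TM",
                "UI", "UL", "US")

.u16le <- function(v) {
  v <- as.integer(v)
  as.raw(rbind(v %% 256L, v %/% 256L))
}

.u32le <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
           (v %/% 16777216) %% 256))
}

.read_u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}

.read_u32 <- function(bytes, pos) {
  as.numeric(bytes[pos]) + 256 * as.numeric(bytes[pos + 1L]) +
    65536 * as.numeric(bytes[pos + 2L]) + 16777216 * as.numeric(bytes[pos + 3L])
}

.dcm_elem <- function(group, elem, vr, value) {
  if (is.character(value)) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L) value <- c(value, pad)
  }
  stopifnot(is.raw(value), length(value) %% 2L == 0L)
  tag <- c(.u16le(group), .u16le(elem))
  if (vr %in% .LONG_VRS) {
    c(tag, charToRaw(vr), as.raw(c(0L, 0L)), .u32le(length(value)), value)
  } else {
    c(tag, charToRaw(vr), .u16le(length(value)), value)
  }
}

.dcm_ds <- function(x) paste(format(x, digits = 10, trim = TRUE,
                                    scientific = FALSE), collapse = "\\")

#' Write an EpidFrame as a DICOM RT Image file
#'
#' Writes explicit-VR little-endian DICOM with 16-bit pixels and a fixed
#' rescale slope of 1e-4, so intensities in [0, 6.5535] already quantized to
#' that grid round-trip bit-for-bit. The pixel spacing stored in the file is
#' the detector-plane spacing \code{frame spacing * sidMm / sadMm}; with the
#' default 1:1 geometry the stored and frame spacings coincide.
#'
#' @param frame an [EpidFrame-class].
#' @param path output file path.
#' @param sadMm,sidMm source-axis and source-imager distances written to the
#'   header (defaults 1000/1000, i.e. the detector at isocenter scale).
#' @return \code{path}, invisibly.
#' @seealso [readRTImage()]
#' @export
writeRTImage <- function(frame, path, sadMm = 1000, sidMm = 1000) {
  stopifnot(is(frame, "EpidFrame"))
  p <- frame@pixels
  if (min(p) < 0 || max(p) > 65535 * .DICOM_SLOPE)
    stop("pixel intensities must lie in [0, ", 65535 * .DICOM_SLOPE,
         "] for 16-bit storage")
  stored <- round(p / .DICOM_SLOPE)   # keeps matrix dims for the transpose
  # UID from a session counter, not the RNG, so writing never perturbs
  # seeded simulations.
  .dicom_uid_counter$n <- .dicom_uid_counter$n + 1L
  sop_uid <- paste0("1.2.826.0.1.3680043.9.7434.", Sys.getpid(), ".",
                    .dicom_uid_counter$n, ".", frame@frameIndex)

  meta <- c(
    .dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    .dcm_elem(0x0002, 0x0002, "UI", "1.2.840.10008.5.1.4.1.1.481.1"),
    .dcm_elem(0x0002, 0x0003, "UI", sop_uid),
    .dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    .dcm_elem(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9.7434.1")
  )
  header <- c(as.raw(rep(0L, 128L)), charToRaw("DICM"),
              .dcm_elem(0x0002, 0x0000, "UL", .u32le(length(meta))), meta)

  spacing_det <- c(frame@rowSpacingMm, frame@colSpacingMm) * sidMm / sadMm
  body <- c(
    .dcm_elem(0x0008, 0x0016, "UI", "1.2.840.10008.5.1.4.1.1.481.1"),
    .dcm_elem(0x0008, 0x0018, "UI", sop_uid),
    if (nzchar(frame@acquisitionTime))
      .dcm_elem(0x0008, 0x0032, "TM", frame@acquisitionTime),
    .dcm_elem(0x0008, 0x0060, "CS", "RTIMAGE"),
    .dcm_elem(0x0008, 0x1030, "LO", frame@fractionId),
    .dcm_elem(0x0008, 0x103e, "LO", frame@beamId),
    .dcm_elem(0x0020, 0x0013, "IS", as.character(frame@frameIndex)),
    .dcm_elem(0x0020, 0x4000, "LT",
              sprintf("field=%s;source=%s;convention=attenuation_up",
                      frame@fieldLabel, frame@source)),
    .dcm_elem(0x0028, 0x0002, "US", .u16le(1L)),
    .dcm_elem(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .dcm_elem(0x0028, 0x0010, "US", .u16le(nrow(p))),
    .dcm_elem(0x0028, 0x0011, "US", .u16le(ncol(p))),
    .dcm_elem(0x0028, 0x0100, "US", .u16le(16L)),
    .dcm_elem(0x0028, 0x0101, "US", .u16le(16L)),
    .dcm_elem(0x0028, 0x0102, "US", .u16le(15L)),
    .dcm_elem(0x0028, 0x0103, "US", .u16le(0L)),
    .dcm_elem(0x0028, 0x1052, "DS", "0"),
    .dcm_elem(0x0028, 0x1053, "DS", .dcm_ds(.DICOM_SLOPE)),
    .dcm_elem(0x3002, 0x0011, "DS", .dcm_ds(spacing_det)),
    .dcm_elem(0x3002, 0x0022, "DS", .dcm_ds(sadMm)),
    .dcm_elem(0x3002, 0x0026, "DS", .dcm_ds(sidMm)),
    .dcm_elem(0x7fe0, 0x0010, "OW", .u16le(as.vector(t(stored))))
  )
  writeBin(c(header, body), path)
  invisible(path)
}

# Parse a DICOM byte stream into a tag -> value environment.
.parse_dicom <- function(bytes) {
  n <- length(bytes)
  if (n < 140L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic)")
  pos <- 133L
  out <- new.env(parent = emptyenv())
  while (pos + 7L <= n) {
    group <- .read_u16(bytes, pos)
    elem <- .read_u16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!vr %in% .KNOWN_VRS)
      stop("unsupported DICOM encoding (expected explicit VR little endian)")
    if (vr %in% .LONG_VRS) {
      len <- .read_u32(bytes, pos + 8L)
      data_pos <- pos + 12L
    } else {
      len <- .read_u16(bytes, pos + 6L)
      data_pos <- pos + 8L
    }
    if (data_pos + len - 1L > n) stop("truncated DICOM element")
    key <- sprintf("%04x%04x", group, elem)
    val_raw <- if (len > 0) bytes[data_pos:(data_pos + len - 1L)] else raw(0)
    assign(key, list(vr = vr, raw = val_raw), envir = out)
    pos <- data_pos + as.integer(len)
  }
  ts <- .dcm_str(out, "00020010")
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported transfer syntax: ", ts)
  out
}

.dcm_str <- function(env, key) {
  if (!exists(key, envir = env)) return(NULL)
  v <- get(key, envir = env)$raw
  v <- v[v != as.raw(0L)]
  if (!length(v)) return("")
  trimws(rawToChar(v))
}

.dcm_ds_val <- function(env, key) {
  s <- .dcm_str(env, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcm_us_val <- function(env, key) {
  if (!exists(key, envir = env)) return(NULL)
  v <- get(key, envir = env)$raw
  .read_u16(v, 1L)
}

#' Read a DICOM RT Image file into an EpidFrame
#'
#' Reads explicit-VR little-endian DICOM (as written by [writeRTImage()] and
#' by Varian Offline Review exports of aS1000 cine frames). When both the
#' radiation machine SAD and the RT image SID are present, the pixel spacing
#' is rescaled to the isocenter plane by SAD/SID so that EPID and DRR
#' measurements subtract meaningfully; otherwise the stored spacing is used
#' as-is and the frame is flagged \code{planeVerified = FALSE}.
#'
#' @param path file path.
#' @param invert set \code{TRUE} for transmission-style images (denser
#'   anatomy darker); the frame is inverted to the canonical attenuation_up
#'   convention.
#' @param flipColumns set \code{TRUE} to mirror columns when the medial field
#'   border is on the right of the stored image.
#' @return an [EpidFrame-class].
#' @examples
#' ph <- renderPhantom(phantomSpec(), seed = 1)
#' f <- tempfile(fileext = ".dcm")
#' writeRTImage(ph$frame, f)
#' readRTImage(f)
#' @export
readRTImage <- function(path, invert = FALSE, flipColumns = FALSE) {
  if (!file.exists(path)) stop("cannot read DICOM file: ", path)
  bytes <- readBin(path, "raw", file.size(path))
  env <- .parse_dicom(bytes)

  if (!exists("7fe00010", envir = env)) stop("no pixel data")
  nr <- .dcm_us_val(env, "00280010")
  nc <- .dcm_us_val(env, "00280011")
  if (is.null(nr) || is.null(nc)) stop("missing Rows/Columns")
  bits <- .dcm_us_val(env, "00280100")
  if (!is.null(bits) && bits != 16L) stop("only 16-bit pixel data supported")

  spacing <- .dcm_ds_val(env, "30020011")          # ImagePlanePixelSpacing
  if (is.null(spacing)) spacing <- .dcm_ds_val(env, "00280030")
  if (is.null(spacing)) stop("no pixel spacing metadata")
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)

  raw_px <- get("7fe00010", envir = env)$raw
  if (length(raw_px) < 2L * nr * nc) stop("pixel data shorter than Rows*Columns")
  idx <- seq_len(nr * nc)
  lo <- as.integer(raw_px[2L * idx - 1L])
  hi <- as.integer(raw_px[2L * idx])
  stored <- lo + 256L * hi
  slope <- .dcm_ds_val(env, "00281053"); if (is.null(slope)) slope <- 1
  inter <- .dcm_ds_val(env, "00281052"); if (is.null(inter)) inter <- 0
  px <- matrix(stored * slope + inter, nrow = nr, ncol = nc, byrow = TRUE)

  sad <- .dcm_ds_val(env, "30020022")
  sid <- .dcm_ds_val(env, "30020026")
  plane_ok <- !is.null(sad) && !is.null(sid) &&
    is.finite(sad) && is.finite(sid) && sid > 0
  if (plane_ok) spacing <- spacing * sad / sid

  comments <- .dcm_str(env, "00204000")
  field <- "lateral"; src <- "EPID"
  if (!is.null(comments)) {
    m <- regmatches(comments, regexec("field=(medial|lateral)", comments))[[1]]
    if (length(m) == 2L) field <- m[2]
    m <- regmatches(comments, regexec("source=(EPID|MV_DRR)", comments))[[1]]
    if (length(m) == 2L) src <- m[2]
  }
  inst <- .dcm_str(env, "00200013")
  frame_idx <- if (!is.null(inst) && nzchar(inst)) as.integer(inst) else 1L
  beam <- .dcm_str(env, "0008103e"); if (is.null(beam) || !nzchar(beam)) beam <- "beam1"
  fx <- .dcm_str(env, "00081030"); if (is.null(fx) || !nzchar(fx)) fx <- "fx1"
  acq <- .dcm_str(env, "00080032"); if (is.null(acq)) acq <- ""

  if (flipColumns) px <- px[, ncol(px):1, drop = FALSE]
  epidFrame(px, spacing[1], spacing[2], frameIndex = frame_idx,
            beamId = beam, fractionId = fx, fieldLabel = field, source = src,
            intensityConvention = if (invert) "transmission_up" else "attenuation_up",
            planeVerified = plane_ok, acquisitionTime = acq)
}

#' Read a cine series of DICOM RT Image files
#'
#' Frames are sorted by acquisition time when every file carries one, else by
#' instance number, else by file name. All frames must share the beam
#' identifier, field label and image shape.
#'
#' @param paths character vector of file paths (at least one).
#' @param ... passed to [readRTImage()].
#' @return a [BeamSeries-class]; the first (earliest) frame is the reference
#'   for intrafraction motion.
#' @export
readCineSeries <- function(paths, ...) {
  if (length(paths) < 1L) stop("need at least one frame")
  fr <- lapply(paths, readRTImage, ...)

  ids <- vapply(fr, beamId, character(1))
  if (length(unique(ids)) != 1L)
    stop("frames mix beam identifiers: ", paste(unique(ids), collapse = ", "))
  shapes <- vapply(fr, function(f) dim(f@pixels), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("frames mix image shapes")

  times <- vapply(fr, function(f) f@acquisitionTime, character(1))
  if (all(nzchar(times))) {
    ord <- order(as.numeric(times))
  } else {
    idx <- vapply(fr, frameIndex, integer(1))
    ord <- if (!anyDuplicated(idx)) order(idx) else order(basename(paths))
  }
  fr <- fr[ord]
  idx <- vapply(fr, frameIndex, integer(1))
  if (any(diff(idx) <= 0L)) {
    warning("instance numbers not strictly increasing after sort; renumbering")
    fr <- mapply(function(f, i) { f@frameIndex <- i; f }, fr,
                 seq_along(fr), SIMPLIFY = FALSE)
  }
  beamSeries(fr)
}
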