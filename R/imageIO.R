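## Frame stack I/O.
##
## The on-disk formats are deliberately simple and text-auditable:
##  - raw binary stacks: consecutive frames of int32 or float64,
##    little-endian, with a plain-text key=value header sidecar (.hdr);
##  - TIFF (single- or multi-page) for ingest of detector output;
##  - TSV peak lists, one file per frame;
##  - a single-panel key/value geometry file for downstream indexers.

#' Write a raw-binary frame stack
#'
#' Stores frames consecutively as little-endian int32 (when all counts are
#' integral) or float64, and writes a plain-text header sidecar
#' (`<path>.hdr`) recording shape, count, dtype and per-frame metadata.
#'
#' @param frames list of [ImageFrame-class] objects of one shape.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readFrames()]
#' @export
writeFrameStack <- function(frames, path) {
  stopIfNot(length(frames) > 0, "no frames to write")
  d <- dim(pixels(frames[[1]]))
  px <- lapply(frames, pixels)
  stopIfNot(all(vapply(px, function(p) identical(dim(p), d), logical(1))),
            "all frames must share one shape")
  allInt <- all(vapply(px, function(p) all(p == round(p)) && max(abs(p)) < 2^31,
                       logical(1)))
  dtype <- if (allInt) "int32" else "float64"
  con <- file(path, "wb")
  on.exit(close(con))
  for (p in px) {
    v <- as.vector(p)  # column-major: fs fastest, matching the convention
    if (dtype == "int32") writeBin(as.integer(v), con, size = 4L,
                                   endian = "little")
    else writeBin(as.numeric(v), con, size = 8L, endian = "little")
  }
  hdr <- c(
    sprintf("n_frames=%d", length(frames)),
    sprintf("n_fast=%d", d[1]),
    sprintf("n_slow=%d", d[2]),
    sprintf("dtype=%s", dtype),
    "byte_order=little",
    sprintf("frame_id=%s",
            paste(vapply(frames, frameId, integer(1)), collapse = ",")),
    sprintf("exposure=%s",
            paste(vapply(frames, function(f) f@exposure, numeric(1)),
                  collapse = ","))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

readStackHeader <- function(path) {
  lines <- readLines(paste0(path, ".hdr"))
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  vals
}

#' Read a stack of detector frames
#'
#' Dispatches on format: `"raw"` reads a raw-binary stack written by
#' [writeFrameStack()] (or any stack matching its header dialect), `"tiff"`
#' reads a single- or multi-page TIFF, `"auto"` guesses from the file
#' extension. Frames are returned ordered by frame id.
#'
#' @param path file path.
#' @param formatHint one of `"auto"`, `"raw"`, `"tiff"`.
#' @param geom optional [DetectorGeometry-class]; when given, the frame shape
#'   is checked against it and a mismatch is an error.
#' @return list of [ImageFrame-class] objects (possibly empty).
#' @export
readFrames <- function(path, formatHint = c("auto", "raw", "tiff"),
                       geom = NULL) {
  formatHint <- match.arg(formatHint)
  stopIfNot(file.exists(path), sprintf("no such file: %s", path))
  if (formatHint == "auto") {
    formatHint <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
    else if (file.exists(paste0(path, ".hdr"))) "raw"
    else stop("cannot guess format of ", path, call. = FALSE)
  }
  frames <- switch(formatHint,
    raw = readRawStack(path),
    tiff = readTiffStack(path))
  if (!is.null(geom) && length(frames)) {
    d <- dim(pixels(frames[[1]]))
    stopIfNot(d[1] == geom@nFast && d[2] == geom@nSlow,
              sprintf("frame shape %d x %d does not match geometry %d x %d",
                      d[1], d[2], geom@nFast, geom@nSlow))
  }
  ids <- vapply(frames, frameId, integer(1))
  frames[order(ids)]
}

readRawStack <- function(path) {
  hdr <- readStackHeader(path)
  n <- as.integer(hdr[["n_frames"]])
  nf <- as.integer(hdr[["n_fast"]]); ns <- as.integer(hdr[["n_slow"]])
  dtype <- hdr[["dtype"]]
  ids <- if (!is.na(hdr["frame_id"]))
    as.integer(strsplit(hdr[["frame_id"]], ",")[[1]]) else seq_len(n) - 1L
  expo <- if (!is.na(hdr["exposure"]))
    as.numeric(strsplit(hdr[["exposure"]], ",")[[1]]) else rep(0.1, n)
  if (n == 0) return(list())
  con <- file(path, "rb")
  on.exit(close(con))
  lapply(seq_len(n), function(i) {
    v <- if (dtype == "int32")
      as.numeric(readBin(con, "integer", nf * ns, size = 4L,
                         endian = "little"))
    else readBin(con, "numeric", nf * ns, size = 8L, endian = "little")
    imageFrame(matrix(v, nf, ns), frameId = ids[i], exposure = expo[i])
  })
}

readTiffStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3) m <- m[, , 1]  # collapse grayscale channels
    ## TIFF stores [row, col] = [ss, fs]; transpose into fs-major layout
    imageFrame(t(m) * 1.0, frameId = i - 1L)
  })
}

#' Write selected hits with their peak lists
#'
#' Writes one corrected image per hit (raw-binary frame stack of length one,
#' `<prefix>_<id>.img`) together with its peak list (`<prefix>_<id>_peaks.tsv`,
#' columns fs/ss/intensity plus snr and d). A frame with no located peaks
#' still gets a peak file with a header and zero rows, so downstream readers
#' always find an N x 3 table. In `format = "tsv"` mode the image itself is
#' also written as text (TSV of counts), trading size for auditability.
#'
#' @param frames list of [ImageFrame-class] hits.
#' @param peakLists list of [PeakList-class], one per frame, same order.
#' @param outDir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param format `"raw"` (binary image + TSV peaks) or `"tsv"` (all text).
#' @return data.frame manifest: frameId, imagePath, peakPath, nPeaks.
#' @export
writeHits <- function(frames, peakLists, outDir, prefix = "hit",
                      format = c("raw", "tsv")) {
  format <- match.arg(format)
  stopIfNot(length(frames) == length(peakLists),
            "need exactly one peak list per frame")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]; pl <- peakLists[[i]]
    stopIfNot(frameId(f) == frameId(pl),
              "frame/peak-list ids out of step")
    stem <- file.path(outDir, sprintf("%s_%06d", prefix, frameId(f)))
    imgPath <- if (format == "raw") {
      writeFrameStack(list(f), paste0(stem, ".img"))
      paste0(stem, ".img")
    } else {
      utils::write.table(pixels(f), paste0(stem, ".img.tsv"),
                         sep = "\t", row.names = FALSE, col.names = FALSE)
      paste0(stem, ".img.tsv")
    }
    pkPath <- paste0(stem, "_peaks.tsv")
    writePeaksTSV(pl, pkPath)
    data.frame(frameId = frameId(f), imagePath = imgPath,
               peakPath = pkPath, nPeaks = nrow(peaks(pl)))
  })
  do.call(rbind, rows)
}

#' Write / read a peak list as TSV
#'
#' Column order fs, ss, intensity, snr, d; the first three columns are the
#' N x 3 table downstream indexers ingest.
#'
#' @param pl a [PeakList-class].
#' @param path file path.
#' @return `writePeaksTSV`: `path` invisibly. `readPeaksTSV`: a
#'   [PeakList-class].
#' @export
writePeaksTSV <- function(pl, path) {
  utils::write.table(peaks(pl), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writePeaksTSV
#' @param frameId frame id to attach on read.
#' @export
readPeaksTSV <- function(path, frameId = 0L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  peakList(frameId, df)
}

#' Write a downstream-indexer geometry file
#'
#' Emits a minimal single-panel plain-text geometry description in the
#' key/value dialect indexing suites consume: panel extent, pixel resolution
#' (pixels per metre), camera length, wavelength and the panel corner
#' position relative to the beam (in pixels, so corner = -beamCenter).
#'
#' @param geom a [DetectorGeometry-class].
#' @param beam optional [BeamParams-class]; adds beam metadata lines.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readGeometryFile()]
#' @export
writeGeometryFile <- function(geom, path, beam = NULL) {
  lines <- c(
    "; single-panel geometry",
    sprintf("wavelength = %.10g A", geom@wavelength),
    sprintf("clen = %.10g", geom@distance / 1000),           # metres
    sprintf("res = %.10g", 1000 / geom@pixelSize),           # pixels per metre
    "panel0/min_fs = 0",
    sprintf("panel0/max_fs = %d", geom@nFast - 1L),
    "panel0/min_ss = 0",
    sprintf("panel0/max_ss = %d", geom@nSlow - 1L),
    sprintf("panel0/corner_x = %.10g", -geom@beamCenter[1]),
    sprintf("panel0/corner_y = %.10g", -geom@beamCenter[2]),
    "panel0/fs = +x",
    "panel0/ss = +y"
  )
  if (!is.null(beam))
    lines <- c(lines,
               sprintf("; beam fluence = %.10g photons/s", beam@fluence),
               sprintf("; beam divergence = %.10g mrad", beam@divergence),
               sprintf("; beam bandwidth = %.10g", beam@bandwidth))
  writeLines(lines, path)
  invisible(path)
}

#' Read a geometry file written by [writeGeometryFile()]
#'
#' @param path geometry file path.
#' @return A [DetectorGeometry-class].
#' @export
readGeometryFile <- function(path) {
  lines <- grep("^\\s*(;|$)", readLines(path), invert = TRUE, value = TRUE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  num <- function(k) as.numeric(sub("\\s.*$", "", vals[match(k, keys)]))
  detectorGeometry(
    nFast = num("panel0/max_fs") + 1, nSlow = num("panel0/max_ss") + 1,
    pixelSize = 1000 / num("res"), distance = num("clen") * 1000,
    beamCenter = c(-num("panel0/corner_x"), -num("panel0/corner_y")),
    wavelength = num("wavelength"))
}

#' Pad a frame so the beam centre is the image centre
#'
#' Grows the frame into a square whose geometric centre coincides with the
#' (rounded) beam-centre pixel, as required by processing suites that assume
#' a centred beam. Added pixels carry the mask sentinel (-1) and are flagged
#' in the mask; original pixels are unchanged. Applying the operation twice
#' is a no-op.
#'
#' @param frame an [ImageFrame-class].
#' @param geom the matching [DetectorGeometry-class].
#' @return list with elements `frame` (padded [ImageFrame-class]) and `geom`
#'   (updated [DetectorGeometry-class]).
#' @export
padToCenter <- function(frame, geom) {
  px <- pixels(frame)
  nf <- nrow(px); ns <- ncol(px)
  cf <- round(geom@beamCenter[1]); cs <- round(geom@beamCenter[2])
  stopIfNot(cf >= 0 && cf < nf && cs >= 0 && cs < ns,
            "beam centre must lie inside the frame")
  size <- 2L * max(cf, nf - 1L - cf, cs, ns - 1L - cs) + 1L
  ctr <- (size - 1L) / 2L
  offF <- ctr - cf; offS <- ctr - cs
  out <- matrix(MASK_SENTINEL, size, size)
  outMask <- matrix(TRUE, size, size)
  out[offF + seq_len(nf), offS + seq_len(ns)] <- px
  outMask[offF + seq_len(nf), offS + seq_len(ns)] <- effectiveMask(frame)
  newGeom <- detectorGeometry(
    size, size, geom@pixelSize, geom@distance,
    beamCenter = c(ctr + (geom@beamCenter[1] - cf),
                   ctr + (geom@beamCenter[2] - cs)),
    wavelength = geom@wavelength)
  list(frame = imageFrame(out, frameId = frameId(frame),
                          scanPos = frame@scanPos, exposure = frame@exposure,
                          mask = outMask),
       geom = newGeom)
}
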