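## Metrology correction and per-pattern scaled background subtraction.
##
## CCD-type detectors need a per-pixel gain (flat-field) correction and a
## geometric-distortion remap before quantitative use. Background must then
## be removed per pattern: crystal and solvent are mutually exclusive in the
## illuminated volume, so the amount of solvent background in a hit varies
## from shot to shot and a single reference cannot simply be subtracted --
## it has to be scaled to each frame first.

#' Apply metrology correction to a frame
#'
#' Multiplies by the flat-field gain map, then resamples the result through
#' the displacement field with bilinear interpolation (pull semantics:
#' corrected pixel (fs, ss) is sampled at (fs + dispFS, ss + dispSS)).
#' Pixels that are masked, or whose source lands outside the panel or on a
#' masked pixel, are set to the sentinel and flagged in the output mask.
#'
#' @param frame an [ImageFrame-class].
#' @param maps a [MetrologyMaps-class] matching the frame shape.
#' @return The corrected [ImageFrame-class].
#' @export
applyMetrology <- function(frame, maps) {
  px <- pixels(frame)
  stopIfNot(identical(dim(px), dim(maps@flatfield)),
            "metrology maps do not match the frame shape")
  gained <- px * maps@flatfield
  nf <- nrow(px); ns <- ncol(px)
  ## 0-based source coordinates for every output pixel
  srcF <- outer(0:(nf - 1), rep(0, ns), `+`) + maps@dispFS
  srcS <- outer(rep(0, nf), 0:(ns - 1), `+`) + maps@dispSS
  f0 <- floor(srcF); s0 <- floor(srcS)
  wf <- srcF - f0; ws <- srcS - s0
  ## per-axis validity: off-grid samples need both neighbours in range,
  ## exact on-grid coordinates only the one
  fsOK <- f0 >= 0 & f0 <= (nf - 1) & (f0 + 1 <= nf - 1 | wf == 0)
  ssOK <- s0 >= 0 & s0 <= (ns - 1) & (s0 + 1 <= ns - 1 | ws == 0)
  ok <- fsOK & ssOK
  out <- matrix(MASK_SENTINEL, nf, ns)
  badSrc <- matrix(FALSE, nf, ns)
  idx <- function(fi, si) fi + 1L + nf * si   # 0-based (fs, ss) -> linear
  i <- which(ok)
  if (length(i)) {
    f0i <- f0[i]; s0i <- s0[i]; wfi <- wf[i]; wsi <- ws[i]
    f1i <- pmin(f0i + 1, nf - 1); s1i <- pmin(s0i + 1, ns - 1)
    v00 <- gained[idx(f0i, s0i)]; v10 <- gained[idx(f1i, s0i)]
    v01 <- gained[idx(f0i, s1i)]; v11 <- gained[idx(f1i, s1i)]
    w00 <- (1 - wfi) * (1 - wsi); w10 <- wfi * (1 - wsi)
    w01 <- (1 - wfi) * wsi; w11 <- wfi * wsi
    out[i] <- w00 * v00 + w10 * v10 + w01 * v01 + w11 * v11
    ## a sample drawing weight from any masked source pixel is invalid
    m <- maps@mask | effectiveMask(frame)
    badSrc[i] <- (w00 > 0 & m[idx(f0i, s0i)]) |
      (w10 > 0 & m[idx(f1i, s0i)]) |
      (w01 > 0 & m[idx(f0i, s1i)]) |
      (w11 > 0 & m[idx(f1i, s1i)])
  }
  outMask <- !ok | badSrc | maps@mask
  out[outMask] <- MASK_SENTINEL
  imageFrame(out, frameId = frameId(frame), scanPos = frame@scanPos,
             exposure = frame@exposure, mask = outMask)
}

#' Estimate a background model from non-hit frames
#'
#' Builds a pixelwise mean or median reference across the supplied frames
#' (typically the non-hits of one scan, which share the same solvent and
#' membrane scatter) and its radial profile about the beam centre.
#'
#' @param frames non-empty list of [ImageFrame-class] non-hits.
#' @param geom a [DetectorGeometry-class] (for the radial profile).
#' @param method `"mean"` or `"median"`.
#' @param nBins radial-profile bin count.
#' @return A [BackgroundModel-class].
#' @export
estimateBackground <- function(frames, geom, method = c("mean", "median"),
                               nBins = 100) {
  method <- match.arg(method)
  stopIfNot(length(frames) >= 1, "need at least one non-hit frame")
  d <- dim(pixels(frames[[1]]))
  arr <- vapply(frames, pixels, matrix(0, d[1], d[2]))
  ref <- if (method == "mean") {
    matrix(rowMeans(matrix(arr, d[1] * d[2])), d[1], d[2])
  } else {
    matrix(apply(matrix(arr, d[1] * d[2]), 1, stats::median), d[1], d[2])
  }
  prof <- radialMean(ref, geom, nBins)
  new("BackgroundModel", reference = ref, profile = prof,
      nSourceFrames = length(frames), method = method)
}

## Azimuthal mean of a plain matrix (helper shared with the hit finder).
radialMean <- function(img, geom, nBins, mask = NULL) {
  r <- radiusField(geom)
  keep <- if (is.null(mask)) rep(TRUE, length(img)) else !as.vector(mask)
  rmax <- max(r)
  edges <- seq(0, rmax * (1 + 1e-9), length.out = nBins + 1)
  bin <- findInterval(as.vector(r), edges, rightmost.closed = TRUE)
  v <- as.vector(img)
  sums <- tapply(v[keep], bin[keep], sum)
  cnts <- tapply(v[keep], bin[keep], length)
  meanI <- rep(NA_real_, nBins)
  nPix <- rep(0L, nBins)
  ix <- as.integer(names(sums))
  meanI[ix] <- sums / cnts
  nPix[ix] <- as.integer(cnts)
  mid <- (edges[-1] + edges[-(nBins + 1)]) / 2
  data.frame(radius = mid, d = radiusToD(mid, geom), meanI = meanI,
             nPix = nPix)
}

#' Subtract a scaled background from one frame
#'
#' The per-pattern scale is the least-squares solution
#' `s = sum(f * b) / sum(b^2)` over pixels that are unmasked, outside the
#' candidate-peak mask and (optionally) inside a resolution annulus; the
#' corrected frame is `f - s * b`. Negative residuals are kept by default --
#' they carry unbiased noise into merging -- and can be clipped at a floor
#' for display.
#'
#' @param frame an [ImageFrame-class].
#' @param bg a [BackgroundModel-class].
#' @param peakMask optional logical matrix, TRUE over candidate Bragg
#'   regions to exclude from the fit.
#' @param geom optional [DetectorGeometry-class]; needed when an annulus is
#'   requested.
#' @param annulusD optional length-2 numeric `c(dMax, dMin)` restricting the
#'   fit to pixels with d-spacings in that range.
#' @param clipFloor optional numeric; residuals below it are raised to it
#'   (e.g. 0 to mimic display-style clipping).
#' @return list with `frame` (corrected [ImageFrame-class]) and `scale`
#'   (the fitted s, >= 0 and free to exceed 1).
#' @export
subtractBackgroundScaled <- function(frame, bg, peakMask = NULL, geom = NULL,
                                     annulusD = NULL, clipFloor = NULL) {
  px <- pixels(frame)
  b <- reference(bg)
  stopIfNot(identical(dim(px), dim(b)), "background does not match frame")
  stopIfNot(any(b != 0), "background reference is identically zero")
  keep <- !effectiveMask(frame)
  if (!is.null(peakMask)) keep <- keep & !peakMask
  if (!is.null(annulusD)) {
    stopIfNot(!is.null(geom), "annulus restriction needs the geometry")
    dmap <- radiusToD(radiusField(geom), geom)
    keep <- keep & dmap <= max(annulusD) & dmap >= min(annulusD)
  }
  denom <- sum(b[keep]^2)
  s <- if (denom > 0) max(0, sum(px[keep] * b[keep]) / denom) else 0
  out <- px - s * b
  if (!is.null(clipFloor)) out[out < clipFloor] <- clipFloor
  m <- effectiveMask(frame)
  out[m] <- MASK_SENTINEL
  list(frame = imageFrame(out, frameId = frameId(frame),
                          scanPos = frame@scanPos, exposure = frame@exposure,
                          mask = m),
       scale = s)
}
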