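## Hit classification and whole-dataset projections.
##
## A "hit" is a frame containing Bragg diffraction from a crystal, as
## opposed to a blank or solvent-only shot. Classification is a two-part
## threshold test: a pixel must exceed a count threshold AND enough such
## pixels must be present, which rejects both blank frames and single hot
## pixels / low-resolution-only images.

#' Classify frames as hits
#'
#' A frame is a hit when at least `minNpix` unmasked pixels strictly exceed
#' `threshold` ADU (boundary inclusive on the pixel count: exactly
#' `minNpix` qualifying pixels is a hit). Deterministic; raising either
#' parameter can only demote hits.
#'
#' @param frames list of [ImageFrame-class] (ideally metrology-corrected and
#'   background-subtracted, so one threshold serves a whole scan).
#' @param threshold pixel threshold (ADU, > 0).
#' @param minNpix minimum number of qualifying pixels (>= 1).
#' @return data.frame of hit records: frameId, isHit, nAbove, maxPixel.
#' @export
findHits <- function(frames, threshold, minNpix = 20L) {
  stopIfNot(threshold > 0, "threshold must be positive")
  stopIfNot(minNpix >= 1, "minNpix must be >= 1")
  rows <- lapply(frames, function(f) {
    v <- pixels(f)[!effectiveMask(f)]
    nAbove <- sum(v > threshold)
    data.frame(frameId = frameId(f), isHit = nAbove >= minNpix,
               nAbove = nAbove, maxPixel = if (length(v)) max(v) else -Inf)
  })
  do.call(rbind, rows)
}

#' Hit rate of a set of hit records
#'
#' @param records data.frame from [findHits()], or a logical vector.
#' @return Hit fraction in percent.
#' @examples
#' hitRate(c(rep(TRUE, 99), rep(FALSE, 901)))  # 9.9
#' @export
hitRate <- function(records) {
  isHit <- if (is.data.frame(records)) records$isHit else records
  100 * mean(isHit)
}

#' Maximum projection of frames
#'
#' Pixelwise maximum over frames, accumulated in a single pass (constant
#' memory in the number of frames). The projection piles every observed
#' Bragg spot into one image, making the effective resolution extent of a
#' serial data set visible. Masked pixels are ignored unless masked in every
#' frame.
#'
#' @param frames non-empty list of [ImageFrame-class].
#' @return An [ImageFrame-class] holding the projection (frameId -1).
#' @export
maxProjection <- function(frames) {
  stopIfNot(length(frames) >= 1, "need at least one frame")
  acc <- NULL; accMask <- NULL
  for (f in frames) {
    px <- pixels(f)
    m <- effectiveMask(f)
    px[m] <- -Inf
    if (is.null(acc)) {
      acc <- px; accMask <- m
    } else {
      acc <- pmax(acc, px)
      accMask <- accMask & m
    }
  }
  acc[accMask] <- MASK_SENTINEL
  imageFrame(acc, frameId = -1L, mask = accMask)
}

#' Azimuthal integration of an image
#'
#' Mean unmasked intensity in equal-width radial bins about the beam centre,
#' with bin radii mapped to d-spacings through the flat-detector geometry
#' (`d = lambda / (2 sin(0.5 atan(r px / L)))`).
#'
#' @param image an [ImageFrame-class] or plain matrix.
#' @param geom a [DetectorGeometry-class].
#' @param nBins number of radial bins.
#' @return data.frame (radius, d, meanI, nPix): a radial profile.
#' @export
azimuthalIntegrate <- function(image, geom, nBins = 100) {
  if (is(image, "ImageFrame")) {
    radialMean(pixels(image), geom, nBins, mask = effectiveMask(image))
  } else {
    radialMean(image, geom, nBins)
  }
}

#' Effective resolution limit from radial profiles
#'
#' Walks the shells from low to high resolution and returns the d-spacing of
#' the finest bin up to which every bin satisfies
#' `(signal - background) / noise >= snrMin`, with Poisson noise
#' `sqrt(background)` per pixel reduced by the bin population. The
#' contiguity requirement (all coarser bins must pass) prevents an isolated
#' noise spike at high resolution from inflating the estimate. Returns `Inf`
#' when no bin qualifies (no resolvable signal).
#'
#' @param profile radial profile of the signal (e.g. of a maximum
#'   projection), as returned by [azimuthalIntegrate()].
#' @param bgProfile radial profile of the background on the same bins.
#' @param snrMin minimum signal-to-noise ratio per bin.
#' @return The limiting d-spacing in Angstrom (`Inf` if none qualifies).
#' @export
estimateResolutionLimit <- function(profile, bgProfile, snrMin = 1) {
  stopIfNot(nrow(profile) == nrow(bgProfile) &&
              isTRUE(all.equal(profile$radius, bgProfile$radius)),
            "profiles must share one bin grid")
  sig <- profile$meanI - bgProfile$meanI
  noise <- sqrt(pmax(bgProfile$meanI, 1)) / sqrt(pmax(profile$nPix, 1))
  snr <- sig / noise
  ok <- !is.na(snr) & snr >= snrMin & profile$nPix > 0
  if (!ok[1]) return(Inf)
  lastPass <- which(!ok)[1]
  lastPass <- if (is.na(lastPass)) length(ok) else lastPass - 1L
  profile$d[lastPass]
}
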