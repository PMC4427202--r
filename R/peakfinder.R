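## Local-maximum Bragg-peak search and concentric-ring integration.
##
## Peaks are seeded at strict local maxima of a window, vetted by a local
## signal-to-noise test against an annulus of background pixels, refined to
## sub-pixel centroids, and integrated with the three concentric rings
## (peak disc, excluded buffer, background annulus) scheme. Default radii
## are 5 / 7 / 9 pixels; distances are Euclidean on pixel centres so the
## annulus areas (and hence sigma estimates) are undistorted.

## Strict local maxima of a matrix over a w x w window, ties broken toward
## the smaller (ss, fs), i.e. raster order. Returns a logical matrix.
localMaxima <- function(img, window) {
  nf <- nrow(img); ns <- ncol(img)
  h <- (window - 1L) / 2L
  ok <- matrix(TRUE, nf, ns)
  for (dss in -h:h) for (dfs in -h:h) {
    if (dss == 0 && dfs == 0) next
    shifted <- matrix(-Inf, nf, ns)
    fSrc <- max(1, 1 + dfs):min(nf, nf + dfs)
    sSrc <- max(1, 1 + dss):min(ns, ns + dss)
    shifted[fSrc - dfs, sSrc - dss] <- img[fSrc, sSrc]
    ## ties with a later (in raster order) neighbour are kept; with an
    ## earlier one, dropped -- so exactly one of two equal maxima survives
    after <- dss > 0 || (dss == 0 && dfs > 0)
    cmp <- if (after) img >= shifted else img > shifted
    ok <- ok & cmp
  }
  ok
}

#' Find Bragg peaks by local-maximum search
#'
#' A pixel seeds a candidate when it is the maximum of its `window` x
#' `window` neighbourhood (equal-valued maxima are resolved toward the
#' smaller (ss, fs)) and its signal-to-noise ratio against the local
#' background annulus (`rBuffer < r <= rBg`) is at least `snrMin`. The local
#' background is the annulus median; the noise is its MAD scaled by 1.4826
#' (robust to neighbouring peaks). Candidates closer than `window` pixels
#' are deduplicated keeping the stronger; centroids are refined over the
#' `r <= rPeak` disc; each survivor is ring-integrated and kept only when
#' its background-subtracted intensity is positive. At most `maxPeaks`
#' peaks are returned, strongest first.
#'
#' @param image an [ImageFrame-class] (corrected frame) or plain matrix.
#' @param geom optional [DetectorGeometry-class]; when given, peak
#'   d-spacings are filled in.
#' @param window odd window size >= 3 (also the minimum peak separation).
#' @param snrMin minimum local signal-to-noise ratio.
#' @param maxPeaks maximum number of peaks to return.
#' @param rPeak,rBuffer,rBg concentric-ring radii (pixels) passed to
#'   [integrateRings()].
#' @return A [PeakList-class].
#' @export
findPeaks <- function(image, geom = NULL, window = 5L, snrMin = 6,
                      maxPeaks = 500L, rPeak = 5, rBuffer = 7, rBg = 9) {
  stopIfNot(window >= 3 && window %% 2 == 1, "window must be odd and >= 3")
  fid <- 0L
  msk <- NULL
  if (is(image, "ImageFrame")) {
    fid <- frameId(image)
    msk <- effectiveMask(image)
    image <- pixels(image)
    image[msk] <- -Inf
  }
  lm <- localMaxima(image, window)
  if (!is.null(msk)) lm <- lm & !msk
  cand <- which(lm, arr.ind = TRUE)
  if (nrow(cand) == 0) return(peakList(fid))
  ## cheap global pre-filter: a candidate that cannot reach even half the
  ## requested SNR against the global noise floor is discarded before the
  ## (much more expensive) local annulus test
  fin <- image[is.finite(image)]
  gMed <- stats::median(fin)
  gNoise <- 1.4826 * stats::median(abs(fin - gMed))
  if (gNoise > 0) {
    cand <- cand[image[cand] - gMed >= 0.5 * snrMin * gNoise, , drop = FALSE]
    if (nrow(cand) == 0) return(peakList(fid))
  }
  ## order candidates by decreasing height for greedy dedup
  hts <- image[cand]
  ord <- order(-hts, cand[, 2], cand[, 1])
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  if (nrow(cand) > 1) {
    for (i in 2:nrow(cand)) {
      if (!keep[i]) next
      prev <- which(keep[seq_len(i - 1)])
      dist2 <- (cand[prev, 1] - cand[i, 1])^2 + (cand[prev, 2] - cand[i, 2])^2
      if (any(dist2 < window^2)) keep[i] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  nf <- nrow(image); ns <- ncol(image)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    fs0 <- cand[i, 1] - 1L; ss0 <- cand[i, 2] - 1L   # 0-based
    ## the seed must dominate its whole integration disc, not only the
    ## search window; otherwise it is a shoulder of a stronger spot and
    ## its disc would integrate that spot's core
    fr <- max(0, fs0 - rPeak):min(nf - 1, fs0 + rPeak)
    sr <- max(0, ss0 - rPeak):min(ns - 1, ss0 + rPeak)
    disc <- image[fr + 1, sr + 1, drop = FALSE]
    dr2 <- outer((fr - fs0)^2, (sr - ss0)^2, `+`)
    if (image[fs0 + 1, ss0 + 1] < max(disc[dr2 <= rPeak^2])) return(NULL)
    meas <- integrateRings(image, c(fs0, ss0), rPeak, rBuffer, rBg,
                           mask = msk)
    if (!meas$valid || is.na(meas$snr) || meas$snr < snrMin ||
          meas$intensity <= 0) return(NULL)
    ctr <- centroidRefine(image, fs0, ss0, rPeak, msk)
    data.frame(fs = ctr[1], ss = ctr[2], intensity = meas$intensity,
               snr = meas$snr, d = NA_real_)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(peakList(fid))
  df <- do.call(rbind, rows)
  df <- df[order(-df$intensity), , drop = FALSE]
  if (nrow(df) > maxPeaks) df <- df[seq_len(maxPeaks), , drop = FALSE]
  if (!is.null(geom)) {
    r <- sqrt((df$fs - geom@beamCenter[1])^2 + (df$ss - geom@beamCenter[2])^2)
    df$d <- radiusToD(r, geom)
  }
  peakList(fid, df)
}

## Intensity-weighted centroid over the r <= rPeak disc around a 0-based
## (fs, ss) pixel; weights are background-floored at zero.
centroidRefine <- function(img, fs0, ss0, rPeak, mask = NULL) {
  nf <- nrow(img); ns <- ncol(img)
  fr <- max(0, fs0 - rPeak):min(nf - 1, fs0 + rPeak)
  sr <- max(0, ss0 - rPeak):min(ns - 1, ss0 + rPeak)
  g <- expand.grid(fs = fr, ss = sr)
  r2 <- (g$fs - fs0)^2 + (g$ss - ss0)^2
  g <- g[r2 <= rPeak^2, ]
  w <- img[cbind(g$fs + 1, g$ss + 1)]
  if (!is.null(mask)) w[mask[cbind(g$fs + 1, g$ss + 1)]] <- 0
  w <- pmax(w, 0)
  if (sum(w) <= 0) return(c(fs0, ss0))
  c(sum(g$fs * w), sum(g$ss * w)) / sum(w)
}

#' Concentric-ring integration of one spot
#'
#' Integrates a spot with three concentric regions about `center`: the peak
#' disc (`r <= rPeak`), an excluded buffer (`rPeak < r <= rBuffer`) and the
#' background annulus (`rBuffer < r <= rBg`). The background level is the
#' annulus mean; the intensity is the background-subtracted sum over the
#' peak disc; sigma propagates the annulus spread over the peak-disc pixel
#' count (including the uncertainty of the background mean itself). The
#' measurement is flagged invalid when fewer than half of the background
#' annulus is usable (on-image and unmasked).
#'
#' @param image numeric matrix or [ImageFrame-class].
#' @param center length-2 numeric, 0-based (fs, ss) spot centre (may be
#'   sub-pixel).
#' @param rPeak,rBuffer,rBg ring radii in pixels, `rPeak < rBuffer < rBg`.
#' @param mask optional logical matrix, TRUE = invalid pixel.
#' @return list: `intensity`, `sigma`, `bgMean`, `nPeakPix`, `valid`, `snr`.
#' @export
integrateRings <- function(image, center, rPeak = 5, rBuffer = 7, rBg = 9,
                           mask = NULL) {
  stopIfNot(rPeak < rBuffer && rBuffer < rBg,
            "ring radii must satisfy rPeak < rBuffer < rBg")
  if (is(image, "ImageFrame")) {
    if (is.null(mask)) mask <- effectiveMask(image)
    image <- pixels(image)
  }
  nf <- nrow(image); ns <- ncol(image)
  fs0 <- center[1]; ss0 <- center[2]
  rb <- ceiling(rBg)
  fr <- max(0, floor(fs0) - rb):min(nf - 1, ceiling(fs0) + rb)
  sr <- max(0, floor(ss0) - rb):min(ns - 1, ceiling(ss0) + rb)
  g <- expand.grid(fs = fr, ss = sr)
  r <- sqrt((g$fs - fs0)^2 + (g$ss - ss0)^2)
  v <- image[cbind(g$fs + 1, g$ss + 1)]
  ok <- is.finite(v)
  if (!is.null(mask)) ok <- ok & !mask[cbind(g$fs + 1, g$ss + 1)]
  peakSel <- ok & r <= rPeak
  bgSel <- ok & r > rBuffer & r <= rBg
  ## nominal annulus population if fully on-image: count by untruncated grid
  full <- expand.grid(fs = (floor(fs0) - rb):(ceiling(fs0) + rb),
                      ss = (floor(ss0) - rb):(ceiling(ss0) + rb))
  rFull <- sqrt((full$fs - fs0)^2 + (full$ss - ss0)^2)
  nBgNominal <- sum(rFull > rBuffer & rFull <= rBg)
  nBg <- sum(bgSel)
  if (nBg < 0.5 * nBgNominal || nBg < 2 || sum(peakSel) == 0)
    return(list(intensity = NA_real_, sigma = NA_real_, bgMean = NA_real_,
                nPeakPix = sum(peakSel), valid = FALSE, snr = NA_real_))
  bgPix <- v[bgSel]
  bgMean <- mean(bgPix)
  nPeak <- sum(peakSel)
  intensity <- sum(v[peakSel]) - nPeak * bgMean
  bgMed <- stats::median(bgPix)
  noise <- 1.4826 * stats::median(abs(bgPix - bgMed))
  sdBg <- stats::sd(bgPix)
  sigma <- sdBg * sqrt(nPeak + nPeak^2 / nBg)
  peakHeight <- max(v[peakSel])
  snr <- if (noise > 0) (peakHeight - bgMed) / noise
  else if (peakHeight > bgMed) Inf else 0
  list(intensity = intensity, sigma = sigma, bgMean = bgMean,
       nPeakPix = nPeak, valid = TRUE, snr = snr)
}
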