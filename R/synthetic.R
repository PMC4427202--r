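## Synthetic raster-scan diffraction simulator.
##
## Generates still-shot frame sets with complete ground truth so the whole
## pre-analysis chain (hit finding, background subtraction, peak finding,
## merging) can be validated without external data. The model: an isotropic
## solvent background (flat level plus a Gaussian water ring), sparse
## crystal hits with a uniformly random orientation each, Bragg spots at
## the detector projections of reciprocal-lattice points lying close enough
## to the Ewald sphere (triangular partiality in the sphere offset), and
## Poisson counting noise on every pixel.

#' Construct simulation parameters
#'
#' Defaults emulate a micro-focused raster scan of tetragonal lysozyme-like
#' microcrystals on a desk-scale detector: the published tetragonal cell
#' (a = b = 78.0, c = 38.3 Angstrom), a 1.5 x 2.5 um beam at 0.954 Angstrom
#' with a 9.9% hit fraction, and a 256 x 256 pixel panel covering the same
#' solid angle as a 2x-binned 1024-pixel CCD (0.4 mm pixels at 80 mm).
#'
#' @param cell a [UnitCell-class].
#' @param geom a [DetectorGeometry-class].
#' @param beam a [BeamParams-class].
#' @param hitFraction probability a shot hits a crystal.
#' @param backgroundLevel flat background (ADU/pixel).
#' @param waterRingD solvent-ring position (Angstrom).
#' @param waterRingAmp ring amplitude (ADU).
#' @param waterRingWidth ring Gaussian sigma (pixels).
#' @param spotSigma Bragg-spot Gaussian sigma (pixels).
#' @param intensityScale global scale of true intensities (ADU).
#' @param mosaicityTol Ewald-offset tolerance (1/Angstrom).
#' @param dMin high-resolution limit of simulated reflections (Angstrom).
#' @param seed integer RNG seed.
#' @return A [SimulationParams-class].
#' @export
simulationParams <- function(
    cell = unitCell(78.0, c = 38.3),
    geom = detectorGeometry(256, 256, pixelSize = 0.4, distance = 80,
                            wavelength = 0.954),
    beam = beamParams(0.954, beamW = 2.5, beamH = 1.5, fluence = 1e11,
                      divergence = 1.0, exposure = 0.2, dosePerFrame = 3.2),
    hitFraction = 0.099, backgroundLevel = 40, waterRingD = 3.7,
    waterRingAmp = 25, waterRingWidth = 6, spotSigma = 1.2,
    intensityScale = 4000, mosaicityTol = 5e-4, dMin = 1.85,
    seed = 1L) {
  new("SimulationParams", cell = cell, geom = geom, beam = beam,
      hitFraction = hitFraction, backgroundLevel = backgroundLevel,
      waterRingD = waterRingD, waterRingAmp = waterRingAmp,
      waterRingWidth = waterRingWidth, spotSigma = spotSigma,
      intensityScale = intensityScale, mosaicityTol = mosaicityTol,
      dMin = dMin, seed = as.integer(seed))
}

## Deterministic per-frame substream seed (kept below 2^31).
frameSeed <- function(seed, frameId, salt = 0) {
  as.integer((as.numeric(seed) + 7919 * (frameId + 1) + salt) %% 2147483647)
}

## Noise-free background expectation image.
backgroundMeanImage <- function(params) {
  g <- params@geom
  r <- radiusField(g)
  out <- matrix(params@backgroundLevel, nrow(r), ncol(r))
  if (params@waterRingAmp > 0) {
    rRing <- dToRadius(params@waterRingD, g)
    out <- out + params@waterRingAmp *
      exp(-(r - rRing)^2 / (2 * params@waterRingWidth^2))
  }
  out
}

#' Simulate a solvent-only (non-hit) frame
#'
#' Radially symmetric expectation (flat level plus Gaussian water ring at
#' the radius of `waterRingD`), Poisson-sampled. Reproducible: the same
#' seed/frameId pair always yields the same frame.
#'
#' @param params a [SimulationParams-class].
#' @param frameId integer frame id (selects the per-frame noise substream).
#' @param meanImage optional precomputed expectation image (a cache, for
#'   speed when simulating many frames).
#' @return An [ImageFrame-class].
#' @export
simulateBackground <- function(params, frameId = 0L, meanImage = NULL) {
  if (is.null(meanImage)) meanImage <- backgroundMeanImage(params)
  set.seed(frameSeed(params@seed, frameId))
  counts <- matrix(stats::rpois(length(meanImage), as.vector(meanImage)),
                   nrow(meanImage), ncol(meanImage))
  imageFrame(counts * 1.0, frameId = frameId,
             exposure = params@beam@exposure)
}

## Full reciprocal lattice (all symmetry equivalents) to dMin, with each
## point's true merged intensity looked up on its asymmetric-unit indices.
## Cached per call site; recomputing is the only cost of not caching.
reciprocalLattice <- function(params) {
  cell <- params@cell
  hmax <- floor(cell@a / params@dMin)
  lmax <- floor(cell@c / params@dMin)
  g <- expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -lmax:lmax)
  g <- g[g$h | g$k | g$l, ]
  d <- dSpacing(as.matrix(g), cell)
  g <- g[d >= params@dMin, ]
  tab <- trueIntensityTable(params)
  asu <- reduceToASU(as.matrix(g[, c("h", "k", "l")]))
  keyG <- paste(asu[, 1], asu[, 2], asu[, 3])
  keyT <- paste(tab$h, tab$k, tab$l)
  iTrue <- stats::setNames(tab$iTrue, keyT)[keyG]
  cbind(as.matrix(g), qx = g$h / cell@a, qy = g$k / cell@a,
        qz = g$l / cell@c, iTrue = unname(iTrue))
}

#' True-intensity table of a simulation
#'
#' Wilson-like (exponential) true intensities per asymmetric-unit
#' reflection, drawn once per seed: the same parameters always imply the
#' same table. Doubling `intensityScale` doubles every entry exactly.
#'
#' @param params a [SimulationParams-class].
#' @return data.frame (h, k, l, d, iTrue).
#' @export
trueIntensityTable <- function(params) {
  asu <- enumerateUnique(params@cell, 100, params@dMin)
  set.seed(frameSeed(params@seed, -1L, salt = 104729))
  asu$iTrue <- stats::rexp(nrow(asu)) * params@intensityScale
  asu
}

## Quaternion (w, x, y, z) to rotation matrix.
quatToMatrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

## Uniform random unit quaternions (rows), n x 4.
randomQuaternions <- function(n) {
  m <- matrix(stats::rnorm(4 * n), n, 4)
  m / sqrt(rowSums(m^2))
}

#' Predict detector spots for one crystal orientation
#'
#' Rotates the reciprocal lattice, selects points whose Ewald-sphere offset
#' `| |k_in + q| - 1/lambda |` is within `mosaicityTol`, assigns each a
#' triangular partiality `1 - |offset|/tol`, and projects the diffracted
#' rays onto the detector. Pure geometry, no noise: the truth against which
#' peak finding and merging are validated.
#'
#' @param params a [SimulationParams-class].
#' @param orientation length-4 unit quaternion (w, x, y, z).
#' @param lattice optional precomputed [reciprocalLattice()] result (cache).
#' @return data.frame (h, k, l, fs, ss, partiality, iTrue) of spots landing
#'   on the panel; `iTrue` is already partiality-scaled.
#' @export
predictSpots <- function(params, orientation, lattice = NULL) {
  if (is.null(lattice)) lattice <- reciprocalLattice(params)
  g <- params@geom
  R <- quatToMatrix(orientation / sqrt(sum(orientation^2)))
  q <- lattice[, c("qx", "qy", "qz")] %*% t(R)
  kinv <- 1 / g@wavelength
  kout <- cbind(q[, 1], q[, 2], q[, 3] + kinv)
  koutLen <- sqrt(rowSums(kout^2))
  offset <- koutLen - kinv
  sel <- abs(offset) <= params@mosaicityTol & kout[, 3] > 0
  if (!any(sel))
    return(data.frame(h = integer(), k = integer(), l = integer(),
                      fs = numeric(), ss = numeric(), partiality = numeric(),
                      iTrue = numeric()))
  kout <- kout[sel, , drop = FALSE]
  xmm <- g@distance * kout[, 1] / kout[, 3]
  ymm <- g@distance * kout[, 2] / kout[, 3]
  fs <- g@beamCenter[1] + xmm / g@pixelSize
  ss <- g@beamCenter[2] + ymm / g@pixelSize
  part <- 1 - abs(offset[sel]) / params@mosaicityTol
  on <- fs >= 0 & fs <= g@nFast - 1 & ss >= 0 & ss <= g@nSlow - 1
  data.frame(h = lattice[sel, "h"][on], k = lattice[sel, "k"][on],
             l = lattice[sel, "l"][on], fs = fs[on], ss = ss[on],
             partiality = part[on],
             iTrue = (lattice[sel, "iTrue"] * part)[on])
}

## Add a 2D Gaussian of given integral onto an image (in place semantics
## via return value); patch limited to +/- 4 sigma.
addGaussianSpot <- function(img, fs, ss, sigma, integral) {
  nf <- nrow(img); ns <- ncol(img)
  h <- ceiling(4 * sigma)
  fr <- max(0, round(fs) - h):min(nf - 1, round(fs) + h)
  sr <- max(0, round(ss) - h):min(ns - 1, round(ss) + h)
  if (!length(fr) || !length(sr)) return(img)
  gf <- exp(-(fr - fs)^2 / (2 * sigma^2))
  gs <- exp(-(sr - ss)^2 / (2 * sigma^2))
  patch <- integral / (2 * pi * sigma^2) * outer(gf, gs)
  img[fr + 1, sr + 1] <- img[fr + 1, sr + 1] + patch
  img
}

#' Simulate one crystal-hit frame
#'
#' Renders the spots predicted by [predictSpots()] as 2D Gaussians of
#' integral `iTrue` on top of the solvent background expectation, then
#' Poisson-samples the whole frame.
#'
#' @param params a [SimulationParams-class].
#' @param orientation length-4 unit quaternion.
#' @param frameId integer frame id.
#' @param meanImage optional precomputed background expectation.
#' @param lattice optional precomputed [reciprocalLattice()] cache.
#' @return list: `frame` (an [ImageFrame-class]) and `truth` (the spot
#'   data.frame from [predictSpots()]).
#' @export
simulateHitFrame <- function(params, orientation, frameId = 0L,
                             meanImage = NULL, lattice = NULL) {
  if (is.null(meanImage)) meanImage <- backgroundMeanImage(params)
  spots <- predictSpots(params, orientation, lattice)
  mu <- meanImage
  for (i in seq_len(nrow(spots)))
    mu <- addGaussianSpot(mu, spots$fs[i], spots$ss[i], params@spotSigma,
                          spots$iTrue[i])
  set.seed(frameSeed(params@seed, frameId))
  counts <- matrix(stats::rpois(length(mu), as.vector(mu)), nrow(mu),
                   ncol(mu))
  list(frame = imageFrame(counts * 1.0, frameId = frameId,
                          exposure = params@beam@exposure),
       truth = spots)
}

#' Simulate a full raster scan
#'
#' Each shot of the plan is independently a hit with probability
#' `hitFraction`; hits receive a uniformly random orientation (normalised
#' four-dimensional Gaussian quaternion). Frames are produced in scan order
#' with frame ids 0, 1, .... Hit labels and orientations are drawn from the
#' run's main stream (keyed by `seed`); pixel noise uses per-frame
#' substreams, so the output is reproducible frame by frame.
#'
#' @param plan a [ScanPlan-class].
#' @param params a [SimulationParams-class].
#' @return list: `frames` (list of [ImageFrame-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @export
simulateScan <- function(plan, params) {
  pos <- scanPositions(plan)
  n <- nrow(pos)
  set.seed(frameSeed(params@seed, -2L, salt = 15485863))
  hits <- stats::runif(n) < params@hitFraction
  quats <- randomQuaternions(n)
  meanImage <- backgroundMeanImage(params)
  lattice <- if (any(hits)) reciprocalLattice(params) else NULL
  frames <- vector("list", n)
  truthRows <- vector("list", n)
  for (i in seq_len(n)) {
    fid <- i - 1L
    if (hits[i]) {
      sim <- simulateHitFrame(params, quats[i, ], fid, meanImage, lattice)
      f <- sim$frame
      if (nrow(sim$truth))
        truthRows[[i]] <- cbind(frameId = fid,
                                sim$truth[, c("fs", "ss", "h", "k", "l",
                                              "iTrue")])
    } else {
      f <- simulateBackground(params, fid, meanImage)
    }
    f@scanPos <- c(pos$iFast[i], pos$iSlow[i])
    frames[[i]] <- f
  }
  truthPeaks <- do.call(rbind, truthRows[!vapply(truthRows, is.null,
                                                 logical(1))])
  if (is.null(truthPeaks))
    truthPeaks <- data.frame(frameId = integer(), fs = numeric(),
                             ss = numeric(), h = integer(), k = integer(),
                             l = integer(), iTrue = numeric())
  truth <- new("GroundTruth", hits = hits, orientations = quats,
               peaks = truthPeaks,
               intensities = trueIntensityTable(params)[, c("h", "k", "l",
                                                            "iTrue")])
  list(frames = frames, truth = truth)
}
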