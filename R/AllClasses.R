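#' @import methods
NULL

## Coordinate convention used throughout the package:
## detector pixels are addressed by 0-based (fs, ss) indices, fs being the
## fastest-varying axis. A frame is stored as a numeric matrix with
## rows = fs and cols = ss, so pixel (fs, ss) lives at pixels[fs + 1, ss + 1].
## Pixel centres sit at integer coordinates.

#' Beam parameters
#'
#' Photon-beam description for a serial crystallography experiment: the
#' wavelength, the focal-spot size (FWHM), the fluence delivered into the
#' spot, beam divergence and bandwidth, the per-frame exposure time and the
#' absorbed dose a crystal receives in one frame.
#'
#' @slot wavelength numeric, X-ray wavelength in Angstrom.
#' @slot beamW,beamH numeric, horizontal/vertical beam size (FWHM) in micrometre.
#' @slot fluence numeric, photons per second delivered into the focal spot.
#' @slot divergence numeric, beam divergence in mrad (may be 0).
#' @slot bandwidth numeric, relative bandwidth dE/E (may be 0).
#' @slot exposure numeric, exposure time per frame in seconds.
#' @slot dosePerFrame numeric, absorbed dose per frame in MGy (may be 0).
#'
#' @seealso [beamParams()] for the user-facing constructor,
#'   [computeFluxDensity()], [computeDoseRate()].
#' @exportClass BeamParams
setClass("BeamParams",
  representation(
    wavelength = "numeric", beamW = "numeric", beamH = "numeric",
    fluence = "numeric", divergence = "numeric", bandwidth = "numeric",
    exposure = "numeric", dosePerFrame = "numeric"
  )
)

setValidity("BeamParams", function(object) {
  msgs <- character()
  for (nm in c("wavelength", "beamW", "beamH", "fluence", "exposure")) {
    v <- slot(object, nm)
    if (length(v) != 1 || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("'%s' must be a single positive finite number", nm))
  }
  for (nm in c("divergence", "bandwidth", "dosePerFrame")) {
    v <- slot(object, nm)
    if (length(v) != 1 || !is.finite(v) || v < 0)
      msgs <- c(msgs, sprintf("'%s' must be a single non-negative finite number", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct beam parameters
#'
#' @param wavelength X-ray wavelength (Angstrom).
#' @param beamW,beamH beam size FWHM, horizontal and vertical (micrometre).
#' @param fluence photon flux through the focal spot (photons/s).
#' @param divergence beam divergence (mrad).
#' @param bandwidth relative bandwidth dE/E.
#' @param exposure exposure time per frame (s).
#' @param dosePerFrame absorbed dose per frame (MGy).
#' @return A [BeamParams-class] object.
#' @examples
#' microBeam <- beamParams(0.954, beamW = 2.5, beamH = 1.5, fluence = 1e11,
#'                         divergence = 1.0, exposure = 0.2, dosePerFrame = 3.2)
#' computeFluxDensity(microBeam)
#' @export
beamParams <- function(wavelength, beamW, beamH, fluence,
                       divergence = 0, bandwidth = 1e-4,
                       exposure = 0.1, dosePerFrame = 0) {
  new("BeamParams",
      wavelength = as.numeric(wavelength),
      beamW = as.numeric(beamW), beamH = as.numeric(beamH),
      fluence = as.numeric(fluence), divergence = as.numeric(divergence),
      bandwidth = as.numeric(bandwidth), exposure = as.numeric(exposure),
      dosePerFrame = as.numeric(dosePerFrame))
}

setMethod("show", "BeamParams", function(object) {
  cat(sprintf("BeamParams: lambda %.4g A, %g x %g um FWHM, %.3g ph/s\n",
              object@wavelength, object@beamW, object@beamH, object@fluence))
  cat(sprintf("  exposure %g s, dose/frame %g MGy, divergence %g mrad, dE/E %g\n",
              object@exposure, object@dosePerFrame, object@divergence,
              object@bandwidth))
})

#' Detector geometry
#'
#' Single-panel area-detector description: pixel grid extent, pixel size,
#' sample-to-detector distance, direct-beam position on the panel and the
#' wavelength used to map radii to d-spacings.
#'
#' @slot nFast,nSlow integer, panel extent in pixels along the fast/slow axes.
#' @slot pixelSize numeric, pixel edge in mm.
#' @slot distance numeric, sample-to-detector distance in mm.
#' @slot beamCenter numeric length-2, direct-beam (fs, ss) position in 0-based
#'   pixel coordinates.
#' @slot wavelength numeric, wavelength in Angstrom.
#'
#' @seealso [detectorGeometry()], [writeGeometryFile()], [azimuthalIntegrate()]
#' @exportClass DetectorGeometry
setClass("DetectorGeometry",
  representation(
    nFast = "integer", nSlow = "integer", pixelSize = "numeric",
    distance = "numeric", beamCenter = "numeric", wavelength = "numeric"
  )
)

setValidity("DetectorGeometry", function(object) {
  msgs <- character()
  if (object@nFast < 1L || object@nSlow < 1L)
    msgs <- c(msgs, "panel extents must be >= 1 pixel")
  if (object@pixelSize <= 0 || object@distance <= 0 || object@wavelength <= 0)
    msgs <- c(msgs, "pixelSize, distance and wavelength must be positive")
  if (length(object@beamCenter) != 2)
    msgs <- c(msgs, "beamCenter must be length 2 (fs, ss)")
  else if (object@beamCenter[1] < 0 || object@beamCenter[1] >= object@nFast ||
           object@beamCenter[2] < 0 || object@beamCenter[2] >= object@nSlow)
    msgs <- c(msgs, "beamCenter must lie within the panel")
  if (length(msgs)) msgs else TRUE
})

#' Construct a detector geometry
#'
#' @param nFast,nSlow panel extent in pixels (fast/slow axes).
#' @param pixelSize pixel edge (mm).
#' @param distance sample-to-detector distance (mm).
#' @param beamCenter direct-beam (fs, ss) position, 0-based pixels; defaults
#'   to the panel centre.
#' @param wavelength wavelength (Angstrom).
#' @return A [DetectorGeometry-class] object.
#' @export
detectorGeometry <- function(nFast, nSlow, pixelSize, distance,
                             beamCenter = c((nFast - 1) / 2, (nSlow - 1) / 2),
                             wavelength = 1.0) {
  new("DetectorGeometry",
      nFast = as.integer(nFast), nSlow = as.integer(nSlow),
      pixelSize = as.numeric(pixelSize), distance = as.numeric(distance),
      beamCenter = as.numeric(beamCenter), wavelength = as.numeric(wavelength))
}

setMethod("show", "DetectorGeometry", function(object) {
  cat(sprintf("DetectorGeometry: %d x %d px, %g mm/px, distance %g mm\n",
              object@nFast, object@nSlow, object@pixelSize, object@distance))
  cat(sprintf("  beam centre (fs, ss) = (%g, %g), lambda %.4g A\n",
              object@beamCenter[1], object@beamCenter[2], object@wavelength))
})

#' One detector exposure
#'
#' A single detector frame with its raster-scan grid position. Pixels are a
#' numeric matrix with rows along the fast axis and columns along the slow
#' axis; masked/padded pixels hold the sentinel value -1 and are flagged in
#' the logical `mask` matrix (TRUE = invalid).
#'
#' @slot pixels numeric matrix of counts (ADU), rows = fs, cols = ss.
#' @slot mask logical matrix, TRUE where a pixel is invalid; may be 0x0
#'   meaning "nothing masked".
#' @slot frameId integer frame identifier.
#' @slot scanPos integer length-2 (iFast, iSlow) grid indices, 0-based.
#' @slot exposure numeric, exposure time (s).
#'
#' @seealso [imageFrame()], [pixels()], [frameMask()]
#' @exportClass ImageFrame
setClass("ImageFrame",
  representation(
    pixels = "matrix", mask = "matrix", frameId = "integer",
    scanPos = "integer", exposure = "numeric"
  )
)

setValidity("ImageFrame", function(object) {
  msgs <- character()
  if (!is.numeric(object@pixels))
    msgs <- c(msgs, "pixels must be numeric")
  if (any(!is.finite(object@pixels)))
    msgs <- c(msgs, "pixel counts must be finite")
  if (length(object@mask) &&
      !identical(dim(object@mask), dim(object@pixels)))
    msgs <- c(msgs, "mask must match the pixel grid")
  if (length(msgs)) msgs else TRUE
})

#' Construct an image frame
#'
#' @param pixels numeric matrix (rows = fast axis, cols = slow axis).
#' @param frameId integer identifier.
#' @param scanPos length-2 integer (iFast, iSlow) raster-grid position.
#' @param exposure exposure time (s).
#' @param mask optional logical matrix, TRUE = invalid pixel.
#' @return An [ImageFrame-class] object.
#' @export
imageFrame <- function(pixels, frameId = 0L, scanPos = c(0L, 0L),
                       exposure = 0.1, mask = NULL) {
  if (is.null(mask)) mask <- matrix(logical(0), 0, 0)
  new("ImageFrame", pixels = pixels, mask = mask,
      frameId = as.integer(frameId), scanPos = as.integer(scanPos),
      exposure = as.numeric(exposure))
}

setMethod("show", "ImageFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageFrame #%d: %d x %d px, scan pos (%d, %d), max %g ADU\n",
              object@frameId, d[1], d[2], object@scanPos[1], object@scanPos[2],
              max(object@pixels)))
})

#' Raster-scan plan
#'
#' An ordered grid of shot positions for a fixed-target raster scan, with a
#' validity flag recording whether the shot spacing clears the beam footprint
#' plus the photoelectron track length (so no position is damaged by a
#' neighbouring shot before being measured).
#'
#' @slot nFast,nSlow integer, shots along the fast (horizontal, inner loop)
#'   and slow (vertical, outer loop) axes.
#' @slot stepFast,stepSlow numeric, shot spacing in micrometre.
#' @slot origin numeric length-2, (x, y) of the first shot in micrometre.
#' @slot positions data.frame with columns shot, iFast, iSlow, x, y; fast axis
#'   varies quickest.
#' @slot spacingValid logical, TRUE when both steps exceed the per-axis beam
#'   dimension plus the track length (strict inequality).
#'
#' @seealso [planRasterScan()]
#' @exportClass ScanPlan
setClass("ScanPlan",
  representation(
    nFast = "integer", nSlow = "integer",
    stepFast = "numeric", stepSlow = "numeric", origin = "numeric",
    positions = "data.frame", spacingValid = "logical"
  )
)

setValidity("ScanPlan", function(object) {
  msgs <- character()
  if (nrow(object@positions) != object@nFast * object@nSlow)
    msgs <- c(msgs, "positions must hold exactly nFast * nSlow shots")
  if (anyDuplicated(object@positions[, c("x", "y")]))
    msgs <- c(msgs, "shot positions must be distinct")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ScanPlan", function(object) {
  cat(sprintf("ScanPlan: %d x %d shots, step (%g, %g) um, origin (%g, %g)\n",
              object@nFast, object@nSlow, object@stepFast, object@stepSlow,
              object@origin[1], object@origin[2]))
  cat(sprintf("  spacing %s\n",
              if (object@spacingValid) "valid" else
                "INVALID (step within beam + photoelectron track)"))
})

#' Detector metrology maps
#'
#' Per-pixel correction maps for a CCD-type detector: a flat-field gain
#' multiplier, a geometric-distortion displacement field and a bad-pixel
#' mask. The displacement field uses pull semantics: corrected pixel (fs, ss)
#' is sampled (bilinearly) from the raw image at (fs + dispFS, ss + dispSS).
#'
#' @slot flatfield numeric matrix of gain multipliers (> 0 where unmasked).
#' @slot dispFS,dispSS numeric matrices, displacement in pixels.
#' @slot mask logical matrix, TRUE = bad pixel.
#'
#' @seealso [metrologyMaps()], [applyMetrology()]
#' @exportClass MetrologyMaps
setClass("MetrologyMaps",
  representation(flatfield = "matrix", dispFS = "matrix",
                 dispSS = "matrix", mask = "matrix")
)

setValidity("MetrologyMaps", function(object) {
  msgs <- character()
  dm <- dim(object@flatfield)
  if (!identical(dim(object@dispFS), dm) || !identical(dim(object@dispSS), dm) ||
      !identical(dim(object@mask), dm))
    msgs <- c(msgs, "all maps must share one shape")
  if (any(!is.finite(object@dispFS)) || any(!is.finite(object@dispSS)))
    msgs <- c(msgs, "displacements must be finite")
  ok <- !object@mask
  if (any(object@flatfield[ok] <= 0))
    msgs <- c(msgs, "flatfield must be positive where unmasked")
  if (length(msgs)) msgs else TRUE
})

#' Construct metrology maps
#'
#' @param nFast,nSlow map extent in pixels.
#' @param flatfield gain map (defaults to 1 everywhere).
#' @param dispFS,dispSS displacement maps in pixels (default 0).
#' @param mask logical bad-pixel map (default none).
#' @return A [MetrologyMaps-class] object.
#' @export
metrologyMaps <- function(nFast, nSlow,
                          flatfield = matrix(1, nFast, nSlow),
                          dispFS = matrix(0, nFast, nSlow),
                          dispSS = matrix(0, nFast, nSlow),
                          mask = matrix(FALSE, nFast, nSlow)) {
  new("MetrologyMaps", flatfield = flatfield, dispFS = dispFS,
      dispSS = dispSS, mask = mask)
}

#' Background model
#'
#' Pixelwise background reference built from non-hit frames of a scan, plus
#' its azimuthally averaged radial profile about the beam centre.
#'
#' @slot reference numeric matrix, the mean/median background image (ADU).
#' @slot profile data.frame (radius, d, meanI, nPix) radial profile.
#' @slot nSourceFrames integer, number of frames averaged.
#' @slot method character, "mean" or "median".
#'
#' @seealso [estimateBackground()], [subtractBackgroundScaled()]
#' @exportClass BackgroundModel
setClass("BackgroundModel",
  representation(reference = "matrix", profile = "data.frame",
                 nSourceFrames = "integer", method = "character")
)

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf("BackgroundModel (%s of %d frames), %d x %d px, mean %.3g ADU\n",
              object@method, object@nSourceFrames, nrow(object@reference),
              ncol(object@reference), mean(object@reference)))
})

#' Bragg peak list for one frame
#'
#' Peaks located on a corrected frame, ordered by descending integrated
#' intensity. Coordinates are 0-based sub-pixel (fs, ss) centroids.
#'
#' @slot frameId integer frame identifier.
#' @slot peaks data.frame with columns fs, ss, intensity, snr, d.
#'
#' @seealso [findPeaks()], [integrateRings()]
#' @exportClass PeakList
setClass("PeakList",
  representation(frameId = "integer", peaks = "data.frame"))

setValidity("PeakList", function(object) {
  need <- c("fs", "ss", "intensity", "snr", "d")
  if (!all(need %in% names(object@peaks)))
    return(paste("peaks must have columns", paste(need, collapse = ", ")))
  if (is.unsorted(rev(object@peaks$intensity)))
    return("peaks must be ordered by descending intensity")
  TRUE
})

#' Construct a peak list
#'
#' @param frameId integer frame identifier.
#' @param peaks data.frame with columns fs, ss, intensity, snr, d.
#' @return A [PeakList-class] object.
#' @export
peakList <- function(frameId = 0L,
                     peaks = data.frame(fs = numeric(), ss = numeric(),
                                        intensity = numeric(), snr = numeric(),
                                        d = numeric())) {
  if (nrow(peaks) > 1) peaks <- peaks[order(-peaks$intensity), , drop = FALSE]
  rownames(peaks) <- NULL
  new("PeakList", frameId = as.integer(frameId), peaks = peaks)
}

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList: frame #%d, %d peaks\n",
              object@frameId, nrow(object@peaks)))
  if (nrow(object@peaks))
    print(utils::head(object@peaks, 5))
})

#' Crystallographic unit cell
#'
#' Unit-cell metric plus lattice/space-group bookkeeping. Only the tetragonal
#' case is fully supported (the validity method enforces a = b and 90-degree
#' angles for it); the d-spacing metric and asymmetric-unit reduction assume
#' Laue class 4/mmm.
#'
#' @slot a,b,c numeric cell edges (Angstrom).
#' @slot alpha,beta,gamma numeric cell angles (degrees).
#' @slot lattice character, e.g. "tetragonal".
#' @slot spaceGroup character symbol, default "P43212".
#'
#' @seealso [unitCell()], [dSpacing()], [reduceToASU()], [enumerateUnique()]
#' @exportClass UnitCell
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric",
                 lattice = "character", spaceGroup = "character")
)

setValidity("UnitCell", function(object) {
  msgs <- character()
  if (any(c(object@a, object@b, object@c) <= 0))
    msgs <- c(msgs, "cell edges must be positive")
  if (object@lattice == "tetragonal") {
    if (!isTRUE(all.equal(object@a, object@b)))
      msgs <- c(msgs, "tetragonal cell requires a = b")
    if (!all(c(object@alpha, object@beta, object@gamma) == 90))
      msgs <- c(msgs, "tetragonal cell requires 90-degree angles")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a unit cell
#'
#' @param a,b,c cell edges (Angstrom); `b` defaults to `a`.
#' @param alpha,beta,gamma cell angles (degrees).
#' @param lattice lattice system; only "tetragonal" carries symmetry support.
#' @param spaceGroup space-group symbol.
#' @return A [UnitCell-class] object.
#' @examples
#' hewl <- unitCell(78.0, c = 38.3)   # tetragonal lysozyme cell
#' dSpacing(cbind(2, 1, 3), hewl)
#' @export
unitCell <- function(a, b = a, c, alpha = 90, beta = 90, gamma = 90,
                     lattice = "tetragonal", spaceGroup = "P43212") {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma), lattice = lattice, spaceGroup = spaceGroup)
}

setMethod("show", "UnitCell", function(object) {
  cat(sprintf("UnitCell (%s, %s): a=%g b=%g c=%g A, %g/%g/%g deg\n",
              object@lattice, object@spaceGroup, object@a, object@b, object@c,
              object@alpha, object@beta, object@gamma))
})

#' Simulation parameters
#'
#' Settings for the synthetic raster-scan diffraction simulator. Defaults
#' emulate a micro-focused raster scan of tetragonal lysozyme-like
#' microcrystals: sparse hits on a solvent-ring background with
#' lattice-predicted Bragg spots and Poisson counting noise.
#'
#' @slot cell a [UnitCell-class].
#' @slot geom a [DetectorGeometry-class].
#' @slot beam a [BeamParams-class].
#' @slot hitFraction numeric in [0, 1], probability a shot hits a crystal.
#' @slot backgroundLevel numeric, flat background level (ADU/pixel).
#' @slot waterRingD numeric, d-spacing of the solvent ring maximum (Angstrom).
#' @slot waterRingAmp numeric, ring amplitude above the flat level (ADU).
#' @slot waterRingWidth numeric, Gaussian sigma of the ring (pixels).
#' @slot spotSigma numeric, Gaussian sigma of rendered Bragg spots (pixels).
#' @slot intensityScale numeric, global scale of true spot integrals (ADU).
#' @slot mosaicityTol numeric, Ewald-sphere offset tolerance (1/Angstrom)
#'   inside which a reflection is considered excited.
#' @slot dMin numeric, high-resolution limit of simulated reflections
#'   (Angstrom).
#' @slot seed integer, RNG seed; same seed means identical output.
#'
#' @seealso [simulationParams()], [simulateScan()]
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    cell = "UnitCell", geom = "DetectorGeometry", beam = "BeamParams",
    hitFraction = "numeric", backgroundLevel = "numeric",
    waterRingD = "numeric", waterRingAmp = "numeric",
    waterRingWidth = "numeric", spotSigma = "numeric",
    intensityScale = "numeric", mosaicityTol = "numeric",
    dMin = "numeric", seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msgs <- character()
  if (object@hitFraction < 0 || object@hitFraction > 1)
    msgs <- c(msgs, "hitFraction must be in [0, 1]")
  if (object@backgroundLevel < 0 || object@waterRingAmp < 0)
    msgs <- c(msgs, "background levels must be non-negative")
  if (object@spotSigma <= 0 || object@dMin <= 0)
    msgs <- c(msgs, "spotSigma and dMin must be positive")
  if (object@mosaicityTol < 0)
    msgs <- c(msgs, "mosaicityTol must be non-negative")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(paste0("SimulationParams: hit fraction %g, background %g ADU ",
                     "(+%g ring at %g A), dmin %g A, seed %d\n"),
              object@hitFraction, object@backgroundLevel, object@waterRingAmp,
              object@waterRingD, object@dMin, object@seed))
})

#' Ground truth of a simulated scan
#'
#' Complete bookkeeping of what the simulator planted, for validating the
#' analysis chain: per-frame hit labels and orientations, every rendered spot
#' with its Miller indices and true (partiality-scaled) integral, and the
#' global true-intensity table per asymmetric-unit reflection.
#'
#' @slot hits logical vector, one per frame.
#' @slot orientations numeric matrix n x 4 of unit quaternions (w, x, y, z).
#' @slot peaks data.frame (frameId, fs, ss, h, k, l, iTrue).
#' @slot intensities data.frame (h, k, l, iTrue) on asymmetric-unit indices.
#'
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(hits = "logical", orientations = "matrix",
                 peaks = "data.frame", intensities = "data.frame"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d frames, %d hits, %d planted spots, %d unique hkl\n",
              length(object@hits), sum(object@hits), nrow(object@peaks),
              nrow(object@intensities)))
})
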