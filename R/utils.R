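## Shared internal helpers: sentinel value, radius fields, d-spacing mapping.

## Sentinel stored in masked/padded pixels (keeps integer dtypes valid).
MASK_SENTINEL <- -1

#' Map detector radius to resolution
#'
#' Converts a radial distance from the beam centre (in pixels) into a
#' d-spacing via the flat-detector scattering geometry:
#' `d = lambda / (2 sin(0.5 atan(r * pixelSize / distance)))`.
#'
#' @param r radial distance from the beam centre (pixels); vectorised.
#' @param geom a [DetectorGeometry-class].
#' @return d-spacings in Angstrom (`Inf` at r = 0).
#' @export
radiusToD <- function(r, geom) {
  theta2 <- atan(r * geom@pixelSize / geom@distance)
  d <- geom@wavelength / (2 * sin(theta2 / 2))
  d[r == 0] <- Inf
  d
}

#' Map resolution to detector radius
#'
#' Inverse of [radiusToD()]: the radius (pixels) at which lattice planes of
#' spacing `d` diffract onto the detector.
#'
#' @param d d-spacing (Angstrom); vectorised.
#' @param geom a [DetectorGeometry-class].
#' @return radii in pixels.
#' @export
dToRadius <- function(d, geom) {
  theta <- asin(geom@wavelength / (2 * d))
  geom@distance * tan(2 * theta) / geom@pixelSize
}

## Matrix of radii (pixels) from the beam centre, pixel centres at integer
## 0-based coordinates; rows = fs, cols = ss.
radiusField <- function(geom) {
  fs <- (0:(geom@nFast - 1)) - geom@beamCenter[1]
  ss <- (0:(geom@nSlow - 1)) - geom@beamCenter[2]
  sqrt(outer(fs^2, ss^2, `+`))
}

## Effective logical mask of a frame: explicit mask OR sentinel pixels.
effectiveMask <- function(frame) {
  m <- frameMask(frame)
  m | (frame@pixels == MASK_SENTINEL)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
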