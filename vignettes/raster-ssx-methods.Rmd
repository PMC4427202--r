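---
title: "Methods: raster-scanning SSX pre-analysis and merging"
author: "rasterSSX"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: raster-scanning SSX pre-analysis and merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasterSSX)
```

## The problem

In serial synchrotron crystallography (SSX) a fixed target carrying
thousands of micrometre-sized crystals is raster-scanned through a focused
X-ray beam, one still exposure per grid position. Most shots hit only
solvent; a minority hit a crystal and record a thin, randomly oriented
slice of reciprocal space. Producing a data set from such frames needs a
pre-analysis chain — hit finding, detector correction, per-pattern
background subtraction, Bragg-peak location — followed by Monte Carlo
merging of the indexed partial intensities and half-dataset quality
control. This package implements that chain, plus the raster-scan/dose
planning arithmetic used to set up such an experiment, and a synthetic
frame simulator so every stage can be validated against known ground
truth.

## Scan planning and dose arithmetic

A raster plan is an `nFast x nSlow` grid of shot positions, fast
(horizontal) axis as the inner loop. The spacing rule guards against
radiation damage leaking into neighbouring, not-yet-measured positions:
photoelectrons travel roughly 3 µm in water/protein at ~1 Å wavelengths,
so each step must strictly exceed the larger beam dimension (FWHM) plus
that track length. A 10 µm step therefore clears a 1.5 × 2.5 µm beam
(10 > 2.5 + 3). The check is advisory (`spacingValid`), because
deliberately denser scans are a legitimate, if lossy, choice.

Flux density divides the fluence by the rectangular FWHM footprint
`w x h`. A Gaussian-integral footprint convention would be defensible too;
the rectangular one is used because it is traceable and matches standard
beamline bookkeeping (1.00e11 photons/s through 1.5 × 2.5 µm is
2.67e16 photons s⁻¹ mm⁻²). Dose rate is simply dose-per-frame over
exposure; absorbed-dose physics is out of scope and doses are taken as
inputs.

## Correction model

Two corrections precede any quantitative use of a CCD frame:

* **Metrology** — multiply by a per-pixel flat-field gain, then resample
  through a displacement field with bilinear interpolation. Pull semantics:
  output pixel (fs, ss) samples the gained image at
  (fs + dispFS, ss + dispSS). Samples drawing any weight from a masked or
  out-of-panel source are invalidated (sentinel −1 plus mask), never
  guessed.
* **Background** — crystal and solvent are mutually exclusive in the
  illuminated volume, so a single background reference cannot simply be
  subtracted: it must be scaled per pattern. The reference is the
  pixelwise mean (or median, robust to stray outlier frames) of the
  non-hit frames of a scan, which share the same solvent and membrane
  scatter; the per-pattern scale is the closed-form least-squares solution
  `s = sum(f·b) / sum(b²)` over pixels that are unmasked, outside a
  candidate-peak mask and optionally inside a resolution annulus. Whether
  the historical implementations fit this scale pixelwise or on the radial
  profile is not documented anywhere we could find; pixelwise least
  squares is this package's declared choice (it uses all the data and has
  an exact solution). Negative residuals are kept by default — clipping at
  zero biases merged intensities upward — with a `clipFloor` option for
  display-style output.

## Hit finding and resolution limit

A frame is a hit when at least `minNpix` unmasked pixels strictly exceed a
count threshold. The two-parameter form rejects both blank frames and
single hot pixels or low-resolution-only images. The default
`minNpix = 20` is sized to demand roughly two genuine Bragg spots' worth
of bright pixels; no published value exists for this parameter, so it is a
package default, not a reconstruction. Hits are best detected on
corrected, background-subtracted frames, which makes one threshold serve a
whole scan; the classification is deterministic and monotone in both
parameters.

The maximum projection (pixelwise max over hits, computed streaming in
constant memory) piles every observed spot into one image. Azimuthal
integration of that projection, against the same integration of an
equal-count projection of non-hit frames, gives a radial
signal-versus-background profile; the effective resolution limit is the
finest bin up to which every bin clears an SNR threshold. The contiguity
requirement exists because a single noisy high-resolution bin should not
inflate the estimate. Radius maps to d-spacing through the flat-detector
geometry `d = lambda / (2 sin(0.5 atan(r·px/L)))`.

## Peak search and ring integration

Peaks seed at strict local maxima of a `window x window` neighbourhood
(default 5 px). Equal-valued adjacent maxima are broken toward the smaller
(ss, fs) so exactly one survives. Each seed must additionally dominate its
whole integration disc — a seed that does not is a noise maximum on the
shoulder of a stronger spot, and integrating its disc would measure that
spot's core. Candidates are vetted by a local signal-to-noise test: the
background is the median of the `rBuffer < r <= rBg` annulus, the noise
its MAD scaled by 1.4826 (robust against neighbouring peaks inside the
annulus). Centroids are refined over the peak disc; candidates closer than
`window` pixels are deduplicated keeping the stronger.

Integration uses three concentric regions of radii 5, 7 and 9 pixels:
peak disc, excluded buffer, background annulus. Distances are Euclidean on
pixel centres — a Chebyshev (square) metric would distort annulus areas
and hence the sigma estimate. Intensity is the background-subtracted sum
over the disc; sigma propagates the annulus standard deviation over the
disc pixel count including the uncertainty of the background mean itself,
`sigma = sd_bg · sqrt(nPeak + nPeak²/nBg)`. A measurement with less than
half its background annulus usable (edge or mask) is flagged invalid
rather than extrapolated. The search window and the 5 px peak radius are
independent parameters that happen to share a default.

## Symmetry, merging and quality statistics

The tetragonal metric `1/d² = (h²+k²)/a² + l²/c²` and the Laue class
4/mmm (16 operations including Friedel) cover the target system; the
asymmetric-unit representative is the closed form `h >= k >= 0, l >= 0`.
Unique-reflection enumeration keeps systematic absences by default:
serial-indexing pipelines predict reflections from the Laue class, which
knows nothing of screw axes, and published unique counts at 100%
completeness follow that convention. The crystallographic alternative
(P43212 rules: 00l absent unless l = 4n, h00 absent unless h even) is
available as `dropAbsences = TRUE`. For the published tetragonal lysozyme
cell (a = b = 78.0, c = 38.3 Å, 50–1.95 Å) the keep-absences enumeration
gives 9094; the corresponding published count, 9091, is a *measured*
unique count, and the 3-reflection deficit is consistent with a few of the
lowest-resolution reflections never being recorded (printed completeness
is rounded to 100%).

Merging is the canonical Monte Carlo estimator: group observations by
asymmetric-unit index and take the unweighted arithmetic mean, which
converges to the full intensity (up to a global scale) as randomly partial
measurements accumulate. Inverse-variance weighting is available but not
default — partiality, not counting noise, dominates the per-observation
error, so the weights would be wrong. The merged sigma is the standard
error `sd/sqrt(n)`, falling back to the observation's own sigma for
singletons. Half-data sets split by frame-id parity: deterministic,
balanced, and uncorrelated with position on the detector or in the scan.

Quality metrics follow their standard definitions:
`R_split = 2^(-1/2) · sum|I1 − I2| / (0.5 · sum(I1 + I2))`, CC1/2 is the
Pearson correlation of half-set intensities, `R_merge(I)` the usual
deviation-from-mean ratio over all observations, and `R_merge(F)`
analogous on `sqrt(max(I, 0))` (negative merged intensities are retained
everywhere else). Shells divide `1/d³` equally so each holds a comparable
reflection count; published tables report only the highest shell, so the
shell count here (default 10) is a free choice. The table reports two
high-resolution cutoffs by walking shells coarse to fine: conservative
(mean I/sigma > 2 and R_split <= 0.5) and progressive (CC1/2 > 0.135, the
advised significance limit). With noise rising monotonically in
resolution, the conservative cutoff is never finer than the progressive
one.

## File formats

No R HDF5 bindings are assumed; all interchange formats are deliberately
simple: raw-binary frame stacks (little-endian int32/float64) with a
plain-text header sidecar, TIFF ingest, TSV peak lists (fs, ss, intensity,
snr, d — the first three columns being the N×3 table downstream indexers
consume), a single-panel key/value geometry file (panel extent, pixels per
metre, camera length, wavelength, corner offsets = −beam centre) that
round-trips through the package's own reader, and a whitespace observation
dialect `h k l I sigma frame_id` plus a subset parser for indexing-stream
reflection blocks. Coordinates are 0-based (fs, ss) with fs the
fastest-varying axis, pixel centres on integers; masked or padded pixels
hold −1 and are flagged in an explicit mask.

## The synthetic generator

The simulator emulates the study conditions of a micro-focused lysozyme
raster scan: tetragonal cell a = b = 78.0, c = 38.3 Å; wavelength
0.954 Å; a 41 × 41 scan with 10 µm steps; hit fraction 9.9% (41.9% in the
nano-like setting); isotropic background of 40 ADU with a Gaussian
solvent ring (amplitude 25 ADU, sigma 6 px) at 3.7 Å, where water scatter
peaks; Poisson counting noise everywhere. Each hit gets one crystal with a
uniformly random orientation (normalised 4-normal quaternion). A
reflection is excited when its rotated reciprocal-lattice point sits
within `mosaicityTol` (default 5e-4 Å⁻¹, the order of the integration
profile radius used by serial indexing suites) of the Ewald sphere;
partiality falls off triangularly in the offset. Spots are rendered as 2D
Gaussians (sigma 1.2 px) of integral `iTrue × partiality`, with true
intensities drawn once per seed from an exponential (Wilson-like)
distribution scaled by `intensityScale = 4000` ADU — sized so that a
median spot clears a peak-height SNR of ~10 over the solvent background.
Reflections are simulated to `dMin = 1.85` Å.

The paper-scale detector (1024 × 1024 px of 0.1 mm at ~80 mm, a distance
chosen so the panel edge reaches ~1.7 Å at 0.954 Å — the distance itself
is not published) is represented at reduced pixel counts that preserve
the full angular coverage: the default is 256 × 256 px of 0.4 mm, and the
test suite runs full 41 × 41 scans at 128 × 128 px of 0.8 mm, which keeps
a whole-scan simulation plus analysis within tens of seconds on one CPU.

What the generator does **not** emulate, and what passing tests therefore
do not show: detector distortion and gain structure beyond the identity
(metrology correction is validated on constructed maps, not emulated
physics); per-shot background variability beyond global scaling; multiple
lattices per shot (the spacing rule exists precisely to avoid re-hitting
crystals); spot shape beyond an isotropic Gaussian; structure-factor
amplitudes from an atomic model (intensities are statistical, so merged
data cannot be phased); readout noise other than Poisson. End-to-end
results on real CCD data will degrade where those effects bite —
particularly hit finding on un-subtracted frames and integration of
streaked or split spots.

## Numerical choices and degenerate inputs

* Determinism: one seed keys the run; hit labels and orientations come
  from the main stream, pixel noise from per-frame substreams derived from
  the frame index, so any frame can be regenerated in isolation.
* Zero-noise SNR: on an exactly flat background the SNR is defined as
  +Inf for a positive excursion and 0 otherwise; peaks must additionally
  have positive integrated intensity.
* `mosaicityTol = 0` excites (almost surely) no reflection — the Ewald
  intersection has measure zero.
* Empty containers read back as empty sequences; a 0-peak frame writes a
  0-row table, not a missing file.
* `enumerateUnique` with `dMax == dMin` is an empty list by convention.
* Padding to centre the beam is idempotent and never alters original
  pixels; the padded region is sentinel + mask.
* Per-shell statistics on shells with fewer than two half-populated
  reflections are NA, never extrapolated.

## Validation strategy

Every estimator is tested against an independent oracle: enumeration
against a brute-force sphere scan over all equivalents; asymmetric-unit
reduction against explicit 16-operation orbits; ring integration against
the analytic Gaussian disc sum; the metrology remap against index-shift
arithmetic; R_split against its closed form under scaled halves
(`sqrt(2)|1−k|/(1+k)`); spot positions against an independently coded
quaternion/ray-intersection projection; and the full chain against the
simulator's ground truth (hit rates within binomial error, peak
recall/precision, background-scale recovery, merged-versus-true intensity
correlation, resolution-limit recovery of the simulated truncation).

## Limitations

Autoindexing is out of scope: observations enter already indexed (the
package reads the text observation dialect and indexing-stream subsets).
Only single-panel detectors and the tetragonal/4-mmm symmetry family are
supported. Scaling between frames beyond the unweighted Monte Carlo
assumption — partiality models, post-refinement — is deliberately absent.
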