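## Shared fixtures and independent oracles for the test suite.

## Small detector for fast tests.
toyGeom <- function(n = 64, pixelSize = 0.4, distance = 80,
                    wavelength = 0.954, beamCenter = NULL) {
  if (is.null(beamCenter)) beamCenter <- c((n - 1) / 2, (n - 1) / 2)
  detectorGeometry(n, n, pixelSize, distance, beamCenter = beamCenter,
                   wavelength = wavelength)
}

## Like toyGeom but preserving the full angular coverage of the reference
## 1024 x 0.1 mm panel (102.4 mm wide at 80 mm), so simulated diffraction
## reaches the same resolution at any pixel count.
toyGeomFull <- function(n = 128) {
  detectorGeometry(n, n, pixelSize = 102.4 / n, distance = 80,
                   wavelength = 0.954)
}

microBeam <- function() {
  beamParams(0.954, beamW = 2.5, beamH = 1.5, fluence = 1.00e11,
             divergence = 1.0, bandwidth = 1e-4, exposure = 0.2,
             dosePerFrame = 3.2)
}

## Independent Gaussian-spot renderer (deliberately not the package's):
## evaluates the Gaussian at every pixel of the full image.
oracleRenderGaussian <- function(img, fs, ss, sigma, integral) {
  nf <- nrow(img); ns <- ncol(img)
  fgrid <- matrix(0:(nf - 1), nf, ns)
  sgrid <- matrix(0:(ns - 1), nf, ns, byrow = TRUE)
  img + integral / (2 * pi * sigma^2) *
    exp(-((fgrid - fs)^2 + (sgrid - ss)^2) / (2 * sigma^2))
}

## Analytic (discrete-sum) oracle for the ring-integrated intensity of a
## Gaussian spot: sum of the Gaussian over pixels within rPeak of the centre.
oracleGaussianDiscSum <- function(fs, ss, sigma, integral, rPeak = 5) {
  fr <- (floor(fs) - 10):(ceiling(fs) + 10)
  sr <- (floor(ss) - 10):(ceiling(ss) + 10)
  g <- expand.grid(fs = fr, ss = sr)
  r <- sqrt((g$fs - fs)^2 + (g$ss - ss)^2)
  v <- integral / (2 * pi * sigma^2) *
    exp(-((g$fs - fs)^2 + (g$ss - ss)^2) / (2 * sigma^2))
  sum(v[r <= rPeak])
}

## Brute-force 4/mmm asymmetric-unit representative: enumerate the full
## 16-element orbit explicitly and pick the unique member with
## h >= k >= 0, l >= 0.
oracleASU <- function(hkl) {
  h <- hkl[1]; k <- hkl[2]; l <- hkl[3]
  orbit <- unique(do.call(rbind, lapply(
    list(c(h, k), c(k, h)),
    function(p) expand.grid(h = c(p[1], -p[1]), k = c(p[2], -p[2]),
                            l = c(l, -l)))))
  sel <- orbit[orbit$h >= orbit$k & orbit$k >= 0 & orbit$l >= 0, ]
  stopifnot(nrow(unique(sel)) == 1)
  as.integer(unlist(unique(sel)))
}

## Brute-force unique-reflection count: scan the full reciprocal box,
## reduce every index with oracleASU-equivalent arithmetic, deduplicate.
oracleUniqueCount <- function(a, cc, dMax, dMin) {
  hmax <- floor(a / dMin); lmax <- floor(cc / dMin)
  g <- expand.grid(h = -hmax:hmax, k = -hmax:hmax, l = -lmax:lmax)
  g <- g[g$h | g$k | g$l, ]
  d <- 1 / sqrt((g$h^2 + g$k^2) / a^2 + g$l^2 / cc^2)
  g <- g[d >= dMin & d <= dMax, ]
  ha <- abs(g$h); ka <- abs(g$k)
  key <- paste(pmax(ha, ka), pmin(ha, ka), abs(g$l))
  length(unique(key))
}

## Independent still-shot projection oracle: own quaternion algebra and
## ray-plane intersection, for checking rendered spot positions.
oracleProject <- function(hkl, quat, cell, geom) {
  q <- quat / sqrt(sum(quat^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- function(v) {
    ## quaternion sandwich product q v q*
    t <- 2 * c(y * v[3] - z * v[2], z * v[1] - x * v[3], x * v[2] - y * v[1])
    v + w * t + c(y * t[3] - z * t[2], z * t[1] - x * t[3],
                  x * t[2] - y * t[1])
  }
  q0 <- c(hkl[1] / cell@a, hkl[2] / cell@a, hkl[3] / cell@c)
  qr <- rot(q0)
  kin <- c(0, 0, 1 / geom@wavelength)
  kout <- qr + kin
  stopifnot(kout[3] > 0)
  xmm <- geom@distance * kout[1] / kout[3]
  ymm <- geom@distance * kout[2] / kout[3]
  c(fs = geom@beamCenter[1] + xmm / geom@pixelSize,
    ss = geom@beamCenter[2] + ymm / geom@pixelSize)
}

## Match found peaks to planted positions within tol pixels; returns
## recall/precision.
matchPeaks <- function(found, planted, tol = 2.5) {
  if (nrow(found) == 0)
    return(list(recall = 0, precision = NA_real_))
  hitPlanted <- vapply(seq_len(nrow(planted)), function(i) {
    any(sqrt((found$fs - planted$fs[i])^2 +
               (found$ss - planted$ss[i])^2) <= tol)
  }, logical(1))
  truePos <- vapply(seq_len(nrow(found)), function(i) {
    any(sqrt((planted$fs - found$fs[i])^2 +
               (planted$ss - found$ss[i])^2) <= tol)
  }, logical(1))
  list(recall = mean(hitPlanted), precision = mean(truePos))
}
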