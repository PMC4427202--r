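test_that("metrology correction is identity for unit maps", {
  px <- matrix(rpois(32 * 32, 50), 32, 32) * 1.0
  f <- imageFrame(px)
  out <- applyMetrology(f, metrologyMaps(32, 32))
  expect_equal(pixels(out), px)
  expect_false(any(frameMask(out)))
})

test_that("flat-field gain scales pixel values", {
  px <- matrix(rpois(16 * 16, 50), 16, 16) * 1.0
  f <- imageFrame(px)
  maps <- metrologyMaps(16, 16, flatfield = matrix(2, 16, 16))
  expect_equal(pixels(applyMetrology(f, maps)), 2 * px)
  expect_error(applyMetrology(imageFrame(matrix(0, 8, 8)), maps),
               "shape")
})

test_that("integer displacement reproduces an index shift exactly", {
  px <- matrix(rpois(24 * 24, 100), 24, 24) * 1.0
  f <- imageFrame(px)
  maps <- metrologyMaps(24, 24, dispFS = matrix(1, 24, 24))
  out <- applyMetrology(f, maps)
  ## pull semantics: output row i sources raw row i+1; last row unmappable
  expect_equal(pixels(out)[1:23, ], px[2:24, ])
  expect_true(all(frameMask(out)[24, ]))
  expect_true(all(pixels(out)[24, ] == -1))

  ## half-pixel displacement averages neighbours (bilinear)
  maps2 <- metrologyMaps(24, 24, dispFS = matrix(0.5, 24, 24))
  out2 <- applyMetrology(f, maps2)
  expect_equal(pixels(out2)[1:23, ], (px[1:23, ] + px[2:24, ]) / 2)
})

test_that("bad pixels propagate through the remap as sentinel", {
  px <- matrix(10, 12, 12)
  mask <- matrix(FALSE, 12, 12); mask[6, 6] <- TRUE
  maps <- metrologyMaps(12, 12, mask = mask)
  out <- applyMetrology(imageFrame(px), maps)
  expect_true(frameMask(out)[6, 6])
  expect_equal(pixels(out)[6, 6], -1)
  expect_equal(sum(frameMask(out)), 1)
})

test_that("background estimation averages non-hit frames", {
  g <- toyGeom(32)
  ## identical frames: reference equals the frame
  f <- imageFrame(matrix(7, 32, 32))
  bgm <- estimateBackground(list(f, f, f), g)
  expect_equal(reference(bgm), matrix(7, 32, 32))
  expect_error(estimateBackground(list(), g), "at least one")

  ## constant + zero-mean noise converges at the 3 sigma / sqrt(n) rate
  set.seed(11)
  n <- 50; c0 <- 100
  frames <- lapply(1:n, function(i)
    imageFrame(matrix(c0 + rnorm(32 * 32, sd = 5), 32, 32), frameId = i))
  bgm <- estimateBackground(frames, g, "mean")
  expect_lt(max(abs(reference(bgm) - c0)), 5 * 5 / sqrt(n) )  # 5 sigma guard
  expect_lt(abs(mean(reference(bgm)) - c0), 3 * 5 / sqrt(n * 32 * 32))
})

test_that("median background ignores a single saturated frame", {
  g <- toyGeom(16)
  set.seed(2)
  base <- matrix(rpois(256, 40), 16, 16) * 1.0
  frames <- lapply(1:10, function(i) imageFrame(base, frameId = i))
  hot <- imageFrame(matrix(65535, 16, 16), frameId = 11L)
  bgm <- estimateBackground(c(frames, list(hot)), g, "median")
  expect_equal(reference(bgm), base)
})

test_that("per-pattern background scale is recovered", {
  g <- toyGeom(64)
  set.seed(4)
  ref <- matrix(rpois(64 * 64, 80), 64, 64) * 1.0
  bgm <- estimateBackground(list(imageFrame(ref)), g)

  ## frame == background: s = 1, residual 0
  out <- subtractBackgroundScaled(imageFrame(ref), bgm)
  expect_equal(out$scale, 1)
  expect_equal(max(abs(pixels(out$frame))), 0)

  ## all-zero frame: s = 0, output 0
  z <- subtractBackgroundScaled(imageFrame(matrix(0, 64, 64)), bgm)
  expect_equal(z$scale, 0)
  expect_equal(pixels(z$frame), matrix(0, 64, 64))

  ## planted scale 0.8 with spots hidden under the peak mask
  spot <- matrix(0, 64, 64)
  for (i in 1:5)
    spot <- oracleRenderGaussian(spot, 10 + 9 * i, 32, 1.5, 2000)
  frame <- imageFrame(0.8 * ref + spot)
  pmask <- spot > 1e-3
  fit <- subtractBackgroundScaled(frame, bgm, peakMask = pmask)
  expect_equal(fit$scale, 0.8, tolerance = 0.01)

  expect_error(subtractBackgroundScaled(
    imageFrame(ref), estimateBackground(list(imageFrame(matrix(0, 64, 64))),
                                        g)),
    "identically zero")
})

test_that("background scale is equivariant under frame scaling", {
  g <- toyGeom(32)
  set.seed(6)
  ref <- matrix(rpois(1024, 50), 32, 32) * 1.0
  bgm <- estimateBackground(list(imageFrame(ref)), g)
  frame <- matrix(rpois(1024, 45), 32, 32) * 1.0
  s1 <- subtractBackgroundScaled(imageFrame(frame), bgm)$scale
  for (k in c(0.5, 2, 3.7)) {
    sk <- subtractBackgroundScaled(imageFrame(k * frame), bgm)$scale
    expect_equal(sk, k * s1, tolerance = 1e-12)
  }
})

test_that("subtraction conserves planted spot intensities within noise", {
  g <- toyGeom(96)
  set.seed(8)
  bgMean <- matrix(70, 96, 96)
  ref <- matrix(rpois(96 * 96 * 1, rep(bgMean, 1)), 96, 96) * 1.0
  nAvg <- 20
  arr <- replicate(nAvg, matrix(rpois(96 * 96, bgMean), 96, 96))
  bgm <- estimateBackground(lapply(seq_len(nAvg), function(i)
    imageFrame(arr[, , i])), g)
  ## plant isolated spots of known integral on a fresh noisy background
  planted <- data.frame(fs = c(20, 50, 75, 30, 70),
                        ss = c(20, 30, 55, 70, 80),
                        A = c(3000, 5000, 2000, 4000, 2500))
  mu <- bgMean
  for (i in 1:5)
    mu <- oracleRenderGaussian(mu, planted$fs[i], planted$ss[i], 1.3,
                               planted$A[i])
  frame <- imageFrame(matrix(rpois(96 * 96, mu), 96, 96) * 1.0)
  pmask <- (mu - bgMean) > 1
  corr <- subtractBackgroundScaled(frame, bgm, peakMask = pmask)$frame
  for (i in 1:5) {
    m <- integrateRings(pixels(corr), c(planted$fs[i], planted$ss[i]))
    ## Poisson error of the disc sum ~ sqrt(A + nPix * bg)
    err <- sqrt(planted$A[i] + m$nPeakPix * 70)
    expect_lt(abs(m$intensity - planted$A[i]), 5 * err)
  }
})
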