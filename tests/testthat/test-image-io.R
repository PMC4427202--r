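test_that("raw-binary frame stacks round-trip bit-exactly", {
  tmp <- withr::local_tempdir()
  set.seed(1)
  frames <- lapply(0:9, function(i)
    imageFrame(matrix(rpois(48 * 32, 100), 48, 32) * 1.0, frameId = i))
  path <- file.path(tmp, "stack.img")
  writeFrameStack(frames, path)
  back <- readFrames(path)
  expect_length(back, 10)
  expect_equal(vapply(back, frameId, integer(1)), 0:9)
  for (i in 1:10)
    expect_identical(pixels(back[[i]]), pixels(frames[[i]]))

  ## float data (e.g. background-subtracted) round-trips too
  fframes <- list(imageFrame(matrix(rnorm(100), 10, 10), frameId = 3L))
  writeFrameStack(fframes, file.path(tmp, "f.img"))
  expect_equal(pixels(readFrames(file.path(tmp, "f.img"))[[1]]),
               pixels(fframes[[1]]))
})

test_that("an empty container yields an empty sequence, not an error", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "empty.img")
  file.create(path)
  writeLines(c("n_frames=0", "n_fast=16", "n_slow=16", "dtype=int32",
               "byte_order=little"), paste0(path, ".hdr"))
  expect_length(readFrames(path), 0)
})

test_that("frame shape is validated against a supplied geometry", {
  tmp <- withr::local_tempdir()
  path <- file.path(tmp, "s.img")
  writeFrameStack(list(imageFrame(matrix(0, 8, 8))), path)
  expect_error(readFrames(path, geom = toyGeom(16)), "does not match")
  expect_length(readFrames(path, geom = toyGeom(8)), 1)
})

test_that("TIFF stacks are ingested with the fs/ss convention", {
  tmp <- withr::local_tempdir()
  px <- matrix(sample(0:4095, 24 * 16), 24, 16)   # fs x ss
  path <- file.path(tmp, "frame.tif")
  ## TIFF pages are [row, col] = [ss, fs]
  tiff::writeTIFF(t(px) / 65535, path, bits.per.sample = 16)
  back <- readFrames(path, "tiff")
  expect_length(back, 1)
  expect_equal(pixels(back[[1]]), px * 1.0)
})

test_that("hit writing produces one image + peak table per hit", {
  tmp <- withr::local_tempdir()
  f1 <- imageFrame(matrix(rpois(64, 10), 8, 8), frameId = 4L)
  f2 <- imageFrame(matrix(rpois(64, 10), 8, 8), frameId = 7L)
  pk <- data.frame(fs = c(2.5, 6.0), ss = c(3.0, 1.0),
                   intensity = c(120, 80), snr = c(12, 8), d = c(3.2, 2.1))
  pl1 <- peakList(4L, pk)
  pl2 <- peakList(7L)                     # no peaks
  man <- writeHits(list(f1, f2), list(pl1, pl2), tmp)
  expect_equal(nrow(man), 2)
  expect_equal(man$nPeaks, c(2, 0))
  expect_true(all(file.exists(man$imagePath), file.exists(man$peakPath)))
  ## peak table round-trips to float precision; empty table is 0-row,
  ## not absent
  back1 <- readPeaksTSV(man$peakPath[1], 4L)
  expect_equal(peaks(back1), peaks(pl1), tolerance = 1e-12)
  back2 <- readPeaksTSV(man$peakPath[2], 7L)
  expect_equal(nrow(peaks(back2)), 0)
  expect_named(peaks(back2), c("fs", "ss", "intensity", "snr", "d"))
  ## peak row counts in the manifest match the peak lists
  expect_equal(man$nPeaks, c(nrow(peaks(pl1)), nrow(peaks(pl2))))
})

test_that("geometry files round-trip through write and read", {
  tmp <- withr::local_tempdir()
  ## 2x-binned CCD fixture: 1024 x 1024 px of 0.1 mm
  geom <- detectorGeometry(1024, 1024, 0.1, 80,
                           beamCenter = c(511.5, 511.5), wavelength = 0.954)
  path <- file.path(tmp, "panel.geom")
  writeGeometryFile(geom, path, beam = microBeam())
  txt <- readLines(path)
  expect_true(any(grepl("max_fs = 1023", txt)))
  expect_true(any(grepl("wavelength = 0.954", txt, fixed = TRUE)))
  back <- readGeometryFile(path)
  expect_equal(back@nFast, geom@nFast)
  expect_equal(back@nSlow, geom@nSlow)
  expect_equal(back@pixelSize, geom@pixelSize, tolerance = 1e-9)
  expect_equal(back@distance, geom@distance, tolerance = 1e-9)
  expect_equal(back@beamCenter, geom@beamCenter, tolerance = 1e-9)
  expect_equal(back@wavelength, geom@wavelength, tolerance = 1e-9)
})

test_that("padding centres the beam and is idempotent", {
  ## already centred: identity shape
  g0 <- toyGeom(21, beamCenter = c(10, 10))
  f0 <- imageFrame(matrix(1:441, 21, 21) * 1.0)
  p0 <- padToCenter(f0, g0)
  expect_equal(dim(pixels(p0$frame)), c(21, 21))
  expect_equal(pixels(p0$frame), pixels(f0))

  ## off-centre beam: square output, original data preserved
  g <- detectorGeometry(100, 100, 0.4, 80, beamCenter = c(10, 50),
                        wavelength = 1)
  px <- matrix(rpois(1e4, 20), 100, 100) * 1.0
  f <- imageFrame(px)
  p <- padToCenter(f, g)
  size <- 2 * max(10, 89, 50, 49) + 1      # fast-axis offset dominates
  expect_equal(dim(pixels(p$frame)), c(size, size))
  expect_equal(p$geom@beamCenter, c((size - 1) / 2, (size - 1) / 2))
  ## original pixels unchanged, padding is sentinel + masked
  ctr <- (size - 1) / 2
  offF <- ctr - 10; offS <- ctr - 50
  expect_equal(pixels(p$frame)[offF + 1:100, offS + 1:100], px)
  expect_true(all(pixels(p$frame)[frameMask(p$frame)] == -1))

  ## twice-padded equals once-padded
  p2 <- padToCenter(p$frame, p$geom)
  expect_equal(pixels(p2$frame), pixels(p$frame))
  expect_equal(p2$geom@beamCenter, p$geom@beamCenter)
})
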