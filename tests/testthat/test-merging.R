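test_that("tetragonal d-spacing metric is exact", {
  cell <- unitCell(78.0, c = 38.3)
  expect_equal(dSpacing(c(1, 0, 0), cell), 78.0)
  expect_equal(dSpacing(c(0, 0, 1), cell), 38.3)
  expect_equal(dSpacing(c(2, 1, 3), cell),
               1 / sqrt(5 / 78^2 + 9 / 38.3^2), tolerance = 1e-12)
  expect_equal(round(dSpacing(c(2, 1, 3), cell), 2), 11.99)
  expect_error(dSpacing(c(0, 0, 0), cell), "no d-spacing")
})

test_that("asymmetric-unit reduction matches the brute-force orbit", {
  expect_equal(unname(reduceToASU(c(0, 0, 5))[1, ]), c(0, 0, 5))
  expect_equal(unname(reduceToASU(c(-1, 2, -3))[1, ]), c(2, 1, 3))
  set.seed(29)
  hkl <- matrix(sample(-12:12, 3 * 500, replace = TRUE), ncol = 3)
  hkl <- hkl[rowSums(hkl != 0) > 0, ]
  red <- reduceToASU(hkl)
  for (i in seq_len(nrow(hkl)))
    expect_equal(unname(red[i, ]), oracleASU(hkl[i, ]))
  ## idempotent
  expect_equal(reduceToASU(red), red)
  ## every Laue operation maps into the same representative
  ops <- rasterSSX:::laueOperations4mmm()
  v <- c(3, -5, 2)
  reps <- t(vapply(ops, function(op) reduceToASU(op(v))[1, ], numeric(3)))
  expect_true(all(apply(reps, 1, identical, reps[1, ])))
})

test_that("unique enumeration equals the brute-force sphere scan", {
  set.seed(31)
  for (i in 1:5) {
    a <- runif(1, 8, 15); cc <- runif(1, 6, 12)
    cell <- unitCell(a, c = cc)
    dMin <- runif(1, 2.2, 3.5)
    got <- nrow(enumerateUnique(cell, 50, dMin))
    expect_equal(got, oracleUniqueCount(a, cc, 50, dMin))
  }
  ## degenerate range: empty list
  expect_equal(nrow(enumerateUnique(unitCell(10, c = 10), 5, 5)), 0)
})

test_that("the absence toggle removes exactly the screw-axis classes", {
  cell <- unitCell(20, c = 16)
  keep <- enumerateUnique(cell, 50, 3)
  drop <- enumerateUnique(cell, 50, 3, dropAbsences = TRUE)
  removed <- setdiff(paste(keep$h, keep$k, keep$l),
                     paste(drop$h, drop$k, drop$l))
  expected <- keep[isSystematicAbsence(as.matrix(keep[, 1:3])), ]
  expect_setequal(removed, paste(expected$h, expected$k, expected$l))
  ## 00l survives only at l = 4n; h00 only at even h
  expect_true(all(drop$l[drop$h == 0 & drop$k == 0] %% 4 == 0))
  expect_true(all(drop$h[drop$k == 0 & drop$l == 0] %% 2 == 0))
})

test_that("Monte Carlo merge averages per unique reflection", {
  one <- data.frame(h = 1, k = 2, l = 3, I = 10, sigma = 1, frameId = 0)
  m <- mergeMonteCarlo(one)
  expect_equal(m$I, 10)
  expect_equal(m$multiplicity, 1)
  expect_equal(m$sigma, 1)      # singleton falls back to the input sigma

  two <- data.frame(h = c(2, 2), k = c(1, 1), l = c(3, 3), I = c(8, 12),
                    sigma = c(1, 1), frameId = c(0, 1))
  m2 <- mergeMonteCarlo(two)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$I, 10)
  expect_equal(m2$multiplicity, 2)
  expect_equal(m2$iEven, 8)
  expect_equal(m2$iOdd, 12)
})

test_that("merge is invariant to order and symmetry equivalents", {
  set.seed(37)
  n <- 400
  base <- data.frame(h = sample(0:5, n, TRUE), k = sample(0:5, n, TRUE),
                     l = sample(0:4, n, TRUE), I = rexp(n, 1 / 100),
                     sigma = runif(n, 1, 3), frameId = sample(0:49, n, TRUE))
  base <- base[rowSums(base[, 1:3] != 0) > 0, ]
  mA <- mergeMonteCarlo(base)
  mB <- mergeMonteCarlo(base[sample(nrow(base)), ])
  expect_equal(mA, mB)
  ## replace each hkl by a random Laue equivalent
  ops <- rasterSSX:::laueOperations4mmm()
  equiv <- base
  for (i in seq_len(nrow(base))) {
    v <- ops[[sample(16, 1)]](as.numeric(base[i, 1:3]))
    equiv[i, 1:3] <- v
  }
  mC <- mergeMonteCarlo(equiv)
  expect_equal(mA, mC)
  ## observation bookkeeping: multiplicities sum to the observation count
  expect_equal(sum(mA$multiplicity), nrow(base))
})

test_that("merging recovers true intensities from noisy partials", {
  set.seed(41)
  nRefl <- 300; mult <- 100
  iTrue <- rexp(nRefl, 1 / 1000)
  obs <- data.frame(
    h = rep(seq_len(nRefl) %% 20 + 1, each = mult),
    k = rep(seq_len(nRefl) %% 7, each = mult),
    l = rep(seq_len(nRefl), each = mult),
    I = rep(iTrue, each = mult) * (1 + rnorm(nRefl * mult, 0, 0.3)),
    sigma = 1, frameId = rep(seq_len(mult), nRefl))
  m <- mergeMonteCarlo(obs)
  key <- paste(reduceToASU(as.matrix(obs[!duplicated(obs$l), 1:3]))[, 1],
               reduceToASU(as.matrix(obs[!duplicated(obs$l), 1:3]))[, 2],
               reduceToASU(as.matrix(obs[!duplicated(obs$l), 1:3]))[, 3])
  got <- setNames(m$I, paste(m$h, m$k, m$l))[key]
  expect_gte(cor(got, iTrue), 0.99)
})

test_that("half-set statistics obey their closed forms", {
  set.seed(43)
  n <- 200
  iEven <- rexp(n, 1 / 500)
  merged <- data.frame(h = 1:n, k = 0, l = 0, I = iEven, sigma = 1,
                       multiplicity = 2, iEven = iEven, iOdd = iEven)
  ## identical halves
  s <- halfSetStats(merged)
  expect_equal(s$overall$rSplit, 0)
  expect_equal(s$overall$cc12, 1)
  ## scaled halves: R_split = sqrt(2) |1 - k| / (1 + k), CC = 1
  for (k in c(0.5, 0.9, 1, 1.1, 2)) {
    merged$iOdd <- k * iEven
    s <- halfSetStats(merged)
    expect_equal(s$overall$rSplit, sqrt(2) * abs(1 - k) / (1 + k),
                 tolerance = 1e-12)
    if (k != 1) expect_equal(s$overall$cc12, 1, tolerance = 1e-12)
  }
  ## independent halves: CC1/2 is null within 3/sqrt(N)
  merged$iEven <- rnorm(n); merged$iOdd <- rnorm(n)
  s <- halfSetStats(merged)
  expect_lt(abs(s$overall$cc12), 3 / sqrt(n))
  expect_error(halfSetStats(merged[1, ]), ">= 2")
})

test_that("per-shell statistics flag underpopulated shells", {
  cell <- unitCell(30, c = 20)
  merged <- mergeMonteCarlo(data.frame(
    h = c(1, 1, 2, 2, 9, 9), k = c(0, 0, 1, 1, 3, 3),
    l = c(0, 0, 1, 1, 5, 5), I = c(10, 12, 20, 22, 5, 6),
    sigma = 1, frameId = c(0, 1, 0, 1, 0, 1)))
  shells <- resolutionShells(40, 2, 4)
  s <- halfSetStats(merged, shells, cell)
  expect_equal(nrow(s$byShell), 4)
  expect_true(any(is.na(s$byShell$rSplit)))   # empty shells undefined
  ## shell edges decrease and are equal-volume in 1/d^3
  expect_true(all(diff(shells) < 0))
  expect_equal(diff(shells^-3), rep(diff(shells^-3)[1], 4), tolerance = 1e-9)
})

test_that("dataset table reports completeness, multiplicity and cutoffs", {
  cell <- unitCell(12, c = 9)
  uniq <- enumerateUnique(cell, 50, 3)
  set.seed(47)
  mult <- 6
  obs <- do.call(rbind, lapply(seq_len(nrow(uniq)), function(i) {
    data.frame(h = uniq$h[i], k = uniq$k[i], l = uniq$l[i],
               I = 100 * uniq$d[i] + rnorm(mult, 0, 5), sigma = 2,
               frameId = seq_len(mult) + i)
  }))
  merged <- mergeMonteCarlo(obs)
  tab <- datasetTable(merged, obs, cell, 50, 3, nShells = 4)
  ## every unique reflection observed: completeness 100%
  expect_equal(tab$overall$completeness, 1)
  expect_equal(tab$overall$multiplicity, mult)
  expect_equal(tab$overall$nUnique, nrow(uniq))
  ## R_merge oracle on a hand-computable toy set
  toy <- data.frame(h = c(1, 1, 2, 2), k = c(0, 0, 1, 1),
                    l = c(0, 0, 1, 1), I = c(8, 12, 20, 20), sigma = 1,
                    frameId = c(0, 1, 0, 1))
  tm <- mergeMonteCarlo(toy)
  tt <- datasetTable(tm, toy, cell, 50, 3, nShells = 1)
  expect_equal(tt$overall$rMergeI, (2 + 2 + 0 + 0) / 60)
  expect_equal(tt$overall$rMergeF,
               (abs(sqrt(8) - sqrt(10)) + abs(sqrt(12) - sqrt(10))) /
                 (sqrt(8) + sqrt(12) + 2 * sqrt(20)))
})

test_that("noise rising with resolution orders the two cutoffs", {
  ## conservative (I/sigma, R_split) cutoff is never finer than the
  ## progressive CC1/2 cutoff when noise grows monotonically
  cell <- unitCell(12, c = 9)
  uniq <- enumerateUnique(cell, 50, 2.2)
  set.seed(53)
  mult <- 8
  obs <- do.call(rbind, lapply(seq_len(nrow(uniq)), function(i) {
    d <- uniq$d[i]
    ## Wilson-like falloff with per-reflection (exponential) spread, so the
    ## half-set correlation survives longer than the mean I/sigma
    iTrue <- rexp(1) * 2000 * exp(-16 / d^2)
    noise <- 1 + 800 * exp(-d)         # rises toward high resolution
    data.frame(h = uniq$h[i], k = uniq$k[i], l = uniq$l[i],
               I = iTrue + rnorm(mult, 0, noise), sigma = noise,
               frameId = seq_len(mult) + i)
  }))
  merged <- mergeMonteCarlo(obs)
  tab <- datasetTable(merged, obs, cell, 50, 2.2, nShells = 6)
  expect_false(is.na(tab$conservativeCutoff))
  expect_gte(tab$conservativeCutoff, tab$progressiveCutoff)
})

test_that("observation tables round-trip through text and stream formats", {
  tmp <- withr::local_tempdir()
  obs <- data.frame(h = c(1, -2, 3), k = c(0, 2, -1), l = c(4, 5, 0),
                    I = c(10.5, -3.25, 800), sigma = c(1, 2, 3),
                    frameId = c(0, 1, 2))
  p <- file.path(tmp, "obs.txt")
  writeObservations(obs, p)
  expect_equal(readObservations(p), obs)

  stream <- c("CrystFEL stream format 2.3",
              "----- Begin chunk -----",
              "Reflections measured after indexing",
              "   h    k    l          I     sigma(I)",
              "   1    0    4      10.50      1.00",
              "  -2    2    5      -3.25      2.00",
              "End of reflections",
              "----- End chunk -----",
              "----- Begin chunk -----",
              "Reflections measured after indexing",
              "   3   -1    0     800.00      3.00",
              "End of reflections")
  sp <- file.path(tmp, "toy.stream")
  writeLines(stream, sp)
  got <- readStreamObservations(sp)
  expect_equal(nrow(got), 3)
  expect_equal(got$I, c(10.5, -3.25, 800))
  expect_equal(got$frameId, c(0, 0, 1))
})
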