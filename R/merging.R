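## Symmetry reduction, unique-reflection enumeration, Monte Carlo merging
## and half-dataset quality statistics.
##
## Still-shot serial data deliver randomly partial intensity measurements;
## merging is a plain (Monte Carlo) average over all observations of each
## symmetry-unique reflection, which converges to the full intensity up to a
## global scale as multiplicity grows. Data quality is judged by comparing
## two half-data sets: R_split (normalised half-set disagreement) and CC1/2
## (Pearson correlation of half-set intensities).

#' @importFrom data.table data.table := .N
NULL

#' d-spacing of reflections in a tetragonal cell
#'
#' `1/d^2 = (h^2 + k^2)/a^2 + l^2/c^2`.
#'
#' @param hkl integer matrix (n x 3) or length-3 vector of Miller indices.
#' @param cell a [UnitCell-class] (tetragonal).
#' @return d-spacings in Angstrom.
#' @examples
#' cell <- unitCell(78.0, c = 38.3)
#' dSpacing(c(1, 0, 0), cell)  # 78.0
#' @export
dSpacing <- function(hkl, cell) {
  hkl <- rbind(hkl)
  stopIfNot(cell@lattice == "tetragonal",
            "d-spacing metric implemented for tetragonal cells")
  stopIfNot(!any(rowSums(hkl != 0) == 0), "(0,0,0) has no d-spacing")
  invd2 <- (hkl[, 1]^2 + hkl[, 2]^2) / cell@a^2 + hkl[, 3]^2 / cell@c^2
  as.vector(1 / sqrt(invd2))
}

#' Reduce Miller indices to the 4/mmm asymmetric unit
#'
#' Applies the 16 Laue-group operations of 4/mmm (the 4/mmm point group plus
#' Friedel inversion; the orbit of (h,k,l) is all sign combinations of
#' (|h|,|k|,|l|) together with the h/k swap) and returns the canonical
#' representative with `h >= k >= 0` and `l >= 0`. Idempotent.
#'
#' @param hkl integer matrix (n x 3) or length-3 vector.
#' @return Integer matrix (n x 3) of asymmetric-unit indices.
#' @examples
#' reduceToASU(c(-1, 2, -3))  # (2, 1, 3)
#' @export
reduceToASU <- function(hkl) {
  hkl <- rbind(hkl)
  h <- abs(hkl[, 1]); k <- abs(hkl[, 2]); l <- abs(hkl[, 3])
  cbind(h = pmax(h, k), k = pmin(h, k), l = l)
}

## All 16 Laue 4/mmm operations applied to one hkl (used by the brute-force
## oracle in the test suite as well as internally nowhere -- reduceToASU is
## closed-form).
laueOperations4mmm <- function() {
  ops <- list()
  for (sh in c(1, -1)) for (sk in c(1, -1)) for (sl in c(1, -1)) {
    ops[[length(ops) + 1]] <- local({
      a <- sh; b <- sk; d <- sl
      function(v) c(a * v[1], b * v[2], d * v[3])
    })
    ops[[length(ops) + 1]] <- local({
      a <- sh; b <- sk; d <- sl
      function(v) c(a * v[2], b * v[1], d * v[3])
    })
  }
  ops
}

#' Systematic-absence test for P43212
#'
#' Screw-axis extinction rules: 00l absent unless l = 4n; h00 absent unless
#' h even (and 0k0 likewise, which reduces onto h00 in the asymmetric unit).
#'
#' @param hkl integer matrix (n x 3) of asymmetric-unit indices.
#' @return logical vector, TRUE where the reflection is systematically
#'   absent.
#' @export
isSystematicAbsence <- function(hkl) {
  hkl <- rbind(hkl)
  h <- hkl[, 1]; k <- hkl[, 2]; l <- hkl[, 3]
  (h == 0 & k == 0 & (l %% 4 != 0)) | (k == 0 & l == 0 & (h %% 2 != 0))
}

#' Enumerate symmetry-unique reflections in a resolution range
#'
#' All asymmetric-unit reflections (`h >= k >= 0, l >= 0`, Laue 4/mmm) of a
#' tetragonal cell with `dMin <= d <= dMax`. Systematic absences are kept by
#' default: serial-indexing pipelines predict and count them like any other
#' reflection (the Laue class does not know about screw axes), which is the
#' convention that reproduces published unique-reflection counts at 100%
#' completeness. Set `dropAbsences = TRUE` for the crystallographic count
#' with P43212 screw-axis extinctions removed.
#'
#' @param cell a [UnitCell-class] (tetragonal).
#' @param dMax low-resolution limit (Angstrom), `dMax > dMin`.
#' @param dMin high-resolution limit (Angstrom).
#' @param dropAbsences drop P43212 systematic absences (default FALSE).
#' @return data.frame (h, k, l, d), sorted by decreasing d.
#' @examples
#' nrow(enumerateUnique(unitCell(78.0, c = 38.3), 50, 1.95))  # 9094
#' @export
enumerateUnique <- function(cell, dMax, dMin, dropAbsences = FALSE) {
  stopIfNot(dMax >= dMin && dMin > 0, "need dMax >= dMin > 0")
  if (dMax == dMin)
    return(data.frame(h = integer(), k = integer(), l = integer(),
                      d = numeric()))
  hmax <- floor(cell@a / dMin)
  lmax <- floor(cell@c / dMin)
  g <- expand.grid(h = 0:hmax, k = 0:hmax, l = 0:lmax)
  g <- g[g$h >= g$k & (g$h | g$k | g$l), ]
  d <- dSpacing(as.matrix(g), cell)
  keep <- d >= dMin & d <= dMax
  if (dropAbsences) keep <- keep & !isSystematicAbsence(as.matrix(g))
  out <- g[keep, ]
  out$d <- d[keep]
  out <- out[order(-out$d, out$h, out$k, out$l), ]
  rownames(out) <- NULL
  out
}

#' Read / write observation tables
#'
#' The plain-text observation dialect is one reflection per line,
#' `h k l I sigma frame_id`, whitespace-separated, with `#` comments.
#'
#' @param path file path.
#' @return `readObservations`: data.frame (h, k, l, I, sigma, frameId).
#' @export
readObservations <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("h", "k", "l", "I", "sigma",
                                        "frameId"))
  stopIfNot(all(df$sigma > 0), "observation sigmas must be positive")
  df
}

#' @rdname readObservations
#' @param obs observation data.frame (h, k, l, I, sigma, frameId).
#' @export
writeObservations <- function(obs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# h k l I sigma frame_id", con)
  utils::write.table(obs[, c("h", "k", "l", "I", "sigma", "frameId")], con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse reflection blocks from an indexing-stream file
#'
#' Minimal subset parser for the stream dialect downstream indexers emit:
#' within each chunk, lines between a header starting with
#' "Reflections measured" and a line "End of reflections" hold whitespace-
#' separated columns beginning with h, k, l, I, sigma. Chunks are numbered
#' 0, 1, ... and used as frame ids.
#'
#' @param path stream file path.
#' @return data.frame (h, k, l, I, sigma, frameId).
#' @export
readStreamObservations <- function(path) {
  lines <- readLines(path)
  starts <- grep("^Reflections measured", lines)
  ends <- grep("^End of reflections", lines)
  stopIfNot(length(starts) == length(ends),
            "malformed stream: unbalanced reflection blocks")
  out <- lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1):(ends[i] - 1)]
    ## drop a column-header line if present
    block <- block[!grepl("^\\s*h\\s+k\\s+l", block)]
    if (!length(block)) return(NULL)
    m <- utils::read.table(text = block)
    data.frame(h = m[, 1], k = m[, 2], l = m[, 3], I = m[, 4],
               sigma = m[, 5], frameId = i - 1L)
  })
  do.call(rbind, out)
}

#' Monte Carlo merge of indexed observations
#'
#' Groups observations by their asymmetric-unit indices and averages: the
#' merged intensity is the unweighted arithmetic mean (the canonical Monte
#' Carlo estimator for randomly partial still-shot measurements), its sigma
#' the standard error `sd/sqrt(n)` (falling back to the observation's own
#' sigma for singletons), and the two half-set means are taken over even-
#' and odd-numbered frames. Invariant to observation order and to replacing
#' any hkl by a symmetry equivalent.
#'
#' @param obs data.frame (h, k, l, I, sigma, frameId).
#' @param weighted use inverse-variance weighting instead of the unweighted
#'   mean (not the canonical serial-merging estimator; off by default).
#' @return data.frame of merged reflections: h, k, l (asymmetric unit),
#'   I, sigma, multiplicity, iEven, iOdd (NA when a half is empty).
#' @export
mergeMonteCarlo <- function(obs, weighted = FALSE) {
  stopIfNot(nrow(obs) >= 1, "need at least one observation")
  asu <- reduceToASU(as.matrix(obs[, c("h", "k", "l")]))
  dt <- data.table::data.table(
    h = asu[, 1], k = asu[, 2], l = asu[, 3],
    I = obs$I, s = obs$sigma, even = obs$frameId %% 2 == 0)
  merged <- if (weighted) {
    dt[, {
      w <- 1 / s^2
      list(I = sum(w * I) / sum(w),
           sigma = if (.N >= 2) stats::sd(I) / sqrt(.N) else s[1],
           multiplicity = .N,
           iEven = if (any(even)) mean(I[even]) else NA_real_,
           iOdd = if (any(!even)) mean(I[!even]) else NA_real_)
    }, by = c("h", "k", "l")]
  } else {
    dt[, list(I = mean(I),
              sigma = if (.N >= 2) stats::sd(I) / sqrt(.N) else s[1],
              multiplicity = .N,
              iEven = if (any(even)) mean(I[even]) else NA_real_,
              iOdd = if (any(!even)) mean(I[!even]) else NA_real_),
       by = c("h", "k", "l")]
  }
  out <- as.data.frame(merged)
  out[order(out$h, out$k, out$l), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Resolution shells with equal reciprocal volume
#'
#' Default shell edges divide the 1/d^3 range into `n` equal-volume bins,
#' so each shell holds a comparable number of reflections.
#'
#' @param dMax,dMin resolution range (Angstrom).
#' @param n number of shells.
#' @return numeric vector of n + 1 shell edges, decreasing from dMax to dMin.
#' @export
resolutionShells <- function(dMax, dMin, n = 10) {
  s <- seq(dMax^-3, dMin^-3, length.out = n + 1)
  s^(-1 / 3)
}

#' Half-dataset agreement statistics
#'
#' For merged reflections with both half-set means defined:
#' `R_split = 2^(-1/2) * sum(|I1 - I2|) / (0.5 * sum(I1 + I2))` and
#' CC1/2 = Pearson correlation of the half-set intensities; computed overall
#' and, when a shell grid and cell are given, per shell. Shells with fewer
#' than two usable reflections are flagged undefined (NA).
#'
#' @param merged data.frame from [mergeMonteCarlo()].
#' @param shells optional vector of shell edges (see [resolutionShells()]).
#' @param cell [UnitCell-class], required with `shells`.
#' @return list with `overall` (data.frame: rSplit, cc12, n) and, when
#'   shells are requested, `byShell` (data.frame with shell edges, rSplit,
#'   cc12, n).
#' @export
halfSetStats <- function(merged, shells = NULL, cell = NULL) {
  use <- !is.na(merged$iEven) & !is.na(merged$iOdd)
  stopIfNot(sum(use) >= 2, "need >= 2 reflections with both halves populated")
  one <- function(e, o) {
    if (length(e) < 2)
      return(data.frame(rSplit = NA_real_, cc12 = NA_real_, n = length(e)))
    data.frame(
      rSplit = (1 / sqrt(2)) * sum(abs(e - o)) / (0.5 * sum(e + o)),
      cc12 = stats::cor(e, o),
      n = length(e))
  }
  res <- list(overall = one(merged$iEven[use], merged$iOdd[use]))
  if (!is.null(shells)) {
    stopIfNot(!is.null(cell), "per-shell statistics need the unit cell")
    d <- dSpacing(as.matrix(merged[, c("h", "k", "l")]), cell)
    rows <- lapply(seq_len(length(shells) - 1), function(i) {
      sel <- use & d <= shells[i] & d > shells[i + 1]
      cbind(dHigh = shells[i], dLow = shells[i + 1],
            one(merged$iEven[sel], merged$iOdd[sel]))
    })
    res$byShell <- do.call(rbind, rows)
  }
  res
}

#' Full per-shell merging-quality table with resolution-cutoff report
#'
#' Computes, overall and per shell: R_split and CC1/2 (half-set statistics),
#' `R_merge(I) = sum|I_i - <I>| / sum I_i` over all observations,
#' R_merge(F) analogously on `sqrt(max(I, 0))`, completeness against
#' [enumerateUnique()], mean multiplicity and mean I/sigma(I). Also reports
#' two high-resolution cutoffs, walking shells from low to high resolution
#' and keeping the finest shell up to which the criterion chain is unbroken:
#' the conservative rule (mean I/sigma > 2 and R_split <= 0.5) and the
#' progressive rule (CC1/2 > 0.135).
#'
#' @param merged data.frame from [mergeMonteCarlo()].
#' @param obs the observation data.frame that produced `merged`.
#' @param cell a [UnitCell-class].
#' @param dMax,dMin resolution range (Angstrom).
#' @param nShells number of equal-volume shells.
#' @param dropAbsences absence convention for the completeness denominator.
#' @param isigCut,rsplitCut,cc12Cut cutoff-rule thresholds.
#' @return list: `overall` (one-row data.frame), `byShell` (data.frame),
#'   `conservativeCutoff` and `progressiveCutoff` (d in Angstrom, NA when
#'   even the first shell fails).
#' @export
datasetTable <- function(merged, obs, cell, dMax, dMin, nShells = 10,
                         dropAbsences = FALSE, isigCut = 2, rsplitCut = 0.5,
                         cc12Cut = 0.135) {
  shells <- resolutionShells(dMax, dMin, nShells)
  uniq <- enumerateUnique(cell, dMax, dMin, dropAbsences = dropAbsences)
  dM <- dSpacing(as.matrix(merged[, c("h", "k", "l")]), cell)
  asuObs <- reduceToASU(as.matrix(obs[, c("h", "k", "l")]))
  dO <- dSpacing(asuObs, cell)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  mergedKey <- key(as.matrix(merged[, c("h", "k", "l")]))
  iMean <- stats::setNames(merged$I, mergedKey)[key(asuObs)]
  absDev <- abs(obs$I - iMean)
  fObs <- sqrt(pmax(obs$I, 0)); fMean <- sqrt(pmax(iMean, 0))
  absDevF <- abs(fObs - fMean)
  hs <- halfSetStats(merged, shells, cell)
  shellRow <- function(selM, selO, half) {
    inRange <- sum(selM)
    data.frame(
      nUnique = inRange,
      nObs = sum(selO),
      completeness = NA_real_,  # filled by caller (needs enumeration count)
      multiplicity = if (inRange) sum(selO) / inRange else NA_real_,
      meanIsig = if (inRange) mean(merged$I[selM] / merged$sigma[selM])
      else NA_real_,
      rMergeI = if (sum(selO) && sum(obs$I[selO]) != 0)
        sum(absDev[selO]) / sum(obs$I[selO]) else NA_real_,
      rMergeF = if (sum(selO) && sum(fObs[selO]) != 0)
        sum(absDevF[selO]) / sum(fObs[selO]) else NA_real_,
      rSplit = half$rSplit, cc12 = half$cc12)
  }
  byShell <- do.call(rbind, lapply(seq_len(nShells), function(i) {
    selM <- dM <= shells[i] & dM > shells[i + 1]
    selO <- dO <= shells[i] & dO > shells[i + 1]
    row <- shellRow(selM, selO, hs$byShell[i, c("rSplit", "cc12")])
    nTheory <- sum(uniq$d <= shells[i] & uniq$d > shells[i + 1])
    row$completeness <- if (nTheory) row$nUnique / nTheory else NA_real_
    cbind(dHigh = shells[i], dLow = shells[i + 1], row)
  }))
  selAllM <- dM <= dMax & dM >= dMin
  selAllO <- dO <= dMax & dO >= dMin
  overall <- shellRow(selAllM, selAllO, hs$overall[, c("rSplit", "cc12")])
  overall$completeness <- overall$nUnique / nrow(uniq)
  consOK <- with(byShell, !is.na(meanIsig) & !is.na(rSplit) &
                   meanIsig > isigCut & rSplit <= rsplitCut)
  progOK <- with(byShell, !is.na(cc12) & cc12 > cc12Cut)
  lastTrue <- function(okv) {
    if (!length(okv) || !okv[1]) return(NA_real_)
    bad <- which(!okv)[1]
    idx <- if (is.na(bad)) length(okv) else bad - 1L
    byShell$dLow[idx]
  }
  list(overall = overall, byShell = byShell,
       conservativeCutoff = lastTrue(consOK),
       progressiveCutoff = lastTrue(progOK))
}
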