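## Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

## A small synthetic study system with a fitted model: 60 x 60 cells,
## 100 presences, 2000 background. Big enough for the model to recover
## the niche, small enough for seconds-scale tests.
smallSystem <- function() {
  if (!is.null(.fixtures$small)) return(.fixtures$small)
  spec <- syntheticSpec(nrow = 60, ncol = 60, nPresences = 100, seed = 421)
  stacks <- makeClimateSeries(spec)
  present <- stacks$present
  truth <- trueSuitability(present, spec)
  bias <- syntheticBias(spec, truth)
  occ <- sampleOccurrences(truth, bias, 100, seed = 422)
  bg <- sampleBackground(bias, 2000, seed = 423)
  pv <- extractValues(present, occ)
  bv <- extractValues(present, bg)
  fit <- fitMaxentOnValues(pv, bv)
  .fixtures$small <- list(spec = spec, stacks = stacks, present = present,
                          truth = truth, bias = bias, occ = occ, bg = bg,
                          pv = pv, bv = bv, fit = fit)
  .fixtures$small
}

## The full-size synthetic system at the recovery-study conditions:
## 120 x 120 cells of 10 km, 6 variables, 200 presences, 5000 background.
fullSystem <- function() {
  if (!is.null(.fixtures$full)) return(.fixtures$full)
  spec <- syntheticSpec(seed = 97)
  stacks <- makeClimateSeries(spec)
  present <- stacks$present
  truth <- trueSuitability(present, spec)
  bias <- syntheticBias(spec, truth)
  occ <- sampleOccurrences(truth, bias, 200, seed = 98)
  bg <- sampleBackground(bias, 5000, seed = 99)
  pv <- extractValues(present, occ)
  bv <- extractValues(present, bg)
  fit <- fitMaxentOnValues(pv, bv)
  .fixtures$full <- list(spec = spec, stacks = stacks, present = present,
                         truth = truth, bias = bias, occ = occ, bg = bg,
                         pv = pv, bv = bv, fit = fit)
  .fixtures$full
}

## Exhaustive maximum-independent-set oracle on the < minDist conflict
## graph: enumerates all subsets (n <= ~15).
misOracleSize <- function(xy, minDistKm) {
  n <- nrow(xy)
  if (n == 0) return(0L)
  D <- as.matrix(stats::dist(xy)) / 1000
  best <- 0L
  for (code in 0:(2^n - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (length(members) <= best) next
    ok <- TRUE
    if (length(members) > 1) {
      sub <- D[members, members]
      ok <- all(sub[upper.tri(sub)] >= minDistKm)
    }
    if (ok) best <- length(members)
  }
  best
}

## O(n^2) pair-counting AUC oracle (ties count one half).
aucOracle <- function(sp, sb) {
  wins <- 0
  for (p in sp) for (b in sb) wins <- wins + (p > b) + 0.5 * (p == b)
  wins / (length(sp) * length(sb))
}

## Exhaustive-scan threshold oracle: max sens + spec over observed scores,
## smallest maximiser.
mtssOracle <- function(sp, sb) {
  cand <- sort(unique(c(sp, sb)))
  best <- -Inf; bestT <- NA
  for (t in cand) {
    v <- mean(sp >= t) + mean(sb < t)
    if (v > best) { best <- v; bestT <- t }
  }
  bestT
}

## Clear the suitable cells of the top `k` rows, then translate the range
## north by `k` rows: the translated map's centroid is exactly k cells
## north of the truncated early map's.
shiftRangeNorth <- function(bmap, k) {
  s <- bmap@suitable
  s[seq_len(k), ] <- FALSE
  early <- new("BinaryMap", suitable = s, mask = bmap@mask,
               threshold = bmap@threshold, period = bmap@period,
               xll = bmap@xll, yll = bmap@yll, cellSize = bmap@cellSize)
  nr <- nrow(s)
  s2 <- rbind(s[(k + 1):nr, , drop = FALSE],
              matrix(FALSE, k, ncol(s)))
  late <- new("BinaryMap", suitable = s2, mask = bmap@mask,
              threshold = bmap@threshold, period = "shifted",
              xll = bmap@xll, yll = bmap@yll, cellSize = bmap@cellSize)
  list(early = early, late = late)
}

## A tiny on-disk pipeline fixture (44 x 44 cells, 60 presences) and a
## fast matching run configuration.
tinyFixture <- function(dir, seed = 11) {
  spec <- syntheticSpec(nrow = 44, ncol = 44, nPresences = 60,
                        seed = seed, corrLengthKm = 40)
  writeFixture(spec, dir)
  spec
}

tinyConfig <- function(fixtureDir, outDir, seed = 3) {
  list(stackDirs = list(LGM = file.path(fixtureDir, "LGM"),
                        present = file.path(fixtureDir, "present"),
                        `2080` = file.path(fixtureDir, "2080")),
       occurrencePath = file.path(fixtureDir, "occurrences.csv"),
       outDir = outDir, seed = seed,
       replicates = 2, backgroundN = 900, minDistKm = 15,
       doJackknife = FALSE, nHingeKnots = 6, verbose = FALSE)
}

## Carve well-separated patches out of a binary range: suitable cells
## within `radiusKm` of lattice points spaced `spacingKm` apart. Nearest-
## centroid matching is only identifiable when source patches are farther
## apart than the imposed displacement, so shift-recovery diagnostics use
## this sparsified range.
sparsePatches <- function(bmap, spacingKm = 240, radiusKm = 20) {
  cc <- cellCenters(bmap)
  sp <- spacingKm * 1000; rad <- radiusKm * 1000
  cx <- seq(bmap@xll + sp / 2, max(cc$x), by = sp)
  cy <- seq(bmap@yll + sp / 2, max(cc$y), by = sp)
  keep <- matrix(FALSE, nrow(bmap@suitable), ncol(bmap@suitable))
  for (x0 in cx) for (y0 in cy)
    keep <- keep | ((cc$X - x0)^2 + (cc$Y - y0)^2 <= rad^2)
  s <- bmap@suitable & keep
  new("BinaryMap", suitable = s, mask = bmap@mask,
      threshold = bmap@threshold, period = bmap@period,
      xll = bmap@xll, yll = bmap@yll, cellSize = bmap@cellSize)
}
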