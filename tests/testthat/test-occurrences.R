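occCsv <- function(df) {
  p <- tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  p
}

test_that("occurrence CSV ingestion enforces the id,x,y schema", {
  p <- occCsv(data.frame(id = c("a", "b", "c"), x = 1:3 * 1000,
                         y = c(0, 500, 900)))
  occ <- readOccurrences(p)
  expect_equal(nrow(occ@points), 3)

  p2 <- occCsv(data.frame(id = c("a", "b"), x = 1:2))
  expect_error(readOccurrences(p2), "y")

  p3 <- occCsv(data.frame(id = c("a", "a"), x = 1:2, y = 1:2))
  expect_error(readOccurrences(p3), "duplicate")

  p4 <- occCsv(data.frame(id = c("a", "b"), x = c("one", "2"), y = 1:2))
  expect_error(readOccurrences(p4), "numeric")
})

mkOcc <- function(xKm, yKm, ids = sprintf("p%02d", seq_along(xKm))) {
  new("OccurrenceSet",
      points = data.frame(id = ids, x = xKm * 1000, y = yKm * 1000,
                          stringsAsFactors = FALSE),
      sourceLabel = "test")
}

test_that("thinning keeps the two ends of a tight collinear triple", {
  occ <- mkOcc(c(0, 6, 12), c(0, 0, 0))
  thin <- thinOccurrences(occ, 10)
  expect_equal(sort(thin@points$id), c("p01", "p03"))
})

test_that("thinning returns the input when no pair conflicts", {
  occ <- mkOcc(c(0, 20, 40, 60), c(0, 0, 0, 0))
  thin <- thinOccurrences(occ, 10)
  expect_identical(thin@points[, c("id", "x", "y")],
                   occ@points[, c("id", "x", "y")])
})

test_that("thinned cardinality matches the exhaustive subset oracle (n <= 12)", {
  for (trial in 1:25) {
    set.seed(1000 + trial)
    n <- sample(4:12, 1)
    xy <- cbind(runif(n, 0, 80) * 1000, runif(n, 0, 80) * 1000)
    d <- as.matrix(dist(xy)) / 1000
    minDist <- as.numeric(quantile(d[upper.tri(d)], 0.3))
    occ <- mkOcc(xy[, 1] / 1000, xy[, 2] / 1000)
    thin <- thinOccurrences(occ, minDist)
    # validity: all pairwise distances respect the minimum
    if (nrow(thin@points) > 1) {
      dd <- as.matrix(dist(cbind(thin@points$x, thin@points$y))) / 1000
      expect_gte(min(dd[upper.tri(dd)]), minDist)
    }
    expect_equal(nrow(thin@points), misOracleSize(xy, minDist))
  }
})

test_that("large conflict components fall back to a seeded greedy search", {
  set.seed(55)
  xy <- cbind(runif(40, 0, 30), runif(40, 0, 30))   # one dense blob, km
  occ <- mkOcc(xy[, 1], xy[, 2])
  t1 <- thinOccurrences(occ, 8)
  t2 <- thinOccurrences(occ, 8)
  expect_identical(t1@points, t2@points)            # deterministic
  dd <- as.matrix(dist(cbind(t1@points$x, t1@points$y))) / 1000
  expect_gte(min(dd[upper.tri(dd)]), 8)
  expect_lt(nrow(t1@points), nrow(occ@points))
})

test_that("bias surface follows the truncated Gaussian kernel", {
  tmpl <- newGrid(matrix(0, 21, 21), cellSize = 10000)
  cc <- cellCenters(tmpl)
  occ <- mkOcc(cc$X[11, 11] / 1000, cc$Y[11, 11] / 1000)   # centre cell
  b <- biasSurface(occ, tmpl, radiusKm = 30)
  v <- gridValues(b)
  expect_equal(which(v == max(v)), (11 - 1) * 21 + 11)      # peak at point
  # value at distance exactly sigma (3 cells east) is exp(-1/2) of the peak
  expect_equal(v[11, 14] / v[11, 11], exp(-0.5))
  # truncated beyond 3 sigma (>9 cells away)
  expect_equal(v[11, 21], 0)

  # mirror-symmetric points give a mirror-symmetric surface
  occ2 <- mkOcc(c(cc$X[11, 5], cc$X[11, 17]) / 1000,
                c(cc$Y[11, 11], cc$Y[11, 11]) / 1000)
  b2 <- gridValues(biasSurface(occ2, tmpl, radiusKm = 40))
  expect_equal(b2, b2[, 21:1])

  # no localities: uniform fallback of 1
  b3 <- biasSurface(mkOcc(numeric(0), numeric(0), character(0)), tmpl, 60)
  expect_true(all(gridValues(b3) == 1))
})

test_that("bias surface is translation-equivariant away from edges", {
  tmpl <- newGrid(matrix(0, 30, 30), cellSize = 10000)
  cc <- cellCenters(tmpl)
  a <- biasSurface(mkOcc(cc$X[15, 14] / 1000, cc$Y[15, 14] / 1000),
                   tmpl, 20)
  b <- biasSurface(mkOcc(cc$X[15, 15] / 1000, cc$Y[15, 15] / 1000),
                   tmpl, 20)
  expect_equal(gridValues(a)[10:20, 8:20], gridValues(b)[10:20, 9:21])
})

test_that("background sampling is bias-weighted, exclusive and seeded", {
  one <- matrix(0, 5, 5); one[2, 3] <- 1
  bias1 <- newGrid(one, cellSize = 1000)
  bs <- sampleBackground(bias1, 1, seed = 1)
  expect_equal(bs@points$cell, (3 - 1) * 5 + 2)

  biasU <- newGrid(matrix(1, 40, 40), cellSize = 1000)
  b1 <- sampleBackground(biasU, 500, seed = 9)
  b2 <- sampleBackground(biasU, 500, seed = 9)
  expect_identical(b1@points, b2@points)

  # uniform bias: draw frequencies over repeated draws pass a chi-square
  counts <- integer(1600)
  for (s in 1:40) {
    bs <- sampleBackground(biasU, 100, seed = 2000 + s)
    counts[bs@points$cell] <- counts[bs@points$cell] + 1
  }
  p <- suppressWarnings(chisq.test(counts, p = rep(1 / 1600, 1600))$p.value)
  expect_gt(p, 0.001)

  expect_error(sampleBackground(bias1, 2, seed = 1), "sampling error")
})
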