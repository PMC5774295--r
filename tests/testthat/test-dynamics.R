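test_that("maximum sensitivity-plus-specificity threshold and its scan oracle", {
  expect_equal(mtssThreshold(c(0.9, 0.8), c(0.1, 0.2)), 0.8)
  expect_equal(mtssThreshold(c(0.7, 0.3), c(0.5, 0.1)),
               mtssOracle(c(0.7, 0.3), c(0.5, 0.1)))
  expect_equal(mtssThreshold(c(0.4, 0.4), c(0.4, 0.4)), 0.4)
  set.seed(14)
  for (i in 1:10) {
    sp <- round(runif(sample(3:40, 1)), 2)
    sb <- round(runif(sample(3:60, 1)), 2)
    expect_equal(mtssThreshold(sp, sb), mtssOracle(sp, sb))
  }
})

test_that("10% training presence threshold is the right order statistic", {
  expect_equal(tenPercentTPThreshold(seq(0.1, 1.0, by = 0.1)), 0.2)
  expect_equal(tenPercentTPThreshold(c(0.5, 0.9, 0.3, 0.7, 0.8)), 0.3)
  expect_equal(tenPercentTPThreshold(rep(0.6, 7)), 0.6)
})

test_that("binarisation respects the threshold boundary and is monotone", {
  v <- matrix(c(0.1, 0.4, 0.4, 0.9), 2, 2)
  g <- newGrid(v, cellSize = 1000)
  expect_equal(sum(binarize(g, 0, "p")@suitable), 4)
  expect_equal(sum(binarize(g, 0.95, "p")@suitable), 0)
  expect_true(binarize(g, 0.4, "p")@suitable[2, 1])    # score == t counts
  set.seed(5)
  gg <- newGrid(matrix(runif(400), 20, 20), cellSize = 1000)
  b1 <- binarize(gg, 0.3, "p")@suitable
  b2 <- binarize(gg, 0.6, "p")@suitable
  expect_true(all(b1[b2]))                             # nested ranges
})

bmapOf <- function(m, cellSize = 10000, period = "p", xll = 0, yll = 0) {
  new("BinaryMap", suitable = m, mask = matrix(FALSE, nrow(m), ncol(m)),
      threshold = 0.5, period = period, xll = xll, yll = yll,
      cellSize = cellSize)
}

test_that("change classification enumerates a hand-built 3x3 pair", {
  early <- bmapOf(matrix(c(TRUE, TRUE, FALSE,
                           TRUE, FALSE, FALSE,
                           FALSE, FALSE, FALSE), 3, 3, byrow = TRUE),
                  period = "early")
  late <- bmapOf(matrix(c(FALSE, TRUE, TRUE,
                          FALSE, TRUE, TRUE,
                          FALSE, FALSE, FALSE), 3, 3, byrow = TRUE),
                 period = "late")
  cm <- changeMap(early, late)
  expect_equal(cm@pairLabel, "early->late")
  exp <- matrix(c(1, 2, 3,
                  1, 3, 3,
                  0, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(cm@classes, matrix(as.integer(exp), 3, 3))

  cmSame <- changeMap(early, early)
  expect_true(all(cmSame@classes %in% c(0L, 2L)))
  cmFromEmpty <- changeMap(bmapOf(matrix(FALSE, 3, 3)), late)
  expect_equal(sum(cmFromEmpty@classes == 3L), sum(late@suitable))
  expect_error(changeMap(early, bmapOf(matrix(FALSE, 4, 4))), "alignment")
})

test_that("change accounting satisfies the period-area identities", {
  set.seed(8)
  for (i in 1:10) {
    e <- bmapOf(matrix(runif(225) < 0.4, 15, 15))
    l <- bmapOf(matrix(runif(225) < 0.5, 15, 15))
    ct <- changeTable(changeMap(e, l))
    a <- setNames(ct$areaKm2, ct$class)
    expect_equal(a[["contraction"]] + a[["no_change"]],
                 areaOf(e@suitable, 100))
    expect_equal(a[["no_change"]] + a[["expansion"]],
                 areaOf(l@suitable, 100))
  }
  ctSame <- changeTable(changeMap(e, e))
  expect_equal(ctSame$areaKm2[ctSame$class == "contraction"], 0)
  expect_equal(ctSame$areaKm2[ctSame$class == "expansion"], 0)
  if (any(e@suitable))
    expect_equal(ctSame$ratioPct[ctSame$class == "no_change"], 100.0)
})

test_that("ratios are undefined (not zero) when a period area is zero", {
  cr <- changeRatios(0, 0, 50)
  expect_true(is.na(cr$ratios[["contraction"]]))
  expect_true(is.na(cr$ratios[["noChange"]]))
  expect_equal(cr$ratios[["expansion"]], 100.0)
})

test_that("centroids average suitable-cell centres", {
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  b <- bmapOf(m)
  cc <- cellCenters(b)
  expect_equal(overallCentroid(b), c(x = cc$X[3, 3], y = cc$Y[3, 3]))

  m2 <- matrix(FALSE, 5, 5); m2[1, 1] <- TRUE; m2[5, 5] <- TRUE
  expect_equal(overallCentroid(bmapOf(m2)), c(x = 25000, y = 25000))

  mL <- matrix(FALSE, 5, 5); mL[4, 2] <- mL[5, 2] <- mL[5, 3] <- TRUE
  expect_equal(overallCentroid(bmapOf(mL)),
               c(x = mean(c(cc$X[4, 2], cc$X[5, 2], cc$X[5, 3])),
                 y = mean(c(cc$Y[4, 2], cc$Y[5, 2], cc$Y[5, 3]))))
  expect_error(overallCentroid(bmapOf(matrix(FALSE, 5, 5))), "centroid")
})

test_that("centroid vectors recover constructed shifts", {
  m <- matrix(FALSE, 12, 12); m[8:10, 3:5] <- TRUE
  early <- bmapOf(m)
  v0 <- centroidVector(early, early)
  expect_equal(v0$distanceKm, 0)

  mN <- matrix(FALSE, 12, 12); mN[3:5, 3:5] <- TRUE   # 5 cells north
  vN <- centroidVector(early, bmapOf(mN, period = "late"))
  expect_equal(vN$distanceKm, 50)
  expect_equal(vN$bearingDeg, 0)

  mNE <- matrix(FALSE, 12, 12); mNE[4:6, 6:8] <- TRUE # east 3, north 4
  vNE <- centroidVector(early, bmapOf(mNE))
  expect_equal(vNE$distanceKm, 50)
  expect_equal(vNE$bearingDeg, atan2(3, 4) * 180 / pi, tolerance = 1e-10)
})

test_that("block centroids aggregate suitable cells per origin-anchored tile", {
  m <- matrix(FALSE, 12, 12); m[2, 3] <- TRUE
  b <- bmapOf(m)                                 # 10-km cells, 60-km blocks
  cc <- cellCenters(b)
  bc <- blockCentroids(b, 60)
  expect_equal(nrow(bc), 1)
  expect_equal(c(bc$x, bc$y), c(cc$X[2, 3], cc$Y[2, 3]))

  mFull <- matrix(FALSE, 12, 12); mFull[7:12, 1:6] <- TRUE  # a full SW tile
  bcF <- blockCentroids(bmapOf(mFull), 60)
  expect_equal(c(bcF$x, bcF$y), c(30000, 30000))  # tile centre
  expect_equal(bcF$nCells, 36)

  mTwo <- matrix(FALSE, 12, 12)
  mTwo[12, 1] <- mTwo[12, 2] <- TRUE               # two cells, SW tile
  mTwo[1, 12] <- TRUE                              # one cell, NE tile
  bc2 <- blockCentroids(bmapOf(mTwo), 60)
  expect_equal(nrow(bc2), 2)
  sw <- bc2[1, ]; ne <- bc2[2, ]
  expect_equal(c(sw$x, sw$y), c(mean(c(5000, 15000)), 5000))
  expect_equal(c(ne$x, ne$y), c(115000, 115000))
  expect_equal(nrow(blockCentroids(bmapOf(matrix(FALSE, 12, 12)), 60)), 0)
})

test_that("migration vectors match each late centroid to its nearest source", {
  e <- data.frame(x = c(0, 200000), y = c(0, 0))
  mv0 <- migrationVectors(e, e)
  expect_equal(mv0$distanceKm, c(0, 0))

  l <- data.frame(x = c(0, 200000), y = c(70000, 70000))
  mv <- migrationVectors(e, l, "a->b")
  expect_equal(mv$distanceKm, c(70, 70))
  expect_equal(mv$bearingDeg, c(0, 0))
  expect_equal(attr(mv, "pairLabel"), "a->b")

  one <- migrationVectors(data.frame(x = 0, y = 0),
                          data.frame(x = 30000, y = 40000))
  expect_equal(one$distanceKm, 50)
  expect_error(migrationVectors(e[0, ], l), "matching error")

  # an early patch matched by nothing is reported, not vectorised
  e2 <- data.frame(x = c(0, 500000), y = c(0, 0))
  l2 <- data.frame(x = 10000, y = 0)
  mv2 <- migrationVectors(e2, l2)
  expect_equal(nrow(mv2), 1)
  expect_equal(attr(mv2, "unmatchedEarly")$x, 500000)
})
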