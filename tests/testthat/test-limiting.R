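## A tiny hand-specified model: linear features only, known lambdas.
toyModel <- function(lams, vars = names(lams), bounds = NULL,
                     backgroundValues) {
  if (is.null(bounds))
    bounds <- rbind(lo = apply(backgroundValues, 2, min),
                    hi = apply(backgroundValues, 2, max))
  features <- list(classes = "linear", variables = vars,
                   bounds = bounds[, vars, drop = FALSE], nHingeKnots = 0,
                   table = data.frame(class = "linear", variable = vars,
                                      knot = NA_real_,
                                      stringsAsFactors = FALSE))
  X <- featureMatrix(features, backgroundValues)
  eta <- as.vector(X %*% lams)
  logZ <- log(sum(exp(eta)))
  q <- exp(eta - logZ)
  new("MaxentModel", features = features, lambdas = unname(lams),
      beta = 1, betaJ = rep(0, length(lams)), logZ = logZ,
      entropyH = -sum(q * log(q)), gain = 0,
      trainInfo = list(nPresence = 10, nBackground = nrow(backgroundValues),
                       converged = TRUE, iterations = 0))
}

stack22 <- function(aVals, bVals) {
  buildStack(list(a = newGrid(aVals, cellSize = 1000),
                  b = newGrid(bVals, cellSize = 1000)), "p")
}

test_that("limiting-factor attribution follows the substitution argmax", {
  set.seed(40)
  bv <- cbind(a = runif(100), b = runif(100))
  a <- matrix(c(0.1, 0.9, 0.4, 0.6), 2, 2)
  b <- matrix(c(0.8, 0.2, 0.5, 0.3), 2, 2)
  stack <- stack22(a, b)
  means <- c(a = 0.7, b = 0.6)

  # only one variable carries weight: every attributed cell names it
  m1 <- toyModel(c(a = 3, b = 0), backgroundValues = bv)
  lf1 <- limitingFactorMap(m1, stack, means)
  attributed <- lf1@factorIndex[!is.na(lf1@factorIndex)]
  expect_true(all(attributed == 1))

  # two active variables: verify the argmax per cell by direct enumeration
  m2 <- toyModel(c(a = 2, b = -1.5), backgroundValues = bv)
  lf2 <- limitingFactorMap(m2, stack, means)
  vals <- stackValues(stack)
  base <- predictScores(m2, vals)
  for (cell in 1:4) {
    deltas <- sapply(c("a", "b"), function(v) {
      sub <- vals[cell, , drop = FALSE]
      sub[1, v] <- means[[v]]
      predictScores(m2, sub) - base[cell]
    })
    want <- if (max(deltas) > 0) which.max(deltas) else NA_integer_
    expect_equal(lf2@factorIndex[cell], as.integer(want))
  }

  # a cell already at the presence means is unattributed
  stackAtMeans <- stack22(matrix(0.7, 2, 2), matrix(0.6, 2, 2))
  lf3 <- limitingFactorMap(m2, stackAtMeans, means)
  expect_true(all(is.na(lf3@factorIndex)))
})

test_that("adding a zero-coefficient variable never claims attribution", {
  set.seed(41)
  bv <- cbind(a = runif(100), b = runif(100), c = runif(100))
  stack <- buildStack(list(a = newGrid(matrix(runif(16), 4, 4), cellSize = 1000),
                           b = newGrid(matrix(runif(16), 4, 4), cellSize = 1000),
                           c = newGrid(matrix(runif(16), 4, 4), cellSize = 1000)),
                      "p")
  m <- toyModel(c(a = 2, b = -1, c = 0), backgroundValues = bv)
  lf <- limitingFactorMap(m, stack, c(a = 0.5, b = 0.5, c = 0.5))
  expect_false(any(lf@factorIndex == 3, na.rm = TRUE))
})

test_that("factor shares sum to 100 minus the unattributed share", {
  idx <- matrix(c(1L, 1L, 1L, 2L,
                  NA, 1L, 2L, 2L,
                  NA, NA, NA, NA), 3, 4, byrow = TRUE)
  lf <- new("LimitingFactorMap", factorIndex = idx,
            variables = c("bio6", "bio12"),
            referenceValues = c(bio6 = 0, bio12 = 0),
            mask = matrix(FALSE, 3, 4), xll = 0, yll = 0, cellSize = 1000)
  cls <- matrix(1L, 3, 4)                       # everything "contraction"
  cm <- new("ChangeMap", classes = cls, mask = matrix(FALSE, 3, 4),
            pairLabel = "e->l", xll = 0, yll = 0, cellSize = 1000)
  fs <- factorShares(lf, cm, "contraction")
  expect_equal(fs$nCells, 12)
  expect_equal(fs$shares$pct[fs$shares$variable == "bio6"],
               roundHalfAwayFromZero(100 * 4 / 12, 1))
  expect_equal(fs$shares$variable[1], "bio6")   # descending order
  expect_equal(sum(fs$shares$pct) + fs$nonePct,
               roundHalfAwayFromZero(100 * 4 / 12, 1) +
                 roundHalfAwayFromZero(100 * 3 / 12, 1) +
                 roundHalfAwayFromZero(100 * 5 / 12, 1))

  # 3:1 split
  idx2 <- matrix(c(1L, 1L, 1L, 2L), 1, 4)
  lf2 <- new("LimitingFactorMap", factorIndex = idx2,
             variables = c("A", "B"), referenceValues = c(A = 0, B = 0),
             mask = matrix(FALSE, 1, 4), xll = 0, yll = 0, cellSize = 1000)
  cm2 <- new("ChangeMap", classes = matrix(3L, 1, 4),
             mask = matrix(FALSE, 1, 4), pairLabel = "e->l",
             xll = 0, yll = 0, cellSize = 1000)
  fs2 <- factorShares(lf2, cm2, "expansion")
  expect_equal(fs2$shares$pct, c(75.0, 25.0))
  expect_warning(factorShares(lf2, cm2, "contraction"), "undefined")
})

test_that("variable change maps are late minus early", {
  a <- matrix(1:9, 3, 3)
  e <- buildStack(list(v = newGrid(a, cellSize = 1000)), "e")
  l <- buildStack(list(v = newGrid(a + 2, cellSize = 1000)), "l")
  expect_true(all(gridValues(variableChangeMap(e, e, "v")) == 0))
  expect_true(all(gridValues(variableChangeMap(e, l, "v")) == 2))
  expect_equal(gridValues(variableChangeMap(l, e, "v")),
               -gridValues(variableChangeMap(e, l, "v")))
})

test_that("a single-variable cooling offset claims the contraction class", {
  spec <- syntheticSpec(nrow = 50, ncol = 50, nPresences = 80, seed = 314,
                        periodOffsets = list(LGM = c(bio6 = -10),
                                             present = c(), `2080` = c()))
  stacks <- makeClimateSeries(spec)
  truth <- trueSuitability(stacks$present, spec)
  bias <- syntheticBias(spec, truth)
  occ <- sampleOccurrences(truth, bias, 80, seed = 315)
  bg <- sampleBackground(bias, 1500, seed = 316)
  pv <- extractValues(stacks$present, occ)
  fit <- fitMaxentOnValues(pv, extractValues(stacks$present, bg),
                           nHingeKnots = 8)
  t <- mtssThreshold(predictScores(fit, pv),
                     predictScores(fit, extractValues(stacks$present, bg)))
  bPres <- binarize(predictLogistic(fit, stacks$present), t, "present")
  bCold <- binarize(predictLogistic(fit, stacks$LGM), t, "LGM")
  cm <- changeMap(bPres, bCold)       # cooling-driven contraction
  lf <- limitingFactorMap(fit, stacks$LGM, colMeans(pv))
  fs <- factorShares(lf, cm, "contraction")
  expect_gt(fs$nCells, 0)
  expect_equal(fs$shares$variable[1], "bio6")   # plurality share
})
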