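test_that("feature transforms hit their defining values", {
  set.seed(3)
  v <- cbind(a = runif(50, 10, 30))
  fb <- buildFeatures(v, nHingeKnots = 1)   # single knot at the midpoint
  lo <- min(v); hi <- max(v); mid <- (lo + hi) / 2
  X <- featureMatrix(fb$features, cbind(a = c(lo, hi, mid)))
  expect_equal(unname(X[1, "linear.a"]), 0)
  expect_equal(unname(X[2, "linear.a"]), 1)
  expect_equal(unname(X[2, "quadratic.a"]), 1)
  expect_equal(X[3, grep("hinge", colnames(X))], 0, ignore_attr = TRUE)
  expect_true(all(X >= 0 & X <= 1))
  expect_warning(buildFeatures(cbind(a = v[, 1], flat = rep(2, 50))),
                 "constant")
})

test_that("a single constant feature yields the uniform model", {
  P <- matrix(1, 5, 1); B <- matrix(1, 100, 1)
  colnames(P) <- colnames(B) <- "f"
  features <- list(classes = "linear", variables = "f",
                   bounds = rbind(lo = 0, hi = 1), nHingeKnots = 0,
                   table = data.frame(class = "linear", variable = "f",
                                      knot = NA_real_))
  fit <- suppressWarnings(fitMaxent(P, B, features))
  expect_equal(fit@lambdas, 0)
  expect_equal(fit@entropyH, log(100))
  expect_equal(fit@gain, 0)
})

test_that("one-binary-feature fit matches a 1-D numerical maximiser", {
  m <- 40; n <- 400
  P <- matrix(1, m, 1)                      # all presences have f = 1
  B <- matrix(rep(c(1, 0), each = n / 2), n, 1)
  colnames(P) <- colnames(B) <- "f"
  features <- list(classes = "linear", variables = "f",
                   bounds = rbind(lo = 0, hi = 1), nHingeKnots = 0,
                   table = data.frame(class = "linear", variable = "f",
                                      knot = NA_real_))
  fit <- suppressWarnings(fitMaxent(P, B, features))
  s <- max(sd(P[, 1]), 0.05 * 1)            # sd floor engages (sd = 0)
  betaJ <- s / sqrt(m)
  obj <- function(l) l - log(sum(exp(B[, 1] * l))) - betaJ * abs(l)
  opt <- optimize(obj, c(-20, 20), maximum = TRUE, tol = 1e-10)
  expect_equal(fit@lambdas, opt$maximum, tolerance = 1e-4)
  # fitted raw mass on the presence class matches the oracle's
  qMass <- sum(exp(B[, 1] * fit@lambdas - fit@logZ)[B[, 1] == 1])
  qOracle <- sum(exp(B[, 1] * opt$maximum)[B[, 1] == 1]) /
    sum(exp(B[, 1] * opt$maximum))
  expect_equal(qMass, qOracle, tolerance = 1e-5)
})

test_that("the fitted raw distribution normalises over the background", {
  sys <- smallSystem()
  fit <- sys$fit
  X <- featureMatrix(fit@features, sys$bv)
  q <- exp(as.vector(X %*% fit@lambdas) - fit@logZ)
  expect_lt(abs(sum(q) - 1), 1e-8)
  expect_gte(fit@entropyH, 0)
  expect_gte(fit@gain, 0)
})

test_that("heavy regularisation collapses to the uniform 0.5 surface", {
  sys <- smallSystem()
  fit <- fitMaxentOnValues(sys$pv, sys$bv, beta = 1e6)
  expect_true(all(fit@lambdas == 0))
  pred <- predictLogistic(fit, sys$present)
  expect_equal(unique(as.vector(gridValues(pred))), 0.5)
})

test_that("rank AUC matches its defining examples and the pair oracle", {
  expect_equal(evaluateAUC(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(evaluateAUC(c(0.3, 0.7), c(0.3, 0.7)), 0.5)
  expect_equal(evaluateAUC(c(0.8, 0.4), c(0.6, 0.2)), 0.75)
  set.seed(12)
  for (i in 1:5) {
    sp <- round(runif(30), 2)               # rounding forces ties
    sb <- round(runif(45), 2)
    expect_equal(evaluateAUC(sp, sb), aucOracle(sp, sb))
  }
})

test_that("projection is consistent between training and identical stacks,
           and clamping pins values beyond the training range", {
  sys <- smallSystem()
  fit <- sys$fit
  sc1 <- predictScores(fit, sys$bv[1:10, , drop = FALSE])
  pred <- predictLogistic(fit, sys$present)
  idx <- cellIndexAt(sys$present@layers[[1]],
                     sys$bg@points$x[1:10], sys$bg@points$y[1:10])
  expect_equal(as.vector(gridValues(pred))[idx], sc1)

  hi <- fit@features$bounds["hi", "bio1"]
  vAtMax <- sys$bv[1, , drop = FALSE]; vAtMax[1, "bio1"] <- hi
  vBeyond <- vAtMax; vBeyond[1, "bio1"] <- hi + 50
  expect_equal(predictScores(fit, vBeyond), predictScores(fit, vAtMax))
})

test_that("replicate split arithmetic, determinism, and model storage", {
  sys <- smallSystem()
  small <- new("OccurrenceSet", points = sys$occ@points[1:8, ],
               sourceLabel = "eight")
  ev <- suppressWarnings(
    replicateRuns(small, sys$bg, sys$present, k = 1, trainFraction = 0.75,
                  seed = 42, nHingeKnots = 4))
  expect_equal(ev$replicates$nTrain, 6)
  expect_equal(ev$replicates$nTest, 2)

  e1 <- replicateRuns(sys$occ, sys$bg, sys$present, k = 2, seed = 7,
                      nHingeKnots = 8)
  e2 <- replicateRuns(sys$occ, sys$bg, sys$present, k = 2, seed = 7,
                      nHingeKnots = 8)
  expect_identical(e1$replicates, e2$replicates)
  expect_error(replicateRuns(small, sys$bg, sys$present, k = 1,
                             trainFraction = 0.1), "config error")

  p <- tempfile(fileext = ".json")
  writeLambdas(e1$model, p)
  m2 <- readLambdas(p)
  expect_equal(predictScores(m2, sys$pv), predictScores(e1$model, sys$pv))
})

test_that("replicated evaluation discriminates well on the synthetic system", {
  sys <- smallSystem()
  ev <- replicateRuns(sys$occ, sys$bg, sys$present, k = 5, seed = 19)
  expect_gt(ev$meanTestAUC, 0.8)
  expect_gt(ev$meanTrainAUC, 0.8)
  expect_true(all(ev$replicates$testAUC >= 0 & ev$replicates$testAUC <= 1))
})
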