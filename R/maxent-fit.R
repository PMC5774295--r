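## L1-penalised maximum-entropy fitting, logistic projection, AUC and
## replicate evaluation.
##
## The model is the Gibbs distribution q(x) = exp(eta(x)) / Z over the
## background cells, eta(x) = sum_j lambda_j f_j(x), fitted by maximising
## the penalised presence log-likelihood dual
##
##   O(lambda) = mean_presence(eta) - log Z_background
##               - sum_j beta_j |lambda_j|,
##
## a concave problem solved here by monotone proximal gradient descent
## (soft-thresholding for the L1 term, backtracking line search, optional
## Nesterov acceleration with a monotone safeguard).

#' Fit the maximum-entropy presence-background model
#'
#' @param presenceX,backgroundX design matrices from [buildFeatures()] /
#'   [featureMatrix()] (rows = locations, columns = features, values in
#'   `[0, 1]`).
#' @param features feature definition to store in the model.
#' @param beta regularisation multiplier; the per-feature penalty is
#'   `beta * s_j / sqrt(m)` with `s_j` the feature's presence-sample
#'   standard deviation floored at 0.05 of its observed range and `m` the
#'   presence count.
#' @param tol KKT (sub)gradient tolerance for convergence.
#' @param maxIter iteration cap; exceeding it is a fit error carrying the
#'   last objective value.
#' @return a [MaxentModel-class].
#' @export
fitMaxent <- function(presenceX, backgroundX, features, beta = 1,
                      tol = 1e-6, maxIter = 5000) {
  m <- nrow(presenceX); n <- nrow(backgroundX)
  if (m < 2) stop("need at least 2 presences")
  if (n < 10 * m)
    warning("background (", n, ") smaller than 10x presences (", m, ")")
  J <- ncol(presenceX)
  pbar <- colMeans(presenceX)
  rng <- apply(rbind(presenceX, backgroundX), 2, function(x)
    diff(range(x)))
  s <- apply(presenceX, 2, stats::sd)
  s <- pmax(s, 0.05 * rng)
  betaJ <- beta * s / sqrt(m)

  smoothF <- function(lam) {
    eta <- as.vector(backgroundX %*% lam)
    logSumExp(eta) - sum(pbar * lam)
  }
  gradF <- function(lam) {
    eta <- as.vector(backgroundX %*% lam)
    q <- exp(eta - logSumExp(eta))
    as.vector(crossprod(backgroundX, q)) - pbar
  }
  penalty <- function(lam) sum(betaJ * abs(lam))
  # coefficients live in a wide box: perfectly separating features would
  # otherwise drive lambda to infinity (their penalty can be below the
  # unpenalised gradient); the box renders such degenerate fits finite
  # and deterministic without affecting regular problems
  bound <- 200
  soft <- function(z, thr) pmin(pmax(sign(z) * pmax(abs(z) - thr, 0),
                                     -bound), bound)

  lam <- numeric(J)
  fv <- smoothF(lam)
  t <- 1
  yv <- lam            # accelerated point
  tk <- 1              # Nesterov momentum term
  converged <- FALSE
  iter <- 0
  while (iter < maxIter) {
    iter <- iter + 1
    g <- gradF(yv)
    fy <- smoothF(yv)
    repeat {
      cand <- soft(yv - t * g, t * betaJ)
      d <- cand - yv
      fc <- smoothF(cand)
      if (is.finite(fc) &&
          fc <= fy + sum(g * d) + sum(d * d) / (2 * t) + 1e-12) break
      t <- t / 2
      if (t < 1e-14) break
    }
    # monotone safeguard: never let the penalised objective worsen
    if (!is.finite(fc) || fc + penalty(cand) > fv + penalty(lam) + 1e-12) {
      g <- gradF(lam)
      fl <- smoothF(lam)
      repeat {
        cand <- soft(lam - t * g, t * betaJ)
        d <- cand - lam
        fc <- smoothF(cand)
        if (is.finite(fc) &&
            fc <= fl + sum(g * d) + sum(d * d) / (2 * t) + 1e-12) break
        t <- t / 2
        if (t < 1e-14) break
      }
    }
    tkNew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yv <- cand + ((tk - 1) / tkNew) * (cand - lam)
    tk <- tkNew
    lamPrev <- lam
    lam <- cand
    fv <- fc
    t <- t * 1.2
    # KKT residual at the new iterate (minimising f + penalty over the box)
    g2 <- gradF(lam)
    kkt <- ifelse(lam == 0, pmax(abs(g2) - betaJ, 0),
                  abs(g2 + betaJ * sign(lam)))
    kkt[lam >= bound] <- pmax(0, g2[lam >= bound] + betaJ[lam >= bound])
    kkt[lam <= -bound] <- pmax(0, betaJ[lam <= -bound] - g2[lam <= -bound])
    if (max(kkt) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf(
      "fit error: no convergence in %d iterations (objective %.6f, KKT %.2e)",
      maxIter, -(fv + penalty(lam)), max(kkt)))
  eta <- as.vector(backgroundX %*% lam)
  logZ <- logSumExp(eta)
  q <- exp(eta - logZ)
  H <- -sum(q * log(q))
  gain <- sum(pbar * lam) - logZ + log(n) - penalty(lam)
  new("MaxentModel", features = features, lambdas = as.numeric(lam),
      beta = beta, betaJ = as.numeric(betaJ), logZ = logZ,
      entropyH = H, gain = gain,
      trainInfo = list(nPresence = m, nBackground = n,
                       converged = converged, iterations = iter))
}

#' Fit from raw variable values
#'
#' Convenience wrapper: builds features (bounds from the pooled presence +
#' background training values) and fits.
#'
#' @param presenceValues,backgroundValues numeric matrices of variable
#'   values (columns = named variables).
#' @inheritParams fitMaxent
#' @inheritParams buildFeatures
#' @return a [MaxentModel-class].
#' @export
fitMaxentOnValues <- function(presenceValues, backgroundValues, beta = 1,
                              classes = c("linear", "quadratic", "hinge"),
                              nHingeKnots = 16, tol = 1e-6,
                              maxIter = 5000) {
  pooled <- rbind(presenceValues, backgroundValues)
  bounds <- rbind(lo = apply(pooled, 2, min, na.rm = TRUE),
                  hi = apply(pooled, 2, max, na.rm = TRUE))
  fb <- buildFeatures(pooled, classes = classes, nHingeKnots = nHingeKnots,
                      bounds = bounds)
  keep <- fb$features$variables
  P <- featureMatrix(fb$features, presenceValues[, keep, drop = FALSE])
  B <- featureMatrix(fb$features, backgroundValues[, keep, drop = FALSE])
  fitMaxent(P, B, fb$features, beta = beta, tol = tol, maxIter = maxIter)
}

#' Logistic scores for variable values
#'
#' The logistic output is `p = exp(H) q(x) / (1 + exp(H) q(x))` with `q`
#' the fitted Gibbs density and `H` its entropy over the training
#' background, i.e. `plogis(eta - logZ + H)`; the uniform model (all
#' lambdas zero) scores 0.5 everywhere.
#'
#' @param model a [MaxentModel-class].
#' @param values numeric matrix of variable values.
#' @param clamp truncate values to training bounds (the transfer default).
#' @return numeric vector of scores in (0, 1).
#' @export
predictScores <- function(model, values, clamp = TRUE) {
  X <- featureMatrix(model@features, values, clamp = clamp)
  eta <- as.vector(X %*% model@lambdas)
  stats::plogis(eta - model@logZ + model@entropyH)
}

#' Project the model onto a climate stack
#'
#' @param model a [MaxentModel-class].
#' @param stack a [ClimateStack-class] supplying every model variable.
#' @param clamp truncate projected values to training bounds; keep on for
#'   transfers outside the training period.
#' @return suitability [GridLayer-class] with the stack's mask.
#' @export
predictLogistic <- function(model, stack, clamp = TRUE) {
  missing <- setdiff(model@features$variables, variableNames(stack))
  if (length(missing))
    stop("projection error: stack lacks variable(s): ",
         paste(missing, collapse = ", "))
  vals <- stackValues(stack, model@features$variables)
  mask <- stackMask(stack)
  out <- rep(NA_real_, nrow(vals))
  ok <- !as.vector(mask)
  out[ok] <- predictScores(model, vals[ok, , drop = FALSE], clamp = clamp)
  tmpl <- stack@layers[[1]]
  newGrid(matrix(out, nrow(mask), ncol(mask)), xll = tmpl@xll,
          yll = tmpl@yll, cellSize = tmpl@cellSize, mask = mask,
          crsLabel = tmpl@crsLabel)
}

#' Rank-based AUC
#'
#' Probability that a presence score outranks a background score, ties
#' counting one half (the Mann-Whitney statistic).
#'
#' @param scoresPresence,scoresBackground numeric score vectors.
#' @return AUC in `[0, 1]`.
#' @export
evaluateAUC <- function(scoresPresence, scoresBackground) {
  stopifnot(length(scoresPresence) > 0, length(scoresBackground) > 0)
  m <- length(scoresPresence); n <- length(scoresBackground)
  r <- rank(c(scoresPresence, scoresBackground))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Replicated split-sample evaluation and final fit
#'
#' Runs `k` seeded random 75/25-style presence splits, reporting training
#' and test AUC per replicate, then refits the mapped model on all
#' presences. The test split takes `floor(m * (1 - trainFraction))`
#' presences; the remainder trains.
#'
#' @param occ presence [OccurrenceSet-class].
#' @param background a [BackgroundSet-class].
#' @param stack training-period [ClimateStack-class].
#' @param k number of replicates.
#' @param trainFraction fraction of presences used for training, in (0,1).
#' @param beta regularisation multiplier.
#' @param seed master seed; each replicate derives its own stream.
#' @inheritParams buildFeatures
#' @param tol,maxIter optimiser controls.
#' @return list of class `EvalReport`: `replicates` data.frame
#'   (replicate, nTrain, nTest, trainAUC, testAUC), `meanTrainAUC`,
#'   `meanTestAUC`, `k`, `trainFraction`, `seed`, and `model`, the final
#'   all-presence [MaxentModel-class].
#' @export
replicateRuns <- function(occ, background, stack, k = 10,
                          trainFraction = 0.75, beta = 1, seed = 1,
                          classes = c("linear", "quadratic", "hinge"),
                          nHingeKnots = 16, tol = 1e-6, maxIter = 5000) {
  stopifnot(k >= 1, trainFraction > 0, trainFraction < 1)
  pv <- extractValues(stack, occ)
  ok <- stats::complete.cases(pv)
  if (!all(ok)) {
    warning(sum(!ok), " presence(s) fall outside the stack and are dropped")
    pv <- pv[ok, , drop = FALSE]
  }
  bv <- extractValues(stack, background)
  bv <- bv[stats::complete.cases(bv), , drop = FALSE]
  m <- nrow(pv)
  nTest <- floor(m * (1 - trainFraction))
  if (m - nTest < 2)
    stop("config error: training split smaller than 2 presences")
  reps <- lapply(seq_len(k), function(i) {
    testIdx <- withSeed(stageSeed(seed, paste0("replicate", i)),
                        sample.int(m, nTest))
    trainIdx <- setdiff(seq_len(m), testIdx)
    fit <- fitMaxentOnValues(pv[trainIdx, , drop = FALSE], bv, beta = beta,
                             classes = classes, nHingeKnots = nHingeKnots,
                             tol = tol, maxIter = maxIter)
    sTrain <- predictScores(fit, pv[trainIdx, , drop = FALSE])
    sTest <- if (nTest) predictScores(fit, pv[testIdx, , drop = FALSE])
    else numeric(0)
    sb <- predictScores(fit, bv)
    data.frame(replicate = i, nTrain = length(trainIdx), nTest = nTest,
               trainAUC = evaluateAUC(sTrain, sb),
               testAUC = if (nTest) evaluateAUC(sTest, sb) else NA_real_)
  })
  reps <- do.call(rbind, reps)
  model <- fitMaxentOnValues(pv, bv, beta = beta, classes = classes,
                             nHingeKnots = nHingeKnots, tol = tol,
                             maxIter = maxIter)
  structure(list(replicates = reps,
                 meanTrainAUC = mean(reps$trainAUC),
                 meanTestAUC = mean(reps$testAUC),
                 k = k, trainFraction = trainFraction, seed = seed,
                 model = model),
            class = "EvalReport")
}

#' Serialise / restore a fitted model as JSON text
#'
#' The "lambdas" file records the feature table with coefficients, the
#' training bounds, the regularisation and the normalising constants, so a
#' stored model reprojects without refitting.
#'
#' @param model a [MaxentModel-class].
#' @param path output path (JSON text).
#' @return `writeLambdas`: invisibly `path`; `readLambdas`: the restored
#'   [MaxentModel-class].
#' @export
writeLambdas <- function(model, path) {
  tab <- model@features$table
  obj <- list(
    classes = model@features$classes,
    variables = model@features$variables,
    nHingeKnots = model@features$nHingeKnots,
    bounds = as.list(as.data.frame(model@features$bounds)),
    featureClass = tab$class, featureVariable = tab$variable,
    featureKnot = tab$knot, lambdas = model@lambdas,
    beta = model@beta, betaJ = model@betaJ, logZ = model@logZ,
    entropyH = model@entropyH, gain = model@gain,
    trainInfo = model@trainInfo)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeLambdas
#' @export
readLambdas <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  bounds <- do.call(cbind, obj$bounds)
  rownames(bounds) <- c("lo", "hi")
  features <- list(classes = obj$classes, variables = obj$variables,
                   bounds = bounds[, obj$variables, drop = FALSE],
                   nHingeKnots = obj$nHingeKnots,
                   table = data.frame(class = obj$featureClass,
                                      variable = obj$featureVariable,
                                      knot = obj$featureKnot,
                                      stringsAsFactors = FALSE))
  new("MaxentModel", features = features, lambdas = obj$lambdas,
      beta = obj$beta, betaJ = obj$betaJ, logZ = obj$logZ,
      entropyH = obj$entropyH, gain = obj$gain,
      trainInfo = as.list(obj$trainInfo))
}
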