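## Bioclimatic variable screening: pairwise Pearson correlation pruning
## and jackknife contribution assessment.

#' Pairwise Pearson correlations across a stack
#'
#' Correlations are computed over all unmasked study-region cells
#' (optionally restricted to a subsample mask). A zero-variance variable
#' yields `NA` correlations and a warning naming it.
#'
#' @param stack a [ClimateStack-class] with at least two variables.
#' @param sampleMask optional logical matrix selecting the cells to use.
#' @return list of class `CorrelationReport`: `variables`, symmetric
#'   matrix `r`, `nCells`.
#' @export
correlationMatrix <- function(stack, sampleMask = NULL) {
  vars <- variableNames(stack)
  if (length(vars) < 2) stop("need at least two variables")
  use <- !stackMask(stack)
  if (!is.null(sampleMask)) use <- use & sampleMask
  if (sum(use) < 3) stop("need at least three unmasked cells")
  m <- stackValues(stack)[as.vector(use), , drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance variable(s): ",
            paste(vars[sds == 0], collapse = ", "),
            "; correlations reported as NA")
  r <- suppressWarnings(stats::cor(m))
  r[, sds == 0] <- NA; r[sds == 0, ] <- NA
  diag(r) <- 1
  structure(list(variables = vars, r = r, nCells = nrow(m)),
            class = "CorrelationReport")
}

#' Prune highly correlated variables
#'
#' Repeatedly removes one member of the most-correlated remaining pair
#' with `|r| > threshold`. Between the two: a variable listed earlier in
#' `priority` survives (the physiological-priority rule); with no priority
#' ranking between them, the variable with the lower mean absolute
#' correlation to all others survives; remaining ties fall back to input
#' order. Deterministic.
#'
#' @param report a `CorrelationReport` from [correlationMatrix()].
#' @param threshold correlation cutoff in (0, 1].
#' @param priority character vector of variable names, most
#'   physiologically direct first; may rank any subset.
#' @return character vector of retained variable names.
#' @export
pruneCorrelated <- function(report, threshold = 0.85, priority = character()) {
  stopifnot(threshold > 0, threshold <= 1)
  unknown <- setdiff(priority, report$variables)
  if (length(unknown))
    stop("priority names unknown variable(s): ",
         paste(unknown, collapse = ", "))
  r <- abs(report$r)
  keep <- report$variables
  prio <- function(v) {
    i <- match(v, priority)
    if (is.na(i)) Inf else i
  }
  repeat {
    sub <- r[keep, keep, drop = FALSE]
    diag(sub) <- 0
    mx <- suppressWarnings(max(sub, na.rm = TRUE))
    if (!is.finite(mx) || mx <= threshold) break
    ij <- which(sub == mx, arr.ind = TRUE)[1, ]
    a <- keep[ij[1]]; b <- keep[ij[2]]
    drop <- if (prio(a) < prio(b)) b
    else if (prio(b) < prio(a)) a
    else {
      ma <- mean(sub[a, keep != a], na.rm = TRUE)
      mb <- mean(sub[b, keep != b], na.rm = TRUE)
      if (ma < mb) b else if (mb < ma) a
      else keep[max(ij)]                      # stable input-order fallback
    }
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Jackknife contribution of each variable
#'
#' For every variable the model is refit with that variable alone and
#' with all variables but it; the regularised training gain and training
#' AUC of each refit are reported next to the all-variable baseline. High
#' `gainAlone` marks a variable carrying information by itself; a
#' `gainWithout` close to the baseline marks a variable whose information
#' is redundant.
#'
#' @param presenceValues,backgroundValues numeric matrices of variable
#'   values at presence and background locations (columns = variables).
#' @param beta regularisation multiplier passed to [fitMaxent()].
#' @param classes,nHingeKnots feature configuration, see [buildFeatures()].
#' @param tol,maxIter optimiser controls, see [fitMaxent()].
#' @return list of class `JackknifeReport`: data.frame `perVariable`
#'   (variable, gainAlone, gainWithout, aucAlone, aucWithout) and baseline
#'   `gainAll`, `aucAll`.
#' @export
jackknifeContribution <- function(presenceValues, backgroundValues,
                                  beta = 1,
                                  classes = c("linear", "quadratic", "hinge"),
                                  nHingeKnots = 16, tol = 1e-6,
                                  maxIter = 5000) {
  vars <- colnames(presenceValues)
  fitOn <- function(sel) {
    fit <- fitMaxentOnValues(presenceValues[, sel, drop = FALSE],
                             backgroundValues[, sel, drop = FALSE],
                             beta = beta, classes = classes,
                             nHingeKnots = nHingeKnots, tol = tol,
                             maxIter = maxIter)
    sp <- predictScores(fit, presenceValues[, sel, drop = FALSE])
    sb <- predictScores(fit, backgroundValues[, sel, drop = FALSE])
    c(gain = fit@gain, auc = evaluateAUC(sp, sb))
  }
  all <- fitOn(vars)
  per <- do.call(rbind, lapply(vars, function(v) {
    alone <- fitOn(v)
    without <- if (length(vars) > 1) fitOn(setdiff(vars, v)) else alone
    data.frame(variable = v,
               gainAlone = alone[["gain"]], gainWithout = without[["gain"]],
               aucAlone = alone[["auc"]], aucWithout = without[["auc"]],
               stringsAsFactors = FALSE)
  }))
  structure(list(perVariable = per, gainAll = all[["gain"]],
                 aucAll = all[["auc"]]),
            class = "JackknifeReport")
}
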