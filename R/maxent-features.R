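## Feature construction for the maximum-entropy model: linear, quadratic
## and hinge transforms of the raw variables, all mapped to [0, 1] over the
## training bounds.

#' Build model features and the training design matrix
#'
#' Features per variable, over training bounds `[lo, hi]`:
#' linear `(v - lo) / (hi - lo)`; quadratic the linear value squared;
#' hinge `max(0, (v - k) / (hi - k))` at `nHingeKnots` evenly spaced
#' interior knots `k`. Values are clamped to the bounds before feature
#' evaluation (see [featureMatrix()]), so every feature lies in `[0, 1]`.
#' Constant variables carry no information and their features are dropped
#' with a warning.
#'
#' @param values numeric matrix of training values (rows = locations,
#'   columns = named variables).
#' @param classes subset of `c("linear", "quadratic", "hinge")`.
#' @param nHingeKnots hinge knots per variable.
#' @param bounds optional 2 x K matrix (rows `lo`, `hi`) of training
#'   bounds; computed from `values` when `NULL`.
#' @return list with `features` (the feature definition reused for
#'   projection and stored in the fitted model) and `X` (design matrix).
#' @export
buildFeatures <- function(values,
                          classes = c("linear", "quadratic", "hinge"),
                          nHingeKnots = 16, bounds = NULL) {
  classes <- match.arg(classes, several.ok = TRUE)
  vars <- colnames(values)
  if (is.null(vars)) stop("values must have named columns")
  if (is.null(bounds)) {
    bounds <- rbind(lo = apply(values, 2, min, na.rm = TRUE),
                    hi = apply(values, 2, max, na.rm = TRUE))
  }
  constant <- bounds["hi", ] <= bounds["lo", ]
  if (any(constant)) {
    warning("constant variable(s) dropped from features: ",
            paste(vars[constant], collapse = ", "))
    vars <- vars[!constant]
    if (!length(vars)) stop("no non-constant variables left")
  }
  rows <- list()
  for (v in vars) {
    if ("linear" %in% classes)
      rows[[length(rows) + 1]] <- data.frame(class = "linear", variable = v,
                                             knot = NA_real_)
    if ("quadratic" %in% classes)
      rows[[length(rows) + 1]] <- data.frame(class = "quadratic",
                                             variable = v, knot = NA_real_)
    if ("hinge" %in% classes && nHingeKnots > 0) {
      ks <- seq(bounds["lo", v], bounds["hi", v],
                length.out = nHingeKnots + 2)[-c(1, nHingeKnots + 2)]
      rows[[length(rows) + 1]] <- data.frame(class = "hinge", variable = v,
                                             knot = ks)
    }
  }
  features <- list(classes = classes,
                   variables = vars,
                   bounds = bounds[, vars, drop = FALSE],
                   nHingeKnots = nHingeKnots,
                   table = do.call(rbind, rows))
  list(features = features, X = featureMatrix(features, values, clamp = TRUE))
}

#' Evaluate features on (possibly new) variable values
#'
#' With `clamp = TRUE` (the transfer default) variable values are
#' truncated to the training bounds before evaluation, so projections
#' beyond the training range behave as at the range edge.
#'
#' @param features feature definition from [buildFeatures()].
#' @param values numeric matrix with the feature variables as columns.
#' @param clamp truncate values to training bounds first.
#' @return design matrix, one column per feature.
#' @export
featureMatrix <- function(features, values, clamp = TRUE) {
  vars <- features$variables
  missing <- setdiff(vars, colnames(values))
  if (length(missing))
    stop("projection error: values lack variable(s): ",
         paste(missing, collapse = ", "))
  tab <- features$table
  X <- matrix(0, nrow(values), nrow(tab))
  for (v in vars) {
    lo <- features$bounds["lo", v]; hi <- features$bounds["hi", v]
    x <- values[, v]
    if (clamp) x <- pmin(pmax(x, lo), hi)
    lin <- (x - lo) / (hi - lo)
    sel <- which(tab$variable == v)
    for (j in sel) {
      X[, j] <- switch(tab$class[j],
                       linear = lin,
                       quadratic = lin^2,
                       hinge = pmax(0, (x - tab$knot[j]) /
                                      (hi - tab$knot[j])))
    }
  }
  colnames(X) <- paste0(tab$class, ".", tab$variable,
                        ifelse(is.na(tab$knot), "",
                               paste0("@", signif(tab$knot, 6))))
  X
}
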