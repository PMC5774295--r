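## Per-cell limiting-factor attribution and between-period variable-change
## maps.

#' Per-cell limiting-factor map
#'
#' For every unmasked cell and every model variable `v`, the prediction is
#' recomputed with `v` replaced by its presence-sample mean (all other
#' variables untouched, clamping as in projection). The limiting factor of
#' the cell is the variable whose substitution raises the logistic
#' prediction most; where no substitution raises it the cell is
#' unattributed (`NA`). Ties break to the first variable in model order.
#'
#' @param model a [MaxentModel-class].
#' @param stack a [ClimateStack-class] supplying every model variable.
#' @param presenceMeans named per-variable means at the training
#'   localities (the substitution reference).
#' @param clamp clamp to training bounds, as in [predictLogistic()].
#' @return a [LimitingFactorMap-class].
#' @export
limitingFactorMap <- function(model, stack, presenceMeans, clamp = TRUE) {
  vars <- model@features$variables
  missing <- setdiff(vars, variableNames(stack))
  if (length(missing))
    stop("projection error: stack lacks variable(s): ",
         paste(missing, collapse = ", "))
  if (!all(vars %in% names(presenceMeans)))
    stop("presenceMeans must cover all model variables")
  mask <- stackMask(stack)
  vals <- stackValues(stack, vars)
  ok <- !as.vector(mask)
  base <- predictScores(model, vals[ok, , drop = FALSE], clamp = clamp)
  delta <- matrix(NA_real_, sum(ok), length(vars))
  for (j in seq_along(vars)) {
    sub <- vals[ok, , drop = FALSE]
    sub[, vars[j]] <- presenceMeans[[vars[j]]]
    delta[, j] <- predictScores(model, sub, clamp = clamp) - base
  }
  bestJ <- max.col(delta, ties.method = "first")
  bestD <- delta[cbind(seq_len(nrow(delta)), bestJ)]
  idxOk <- ifelse(bestD > 0, bestJ, NA_integer_)
  idx <- rep(NA_integer_, length(ok))
  idx[ok] <- idxOk
  tmpl <- stack@layers[[1]]
  new("LimitingFactorMap",
      factorIndex = matrix(as.integer(idx), nrow(mask), ncol(mask)),
      variables = vars,
      referenceValues = vapply(vars, function(v) presenceMeans[[v]],
                               numeric(1)),
      mask = mask, xll = tmpl@xll, yll = tmpl@yll,
      cellSize = tmpl@cellSize)
}

#' Limiting-factor shares within a change class
#'
#' Among the cells of one change class, the percentage attributed to each
#' variable (one decimal, half away from zero), in descending order; the
#' unattributed remainder is reported as `nonePct`. Shares are cell
#' counts (the grid is equal-area, so counts and areas are proportional).
#'
#' @param lfmap a [LimitingFactorMap-class].
#' @param cmap an aligned [ChangeMap-class].
#' @param classLabel one of `"contraction"`, `"no_change"`, `"expansion"`,
#'   `"absent"`.
#' @return list of class `FactorShareRow`: `class`, `nCells`, data.frame
#'   `shares` (variable, pct, descending), `nonePct`. Empty classes yield
#'   `NA` shares with a warning.
#' @export
factorShares <- function(lfmap, cmap, classLabel) {
  if (!sameGeometry(lfmap, cmap))
    stop("alignment error: maps do not share geometry")
  code <- match(classLabel,
                c("absent", "contraction", "no_change", "expansion")) - 1L
  if (is.na(code)) stop("unknown change class: ", classLabel)
  inClass <- !cmap@mask & !is.na(cmap@classes) & cmap@classes == code
  nClass <- sum(inClass)
  if (nClass == 0) {
    warning("no cells in class '", classLabel, "'; shares undefined")
    return(structure(list(class = classLabel, nCells = 0L,
                          shares = data.frame(variable = character(0),
                                              pct = numeric(0)),
                          nonePct = NA_real_),
                     class = "FactorShareRow"))
  }
  f <- lfmap@factorIndex[inClass]
  counts <- tabulate(f[!is.na(f)], nbins = length(lfmap@variables))
  pct <- roundHalfAwayFromZero(100 * counts / nClass, 1)
  ord <- order(-counts, seq_along(counts))
  shares <- data.frame(variable = lfmap@variables[ord], pct = pct[ord],
                       stringsAsFactors = FALSE)
  structure(list(class = classLabel, nCells = nClass, shares = shares,
                 nonePct = roundHalfAwayFromZero(
                   100 * sum(is.na(f)) / nClass, 1)),
            class = "FactorShareRow")
}

#' Between-period change of one variable
#'
#' Per-cell late-minus-early difference of a variable (the amplitude map
#' read next to the limiting-factor classes).
#'
#' @param early,late aligned [ClimateStack-class] objects sharing the
#'   variable.
#' @param variable variable name.
#' @return difference [GridLayer-class] (late - early).
#' @export
variableChangeMap <- function(early, late, variable) {
  ge <- getLayer(early, variable)
  gl <- getLayer(late, variable)
  if (!sameGeometry(ge, gl)) stop("alignment error: stacks not aligned")
  mask <- ge@mask | gl@mask
  newGrid(gl@values - ge@values, xll = ge@xll, yll = ge@yll,
          cellSize = ge@cellSize, mask = mask, crsLabel = ge@crsLabel)
}
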