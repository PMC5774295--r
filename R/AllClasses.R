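#' @import methods
NULL

#' GridLayer: a single projected raster variable
#'
#' A 2-D raster on a projected planar grid with square cells. Row 1 is the
#' northernmost row; x increases east and y north. Cell size is in metres;
#' all cells are treated as equal-area (the grids are assumed already
#' projected to an equal-area/equidistant plane, as is standard before
#' range-change accounting).
#'
#' @slot values numeric matrix of cell values (row 1 = north).
#' @slot mask logical matrix, `TRUE` where the cell is nodata.
#' @slot xll,yll numeric, coordinates (metres) of the lower-left corner of
#'   the grid (corner of the south-west cell, not its centre).
#' @slot cellSize numeric, cell width = height in metres.
#' @slot crsLabel free-text projection identifier.
#'
#' @examples
#' g <- newGrid(matrix(1:9, 3, 3), cellSize = 60000)
#' cellAreaKm2(g)   # 3600 km^2 per cell
#' @export
setClass("GridLayer", representation(
  values = "matrix", mask = "matrix",
  xll = "numeric", yll = "numeric",
  cellSize = "numeric", crsLabel = "character"
))

setValidity("GridLayer", function(object) {
  msgs <- character()
  if (!all(dim(object@values) == dim(object@mask)))
    msgs <- c(msgs, "values and mask must have identical dimensions")
  if (!is.logical(object@mask))
    msgs <- c(msgs, "mask must be logical")
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@xll) != 1 || length(object@yll) != 1 ||
      !all(is.finite(c(object@xll, object@yll))))
    msgs <- c(msgs, "xll/yll must be single finite numbers")
  un <- object@values[!object@mask]
  if (length(un) && any(!is.finite(un)))
    msgs <- c(msgs, "unmasked cells must hold finite values")
  if (length(msgs)) msgs else TRUE
})

#' ClimateStack: aligned raster variables for one time period
#'
#' Named [GridLayer-class] objects sharing shape, georeferencing and a
#' unified nodata mask. Variable names follow the bio1-bio19 bioclimatic
#' convention where applicable.
#'
#' @slot period period label, e.g. "LIG", "LGM", "present", "2080".
#' @slot layers named list of [GridLayer-class] objects.
#' @export
setClass("ClimateStack", representation(
  period = "character", layers = "list"
))

setValidity("ClimateStack", function(object) {
  if (length(object@layers) < 1) return("stack needs at least one layer")
  if (is.null(names(object@layers)) || anyDuplicated(names(object@layers)))
    return("layers must be uniquely named")
  if (!all(vapply(object@layers, is, logical(1), "GridLayer")))
    return("all layers must be GridLayer objects")
  ref <- object@layers[[1]]
  for (g in object@layers) {
    if (!sameGeometry(ref, g)) return("layers must share geometry")
    if (!identical(g@mask, ref@mask)) return("layers must share the nodata mask")
  }
  TRUE
})

#' OccurrenceSet: presence localities in projected coordinates
#'
#' @slot points data.frame with columns `id` (unique character), `x`, `y`
#'   (metres).
#' @slot sourceLabel free-text provenance note.
#' @export
setClass("OccurrenceSet", representation(
  points = "data.frame", sourceLabel = "character"
))

setValidity("OccurrenceSet", function(object) {
  p <- object@points
  if (!all(c("id", "x", "y") %in% names(p)))
    return("points must have columns id, x, y")
  if (anyDuplicated(p$id)) return("occurrence ids must be unique")
  if (nrow(p) && !all(is.finite(p$x) & is.finite(p$y)))
    return("coordinates must be finite")
  TRUE
})

#' BackgroundSet: bias-weighted background (pseudo-absence) cells
#'
#' @slot points data.frame with columns `x`, `y` (cell-centre metres) and
#'   `cell` (linear cell index into the bias grid).
#' @slot seed integer seed used for the draw.
#' @export
setClass("BackgroundSet", representation(
  points = "data.frame", seed = "numeric"
))

#' MaxentModel: fitted maximum-entropy presence-background model
#'
#' Gibbs model q(x) proportional to exp(sum_j lambda_j f_j(x)) over the
#' background, with L1-penalised coefficients and the entropy-based
#' logistic output transform.
#'
#' @slot features feature definition list produced by [buildFeatures()]
#'   (classes, per-variable bounds, hinge knots, feature table).
#' @slot lambdas numeric vector of per-feature coefficients.
#' @slot beta regularisation multiplier supplied at fit time.
#' @slot betaJ per-feature penalty actually applied.
#' @slot logZ log partition constant over the training background.
#' @slot entropyH entropy of the fitted distribution over the background.
#' @slot gain regularised training gain relative to the uniform model.
#' @slot trainInfo list: nPresence, nBackground, converged, iterations.
#' @export
setClass("MaxentModel", representation(
  features = "list", lambdas = "numeric", beta = "numeric",
  betaJ = "numeric", logZ = "numeric", entropyH = "numeric",
  gain = "numeric", trainInfo = "list"
))

setValidity("MaxentModel", function(object) {
  if (length(object@lambdas) != nrow(object@features$table))
    return("one lambda per feature required")
  if (object@entropyH < -1e-8) return("entropy must be non-negative")
  TRUE
})

#' BinaryMap: thresholded presence/absence surface
#'
#' @slot suitable logical matrix, `TRUE` where the suitability score met
#'   the threshold; masked cells are never suitable.
#' @slot mask logical nodata matrix.
#' @slot threshold the score threshold applied (suitable iff score >= t).
#' @slot period period label.
#' @slot xll,yll,cellSize georeferencing as in [GridLayer-class].
#' @export
setClass("BinaryMap", representation(
  suitable = "matrix", mask = "matrix", threshold = "numeric",
  period = "character", xll = "numeric", yll = "numeric",
  cellSize = "numeric"
))

setValidity("BinaryMap", function(object) {
  if (!all(dim(object@suitable) == dim(object@mask)))
    return("suitable and mask must share dimensions")
  if (any(object@suitable & object@mask))
    return("masked cells cannot be suitable")
  TRUE
})

#' ChangeMap: per-cell range-transition classes between two periods
#'
#' Classes: 0 = absent (suitable in neither period), 1 = contraction
#' (suitable early only), 2 = no change (suitable in both), 3 = expansion
#' (suitable late only). Masked cells are `NA`.
#'
#' @slot classes integer matrix of class codes.
#' @slot mask logical nodata matrix.
#' @slot pairLabel transition label, e.g. "LIG->LGM".
#' @slot xll,yll,cellSize georeferencing.
#' @export
setClass("ChangeMap", representation(
  classes = "matrix", mask = "matrix", pairLabel = "character",
  xll = "numeric", yll = "numeric", cellSize = "numeric"
))

#' LimitingFactorMap: per-cell attribution of the most limiting variable
#'
#' @slot factorIndex integer matrix indexing into `variables`; `NA` where no
#'   variable substitution increases the prediction (or the cell is masked).
#' @slot variables model variable names, in model order.
#' @slot referenceValues per-variable presence-sample means substituted in.
#' @slot mask logical nodata matrix.
#' @slot xll,yll,cellSize georeferencing.
#' @export
setClass("LimitingFactorMap", representation(
  factorIndex = "matrix", variables = "character",
  referenceValues = "numeric", mask = "matrix",
  xll = "numeric", yll = "numeric", cellSize = "numeric"
))

#' SyntheticSpec: parameters of the synthetic climate/occurrence generator
#'
#' Defines a multi-period synthetic study system: spatially autocorrelated,
#' cross-correlated bioclimatic surfaces; per-period additive climate
#' offsets; a known logistic suitability function; and a spatially biased
#' sampling kernel. See [syntheticSpec()] for defaults and units.
#'
#' @slot nrow,ncol grid shape (cells).
#' @slot cellSizeKm cell size in km.
#' @slot variables variable names (bio1-bio19 convention).
#' @slot variableMeans,variableSds per-variable generative mean and sd (in
#'   the variable's natural units).
#' @slot corrLengthKm Gaussian smoothing scale of the noise fields.
#' @slot gradientWeight share of variance carried by the smooth gradient.
#' @slot crossCorrelation data.frame (var1, var2, r) of designated pairs.
#' @slot periods period labels, earliest first.
#' @slot periodOffsets named list: per period, named additive shifts.
#' @slot trueIntercept,trueCoefficients generating logistic model on
#'   standardised variables.
#' @slot biasCenter,biasSdKm centre (km, x/y) and sd of the sampling kernel.
#' @slot nPresences presences to draw.
#' @slot seed master seed.
#' @export
setClass("SyntheticSpec", representation(
  nrow = "numeric", ncol = "numeric", cellSizeKm = "numeric",
  variables = "character", variableMeans = "numeric",
  variableSds = "numeric", corrLengthKm = "numeric",
  gradientWeight = "numeric", crossCorrelation = "data.frame",
  periods = "character", periodOffsets = "list",
  trueIntercept = "numeric", trueCoefficients = "numeric",
  biasCenter = "numeric", biasSdKm = "numeric",
  nPresences = "numeric", seed = "numeric"
))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (object@nrow < 2 || object@ncol < 2)
    msgs <- c(msgs, "grid shape must be at least 2x2")
  if (object@nPresences < 1) msgs <- c(msgs, "nPresences must be >= 1")
  if (nrow(object@crossCorrelation) &&
      any(abs(object@crossCorrelation$r) > 1))
    msgs <- c(msgs, "cross-correlations must lie in [-1, 1]")
  if (!all(names(object@variableMeans) == object@variables) ||
      !all(names(object@variableSds) == object@variables))
    msgs <- c(msgs, "variableMeans/variableSds must be named by variables")
  if (length(msgs)) msgs else TRUE
})

## ---- show methods ----

setMethod("show", "GridLayer", function(object) {
  d <- dim(object@values)
  cat(sprintf("GridLayer: %d x %d cells of %.6g m (%.6g km2/cell), %d masked\n",
              d[1], d[2], object@cellSize, cellAreaKm2(object),
              sum(object@mask)))
  cat(sprintf("  origin (xll, yll) = (%.6g, %.6g) m; crs: %s\n",
              object@xll, object@yll, object@crsLabel))
  un <- object@values[!object@mask]
  if (length(un))
    cat(sprintf("  values: [%.4g, %.4g]\n", min(un), max(un)))
})

setMethod("show", "ClimateStack", function(object) {
  cat(sprintf("ClimateStack '%s': %d variables (%s)\n", object@period,
              length(object@layers),
              paste(names(object@layers), collapse = ", ")))
  show(object@layers[[1]])
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet '%s': %d localities\n", object@sourceLabel,
              nrow(object@points)))
})

setMethod("show", "MaxentModel", function(object) {
  nz <- sum(abs(object@lambdas) > 0)
  cat(sprintf(
    "MaxentModel: %d features (%d active), beta = %g\n",
    length(object@lambdas), nz, object@beta))
  cat(sprintf("  logZ = %.4f, H = %.4f, regularised gain = %.4f\n",
              object@logZ, object@entropyH, object@gain))
  cat(sprintf("  trained on %d presences / %d background\n",
              object@trainInfo$nPresence, object@trainInfo$nBackground))
})

setMethod("show", "BinaryMap", function(object) {
  cat(sprintf("BinaryMap '%s': %d suitable cells (t = %.4f), area %.1f km2\n",
              object@period, sum(object@suitable), object@threshold,
              sum(object@suitable) * (object@cellSize / 1000)^2))
})

setMethod("show", "ChangeMap", function(object) {
  tab <- tabulate(object@classes[!object@mask] + 1L, 4L)
  cat(sprintf(
    "ChangeMap '%s': %d contraction, %d no-change, %d expansion, %d absent\n",
    object@pairLabel, tab[2], tab[3], tab[4], tab[1]))
})
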