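## Thresholding, binarisation, contraction/expansion accounting, and
## centroid / block-centroid migration-vector analysis.

#' Maximum training sensitivity plus specificity threshold
#'
#' Scans every observed score (presence and background) as a candidate
#' cutoff and returns the one maximising
#' `sensitivity(presence >= t) + specificity(background < t)`; ties break
#' to the smallest such threshold. The negative class is the background
#' sample, matching the training threshold of presence-background models.
#'
#' @param scoresPresence,scoresBackground numeric score vectors.
#' @return the threshold score.
#' @export
mtssThreshold <- function(scoresPresence, scoresBackground) {
  stopifnot(length(scoresPresence) > 0, length(scoresBackground) > 0)
  cand <- sort(unique(c(scoresPresence, scoresBackground)))
  sens <- vapply(cand, function(t) mean(scoresPresence >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scoresBackground < t), numeric(1))
  ss <- sens + spec
  cand[which(ss == max(ss))[1]]
}

#' 10th percentile training presence threshold
#'
#' Excludes the `floor(0.10 * m)` lowest-scoring training presences and
#' returns the smallest score among the remainder, i.e. the
#' `floor(0.10 * m) + 1`-th order statistic of the presence scores.
#'
#' @param scoresPresence numeric presence scores.
#' @param fraction fraction excluded (default 0.10).
#' @return the threshold score.
#' @export
tenPercentTPThreshold <- function(scoresPresence, fraction = 0.10) {
  m <- length(scoresPresence)
  stopifnot(m >= 1)
  sort(scoresPresence)[floor(fraction * m) + 1]
}

#' Binarise a suitability surface
#'
#' A cell is suitable iff it is unmasked and its score is `>= t` (scores
#' exactly at the threshold are suitable).
#'
#' @param prediction suitability [GridLayer-class].
#' @param t threshold in `[0, 1]`.
#' @param period period label carried on the map.
#' @return a [BinaryMap-class].
#' @export
binarize <- function(prediction, t, period) {
  stopifnot(t >= 0, t <= 1)
  suit <- !prediction@mask & !is.na(prediction@values) &
    prediction@values >= t
  new("BinaryMap", suitable = suit, mask = prediction@mask, threshold = t,
      period = period, xll = prediction@xll, yll = prediction@yll,
      cellSize = prediction@cellSize)
}

#' Classify per-cell range change between two periods
#'
#' Classes: contraction (suitable early only), no change (both),
#' expansion (late only), absent (neither).
#'
#' @param early,late aligned [BinaryMap-class] objects.
#' @return a [ChangeMap-class] labelled `"<early>-><late>"`.
#' @export
changeMap <- function(early, late) {
  if (!sameGeometry(early, late))
    stop("alignment error: binary maps do not share geometry")
  cls <- matrix(0L, nrow(early@suitable), ncol(early@suitable))
  cls[early@suitable & !late@suitable] <- 1L
  cls[early@suitable & late@suitable] <- 2L
  cls[!early@suitable & late@suitable] <- 3L
  mask <- early@mask | late@mask
  cls[mask] <- NA_integer_
  new("ChangeMap", classes = cls, mask = mask,
      pairLabel = paste0(early@period, "->", late@period),
      xll = early@xll, yll = early@yll, cellSize = early@cellSize)
}

#' Change-accounting ratios
#'
#' Contraction and no-change are expressed as percentages of the
#' early-period area, expansion as a percentage of the late-period area
#' (the table convention of range-change accounting); percentages are
#' rounded to one decimal, halves away from zero. By default the period
#' areas are reconstructed from the class-area identities
#' `early = contraction + no-change` and `late = no-change + expansion`;
#' explicit `earlyArea` / `lateArea` override them (useful when areas are
#' known at higher precision than the class breakdown).
#'
#' @param contraction,noChange,expansion class areas (any common unit).
#' @param earlyArea,lateArea optional period-area overrides.
#' @return list: `areas` (named class areas plus `early`, `late`) and
#'   `ratios` (named percentages; `NA` where the denominator is zero).
#' @export
changeRatios <- function(contraction, noChange, expansion,
                         earlyArea = NULL, lateArea = NULL) {
  early <- earlyArea %||% (contraction + noChange)
  late <- lateArea %||% (noChange + expansion)
  pct <- function(num, den) {
    if (den <= 0) NA_real_ else roundHalfAwayFromZero(100 * num / den, 1)
  }
  list(areas = c(contraction = contraction, noChange = noChange,
                 expansion = expansion, early = early, late = late),
       ratios = c(contraction = pct(contraction, early),
                  noChange = pct(noChange, early),
                  expansion = pct(expansion, late)))
}

#' Area and ratio accounting of a change map
#'
#' @param cmap a [ChangeMap-class].
#' @param cellArea km^2 per cell (default from the map's cell size).
#' @return data.frame with one row per class (`contraction`, `no_change`,
#'   `expansion`): `areaKm2` and `ratioPct` (contraction and no-change as
#'   % of the early-period area, expansion as % of the late-period area,
#'   one decimal, half away from zero; `NA` where a period area is zero).
#' @export
changeTable <- function(cmap, cellArea = (cmap@cellSize / 1000)^2) {
  cls <- cmap@classes[!cmap@mask]
  a <- vapply(1:3, function(k) areaOf(cls == k, cellArea), numeric(1))
  cr <- changeRatios(a[1], a[2], a[3])
  data.frame(class = c("contraction", "no_change", "expansion"),
             areaKm2 = a,
             ratioPct = unname(cr$ratios),
             row.names = NULL)
}

#' Overall range centroid
#'
#' Unweighted mean of the suitable-cell centre coordinates.
#'
#' @param bmap a [BinaryMap-class] with at least one suitable cell.
#' @return named numeric `c(x, y)` in metres.
#' @export
overallCentroid <- function(bmap) {
  if (!any(bmap@suitable)) stop("centroid error: no suitable cells")
  cc <- cellCenters(bmap)
  c(x = mean(cc$X[bmap@suitable]), y = mean(cc$Y[bmap@suitable]))
}

#' Single centroid-shift vector between two periods
#'
#' @param early,late [BinaryMap-class] objects.
#' @return one-row data.frame: source and target coordinates (m),
#'   `distanceKm`, and `bearingDeg` clockwise from north.
#' @export
centroidVector <- function(early, late) {
  s <- overallCentroid(early); t <- overallCentroid(late)
  vectorsBetween(matrix(s, 1, 2, dimnames = list(NULL, c("x", "y"))),
                 matrix(t, 1, 2, dimnames = list(NULL, c("x", "y"))),
                 paste0(early@period, "->", late@period))
}

vectorsBetween <- function(src, dst, pairLabel) {
  dx <- dst[, 1] - src[, 1]; dy <- dst[, 2] - src[, 2]
  out <- data.frame(srcX = src[, 1], srcY = src[, 2],
                    dstX = dst[, 1], dstY = dst[, 2],
                    distanceKm = sqrt(dx^2 + dy^2) / 1000,
                    bearingDeg = ifelse(dx == 0 & dy == 0, 0,
                                        bearingDeg(dx, dy)))
  attr(out, "pairLabel") <- pairLabel
  out
}

#' Block centroids of a range
#'
#' Partitions the plane into `blockKm` x `blockKm` tiles anchored at the
#' raster origin (partial edge tiles allowed) and returns, for each tile
#' holding at least one suitable cell, the mean of its suitable-cell
#' centres.
#'
#' @param bmap a [BinaryMap-class].
#' @param blockKm tile edge, km; must be at least the cell size.
#' @return data.frame `x`, `y` (m), `nCells`, ordered by tile (west-east,
#'   then south-north); empty for an empty map.
#' @export
blockCentroids <- function(bmap, blockKm = 60) {
  stopifnot(blockKm * 1000 >= bmap@cellSize)
  if (!any(bmap@suitable))
    return(data.frame(x = numeric(0), y = numeric(0), nCells = integer(0)))
  cc <- cellCenters(bmap)
  xs <- cc$X[bmap@suitable]; ys <- cc$Y[bmap@suitable]
  bs <- blockKm * 1000
  bx <- floor((xs - bmap@xll) / bs)
  by <- floor((ys - bmap@yll) / bs)
  key <- paste(bx, by)
  sp <- split(seq_along(xs), key)
  ordKeys <- names(sp)[order(vapply(sp, function(i) bx[i[1]], numeric(1)),
                             vapply(sp, function(i) by[i[1]], numeric(1)))]
  out <- do.call(rbind, lapply(ordKeys, function(k) {
    i <- sp[[k]]
    data.frame(x = mean(xs[i]), y = mean(ys[i]), nCells = length(i))
  }))
  rownames(out) <- NULL
  out
}

#' Migration vectors by nearest-source matching
#'
#' For each late-period centroid, the nearest early-period centroid is
#' taken as its source (each new range patch is assigned the closest
#' patch it could have come from); ties break to the smallest distance,
#' then lexicographic (x, y) order of the early centroids. Early
#' centroids matched by no late centroid (extinct patches) are reported
#' in the `"unmatchedEarly"` attribute, not vectorised.
#'
#' @param centroidsEarly,centroidsLate data.frames with `x`, `y` columns
#'   (e.g. from [blockCentroids()]).
#' @param pairLabel transition label attached to the result.
#' @return data.frame of vectors as in [centroidVector()], one per late
#'   centroid, with attributes `pairLabel` and `unmatchedEarly`.
#' @export
migrationVectors <- function(centroidsEarly, centroidsLate,
                             pairLabel = "early->late") {
  if (!nrow(centroidsEarly)) stop("matching error: no early centroids")
  if (!nrow(centroidsLate)) stop("matching error: no late centroids")
  eo <- order(centroidsEarly$x, centroidsEarly$y)
  e <- centroidsEarly[eo, , drop = FALSE]
  D <- pointDist(cbind(centroidsLate$x, centroidsLate$y),
                 cbind(e$x, e$y))
  src <- apply(D, 1, which.min)   # first minimum = lexicographic tie-break
  out <- vectorsBetween(cbind(x = e$x[src], y = e$y[src]),
                        cbind(x = centroidsLate$x, y = centroidsLate$y),
                        pairLabel)
  attr(out, "unmatchedEarly") <- e[setdiff(seq_len(nrow(e)), unique(src)),
                                   c("x", "y"), drop = FALSE]
  out
}
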