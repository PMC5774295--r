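## Occurrence ingestion, distance-constrained thinning, the sampling-bias
## kernel surface, and bias-weighted background sampling.

#' Read / write occurrence localities
#'
#' The CSV schema is `id,x,y` with a header; coordinates are projected
#' metres. Duplicate coordinates are retained (thinning resolves them);
#' duplicate ids are an error.
#'
#' @param path CSV file path.
#' @param sourceLabel provenance note attached to the set.
#' @return an [OccurrenceSet-class].
#' @export
readOccurrences <- function(path, sourceLabel = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("occurrence CSV lacks column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("occurrence coordinates must be numeric")
  if (anyDuplicated(df$id))
    stop("duplicate occurrence id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  new("OccurrenceSet", points = df[, need], sourceLabel = sourceLabel)
}

#' @rdname readOccurrences
#' @param occ an [OccurrenceSet-class].
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(occ@points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## exact maximum independent set on a conflict graph, include-first
## branch and bound over vertices in the given order
misExact <- function(adj, order) {
  best <- integer(0)
  recurse <- function(chosen, cand) {
    if (length(chosen) + length(cand) <= length(best)) return()
    if (!length(cand)) {
      if (length(chosen) > length(best)) best <<- chosen
      return()
    }
    v <- cand[1]
    recurse(c(chosen, v), setdiff(cand[-1], adj[[v]]))   # include v
    recurse(chosen, cand[-1])                            # exclude v
  }
  recurse(integer(0), order)
  best
}

## randomized greedy fallback for big components: repeatedly pick a random
## vertex, drop its conflicts; keep the best of `restarts` seeded runs
misGreedy <- function(adj, order, restarts = 1000, seed = 73939133) {
  best <- integer(0)
  withSeed(seed, {
    for (r in seq_len(restarts)) {
      cand <- if (r == 1) order else sample(order)
      chosen <- integer(0)
      while (length(cand)) {
        v <- cand[1]
        chosen <- c(chosen, v)
        cand <- setdiff(cand[-1], adj[[v]])
      }
      if (length(chosen) > length(best)) best <- chosen
    }
  })
  best
}

#' Spatially thin occurrences to a minimum separation
#'
#' Returns the largest subset of localities whose pairwise distances are
#' all at least `minDistKm` (the standard rarefaction used to reduce
#' sampling bias before presence-background modelling). The problem is
#' solved as maximum independent set on the conflict graph, exactly by
#' branch and bound within each connected component of up to
#' `exactLimit` localities; larger components use a seeded randomized
#' greedy search with 1000 restarts. Ties are broken deterministically by
#' lexicographic id order.
#'
#' @param occ an [OccurrenceSet-class].
#' @param minDistKm minimum pairwise distance, km.
#' @param exactLimit largest component size solved exactly.
#' @return a thinned [OccurrenceSet-class].
#' @export
thinOccurrences <- function(occ, minDistKm, exactLimit = 25) {
  stopifnot(minDistKm > 0)
  p <- occ@points
  n <- nrow(p)
  if (n <= 1) return(occ)
  ord <- order(p$id)
  p <- p[ord, , drop = FALSE]
  D <- pointDist(cbind(p$x, p$y), cbind(p$x, p$y)) / 1000
  conflict <- D < minDistKm
  diag(conflict) <- FALSE
  adj <- lapply(seq_len(n), function(i) which(conflict[i, ]))
  # connected components of the conflict graph
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v]) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }
  keep <- integer(0)
  for (k in seq_len(cid)) {
    vs <- which(comp == k)        # already in lexicographic id order
    if (length(vs) == 1) { keep <- c(keep, vs); next }
    sel <- if (length(vs) <= exactLimit) misExact(adj, vs)
    else misGreedy(adj, vs, seed = stageSeed(k, "thin-greedy"))
    keep <- c(keep, sel)
  }
  keep <- sort(keep)
  new("OccurrenceSet", points = p[keep, , drop = FALSE],
      sourceLabel = paste0(occ@sourceLabel, " (thinned ", minDistKm, " km)"))
}

#' Gaussian kernel sampling-bias surface
#'
#' Each unmasked cell receives `sum_i exp(-d_i^2 / (2 sigma^2))` over the
#' occurrence localities, with `sigma = radiusKm` and the kernel truncated
#' at 3 sigma; the surface is then rescaled to a maximum of 1. With no
#' localities the surface is uniformly 1 over unmasked cells (documented
#' fallback: no information, no bias).
#'
#' @param occ an [OccurrenceSet-class].
#' @param template [GridLayer-class] providing geometry and mask.
#' @param radiusKm kernel scale (sigma), km.
#' @return bias [GridLayer-class] in `[0, 1]`.
#' @export
biasSurface <- function(occ, template, radiusKm) {
  stopifnot(radiusKm > 0)
  d <- gridDim(template)
  cc <- cellCenters(template)
  sigma <- radiusKm * 1000
  acc <- matrix(0, d[1], d[2])
  p <- occ@points
  if (nrow(p)) {
    cut2 <- (3 * sigma)^2
    for (i in seq_len(nrow(p))) {
      d2 <- (cc$X - p$x[i])^2 + (cc$Y - p$y[i])^2
      kern <- exp(-d2 / (2 * sigma^2))
      kern[d2 > cut2] <- 0
      acc <- acc + kern
    }
    mx <- max(acc[!template@mask])
    if (mx > 0) acc <- acc / mx
  } else {
    acc[] <- 1
  }
  newGrid(acc, xll = template@xll, yll = template@yll,
          cellSize = template@cellSize, mask = template@mask)
}

#' Bias-weighted background sample
#'
#' Draws `n` distinct cells with probability proportional to the bias
#' surface (no cell repeated), placing points at cell centres.
#' Deterministic given `seed`.
#'
#' @param bias bias [GridLayer-class]; values must be non-negative with
#'   positive mass on at least `n` cells.
#' @param n number of background cells.
#' @param seed integer seed.
#' @param exclude optional [OccurrenceSet-class] whose cells are removed
#'   from the candidate pool (by default presence cells stay eligible, the
#'   common presence-background convention).
#' @return a [BackgroundSet-class].
#' @export
sampleBackground <- function(bias, n, seed, exclude = NULL) {
  stopifnot(n >= 1)
  w <- as.vector(bias@values)
  w[as.vector(bias@mask)] <- 0
  w[!is.finite(w) | w < 0] <- 0
  if (!is.null(exclude)) {
    drop <- cellIndexAt(bias, exclude@points$x, exclude@points$y)
    w[drop[!is.na(drop)]] <- 0
  }
  if (sum(w > 0) < n)
    stop("sampling error: only ", sum(w > 0),
         " cells with positive bias for n = ", n)
  cells <- withSeed(seed, sample.int(length(w), n, prob = w))
  cc <- cellCenters(bias)
  new("BackgroundSet",
      points = data.frame(x = cc$X[cells], y = cc$Y[cells], cell = cells),
      seed = as.numeric(seed))
}
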