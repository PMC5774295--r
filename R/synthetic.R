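## Synthetic multi-period climate stacks and biased presence samples with a
## known generating suitability function. Every downstream stage of the
## pipeline can be exercised and validated against this ground truth with
## no external data.

#' Define a synthetic study system
#'
#' The generator emulates the ingredients of a multi-period bioclimatic
#' analysis: each variable is a smooth planar gradient plus a spatially
#' autocorrelated Gaussian noise field (white noise smoothed at
#' `corrLengthKm`), standardised and rescaled to the variable's natural
#' units; designated variable pairs are mixed to a target Pearson
#' correlation; each period adds its configured offsets (a "cooling" of
#' winter minima in a glacial period, a "warming" in a future period); the
#' species' true suitability is a logistic function of the standardised
#' variables; and collections are drawn with spatial sampling bias from a
#' Gaussian kernel centred at `biasCenter`.
#'
#' Defaults describe a 120 x 120 grid of 10-km cells with six bioclimatic
#' variables over three periods (a cold "LGM", a "present" baseline and a
#' warmed "2080"), 200 presences and a south-eastern sampling bias.
#'
#' @param nrow,ncol grid shape.
#' @param cellSizeKm cell size in km.
#' @param variables variable names (bio1-bio19 convention).
#' @param variableMeans,variableSds generative mean and sd per variable in
#'   natural units (degC, mm, sd-units for seasonality).
#' @param corrLengthKm spatial autocorrelation scale of the noise.
#' @param gradientWeight fraction of each field's variance carried by the
#'   smooth gradient (0-1).
#' @param crossCorrelation data.frame (var1, var2, r): designated pairs and
#'   their target Pearson correlation.
#' @param periods period labels, earliest first.
#' @param periodOffsets named list mapping period -> named numeric additive
#'   offsets (natural units); variables not named shift by 0.
#' @param trueIntercept,trueCoefficients generating logistic model on
#'   standardised variables.
#' @param biasCenter sampling-kernel centre, km (x, y).
#' @param biasSdKm sampling-kernel sd, km.
#' @param nPresences number of presences to draw.
#' @param seed master seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(
    nrow = 120, ncol = 120, cellSizeKm = 10,
    variables = c("bio1", "bio4", "bio6", "bio9", "bio12", "bio14"),
    variableMeans = c(bio1 = 15, bio4 = 700, bio6 = 2, bio9 = 8,
                      bio12 = 1200, bio14 = 40),
    variableSds = c(bio1 = 4, bio4 = 120, bio6 = 5, bio9 = 5,
                    bio12 = 350, bio14 = 18),
    corrLengthKm = 60,
    gradientWeight = 0.5,
    crossCorrelation = data.frame(var1 = "bio1", var2 = "bio9", r = 0.9),
    periods = c("LGM", "present", "2080"),
    periodOffsets = list(
      LGM = c(bio1 = -1.5, bio4 = 40, bio6 = -2.2, bio9 = -1.5,
              bio12 = -90, bio14 = -4),
      present = c(),
      `2080` = c(bio1 = 1.2, bio4 = -25, bio6 = 1.4, bio9 = 1.2,
                 bio12 = 60, bio14 = 2.5)),
    trueIntercept = -5,
    trueCoefficients = c(bio1 = 2, bio4 = -2.5, bio6 = 3.75, bio9 = 0,
                         bio12 = 2.5, bio14 = 1.25),
    biasCenter = c(0.75, 0.35) * c(ncol, nrow) * cellSizeKm,
    biasSdKm = 0.15 * nrow * cellSizeKm,
    nPresences = 200, seed = 2024) {
  new("SyntheticSpec",
      nrow = nrow, ncol = ncol, cellSizeKm = cellSizeKm,
      variables = variables,
      variableMeans = variableMeans[variables],
      variableSds = variableSds[variables],
      corrLengthKm = corrLengthKm, gradientWeight = gradientWeight,
      crossCorrelation = crossCorrelation, periods = periods,
      periodOffsets = periodOffsets, trueIntercept = trueIntercept,
      trueCoefficients = trueCoefficients[variables],
      biasCenter = biasCenter, biasSdKm = biasSdKm,
      nPresences = nPresences, seed = seed)
}

## standardised spatial field: gradient (direction varies by index) mixed
## with smoothed noise
syntheticField <- function(spec, k) {
  nr <- spec@nrow; nc <- spec@ncol
  theta <- pi * (k - 1) / max(1, length(spec@variables))
  X <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  Y <- matrix(rev(seq_len(nr)), nr, nc)      # row 1 = north = largest y
  G <- cos(theta) * (X - mean(X)) / stats::sd(X) +
    sin(theta) * (Y - mean(Y)) / stats::sd(Y)
  G <- (G - mean(G)) / stats::sd(G)
  E <- gaussianSmooth(matrix(stats::rnorm(nr * nc), nr, nc),
                      spec@corrLengthKm / spec@cellSizeKm)
  E <- (E - mean(E)) / stats::sd(E)
  w <- spec@gradientWeight
  Z <- sqrt(w) * G + sqrt(1 - w) * E
  (Z - mean(Z)) / stats::sd(Z)
}

#' Generate the multi-period climate series
#'
#' Deterministic given `spec@seed`. For each designated pair the second
#' variable's standardised field is rebuilt as `r * Z1 + sqrt(1 - r^2) *
#' resid`, where `resid` is the second field orthogonalised against the
#' first, so the realised cell-level Pearson correlation hits the target.
#' Period offsets are purely additive, so zero offsets reproduce the base
#' period exactly.
#'
#' @param spec a [SyntheticSpec-class].
#' @return named list of [ClimateStack-class], one per period.
#' @export
makeClimateSeries <- function(spec) {
  validObject(spec)
  withSeed(stageSeed(spec@seed, "climate"), {
    K <- length(spec@variables)
    fields <- lapply(seq_len(K), function(k) syntheticField(spec, k))
    names(fields) <- spec@variables
    cc <- spec@crossCorrelation
    for (i in seq_len(nrow(cc))) {
      a <- as.character(cc$var1[i]); b <- as.character(cc$var2[i])
      r <- cc$r[i]
      if (!all(c(a, b) %in% spec@variables))
        stop("cross-correlation names unknown variable: ", a, "/", b)
      if (abs(r) > 1) stop("unreachable cross-correlation ", r)
      za <- as.vector(fields[[a]]); zb <- as.vector(fields[[b]])
      resid <- zb - za * sum(za * zb) / sum(za * za)
      resid <- (resid - mean(resid)) / stats::sd(resid)
      zb2 <- r * za + sqrt(1 - r^2) * resid
      zb2 <- (zb2 - mean(zb2)) / stats::sd(zb2)
      fields[[b]] <- matrix(zb2, spec@nrow, spec@ncol)
    }
    cellM <- spec@cellSizeKm * 1000
    stacks <- lapply(spec@periods, function(p) {
      off <- spec@periodOffsets[[p]] %||% c()
      grids <- lapply(spec@variables, function(v) {
        vals <- spec@variableMeans[[v]] + spec@variableSds[[v]] * fields[[v]] +
          (if (v %in% names(off)) off[[v]] else 0)
        newGrid(vals, xll = 0, yll = 0, cellSize = cellM,
                crsLabel = "synthetic-km-plane")
      })
      names(grids) <- spec@variables
      buildStack(grids, p)
    })
    names(stacks) <- spec@periods
    stacks
  })
}

#' Ground-truth suitability of a synthetic stack
#'
#' Logistic of the generating linear predictor evaluated on variables
#' standardised by the spec's generative means and sds (so period offsets
#' shift suitability, as climate change should).
#'
#' @param stack a [ClimateStack-class] from [makeClimateSeries()].
#' @param spec the generating [SyntheticSpec-class].
#' @return suitability [GridLayer-class] with values in (0, 1).
#' @export
trueSuitability <- function(stack, spec) {
  missing <- setdiff(names(spec@trueCoefficients)[spec@trueCoefficients != 0],
                     variableNames(stack))
  if (length(missing))
    stop("stack lacks variables required by the truth: ",
         paste(missing, collapse = ", "))
  lp <- spec@trueIntercept
  for (v in spec@variables) {
    if (!v %in% variableNames(stack)) next
    z <- (getLayer(stack, v)@values - spec@variableMeans[[v]]) /
      spec@variableSds[[v]]
    lp <- lp + spec@trueCoefficients[[v]] * z
  }
  tmpl <- stack@layers[[1]]
  newGrid(1 / (1 + exp(-lp)), xll = tmpl@xll, yll = tmpl@yll,
          cellSize = tmpl@cellSize, mask = tmpl@mask,
          crsLabel = tmpl@crsLabel)
}

#' Synthetic sampling-bias kernel
#'
#' Gaussian bump at the spec's bias centre plus a small uniform floor, so
#' every cell retains positive sampling mass.
#'
#' @param spec a [SyntheticSpec-class].
#' @param template a [GridLayer-class] providing geometry and mask.
#' @param floor uniform baseline added to the kernel.
#' @return bias [GridLayer-class], maximum 1 on unmasked cells.
#' @export
syntheticBias <- function(spec, template, floor = 0.05) {
  cc <- cellCenters(template)
  d2 <- (cc$X - spec@biasCenter[1] * 1000)^2 +
    (cc$Y - spec@biasCenter[2] * 1000)^2
  b <- exp(-d2 / (2 * (spec@biasSdKm * 1000)^2)) + floor
  b <- b / max(b[!template@mask])
  newGrid(b, xll = template@xll, yll = template@yll,
          cellSize = template@cellSize, mask = template@mask)
}

#' Draw biased presence localities from a truth surface
#'
#' Cells are drawn without replacement with probability proportional to
#' `truth * bias`; points are placed at cell centres. Deterministic given
#' `seed`.
#'
#' @param truth suitability [GridLayer-class].
#' @param bias sampling-bias [GridLayer-class], aligned with `truth`.
#' @param n number of presences.
#' @param seed integer seed.
#' @return an [OccurrenceSet-class].
#' @export
sampleOccurrences <- function(truth, bias, n, seed) {
  if (!sameGeometry(truth, bias)) stop("truth and bias grids not aligned")
  w <- as.vector(truth@values * bias@values)
  w[as.vector(truth@mask)] <- 0
  w[!is.finite(w) | w < 0] <- 0
  if (sum(w > 0) < n)
    stop("sampling error: only ", sum(w > 0),
         " cells with positive weight for n = ", n)
  cells <- withSeed(seed, sample.int(length(w), n, prob = w))
  cc <- cellCenters(truth)
  new("OccurrenceSet",
      points = data.frame(id = sprintf("occ%04d", seq_len(n)),
                          x = cc$X[cells], y = cc$Y[cells],
                          stringsAsFactors = FALSE),
      sourceLabel = "synthetic")
}

#' Write a complete synthetic fixture to disk
#'
#' Emits the same artefacts the pipeline consumes: one grid file per
#' variable per period, plus the occurrence CSV (drawn from the present
#' period's truth with the spec's sampling bias).
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir output directory.
#' @param format grid format, `"ascii_grid"` or `"geotiff"`.
#' @param trainingPeriod period whose truth generates the presences.
#' @return invisibly, a list with the stack directories and occurrence CSV
#'   path.
#' @export
writeFixture <- function(spec, dir, format = "ascii_grid",
                         trainingPeriod = "present") {
  stacks <- makeClimateSeries(spec)
  dirs <- character(0)
  for (p in names(stacks)) {
    d <- file.path(dir, p)
    writeStackDir(stacks[[p]], d, format)
    dirs[p] <- d
  }
  truth <- trueSuitability(stacks[[trainingPeriod]], spec)
  bias <- syntheticBias(spec, truth)
  occ <- sampleOccurrences(truth, bias, spec@nPresences,
                           stageSeed(spec@seed, "occurrences"))
  occPath <- file.path(dir, "occurrences.csv")
  writeOccurrences(occ, occPath)
  invisible(list(stackDirs = dirs, occurrences = occPath))
}
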