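## Internal numerical and RNG helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves moving away from zero
#' (so 0.05 -> 0.1 and -0.05 -> -0.1), the convention used by the
#' change-accounting tables. Base `round()` rounds halves to even, which
#' makes table reproduction depend on binary representation.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
roundHalfAwayFromZero <- function(x, digits = 1) {
  p <- 10^digits
  # nudge by a few ulps so values stored as e.g. 16.7499999... still behave
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

## log(sum(exp(x))) without overflow
logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Derive a per-stage seed from a master seed and a stage name, so adding
## replicates to one stage cannot perturb another stage's draws. Kept
## strictly below 2^31.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 7919 + h * 104729) %% 2147483647
}

## Euclidean distance matrix between two point sets given as two-column
## matrices (metres in, metres out).
pointDist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

## Compass bearing (degrees clockwise from north) of displacement (dx, dy).
bearingDeg <- function(dx, dy) {
  b <- atan2(dx, dy) * 180 / pi
  (b + 360) %% 360
}

## Separable Gaussian smoothing of a matrix with reflected edges; sigma in
## cell units, kernel truncated at 3 sigma.
gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(v) {
    n <- length(v)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
    idx[idx < 1] <- 1 - idx[idx < 1]        # reflect
    idx[idx > n] <- 2 * n + 1 - idx[idx > n]
    padded <- v[idx]
    as.numeric(stats::filter(padded, k, sides = 2))[(r + 1):(r + n)]
  }
  m2 <- apply(m, 2, smooth1)
  t(apply(m2, 1, smooth1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
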