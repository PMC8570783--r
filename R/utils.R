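## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so package functions that
#' take an explicit `seed` argument never disturb the session RNG stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Gaussian-kernel smoothing of an equally spaced series, edge-normalized
#' @param x numeric series
#' @param sd kernel standard deviation in grid cells
#' @noRd
smoothField <- function(x, sd) {
  if (sd <= 0) return(x)
  ## 5-sigma support: truncating nearer injects micro-jitter (kernel edge
  ## discontinuities) that riddles the field with spurious local extrema
  half <- max(1L, ceiling(5 * sd))
  k <- dnorm(seq(-half, half), sd = sd)
  n <- length(x)
  ## zero-pad and renormalize by the kernel mass inside the range, so edges
  ## are averages of fewer points rather than extrapolations of one draw
  xp <- c(rep(0, half), x, rep(0, half))
  wp <- c(rep(0, half), rep(1, n), rep(0, half))
  num <- stats::filter(xp, k, sides = 2)
  den <- stats::filter(wp, k, sides = 2)
  as.numeric(num[(half + 1L):(half + n)]) /
    as.numeric(den[(half + 1L):(half + n)])
}

## --- alignability masks -----------------------------------------------------
## A mask is a named list of logical Rle, one per chromosome, one element per
## base pair. Cumulative-count queries are answered from run boundaries.

maskRunTable <- function(rle) {
  rl <- runLength(rle)
  rv <- as.logical(runValue(rle))
  ends <- cumsum(as.numeric(rl))
  cumAlign <- cumsum(as.numeric(rl) * rv)
  list(ends = ends, val = rv, cumAlign = cumAlign,
       ends0 = c(0, ends), cum0 = c(0, cumAlign))
}

## number of alignable positions in [1, p] for a vector of positions p
maskCumAlign <- function(rt, p) {
  p <- pmin(pmax(p, 0), rt$ends[length(rt$ends)])
  i <- findInterval(p, rt$ends + 0.5) + 1L   # run index containing p
  rt$cum0[i] + ifelse(rt$val[i], p - rt$ends0[i], 0)
}

## alignable positions in (a, b] (i.e. 0-based half-open [a, b))
maskCountRange <- function(rt, a, b) maskCumAlign(rt, b) - maskCumAlign(rt, a)

## 1-based position of the m-th alignable base (vectorized over m)
maskNthAlignable <- function(rt, m) {
  ca <- rt$cumAlign
  i <- findInterval(m - 0.5, ca) + 1L         # run index holding the m-th
  prevEnd <- c(0, rt$ends)[i]
  prevCum <- c(0, ca)[i]
  prevEnd + (m - prevCum)
}

checkMask <- function(mask) {
  if (!is.list(mask) || is.null(names(mask)) || any(!nzchar(names(mask))))
    stop("alignability mask must be a named list of logical Rle, one per chromosome")
  invisible(mask)
}

## GC-dependent coverage bias: multiplicative, unimodal (log-quadratic),
## peaked near gc = `peak`, strictly positive.
gcBiasCurve <- function(gc, amplitude, peak = 0.40) {
  exp(-amplitude * (gc - peak)^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
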