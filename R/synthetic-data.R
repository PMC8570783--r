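## Ground-truthed simulator of polyploid-tissue sequencing depth.
##
## The signal model: in a population with S-phase fraction s, a cell outside
## S phase contributes 1 (relative) copy of every locus; a cell in S phase
## contributes 1 + r(i), where r(i) is the fraction of S-phase cells that
## have already replicated locus i. Cells are uniform in S-phase time t in
## [0, 1] and a locus with replication time rt(i) (1 = earliest) replicates
## when t >= 1 - rt(i), so E[r(i)] = rt(i). Underreplication multiplies the
## expected copy by the region's retention u, GC bias multiplies by a
## unimodal positive curve, and counts are Poisson (optionally
## negative-binomial) around the window's expected depth.

#' Generate a synthetic reference genome
#'
#' Builds chromosomes with a smooth GC landscape (clipped Gaussian random
#' field, mean approximately 0.42) and a uniquely-alignable mask. Alignability
#' is block-structured: consecutive 100-bp blocks are independently alignable
#' with probability `alignableFraction`, mimicking the patchy mappability of
#' a real reference at read-length resolution.
#'
#' @param nChrom number of chromosomes
#' @param chromLength chromosome length in bp (positive multiple of `grid`)
#' @param grid GC-track grid step in bp
#' @param gcSmoothness characteristic width of GC variation, bp
#' @param alignableFraction probability that a 100-bp block is alignable,
#'   in `(0, 1]`
#' @param seed integer seed (mandatory; generation is deterministic given it)
#' @param gcSD standard deviation of the GC field before clipping
#' @return a [SyntheticGenome-class]
#' @export
generateGenome <- function(nChrom = 2L, chromLength = 20e6, grid = 1000,
                           gcSmoothness = 200e3, alignableFraction = 1,
                           seed, gcSD = 0.06) {
  if (nChrom < 1L) stop("nChrom must be >= 1")
  if (chromLength <= 0) stop("chromosome length must be positive")
  if (chromLength %% grid != 0) stop("grid must divide chromLength")
  if (alignableFraction <= 0 || alignableFraction > 1)
    stop("alignableFraction must be in (0, 1]")
  block <- 100L
  if (chromLength %% block != 0) stop("chromLength must be a multiple of 100 bp")
  withSeed(seed, {
    nCell <- chromLength / grid
    gc <- list(); al <- list()
    for (i in seq_len(nChrom)) {
      f <- smoothField(rnorm(nCell), sd = gcSmoothness / (2 * grid))
      f <- (f - mean(f)) / sd(f)
      gc[[i]] <- pmin(1, pmax(0, 0.42 + gcSD * f))
      if (alignableFraction == 1) {
        al[[i]] <- Rle(TRUE, chromLength)
      } else {
        nb <- chromLength / block
        ok <- runif(nb) < alignableFraction
        if (!any(ok)) ok[1L] <- TRUE
        al[[i]] <- Rle(ok, rep(block, nb))
      }
    }
    names(al) <- paste0("chr", seq_len(nChrom))
    new("SyntheticGenome", chromNames = names(al),
        chromLengths = rep(chromLength, nChrom), grid = grid,
        gc = gc, alignability = al, seed = as.integer(seed))
  })
}

#' Simulate a smooth replication-timing landscape
#'
#' A Gaussian random field smoothed at `domainScale`, then rank-uniformized
#' per chromosome (a Gaussian copula) so the values span `[0, 1]` with a
#' uniform marginal (1 = earliest). The smooth field contributes the domain
#' structure — peaks and troughs every few hundred kb, strong
#' autocorrelation — while the uniform marginal matches the broad spread of
#' replication times across S phase seen in empirical RT profiles (a raw
#' range-rescaled Gaussian field would instead concentrate most of the
#' genome in a narrow mid-range band).
#'
#' @param genome a [SyntheticGenome-class]
#' @param domainScale characteristic domain width in bp (must be at least
#'   10 grid steps)
#' @param seed integer seed
#' @return a [TrueRT-class]
#' @export
simulateRTLandscape <- function(genome, domainScale = 500e3, seed) {
  grid <- genome@grid
  if (domainScale < 10 * grid)
    stop("domainScale must be at least 10 grid steps")
  withSeed(seed, {
    rt <- lapply(genome@gc, function(g) {
      f <- smoothField(rnorm(length(g)), sd = domainScale / (2 * grid))
      (rank(f) - 1) / (length(f) - 1)     # uniform marginal, spans [0, 1]
    })
    new("TrueRT", rt = rt, grid = grid, domainScale = domainScale)
  })
}

#' Assemble the full ground truth of one simulated condition
#'
#' Places underreplicated (UR) regions of random length on each chromosome
#' arm and one pericentric-heterochromatin (PH) block at each chromosome end.
#' PH blocks get reduced alignability (patchy mappability) and partial copy
#' retention; the latent RT inside UR and PH regions is pulled toward late
#' (multiplied by `urLateFactor` / `phLateFactor`), since underreplicated
#' regions are late replicating.
#'
#' @param nChrom,chromLength,grid,gcSmoothness,alignableFraction,gcSD passed
#'   to [generateGenome()]
#' @param domainScale passed to [simulateRTLandscape()]
#' @param sFraction fraction of cells in S phase (default 0.15; the method
#'   assumes roughly 0.10 or more)
#' @param ploidy nominal tissue ploidy (informational)
#' @param meanDepth expected reads per full window
#' @param u copy retention inside UR regions, in `(0, 1]`
#' @param urPerChrom number of UR regions per chromosome
#' @param urLengthRange UR region length range, bp
#' @param phFraction fraction of each chromosome (at its right end) modelled
#'   as PH
#' @param phU copy retention inside PH
#' @param phAlignableFactor multiplicative thinning of alignability inside PH
#' @param gcBiasAmplitude,gcBiasPeak GC-bias curve `exp(-a (gc - peak)^2)`
#' @param urLateFactor,phLateFactor RT multipliers inside UR / PH
#' @param seed integer seed (mandatory)
#' @return a [SyntheticTruth-class]
#' @export
simulateTruth <- function(nChrom = 2L, chromLength = 20e6, grid = 1000,
                          gcSmoothness = 200e3, alignableFraction = 0.85,
                          gcSD = 0.06, domainScale = 500e3,
                          sFraction = 0.15, ploidy = 1024L, meanDepth = 100,
                          u = 0.3, urPerChrom = 3L,
                          urLengthRange = c(60e3, 200e3),
                          phFraction = 0.08, phU = 0.6,
                          phAlignableFactor = 0.5,
                          gcBiasAmplitude = 8, gcBiasPeak = 0.40,
                          urLateFactor = 0.4, phLateFactor = 0.3, seed) {
  if (missing(seed)) stop("an explicit 'seed' is required")
  genome <- generateGenome(nChrom, chromLength, grid, gcSmoothness,
                           alignableFraction, seed = seed, gcSD = gcSD)
  rt <- simulateRTLandscape(genome, domainScale, seed = seed + 1L)

  phLen <- floor(chromLength * phFraction / grid) * grid
  if (phLen > 0) {
    ph <- GRanges(genome@chromNames,
                  IRanges(start = chromLength - phLen + 1L, end = chromLength))
    ph$label <- "PH"
    ph$u <- phU
  } else {
    ph <- GRanges()
    ph$label <- character(0)
    ph$u <- numeric(0)
  }

  ur <- withSeed(seed + 2L, {
    out <- GRanges()
    for (ch in genome@chromNames) {
      placed <- GRanges()
      tries <- 0L
      while (length(placed) < urPerChrom && tries < 200L) {
        tries <- tries + 1L
        len <- round(runif(1, urLengthRange[1], urLengthRange[2]) / grid) * grid
        s <- floor(runif(1, 0.03, 0.85) * chromLength / grid) * grid + 1
        cand <- GRanges(ch, IRanges(start = s, width = len))
        if (end(cand) > chromLength - phLen - 200e3) next
        if (length(placed) &&
            any(overlapsAny(cand + 500e3, placed))) next
        placed <- suppressWarnings(c(placed, cand))
      }
      out <- suppressWarnings(c(out, placed))
    }
    out <- sort(out)
    out$label <- rep("eUR", length(out))
    out$u <- rep(u, length(out))
    out
  })

  ## thin alignability and pull RT late inside PH; pull RT late inside UR
  nCell <- chromLength / grid
  for (i in seq_along(genome@chromNames)) {
    m <- genome@alignability[[i]]
    phStart <- chromLength - phLen + 1L
    if (phAlignableFactor < 1 && phLen > 0) {
      sub <- as.logical(m[phStart:chromLength])
      keep <- withSeed(seed + 10L + i,
                       runif(length(sub)) < phAlignableFactor)
      newsub <- sub & keep
      if (!any(newsub)) newsub[which(sub)[1L]] <- TRUE
      genome@alignability[[i]] <-
        c(m[1:(phStart - 1L)], Rle(newsub))
    }
    cellMid <- (seq_len(nCell) - 0.5) * grid
    inPH <- cellMid >= phStart
    rt@rt[[i]][inPH] <- rt@rt[[i]][inPH] * phLateFactor
    urHere <- ur[seqnames(ur) == genome@chromNames[i]]
    for (j in seq_along(urHere)) {
      inUR <- cellMid >= start(urHere)[j] & cellMid <= end(urHere)[j]
      rt@rt[[i]][inUR] <- rt@rt[[i]][inUR] * urLateFactor
    }
  }

  new("SyntheticTruth", genome = genome, rt = rt, urRegions = ur,
      phRegions = ph, sFraction = sFraction, ploidy = as.integer(ploidy),
      meanDepth = meanDepth, gcBias = c(amplitude = gcBiasAmplitude,
                                        peak = gcBiasPeak),
      seed = as.integer(seed))
}

#' Expected relative copy number per grid cell
#'
#' The closed form of the simulator's signal model:
#' `u(i) * ((1 - s) + s * (1 + r(i))) * bias(gc(i))`, where `r(i)` is the
#' fraction of S-phase cells that have replicated cell `i` (equal to `rt(i)`
#' for an infinite population, or a sampled fraction for `nCells` finite).
#'
#' @param truth a [SyntheticTruth-class]
#' @param nCells number of S-phase cells to sample (default `Inf`: use the
#'   analytic expectation `r = rt`)
#' @param seed seed for the finite-cell sample (required if `nCells < Inf`)
#' @return list of numeric vectors, one per chromosome, one value per grid
#'   cell
#' @export
expectedCopy <- function(truth, nCells = Inf, seed = NULL) {
  g <- truth@genome
  s <- truth@sFraction
  tS <- NULL
  if (is.finite(nCells)) {
    if (is.null(seed)) stop("seed required for finite nCells")
    tS <- sort(withSeed(seed, runif(nCells)))
  }
  out <- vector("list", length(g@chromNames))
  names(out) <- g@chromNames
  for (i in seq_along(out)) {
    rt <- truth@rt@rt[[i]]
    r <- if (is.null(tS)) rt else
      (nCells - findInterval(1 - rt, tS, left.open = TRUE)) / nCells
    uCell <- rep(1, length(rt))
    cellMid <- (seq_along(rt) - 0.5) * g@grid
    for (reg in list(truth@urRegions, truth@phRegions)) {
      rc <- reg[seqnames(reg) == g@chromNames[i]]
      for (j in seq_along(rc)) {
        hit <- cellMid >= start(rc)[j] & cellMid <= end(rc)[j]
        uCell[hit] <- rc$u[j]
      }
    }
    bias <- gcBiasCurve(g@gc[[i]], truth@gcBias[["amplitude"]],
                        truth@gcBias[["peak"]])
    out[[i]] <- uCell * ((1 - s) + s * (1 + r)) * bias
  }
  out
}

#' Simulate window read counts from a ground truth
#'
#' Computes the expected relative copy per grid cell ([expectedCopy()]),
#' integrates it over each window's alignable base pairs, scales so the
#' genome-average full window receives `meanDepth` reads, and draws Poisson
#' (or negative-binomial) counts.
#'
#' @param truth a [SyntheticTruth-class]
#' @param grid optional [WindowGrid-class]; built from the truth's
#'   alignability mask (target 1000 alignable bp) when omitted
#' @param seed integer seed for the count draw (mandatory)
#' @param nCells finite S-phase population size, or `Inf` for the analytic
#'   replication fraction
#' @param dispersion negative-binomial size parameter; `NULL` (default) for
#'   Poisson counts
#' @return list with elements `track` (a raw [DepthTrack-class]), `expected`
#'   (per-window expected counts), `copy` (per-grid-cell expected relative
#'   copy) and `grid`
#' @export
simulateDepth <- function(truth, grid = NULL, seed, nCells = Inf,
                          dispersion = NULL) {
  if (missing(seed)) stop("an explicit 'seed' is required")
  if (truth@meanDepth <= 0) stop("meanDepth must be positive")
  g <- truth@genome
  if (is.null(grid)) {
    grid <- makeWindows(g@alignability, targetAlignable = 1000L)
    grid <- computeGC(g, grid)
  }
  copy <- expectedCopy(truth, nCells = nCells,
                       seed = if (is.finite(nCells)) seed + 1L else NULL)

  nw <- length(grid)
  ew <- numeric(nw)
  chr <- as.character(seqnames(grid))
  for (i in seq_along(g@chromNames)) {
    ch <- g@chromNames[i]
    idx <- which(chr == ch)
    if (!length(idx)) next
    rt <- maskRunTable(g@alignability[[ch]])
    step <- g@grid
    cellStarts <- (seq_along(copy[[i]]) - 1) * step
    cellAlign <- maskCountRange(rt, cellStarts, cellStarts + step)
    cumCA <- c(0, cumsum(copy[[i]] * cellAlign))
    S <- function(p) { # weighted alignable mass in [0, p)
      ci <- pmin(ceiling(p / step), length(cellAlign))
      ci[p == 0] <- 1L
      part <- copy[[i]][ci] *
        (maskCumAlign(rt, p) - maskCumAlign(rt, (ci - 1) * step))
      cumCA[ci] + part
    }
    ew[idx] <- S(end(grid)[idx]) - S(start(grid)[idx] - 1)
  }
  ab <- mcols(grid)$alignable_bp
  target <- max(ab)
  dens <- sum(ew) / sum(ab)          # genome-mean copy per alignable bp
  expected <- truth@meanDepth * ew / (dens * target)

  counts <- withSeed(seed, {
    if (is.null(dispersion)) rpois(nw, expected)
    else rnbinom(nw, mu = expected, size = dispersion)
  })
  list(track = DepthTrack(grid, counts, stage = "raw"),
       expected = expected, copy = copy, grid = grid)
}

#' Derive a perturbed condition from a ground truth
#'
#' Emulates mutant or tissue contrasts: `rtShifts` adds a per-region `delta`
#' to the latent RT (then clips to `[0, 1]`); `urRemoved = TRUE` sets copy
#' retention to 1 everywhere (underreplication fully suppressed), keeping
#' the region annotations themselves.
#'
#' @param truth a [SyntheticTruth-class]
#' @param rtShifts `GRanges` with a numeric `delta` metadata column, or `NULL`
#' @param urRemoved logical
#' @return an independent, modified [SyntheticTruth-class]
#' @export
perturbCondition <- function(truth, rtShifts = NULL, urRemoved = FALSE) {
  out <- truth
  if (urRemoved) {
    if (length(out@urRegions)) out@urRegions$u <- 1
    if (length(out@phRegions)) out@phRegions$u <- 1
  }
  if (!is.null(rtShifts)) {
    if (!is(rtShifts, "GRanges") || is.null(rtShifts$delta))
      stop("rtShifts must be a GRanges with a numeric 'delta' metadata column")
    g <- out@genome
    for (i in seq_along(g@chromNames)) {
      sh <- rtShifts[seqnames(rtShifts) == g@chromNames[i]]
      if (!length(sh)) next
      cellMid <- (seq_along(out@rt@rt[[i]]) - 0.5) * g@grid
      for (j in seq_along(sh)) {
        hit <- cellMid >= start(sh)[j] & cellMid <= end(sh)[j]
        out@rt@rt[[i]][hit] <-
          pmin(1, pmax(0, out@rt@rt[[i]][hit] + sh$delta[j]))
      }
    }
  }
  out
}
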