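## From raw counts to rawRT and smoothed RT: GC correction (bias fit
## excluding eUR/PH), arm-anchored dual normalization, gap-aware spline
## smoothing with per-chromosome standardization, and quartile assignment.

#' GC-bias correction
#'
#' Converts counts to relative copy (mean 1 over usable full windows) and
#' fits the coverage-vs-GC bias curve by robust local regression on the
#' non-excluded windows. Known underreplicated and heterochromatic regions
#' (`exclude`) are held out of the fit so their low copy does not
#' masquerade as GC bias; segmentation-detected low-copy segments with a
#' sharp genomic edge (the signature of a copy dip, as opposed to a smooth
#' GC-bias valley) are held out as well. Every window — excluded ones
#' included — is then divided by its fitted bias and rescaled to preserve
#' the included-set mean.
#'
#' @param track a raw [DepthTrack-class] (counts)
#' @param gc per-window GC fractions; defaults to the grid's `gc` column
#' @param exclude `GRanges` of regions (eUR, PH) held out of the bias fit
#' @param span `loess` span of the bias fit
#' @param segR2 noise variance for the pre-fit segmentation smoothing
#' @param minFit minimum usable windows for the fit
#' @param maxFit windows are subsampled to at most this many for the loess
#'   fit (the curve has one argument; a few thousand points determine it)
#' @return a `gc_corrected` [DepthTrack-class] (relative copy, mean 1 over
#'   included windows)
#' @export
gcCorrect <- function(track, gc = NULL, exclude = GRanges(), span = 0.4,
                      segR2 = 0.04, minFit = 100L, maxFit = 5000L) {
  if (trackStage(track) != "raw")
    stop("gcCorrect expects a raw (count) track")
  grid <- windowGrid(track)
  gc <- gc %||% mcols(grid)$gc
  if (mean(!is.na(gc)) < 0.95)
    stop("GC available for fewer than 95% of windows")
  v <- trackValues(track)
  short <- mcols(grid)$is_short
  usable <- !is.na(v) & !short & !is.na(gc)
  v <- v / mean(v[usable])              # relative copy
  excl <- if (length(exclude))
    labelWindows(grid, eur = exclude) != "arm" else rep(FALSE, length(grid))
  fitIdx <- which(usable & !excl)
  if (length(fitIdx) < minFit)
    stop("fewer than ", minFit, " usable windows for the GC fit")

  ## hold low-copy segments (undiscovered UR dips) out of the fit.
  ## Identification: a copy dip drops discontinuously at its genomic border
  ## (retention u switches while GC varies smoothly), so the value just
  ## outside the segment is much higher than just inside; a deep GC-bias
  ## valley declines continuously with GC and shows no edge jump. Only
  ## jump-edged segments are excluded — removing a genuine bias valley
  ## would leave the curve's tail unconstrained.
  chr <- as.character(seqnames(grid))
  lowSegs <- list()
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    vv <- v[idx]
    vv[!(idx %in% fitIdx)] <- NA
    if (sum(!is.na(vv)) >= 10L) {
      sm <- segmentSeries(vv / mean(vv, na.rm = TRUE), r2 = segR2)
      low <- lowSegments(sm, sdThreshold = 1)
      for (k in seq_along(low))
        lowSegs[[length(lowSegs) + 1L]] <- idx[start(low)[k]:end(low)[k]]
    }
  }
  if (length(lowSegs)) {
    lowWin <- unlist(lowSegs)
    nonLow <- intersect(fitIdx, setdiff(seq_along(v), lowWin))
    edgeJump <- function(w) {
      flank <- 10L
      inn <- c(head(w, flank), tail(w, flank))
      ratios <- c()
      for (side in list(seq(min(w) - flank, min(w) - 1L),
                        seq(max(w) + 1L, max(w) + flank))) {
        side <- side[side %in% nonLow]
        if (length(side) >= 3L)
          ratios <- c(ratios, mean(v[side]) / mean(v[inn], na.rm = TRUE))
      }
      length(ratios) && max(ratios) >= 1.5
    }
    drop <- unlist(lowSegs[vapply(lowSegs, edgeJump, logical(1))])
    if (length(setdiff(fitIdx, drop)) >= minFit)
      fitIdx <- setdiff(fitIdx, drop)
  }

  fi <- fitIdx
  if (length(fi) > maxFit)   # deterministic thinning: runs are reproducible
    fi <- fi[unique(round(seq(1L, length(fi), length.out = maxFit)))]
  fit <- loess(y ~ x, data = data.frame(x = gc[fi], y = v[fi]),
               span = span, degree = 2, family = "symmetric",
               control = loess.control(surface = "interpolate"))
  rng <- range(gc[fi])
  bias <- predict(fit, newdata = data.frame(x = pmin(pmax(gc, rng[1]), rng[2])))
  bias <- pmax(bias, 0.1 * median(bias, na.rm = TRUE))
  corrected <- v / bias
  corrected <- corrected * mean(v[fitIdx]) / mean(corrected[fitIdx])
  new("DepthTrack", grid = grid, values = corrected,
      label = track@label, stage = "gc_corrected")
}

#' @importFrom stats loess.control
NULL

#' Arm-anchored dual normalization
#'
#' Computes the mean and SD of the non-missing, full (not short-flagged)
#' windows labeled `arm`, and applies the same affine transform
#' `(v - mean_arm) / sd_arm` to every window — arm, eUR and PH alike. Arm
#' windows end up with exactly mean 0 and SD 1, while underreplicated
#' windows keep their depressed copy number (they may lie far below 0)
#' instead of being absorbed into the genome-wide scale.
#'
#' @param track a `gc_corrected`, outlier-filtered [DepthTrack-class]
#' @param labels per-window labels (default: the track's)
#' @param perChromosome anchor per chromosome instead of genome-wide
#'   (default `FALSE`)
#' @return a `rawRT` [DepthTrack-class]
#' @export
dualNormalize <- function(track, labels = NULL, perChromosome = FALSE) {
  if (!trackStage(track) %in% c("gc_corrected"))
    stop("dualNormalize expects a gc_corrected track")
  grid <- windowGrid(track)
  lab <- if (is.null(labels)) trackLabels(track)
         else asRegionLabel(labels, length(grid))
  v <- trackValues(track)
  arm <- lab == "arm" & !is.na(v) & !mcols(grid)$is_short
  chr <- as.character(seqnames(grid))
  for (ch in unique(chr))
    if (sum(arm[chr == ch]) < 2L)
      stop("fewer than 2 usable arm windows on ", ch)
  z <- v
  if (perChromosome) {
    for (ch in unique(chr)) {
      idx <- chr == ch
      mu <- mean(v[idx & arm]); sg <- sd(v[idx & arm])
      if (sg == 0) stop("zero arm variance on ", ch)
      z[idx] <- (v[idx] - mu) / sg
    }
  } else {
    mu <- mean(v[arm]); sg <- sd(v[arm])
    if (sg == 0) stop("zero arm variance")
    z <- (v - mu) / sg
  }
  new("DepthTrack", grid = grid, values = z, label = lab, stage = "rawRT")
}

#' Cubic smoothing-spline RT profile
#'
#' Splits each chromosome into contiguity zones — consecutive non-missing
#' windows of one region label, bridging missing stretches only when their
#' genomic span is at most `maxGap` bp — and fits each zone with a cubic
#' smoothing spline. Zones break at arm/eUR/PH label boundaries because the
#' copy-number step at an underreplicated-region border is not replication
#' signal; smoothing across it would bleed the dip into its neighbours.
#' Each zone is fit with a spline
#' minimizing `p * sum((y - f)^2) + (1 - p) * integral(f'')^2` with x the
#' window genomic midpoint in bp. Zones with fewer than `minZone`
#' non-missing windows are dropped (left missing). Smoothed values are then
#' standardized to mean 0, SD 1 per chromosome.
#'
#' @param track a `rawRT` [DepthTrack-class]
#' @param p smoothing parameter in `(0, 1)`; the default `1e-15` gives an
#'   equivalent smoothing bandwidth of a few tens of kb at 1-kb windows
#' @param minZone minimum non-missing windows per zone (default 21, i.e.
#'   zones of more than 20 windows)
#' @param maxGap largest missing genomic span smoothed across, bp
#' @return a `smoothedRT` [DepthTrack-class]
#' @export
smoothRT <- function(track, p = 1e-15, minZone = 21L, maxGap = 5e3) {
  if (trackStage(track) != "rawRT")
    stop("smoothRT expects a rawRT track")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  grid <- windowGrid(track)
  v <- trackValues(track)
  chr <- as.character(seqnames(grid))
  mid <- (start(grid) + end(grid)) / 2
  out <- rep(NA_real_, length(v))
  lab <- as.integer(track@label)
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    ok <- idx[!is.na(v[idx])]
    if (length(ok) < minZone) next
    ## zone split: genomic gap between consecutive usable windows > maxGap,
    ## or a region-label change
    gapBp <- start(grid)[ok[-1]] - end(grid)[ok[-length(ok)]] - 1
    labChange <- lab[ok[-1]] != lab[ok[-length(ok)]]
    zone <- cumsum(c(0, gapBp > maxGap | labChange))
    for (z in unique(zone)) {
      zi <- ok[zone == z]
      if (length(zi) < minZone) next
      x <- mid[zi]; y <- v[zi]
      lam <- ((1 - p) / p) / diff(range(x))^3
      fit <- smooth.spline(x, y, lambda = lam, all.knots = TRUE,
                           keep.data = FALSE)
      out[zi] <- predict(fit, x)$y
    }
  }
  ## per-chromosome standardization of the smoothed profile
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    s <- out[idx]
    if (sum(!is.na(s)) >= 2L) {
      mu <- mean(s, na.rm = TRUE); sg <- sd(s, na.rm = TRUE)
      if (sg > 0) out[idx] <- (s - mu) / sg
    }
  }
  new("DepthTrack", grid = grid, values = out, label = track@label,
      stage = "smoothedRT")
}

#' Genome-wide RT quartiles
#'
#' Ranks the non-missing values genome-wide and assigns the highest-value
#' quarter to `Q1` (earliest replicating) down to `Q4` (latest). Assignment
#' is by rank, so quartile occupancies differ by at most one window and ties
#' break deterministically in series order. The reported cutoffs are the
#' 75th/50th/25th percentiles (R's default quantile type, missing removed).
#'
#' @param values numeric RT values (missing allowed; at least 4 non-missing)
#' @return list with `quartile` (factor `Q1`..`Q4`, `NA` where missing) and
#'   `cutoffs` (named numeric of length 3)
#' @export
assignQuartiles <- function(values) {
  v <- as.numeric(values)
  m <- sum(!is.na(v))
  if (m < 4L) stop("need at least 4 non-missing values")
  r <- rank(-v, ties.method = "first", na.last = "keep")
  q <- ceiling(4 * r / m)
  qf <- factor(paste0("Q", q), levels = paste0("Q", 1:4))
  cutoffs <- quantile(v, probs = c(0.75, 0.5, 0.25), na.rm = TRUE)
  names(cutoffs) <- c("q75", "q50", "q25")
  list(quartile = qf, cutoffs = cutoffs)
}

#' Run the full RT pipeline on one raw count track
#'
#' Orchestrates the stages: a provisional low-copy screen (segmentation of
#' the raw counts) plus the supplied PH regions are held out of the GC-bias
#' fit; GC correction; eUR calling on the corrected copy number (optionally
#' merged with a prior region list); arm/eUR/PH window labeling; separate
#' outlier filtering of arm (`sdArm` SDs) and eUR (`sdEUR` SDs) windows
#' (PH is left unfiltered); arm-anchored dual normalization; spline
#' smoothing; quartile assignment.
#'
#' @param track a raw [DepthTrack-class] (counts) with GC in its grid
#' @param ph `GRanges` of pericentric-heterochromatin regions (annotation
#'   input; PH is masked, never discovered)
#' @param publishedUR optional `GRanges` of prior UR regions merged into the
#'   eUR call
#' @param params pipeline parameters, see [defaultParams()]
#' @param quartileOn classify quartiles on the `smoothed` (default) or
#'   `rawRT` track
#' @return an [RTProfile-class]
#' @export
buildRTProfile <- function(track, ph = GRanges(), publishedUR = NULL,
                           params = defaultParams(),
                           quartileOn = c("smoothed", "rawRT")) {
  quartileOn <- match.arg(quartileOn)
  grid <- windowGrid(track)

  ## GC correction holds out the annotated PH (and any prior UR list); the
  ## two-pass fit inside gcCorrect handles the not-yet-discovered eUR dips
  exclude <- if (length(ph)) granges(ph) else GRanges()
  if (!is.null(publishedUR) && length(publishedUR))
    exclude <- mergeRegions(exclude, granges(publishedUR), gap = 0)
  corrected <- gcCorrect(track, exclude = exclude, span = params$gcSpan,
                         segR2 = params$eurR2)

  eur <- callEUR(corrected, r2 = params$eurR2, sdThreshold = params$eurSD,
                 minLen = params$eurMinLen, maxGap = params$eurMaxGap,
                 minSeg = params$minSeg)
  if (length(ph) && length(eur)) {
    ## PH is masked, never discovered: low-copy calls inside PH are PH;
    ## sub-threshold slivers left at PH borders are dropped
    eur <- suppressWarnings(GenomicRanges::setdiff(granges(eur), granges(ph)))
    eur <- eur[width(eur) >= params$eurMinLen]
    if (length(eur)) eur$label <- "eUR"
  }
  if (!is.null(publishedUR) && length(publishedUR))
    eur <- mergeRegions(eur, publishedUR, gap = 0)

  lab <- labelWindows(grid, eur = eur, ph = ph,
                      minFraction = params$overlapFraction)
  trackLabels(corrected) <- lab

  ## outlier filtering: arm and eUR separately, PH untouched
  vv <- trackValues(corrected)
  filt <- vv
  for (which in c("arm", "eUR")) {
    sub <- vv
    sub[lab != which] <- NA
    if (sum(!is.na(sub)) < 2L * params$minSeg) next
    tmp <- new("DepthTrack", grid = grid, values = sub, label = lab,
               stage = "gc_corrected")
    thr <- if (which == "arm") params$outlierSDArm else params$outlierSDEUR
    f <- outlierFilter(tmp, r2 = params$outlierR2, sdThreshold = thr,
                       minSeg = params$minSeg)
    newNA <- is.na(trackValues(f)) & !is.na(sub)
    filt[newNA] <- NA
  }
  corrected@values <- filt

  raw <- dualNormalize(corrected, labels = lab,
                       perChromosome = params$perChromosomeAnchor)
  smoothed <- smoothRT(raw, p = params$splineP, minZone = params$minZone,
                       maxGap = params$smoothMaxGap)
  qsrc <- if (quartileOn == "smoothed") trackValues(smoothed)
          else trackValues(raw)
  qa <- assignQuartiles(qsrc)
  new("RTProfile", rawRT = raw, smoothed = smoothed,
      quartile = qa$quartile, cutoffs = qa$cutoffs)
}
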