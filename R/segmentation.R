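## Penalized least-squares change-point segmentation with an r2 noise
## parameter, used for GC-correction masking, eUR discovery and outlier
## filtering.

## Penalty factor c(n): smallest per-changepoint penalty (in units of noise
## variance) keeping pure Gaussian noise of length n to a single segment in
## >= 95% of runs. Calibrated once by simulation over n = 50..20000 and
## frozen as a linear-in-log(n) envelope with a safety margin.
penaltyFactor <- function(n) 5.9 + 0.87 * log(pmax(n, 2L))

#' Piecewise-constant segmentation of a window-value series
#'
#' Optimal partitioning by penalized least squares: minimizes the sum of
#' within-segment squared errors plus `beta` per additional segment, with
#' `beta = r2 * c(n)` where `r2` is the assumed noise variance *on the scale
#' of the input series* and `c(n)` is a simulation-calibrated factor chosen
#' so that pure noise of variance `r2` yields one segment with probability
#' at least 0.95. Missing values are bridged: they belong to the enclosing
#' segment but contribute no error. Each segment must contain at least
#' `minSeg` non-missing values (forbidding spike-chasing segments).
#'
#' Larger `r2` means "assume more noise" and yields fewer, longer segments;
#' rescaling the series by a factor `a` together with `r2` by `a^2` yields
#' identical breakpoints.
#'
#' @param values numeric series (may contain `NA`)
#' @param r2 assumed noise variance of the series (> 0)
#' @param minSeg minimum non-missing values per segment (default 5)
#' @return a [SegmentModel-class]
#' @export
segmentSeries <- function(values, r2, minSeg = 5L) {
  if (!is.numeric(r2) || length(r2) != 1L || is.na(r2) || r2 <= 0)
    stop("r2 must be a single positive number")
  v <- as.numeric(values)
  ok <- !is.na(v)
  m <- sum(ok)
  if (m == 0L) stop("all values are missing")
  if (m < 2L * minSeg)
    stop("need at least 2 * minSeg = ", 2L * minSeg, " non-missing values")
  beta <- r2 * penaltyFactor(m)
  bp <- .peltSegment(v, beta, as.integer(minSeg))
  segs <- IRanges(start = c(1L, bp + 1L), end = c(bp, length(v)))
  means <- vapply(seq_along(segs), function(i) {
    vv <- v[start(segs)[i]:end(segs)[i]]
    mean(vv, na.rm = TRUE)
  }, numeric(1))
  fitted <- rep(means, width(segs))
  resid <- v - fitted
  new("SegmentModel", breakpoints = as.integer(bp), means = means,
      n = length(v), r2 = r2, penalty = beta, minSeg = as.integer(minSeg),
      seriesMean = mean(v[ok]), seriesSD = sd(v[ok]),
      residSD = sd(resid[ok]))
}

#' Low segments of a segmentation
#'
#' Maximal runs of windows whose segment mean lies at least `sdThreshold`
#' standard deviations below the series mean (mean and SD taken over the
#' non-missing values of the input series).
#'
#' @param model a [SegmentModel-class]
#' @param sdThreshold threshold in multiples of the series SD
#' @return an `IRanges` of window-index intervals (possibly empty)
#' @export
lowSegments <- function(model, sdThreshold = 1) {
  cut <- model@seriesMean - sdThreshold * model@seriesSD
  segs <- segmentRanges(model)
  low <- model@means <= cut
  if (!any(low)) return(IRanges())
  reduce(segs[low])
}

#' Mask outlier windows of a track
#'
#' Segments each chromosome's values, computes the residual SD over the
#' whole series after subtracting segment means, and masks (sets missing)
#' every window whose residual exceeds `sdThreshold` residual SDs. Surviving
#' values are never altered.
#'
#' @param track a [DepthTrack-class] at stage `gc_corrected`
#' @param r2 segmentation noise variance (default 0.06)
#' @param sdThreshold outlier threshold in residual SDs (default 2)
#' @param minSeg minimum non-missing values per segment
#' @return the track with outliers set to `NA`
#' @export
outlierFilter <- function(track, r2 = 0.06, sdThreshold = 2, minSeg = 5L) {
  if (trackStage(track) != "gc_corrected")
    stop("outlierFilter expects a gc_corrected track")
  v <- trackValues(track)
  chr <- as.character(seqnames(windowGrid(track)))
  fitted <- rep(NA_real_, length(v))
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    vv <- v[idx]
    if (sum(!is.na(vv)) < 2L * minSeg)
      stop("fewer than ", 2L * minSeg, " usable windows on ", ch)
    sm <- segmentSeries(vv, r2 = r2, minSeg = minSeg)
    fitted[idx] <- rep(segmentMeans(sm), width(segmentRanges(sm)))
  }
  resid <- v - fitted
  rsd <- sd(resid, na.rm = TRUE)
  out <- !is.na(resid) & abs(resid) > sdThreshold * rsd
  v[out] <- NA_real_
  trackValues(track) <- v
  track
}
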