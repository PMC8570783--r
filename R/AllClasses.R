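## Central S4 data containers. Region sets (eUR, PH, variant, published UR)
## are plain GRanges with a `label` metadata column; everything windowed is
## built on a WindowGrid.

#' WindowGrid: genomic windows of fixed uniquely-alignable content
#'
#' A `GRanges` subclass in which each range is one depth window. Windows are
#' sorted and non-overlapping within a chromosome, and each contains the
#' target number of uniquely alignable base pairs (metadata column
#' `alignable_bp`), except possibly the last window of a chromosome, which is
#' flagged `is_short` and excluded from normalization statistics. The `gc`
#' column holds the G+C fraction of the window's alignable positions (may be
#' `NA` until [computeGC()] is run).
#'
#' @slot .  inherits all slots from `GRanges`
#' @seealso [makeWindows()], [computeGC()]
#' @export
setClass("WindowGrid", contains = "GRanges")

setValidity("WindowGrid", function(object) {
  mc <- mcols(object)
  need <- c("alignable_bp", "gc", "is_short")
  if (!all(need %in% colnames(mc)))
    return(paste("missing metadata columns:",
                 paste(setdiff(need, colnames(mc)), collapse = ", ")))
  if (length(object) > 1L) {
    bychr <- split(object, as.character(seqnames(object)))
    for (g in bychr) {
      if (length(g) < 2L) next
      if (is.unsorted(start(g))) return("windows not sorted within chromosome")
      if (any(start(g)[-1L] < end(g)[-length(g)] + 1L))
        return("windows overlap within chromosome")
    }
  }
  if (any(mc$alignable_bp < 0, na.rm = TRUE))
    return("negative alignable_bp")
  if (any(mc$gc < 0 | mc$gc > 1, na.rm = TRUE))
    return("gc outside [0, 1]")
  TRUE
})

#' DepthTrack: one value per window, with stage and region labels
#'
#' Carries per-window values through the pipeline stages `raw` (read counts),
#' `gc_corrected` (relative copy number), `rawRT` (arm-anchored z scale) and
#' `smoothedRT`. Missing values are explicit `NA`s — never zero-filled. Every
#' window carries exactly one region label: `arm` (fully replicated
#' euchromatin), `eUR` (euchromatic underreplicated) or `PH` (pericentric
#' heterochromatin).
#'
#' @slot grid a [WindowGrid-class]
#' @slot values numeric, one per window, `NA` = missing
#' @slot label factor with levels `arm`, `eUR`, `PH`
#' @slot stage character scalar stage tag
#' @export
setClass("DepthTrack",
  representation(grid = "WindowGrid", values = "numeric",
                 label = "factor", stage = "character"))

.TRACK_STAGES <- c("raw", "gc_corrected", "rawRT", "smoothedRT")

setValidity("DepthTrack", function(object) {
  if (length(object@values) != length(object@grid))
    return("values length differs from grid length")
  if (length(object@label) != length(object@grid))
    return("label length differs from grid length")
  if (!all(levels(object@label) %in% c("arm", "eUR", "PH")))
    return("label levels must be within {arm, eUR, PH}")
  if (anyNA(object@label))
    return("label partition must be total (no NA labels)")
  if (length(object@stage) != 1L || !object@stage %in% .TRACK_STAGES)
    return(paste("stage must be one of:", paste(.TRACK_STAGES, collapse = ", ")))
  TRUE
})

#' SegmentModel: piecewise-constant fit of a window-value series
#'
#' Result of [segmentSeries()]: breakpoints (the last index of every segment
#' but the final one), per-segment means over non-missing members, and the
#' parameters of the fit. `seriesMean`/`seriesSD` are the mean and SD of the
#' non-missing input values (used by [lowSegments()]); `residSD` is the SD of
#' the residuals about the segment means (used by [outlierFilter()]).
#'
#' @export
setClass("SegmentModel",
  representation(breakpoints = "integer", means = "numeric", n = "integer",
                 r2 = "numeric", penalty = "numeric", minSeg = "integer",
                 seriesMean = "numeric", seriesSD = "numeric",
                 residSD = "numeric"))

setValidity("SegmentModel", function(object) {
  b <- object@breakpoints
  if (length(b) && (is.unsorted(b, strictly = TRUE) || b[1L] < 1L ||
                    b[length(b)] >= object@n))
    return("breakpoints must be strictly increasing and inside (0, n)")
  if (length(object@means) != length(b) + 1L)
    return("number of means must equal number of segments")
  TRUE
})

#' RTProfile: rawRT, smoothed RT and quartile classification
#'
#' @slot rawRT [DepthTrack-class] at stage `rawRT` (arm-anchored, unsmoothed;
#'   the unit of all statistical testing)
#' @slot smoothed [DepthTrack-class] at stage `smoothedRT` (spline-smoothed,
#'   standardized per chromosome)
#' @slot quartile factor `Q1`..`Q4` per window (`Q1` = earliest), `NA` where
#'   no RT value exists
#' @slot cutoffs the three genome-wide quartile cutoffs (75th/50th/25th
#'   percentiles of the classified values)
#' @export
setClass("RTProfile",
  representation(rawRT = "DepthTrack", smoothed = "DepthTrack",
                 quartile = "factor", cutoffs = "numeric"))

setValidity("RTProfile", function(object) {
  n <- length(object@rawRT@grid)
  if (length(object@smoothed@grid) != n || length(object@quartile) != n)
    return("rawRT, smoothed and quartile must share one grid")
  if (!identical(levels(object@quartile), c("Q1", "Q2", "Q3", "Q4")))
    return("quartile levels must be Q1..Q4")
  if (length(object@cutoffs) != 3L)
    return("cutoffs must have length 3")
  TRUE
})

#' SyntheticGenome: reference stand-in for depth simulation
#'
#' Chromosome lengths, a per-grid-cell GC fraction track and a per-position
#' uniquely-alignable mask, generated by [generateGenome()].
#'
#' @slot chromNames,chromLengths chromosomes (lengths are multiples of `grid`)
#' @slot grid grid step in bp (GC resolution; default 1000)
#' @slot gc list of numeric vectors, GC fraction per grid cell, in `[0, 1]`
#' @slot alignability named list of logical `Rle`, one element per base pair
#' @export
setClass("SyntheticGenome",
  representation(chromNames = "character", chromLengths = "numeric",
                 grid = "numeric", gc = "list", alignability = "list",
                 seed = "integer"))

setValidity("SyntheticGenome", function(object) {
  if (length(object@chromNames) != length(object@chromLengths))
    return("chromNames and chromLengths differ in length")
  if (any(object@chromLengths <= 0) ||
      any(object@chromLengths %% object@grid != 0))
    return("every chromosome length must be a positive multiple of the grid step")
  for (i in seq_along(object@chromNames)) {
    g <- object@gc[[i]]
    if (length(g) != object@chromLengths[i] / object@grid)
      return("gc track length mismatch")
    if (any(g < 0 | g > 1)) return("gc fractions outside [0, 1]")
    al <- object@alignability[[i]]
    f <- sum(runLength(al) * as.numeric(runValue(al))) / object@chromLengths[i]
    if (f <= 0 || f > 1) return("alignable fraction per chromosome must be in (0, 1]")
  }
  TRUE
})

#' TrueRT: latent replication-timing landscape
#'
#' Per-grid-cell replication time in `[0, 1]`, 1 = earliest-replicating.
#' @slot rt list of numeric vectors (one per chromosome, one per grid cell)
#' @slot grid grid step in bp
#' @slot domainScale characteristic domain width in bp
#' @export
setClass("TrueRT",
  representation(rt = "list", grid = "numeric", domainScale = "numeric"))

setValidity("TrueRT", function(object) {
  for (r in object@rt)
    if (any(r < 0 | r > 1)) return("rt values outside [0, 1]")
  TRUE
})

#' SyntheticTruth: full ground truth of one simulated condition
#'
#' @slot genome [SyntheticGenome-class]
#' @slot rt [TrueRT-class]
#' @slot urRegions `GRanges` of underreplicated regions with a per-region
#'   copy-retention score `u` in `(0, 1]`
#' @slot phRegions `GRanges` of pericentric-heterochromatin blocks (score `u`)
#' @slot sFraction fraction of cells in S phase, in `(0, 1)`
#' @slot ploidy nominal ploidy of the tissue (informational; depth is
#'   normalized, so only relative copy matters)
#' @slot meanDepth expected reads per full window
#' @slot gcBias `c(amplitude, peak)` of the multiplicative GC bias
#' @export
setClass("SyntheticTruth",
  representation(genome = "SyntheticGenome", rt = "TrueRT",
                 urRegions = "GRanges", phRegions = "GRanges",
                 sFraction = "numeric", ploidy = "integer",
                 meanDepth = "numeric", gcBias = "numeric", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  if (object@sFraction <= 0 || object@sFraction >= 1)
    return("sFraction must be in (0, 1)")
  if (object@meanDepth <= 0) return("meanDepth must be positive")
  both <- suppressWarnings(c(granges(object@urRegions),
                             granges(object@phRegions)))
  if (length(both) > 1L) {
    hits <- findOverlaps(both, drop.self = TRUE)
    if (length(hits)) return("ur and PH regions must be disjoint, non-overlapping")
  }
  u <- c(object@urRegions$u, object@phRegions$u)
  if (any(u <= 0 | u > 1)) return("copy retention u must be in (0, 1]")
  TRUE
})

#' VariantTable: windowed ANOVA comparison of rawRT between two groups
#'
#' @slot table data.frame with one row per tested 50-kb window: coordinates,
#'   group means, F statistic, p, Bonferroni-adjusted p, significance flag
#' @slot regions `GRanges` of merged variant regions (adjacent significant
#'   windows, genomic span strictly greater than `min_region`)
#' @slot params the parameters of the call
#' @export
setClass("VariantTable",
  representation(table = "data.frame", regions = "GRanges", params = "list"))

setValidity("VariantTable", function(object) {
  need <- c("chrom", "start", "end", "F", "p", "p_adj", "significant")
  if (!all(need %in% colnames(object@table)))
    return(paste("table missing columns:",
                 paste(setdiff(need, colnames(object@table)), collapse = ", ")))
  TRUE
})
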