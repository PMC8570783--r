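## Euchromatic underreplicated (eUR) region discovery, region-set merging
## and the arm/eUR/PH window labeling on which the dual normalization rests.

#' Call euchromatic underreplicated regions from copy-number depth
#'
#' Segments each chromosome's (mean-normalized) copy-number values and takes
#' segments at least `sdThreshold` SDs below the series mean
#' ([lowSegments()]). Low intervals are chained: a chain breaks only where
#' `maxGap` or more consecutive windows sit above the cutoff (gap counted in
#' windows of the grid, i.e. units of 1 kb alignable content). Chains whose
#' genomic span reaches `minLen` bp are emitted as eUR regions.
#'
#' @param track a [DepthTrack-class] at stage `raw` or `gc_corrected`
#'   (pre-normalization copy number)
#' @param r2 segmentation noise variance on the mean-1 copy scale
#'   (default 0.04)
#' @param sdThreshold low-segment threshold in series SDs (default 1)
#' @param minLen minimum genomic span in bp (default 50 kb)
#' @param maxGap gap tolerance in bp of window content: a run of
#'   `maxGap / 1000` or more consecutive above-cutoff windows breaks a chain
#'   (default 10 kb, i.e. 10 windows)
#' @param minSeg minimum non-missing windows per segment
#' @return `GRanges` of eUR regions (label `eUR`, score = mean relative copy)
#' @export
callEUR <- function(track, r2 = 0.04, sdThreshold = 1, minLen = 50e3,
                    maxGap = 10e3, minSeg = 5L) {
  if (!trackStage(track) %in% c("raw", "gc_corrected"))
    stop("callEUR expects a raw or gc_corrected (pre-normalization) track")
  grid <- windowGrid(track)
  v <- trackValues(track)
  v <- v / mean(v, na.rm = TRUE)          # relative copy, mean 1
  gapWin <- max(1L, round(maxGap / 1000))
  chr <- as.character(seqnames(grid))
  out <- GRanges()
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    vv <- v[idx]
    if (sum(!is.na(vv)) < 2L * minSeg) next
    sm <- segmentSeries(vv, r2 = r2, minSeg = minSeg)
    low <- lowSegments(sm, sdThreshold = sdThreshold)
    if (!length(low)) next
    ## chain low intervals: merge across above-cutoff gaps of < gapWin windows
    chained <- reduce(low, min.gapwidth = gapWin)
    gs <- start(grid)[idx[start(chained)]]
    ge <- end(grid)[idx[end(chained)]]
    keep <- (ge - gs + 1) >= minLen
    if (!any(keep)) next
    sc <- vapply(which(keep), function(k)
      mean(vv[start(chained)[k]:end(chained)[k]], na.rm = TRUE), numeric(1))
    reg <- GRanges(ch, IRanges(start = gs[keep], end = ge[keep]),
                   label = "eUR", score = sc)
    out <- suppressWarnings(c(out, reg))
  }
  sort(out)
}

#' Merge two region sets
#'
#' Union of the intervals of `a` and `b`, merging any pair separated by at
#' most `gap` bp (bedtools `merge -d` semantics; `gap = 0` merges book-ended
#' intervals). Labels of merged intervals are the comma-joined unique labels
#' of their members (provenance).
#'
#' @param a,b `GRanges` (with optional `label` column); `b` may be `NULL`
#' @param gap maximum separation in bp still merged (default 0)
#' @return merged, sorted `GRanges` with a `label` column
#' @export
mergeRegions <- function(a, b = NULL, gap = 0) {
  lab <- function(g) if (!is.null(g$label)) as.character(g$label)
                     else rep(NA_character_, length(g))
  if (!is.null(b) && length(a) && length(b)) {
    shared <- intersect(unique(as.character(seqnames(a))),
                        unique(as.character(seqnames(b))))
    if (!length(shared))
      stop("chromosome-name mismatch between region sets: ",
           paste(unique(as.character(seqnames(a))), collapse = ","), " vs ",
           paste(unique(as.character(seqnames(b))), collapse = ","))
  }
  labs <- c(lab(a), if (is.null(b)) NULL else lab(b))
  all <- suppressWarnings(c(granges(a),
                            if (is.null(b)) GRanges() else granges(b)))
  if (!length(all)) return(GRanges())
  merged <- reduce(sort(all), min.gapwidth = gap + 1)
  hits <- findOverlaps(all, merged)
  ml <- vapply(seq_along(merged), function(i) {
    l <- unique(labs[queryHits(hits)[subjectHits(hits) == i]])
    l <- l[!is.na(l)]
    if (!length(l)) NA_character_ else paste(sort(l), collapse = ",")
  }, character(1))
  merged$label <- ml
  merged
}

#' Label windows as arm, eUR or PH
#'
#' A window is labeled `eUR` or `PH` if at least `minFraction` of its
#' genomic span overlaps that region set; `PH` wins ties with `eUR`; all
#' other windows are `arm`. The 50% rule mirrors the overlap-fraction
#' convention used for all interval assignment in the pipeline.
#'
#' @param grid a [WindowGrid-class]
#' @param eur,ph `GRanges` region sets (either may be empty)
#' @param minFraction overlap fraction of the window span (default 0.5)
#' @return factor of per-window labels (`arm`, `eUR`, `PH`)
#' @export
labelWindows <- function(grid, eur = GRanges(), ph = GRanges(),
                         minFraction = 0.5) {
  frac <- function(regions) {
    f <- numeric(length(grid))
    if (!length(regions)) return(f)
    red <- reduce(granges(regions))
    hits <- findOverlaps(grid, red)
    if (length(hits)) {
      ov <- width(pintersect(grid[queryHits(hits)], red[subjectHits(hits)]))
      agg <- tapply(ov, queryHits(hits), sum)
      f[as.integer(names(agg))] <- as.numeric(agg) / width(grid)[as.integer(names(agg))]
    }
    f
  }
  fPH <- frac(ph)
  fEUR <- frac(eur)
  lab <- rep("arm", length(grid))
  lab[fEUR >= minFraction] <- "eUR"
  lab[fPH >= minFraction] <- "PH"   # PH assigned last: wins ties
  asRegionLabel(lab, length(grid))
}
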