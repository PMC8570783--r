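## Generics and accessor/show methods for the package classes.

#' @export
setGeneric("windowGrid", function(x) standardGeneric("windowGrid"))
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @export
setGeneric("trackValues<-", function(x, value) standardGeneric("trackValues<-"))
#' @export
setGeneric("trackLabels", function(x) standardGeneric("trackLabels"))
#' @export
setGeneric("trackLabels<-", function(x, value) standardGeneric("trackLabels<-"))
#' @export
setGeneric("trackStage", function(x) standardGeneric("trackStage"))
#' @export
setGeneric("breakpoints", function(x) standardGeneric("breakpoints"))
#' @export
setGeneric("segmentMeans", function(x) standardGeneric("segmentMeans"))
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))
#' @export
setGeneric("rawRT", function(x) standardGeneric("rawRT"))
#' @export
setGeneric("smoothedRT", function(x) standardGeneric("smoothedRT"))
#' @export
setGeneric("quartiles", function(x) standardGeneric("quartiles"))
#' @export
setGeneric("quartileCutoffs", function(x) standardGeneric("quartileCutoffs"))
#' @export
setGeneric("urRegions", function(x) standardGeneric("urRegions"))
#' @export
setGeneric("phRegions", function(x) standardGeneric("phRegions"))
#' @export
setGeneric("trueRT", function(x) standardGeneric("trueRT"))
#' @export
setGeneric("variantRegions", function(x) standardGeneric("variantRegions"))
#' @export
setGeneric("variantStats", function(x) standardGeneric("variantStats"))

## ---- DepthTrack ------------------------------------------------------------

#' @describeIn DepthTrack-class the underlying [WindowGrid-class]
#' @param x a `DepthTrack`
#' @export
setMethod("windowGrid", "DepthTrack", function(x) x@grid)

#' @describeIn DepthTrack-class per-window values (`NA` = missing)
#' @export
setMethod("trackValues", "DepthTrack", function(x) x@values)

#' @describeIn DepthTrack-class replace values (length-preserving)
#' @param value replacement
#' @export
setMethod("trackValues<-", "DepthTrack", function(x, value) {
  x@values <- value
  validObject(x)
  x
})

#' @describeIn DepthTrack-class per-window region label
#' @export
setMethod("trackLabels", "DepthTrack", function(x) x@label)

#' @describeIn DepthTrack-class replace labels
#' @export
setMethod("trackLabels<-", "DepthTrack", function(x, value) {
  x@label <- asRegionLabel(value, length(x@grid))
  validObject(x)
  x
})

#' @describeIn DepthTrack-class processing stage tag
#' @export
setMethod("trackStage", "DepthTrack", function(x) x@stage)

#' @describeIn DepthTrack-class number of windows
#' @export
setMethod("length", "DepthTrack", function(x) length(x@grid))

setMethod("show", "DepthTrack", function(object) {
  v <- object@values
  cat(sprintf("DepthTrack [%s]: %d windows on %d chromosome(s); %d missing\n",
              object@stage, length(v),
              length(unique(as.character(seqnames(object@grid)))),
              sum(is.na(v))))
  cat("  labels:", paste(sprintf("%s=%d", levels(object@label),
                                 tabulate(object@label, nbins = nlevels(object@label))),
                         collapse = ", "), "\n")
})

## constructor used throughout the package
asRegionLabel <- function(label, n) {
  if (is.null(label)) label <- rep("arm", n)
  factor(as.character(label), levels = c("arm", "eUR", "PH"))
}

#' Create a DepthTrack
#'
#' @param grid a [WindowGrid-class]
#' @param values numeric, one per window (`NA` = missing)
#' @param label per-window region label (`arm`, `eUR`, `PH`); default all `arm`
#' @param stage stage tag (`raw`, `gc_corrected`, `rawRT`, `smoothedRT`)
#' @return a [DepthTrack-class]
#' @export
DepthTrack <- function(grid, values, label = NULL, stage = "raw") {
  new("DepthTrack", grid = grid, values = as.numeric(values),
      label = asRegionLabel(label, length(grid)), stage = stage)
}

## ---- SegmentModel ----------------------------------------------------------

#' @describeIn SegmentModel-class breakpoint indices (end of each segment but
#'   the last)
#' @param x a `SegmentModel`
#' @export
setMethod("breakpoints", "SegmentModel", function(x) x@breakpoints)

#' @describeIn SegmentModel-class per-segment means
#' @export
setMethod("segmentMeans", "SegmentModel", function(x) x@means)

#' @describeIn SegmentModel-class segments as an `IRanges` of window indices
#' @export
setMethod("segmentRanges", "SegmentModel", function(x) {
  s <- c(1L, x@breakpoints + 1L)
  e <- c(x@breakpoints, x@n)
  IRanges(start = s, end = e)
})

setMethod("show", "SegmentModel", function(object) {
  cat(sprintf("SegmentModel: %d segment(s) over %d windows (r2=%g, penalty=%.3g)\n",
              length(object@means), object@n, object@r2, object@penalty))
})

## ---- RTProfile -------------------------------------------------------------

#' @describeIn RTProfile-class the unsmoothed, arm-anchored rawRT track
#' @param x an `RTProfile`
#' @export
setMethod("rawRT", "RTProfile", function(x) x@rawRT)

#' @describeIn RTProfile-class the smoothed, per-chromosome standardized track
#' @export
setMethod("smoothedRT", "RTProfile", function(x) x@smoothed)

#' @describeIn RTProfile-class per-window quartile (`Q1` earliest .. `Q4` latest)
#' @export
setMethod("quartiles", "RTProfile", function(x) x@quartile)

#' @describeIn RTProfile-class genome-wide quartile cutoffs (75/50/25th
#'   percentiles)
#' @export
setMethod("quartileCutoffs", "RTProfile", function(x) x@cutoffs)

#' @describeIn RTProfile-class the shared window grid
#' @export
setMethod("windowGrid", "RTProfile", function(x) x@rawRT@grid)

setMethod("show", "RTProfile", function(object) {
  cat(sprintf("RTProfile: %d windows; %d with smoothed RT\n",
              length(object@rawRT), sum(!is.na(object@smoothed@values))))
  occ <- table(object@quartile)
  cat("  quartiles:", paste(sprintf("%s=%d", names(occ), occ), collapse = ", "), "\n")
  cat(sprintf("  cutoffs (75/50/25): %.3f / %.3f / %.3f\n",
              object@cutoffs[1], object@cutoffs[2], object@cutoffs[3]))
})

## ---- SyntheticTruth --------------------------------------------------------

#' @describeIn SyntheticTruth-class underreplicated regions with retention `u`
#' @param x a `SyntheticTruth`
#' @export
setMethod("urRegions", "SyntheticTruth", function(x) x@urRegions)

#' @describeIn SyntheticTruth-class pericentric-heterochromatin blocks
#' @export
setMethod("phRegions", "SyntheticTruth", function(x) x@phRegions)

#' @describeIn SyntheticTruth-class the latent RT landscape
#' @export
setMethod("trueRT", "SyntheticTruth", function(x) x@rt)

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d chromosome(s), s=%.2f, depth=%g, ",
                     "%d UR region(s), %d PH block(s), seed=%d\n"),
              length(object@genome@chromNames), object@sFraction,
              object@meanDepth, length(object@urRegions),
              length(object@phRegions), object@seed))
})

setMethod("show", "SyntheticGenome", function(object) {
  cat(sprintf("SyntheticGenome: %d chromosome(s), %.1f Mb total, grid %d bp\n",
              length(object@chromNames), sum(object@chromLengths) / 1e6,
              as.integer(object@grid)))
})

## ---- VariantTable ----------------------------------------------------------

#' @describeIn VariantTable-class merged variant regions as `GRanges`
#' @param x a `VariantTable`
#' @export
setMethod("variantRegions", "VariantTable", function(x) x@regions)

#' @describeIn VariantTable-class the per-window test table
#' @export
setMethod("variantStats", "VariantTable", function(x) x@table)

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d tested windows, %d significant, %d variant region(s)\n",
              nrow(object@table), sum(object@table$significant, na.rm = TRUE),
              length(object@regions)))
})
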