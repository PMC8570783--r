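## Plain-text interchange: the window count-table dialect, BED and bedGraph.
## All on-disk intervals are 0-based half-open (BED convention); in-memory
## GRanges are 1-based closed (IRanges convention).

#' Write a window count table
#'
#' TSV with columns `chrom`, `start` (0-based), `end` (half-open),
#' `alignable_bp`, `gc`, `count`.
#'
#' @param track a raw [DepthTrack-class]
#' @param path output file
#' @export
writeCountTable <- function(track, path) {
  grid <- windowGrid(track)
  df <- data.frame(chrom = as.character(seqnames(grid)),
                   start = start(grid) - 1L, end = end(grid),
                   alignable_bp = mcols(grid)$alignable_bp,
                   gc = mcols(grid)$gc,
                   count = trackValues(track))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a window count table
#'
#' @param path file written by [writeCountTable()] (or any TSV with the same
#'   columns)
#' @return a raw [DepthTrack-class]
#' @export
readCountTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "alignable_bp", "gc", "count")
  if (!all(need %in% colnames(df)))
    stop("count table missing columns: ",
         paste(setdiff(need, colnames(df)), collapse = ", "))
  target <- max(df$alignable_bp)
  byChr <- split(seq_len(nrow(df)), df$chrom)
  short <- rep(FALSE, nrow(df))
  for (idx in byChr)
    short[idx] <- df$alignable_bp[idx] < target &
      seq_along(idx) == length(idx)
  gr <- GRanges(df$chrom, IRanges(start = df$start + 1L, end = df$end),
                alignable_bp = df$alignable_bp, gc = df$gc,
                is_short = short)
  DepthTrack(new("WindowGrid", gr), df$count, stage = "raw")
}

#' Write a track as bedGraph
#'
#' Missing-value windows are omitted from the file (never zero-filled).
#' @param track a [DepthTrack-class], or a numeric vector with `grid`
#' @param path output file
#' @param grid required when `track` is a plain vector
#' @export
writeBedGraph <- function(track, path, grid = NULL) {
  if (is(track, "DepthTrack")) {
    v <- trackValues(track); grid <- windowGrid(track)
  } else v <- as.numeric(track)
  ok <- !is.na(v)
  gr <- granges(grid)[ok]
  gr$score <- v[ok]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a region set as BED
#'
#' @param regions `GRanges`; a `label` or `name` column becomes the BED name
#' @param path output file
#' @export
writeRegionsBed <- function(regions, path) {
  gr <- granges(regions)
  nm <- regions$name %||% regions$label
  if (!is.null(nm)) gr$name <- as.character(nm)
  if (!is.null(regions$score)) gr$score <- regions$score
  rtracklayer::export(sort(gr), path, format = "BED")
  invisible(path)
}

#' Read a BED file as a region set
#'
#' @param path BED file
#' @param label label assigned when the file has no name column
#' @return sorted `GRanges` with a `label` column
#' @export
readRegionsBed <- function(path, label = NA_character_) {
  gr <- rtracklayer::import(path, format = "BED")
  gr$label <- if (!is.null(gr$name)) as.character(gr$name) else label
  sort(gr)
}
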