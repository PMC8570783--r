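## Windowing: alignability mask, fixed-alignable-bp windows, read counting
## and per-window GC.

#' Build a per-position uniquely-alignable mask
#'
#' Position `p` of a chromosome is alignable iff the `readLength`-mer
#' starting at `p` occurs exactly once in the genome counting both strands:
#' the number of start locations (either strand) whose read sequence equals
#' that k-mer is one. A reverse-complement-palindromic k-mer therefore can
#' never be alignable (its own position matches on both strands). Positions
#' within `readLength - 1` of the chromosome end are not alignable.
#'
#' Intended for small test genomes (exhaustive k-mer census); synthetic
#' masks (a named list of logical `Rle`, or a [SyntheticGenome-class]) are
#' passed through unchanged.
#'
#' @param x a `DNAStringSet` (named), a [SyntheticGenome-class], or an
#'   already-built mask (named list of logical `Rle`)
#' @param readLength read length in bp (default 100)
#' @return named list of logical `Rle`, one element per base pair
#' @export
buildAlignabilityMask <- function(x, readLength = 100L) {
  if (is(x, "SyntheticGenome")) return(x@alignability)
  if (is.list(x) && all(vapply(x, is, logical(1), "Rle")))
    return(checkMask(x))
  if (!is(x, "DNAStringSet"))
    x <- DNAStringSet(x)
  if (is.null(names(x))) names(x) <- paste0("chr", seq_along(x))
  k <- as.integer(readLength)
  if (any(Biostrings::width(x) < k))
    stop("readLength longer than the shortest chromosome")
  seqs <- as.character(x)
  fwd <- lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  })
  allF <- unlist(fwd, use.names = FALSE)
  cnt <- table(allF)
  rcOf <- function(km) as.character(reverseComplement(DNAStringSet(km)))
  mask <- vector("list", length(x))
  names(mask) <- names(x)
  for (i in seq_along(x)) {
    km <- fwd[[i]]
    rc <- rcOf(km)
    tot <- as.integer(cnt[km]) +
      ifelse(is.na(cnt[rc]), 0L, as.integer(cnt[rc]))
    ok <- c(tot == 1L, rep(FALSE, k - 1L))
    mask[[i]] <- Rle(ok)
  }
  mask
}

#' Partition a genome into windows of fixed alignable content
#'
#' Greedy left-to-right packing: a window closes at the base pair where its
#' cumulative count of alignable positions reaches `targetAlignable`, so the
#' genomic span of a window varies inversely with local alignability. The
#' last window of each chromosome may hold fewer alignable positions; it is
#' kept, flagged `is_short`, and excluded from normalization statistics
#' downstream.
#'
#' @param mask a named list of logical `Rle` (or a [SyntheticGenome-class])
#' @param targetAlignable alignable base pairs per window (default 1000)
#' @return a [WindowGrid-class] (GC column `NA`; see [computeGC()])
#' @export
makeWindows <- function(mask, targetAlignable = 1000L) {
  if (is(mask, "SyntheticGenome")) mask <- mask@alignability
  checkMask(mask)
  target <- as.integer(targetAlignable)
  if (target < 1L) stop("targetAlignable must be positive")
  chroms <- names(mask)
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    rt <- maskRunTable(mask[[i]])
    total <- rt$cumAlign[length(rt$cumAlign)]
    if (total == 0)
      stop("chromosome '", chroms[i], "' has no alignable positions")
    nFull <- floor(total / target)
    cuts <- if (nFull > 0) maskNthAlignable(rt, seq_len(nFull) * target)
            else integer(0)
    starts <- c(1, head(cuts, -1) + 1)
    ends <- cuts
    ab <- rep(target, nFull)
    short <- rep(FALSE, nFull)
    rem <- total - nFull * target
    if (rem > 0) {
      starts <- c(starts, if (nFull > 0) cuts[nFull] + 1 else 1)
      ends <- c(ends, rt$ends[length(rt$ends)])  # to chromosome end
      ab <- c(ab, rem)
      short <- c(short, TRUE)
    }
    out[[i]] <- GRanges(chroms[i], IRanges(start = starts, end = ends),
                        alignable_bp = ab, gc = NA_real_, is_short = short)
  }
  gr <- suppressWarnings(do.call(c, out))   # per-chromosome seqlevels merge
  new("WindowGrid", gr)
}

#' Per-window GC fraction
#'
#' GC fraction over each window's alignable positions. For a
#' [SyntheticGenome-class] this is the alignable-bp-weighted mean of the
#' generator's per-grid-cell GC field (alignability is uniform within the
#' sub-cell overlap, so the weighting is exact). For sequences, the G+C
#' fraction of the window span is used (with the alignability mask, only
#' alignable positions are counted).
#'
#' @param x a [SyntheticGenome-class] or a `DNAStringSet`
#' @param grid a [WindowGrid-class]
#' @param mask optional mask (for sequence input) restricting the GC count
#'   to alignable positions
#' @return the grid with its `gc` metadata column filled
#' @export
computeGC <- function(x, grid, mask = NULL) {
  chr <- as.character(seqnames(grid))
  gc <- rep(NA_real_, length(grid))
  if (is(x, "SyntheticGenome")) {
    for (i in seq_along(x@chromNames)) {
      ch <- x@chromNames[i]
      idx <- which(chr == ch)
      if (!length(idx)) next
      rt <- maskRunTable(x@alignability[[ch]])
      step <- x@grid
      cellGC <- x@gc[[i]]
      ws <- start(grid)[idx] - 1; we <- end(grid)[idx]
      c1 <- floor(ws / step) + 1L
      c2 <- pmin(ceiling(we / step), length(cellGC))
      nc <- c2 - c1 + 1L
      win <- rep(seq_along(idx), nc)            # (window, cell) pairs
      cell <- unlist(lapply(seq_along(idx), function(j) c1[j]:c2[j]))
      a <- pmax(ws[win], (cell - 1) * step)
      b <- pmin(we[win], cell * step)
      w <- maskCountRange(rt, a, b)
      num <- rowsum(w * cellGC[cell], win)
      den <- rowsum(w, win)
      gc[idx] <- ifelse(den[, 1] > 0, num[, 1] / den[, 1], NA_real_)
    }
  } else {
    if (!is(x, "DNAStringSet")) x <- DNAStringSet(x)
    if (is.null(names(x))) names(x) <- paste0("chr", seq_along(x))
    for (ch in unique(chr)) {
      if (!ch %in% names(x))
        stop("no sequence for chromosome '", ch, "'")
      idx <- which(chr == ch)
      s <- x[[ch]]
      gc[idx] <- vapply(idx, function(j) {
        pos <- start(grid)[j]:end(grid)[j]
        if (!is.null(mask)) pos <- pos[as.logical(mask[[ch]][pos])]
        if (!length(pos)) return(NA_real_)
        sub <- s[pos]
        as.numeric(letterFrequency(sub, "GC") / length(pos))
      }, numeric(1))
    }
  }
  mcols(grid)$gc <- gc
  grid
}

#' Count reads into windows
#'
#' Tallies alignments into the window containing their leftmost aligned
#' reference coordinate (the 5'-most mapped position in reference
#' orientation). Duplicates, secondary alignments and second-in-pair mates
#' are excluded, as are reads below the MAPQ threshold (the standard flag
#' filter `-F 1024 -F 256 -F 128 -q 10`). If an alignability mask is given,
#' reads starting at non-alignable positions are discarded.
#'
#' @param x path to an indexed BAM file, or a data.frame of read positions
#'   with columns `chrom` and `pos` (1-based leftmost coordinate) for
#'   pre-filtered input
#' @param grid a [WindowGrid-class]
#' @param mapqMin minimum MAPQ kept (reads with MAPQ < `mapqMin` dropped)
#' @param mask optional alignability mask (named list of logical `Rle`)
#' @return a raw-stage [DepthTrack-class]
#' @export
countReads <- function(x, grid, mapqMin = 10L, mask = NULL) {
  if (is.character(x)) {
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isDuplicate = FALSE,
                                   isSecondMateRead = FALSE)
    p <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos"),
                                 mapqFilter = mapqMin)
    res <- Rsamtools::scanBam(x, param = p)[[1L]]
    reads <- data.frame(chrom = as.character(res$rname), pos = res$pos)
  } else {
    reads <- as.data.frame(x)
    if (!all(c("chrom", "pos") %in% colnames(reads)))
      stop("read table needs columns 'chrom' and 'pos'")
  }
  counts <- integer(length(grid))
  if (nrow(reads) == 0L) {
    warning("no reads pass the filters; returning an empty track")
    return(DepthTrack(grid, counts, stage = "raw"))
  }
  bad <- setdiff(unique(reads$chrom), seqlevels(grid))
  if (length(bad))
    stop("unknown reference name(s): ", paste(bad, collapse = ", "))
  if (!is.null(mask)) {
    checkMask(mask)
    ok <- vapply(seq_len(nrow(reads)), function(i)
      as.logical(mask[[reads$chrom[i]]][reads$pos[i]]), logical(1))
    reads <- reads[ok, , drop = FALSE]
  }
  if (nrow(reads)) {
    rg <- GRanges(reads$chrom, IRanges(start = reads$pos, width = 1L))
    hits <- findOverlaps(rg, grid)
    tab <- tabulate(subjectHits(hits), nbins = length(grid))
    counts <- tab
  }
  DepthTrack(grid, counts, stage = "raw")
}
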