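## Shared small fixtures, built once per test run and cached.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

## 1 chromosome x 4 Mb truth: fast enough for per-module tests
smallTruth <- function() fixture("smallTruth", function()
  simulateTruth(nChrom = 1L, chromLength = 4e6, seed = 7))

smallSim <- function() fixture("smallSim", function()
  simulateDepth(smallTruth(), seed = 17))

smallProfile <- function() fixture("smallProfile", function()
  buildRTProfile(smallSim()$track, ph = phRegions(smallTruth())))

## fully alignable mask of given length
fullMask <- function(len, chrom = "chr1") {
  m <- list(Rle(TRUE, len))
  names(m) <- chrom
  m
}

## uniform fully-alignable WindowGrid: n windows of `width` bp
uniformGrid <- function(n, width = 1000, chrom = "chr1") {
  gr <- GRanges(chrom,
                IRanges(start = (seq_len(n) - 1) * width + 1,
                        width = width),
                alignable_bp = width, gc = 0.4,
                is_short = FALSE)
  new("WindowGrid", gr)
}

## map per-window true RT onto a grid from a truth object
truthRTOnGrid <- function(truth, grid) {
  chr <- as.character(seqnames(grid))
  mid <- (start(grid) + end(grid)) / 2
  out <- numeric(length(grid))
  for (i in seq_along(truth@genome@chromNames)) {
    ch <- truth@genome@chromNames[i]
    idx <- chr == ch
    r <- trueRT(truth)@rt[[i]]
    out[idx] <- r[pmin(ceiling(mid[idx] / truth@genome@grid), length(r))]
  }
  out
}

## region-level match: Jaccard of two intervals on the same chromosome
regionJaccard <- function(a, b) {
  inter <- sum(width(GenomicRanges::pintersect(
    findOverlapPairs(a, b))))
  uni <- sum(width(reduce(suppressWarnings(c(granges(a), granges(b))))))
  if (uni == 0) return(0)
  inter / uni
}
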