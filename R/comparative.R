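## Between-sample statistics: replicate correlation, autocorrelation QC,
## 50-kb windowed ANOVA variant calling with Bonferroni control, and
## quartile-feature association.

trackFrom <- function(x, on = "rawRT") {
  if (is(x, "RTProfile")) {
    if (on == "rawRT") rawRT(x) else smoothedRT(x)
  } else if (is(x, "DepthTrack")) x
  else stop("expected an RTProfile or DepthTrack")
}

#' Pearson correlation of two RT profiles
#'
#' @param a,b [RTProfile-class] or [DepthTrack-class] objects on the same
#'   window grid
#' @param on which track of an `RTProfile` to use (`smoothed` or `rawRT`)
#' @return list with `r` (Pearson correlation over shared non-missing
#'   windows) and `n` (number of shared windows)
#' @export
rtCorrelation <- function(a, b, on = c("smoothed", "rawRT")) {
  on <- match.arg(on)
  ta <- trackFrom(a, on); tb <- trackFrom(b, on)
  if (length(ta) != length(tb))
    stop("profiles are not on the same grid")
  va <- trackValues(ta); vb <- trackValues(tb)
  ok <- !is.na(va) & !is.na(vb)
  if (sum(ok) < 10L) stop("fewer than 10 shared non-missing windows")
  list(r = cor(va[ok], vb[ok]), n = sum(ok))
}

#' Autocorrelation of a rawRT track
#'
#' Sample autocorrelation per chromosome, missing values handled by
#' pairwise-complete products, averaged across chromosomes weighted by
#' window count. High, slowly decaying autocorrelation is the signature of
#' a domain-structured RT landscape; a permuted track gives values inside
#' the white-noise band.
#'
#' @param track a [DepthTrack-class] (conventionally rawRT: smoothing would
#'   trivially inflate the autocorrelation)
#' @param nLags number of lags (default 1000; shortened with a warning when
#'   a chromosome has fewer windows)
#' @return numeric vector `acf[1..nLags]` (lag 0 omitted)
#' @export
rtAutocorrelation <- function(track, nLags = 1000L) {
  grid <- windowGrid(track)
  v <- trackValues(track)
  chr <- as.character(seqnames(grid))
  chroms <- unique(chr)
  maxFeasible <- max(vapply(chroms, function(ch) sum(chr == ch), 0L)) - 1L
  if (maxFeasible < nLags) {
    warning("series shorter than nLags; computing to lag ", maxFeasible)
    nLags <- maxFeasible
  }
  acc <- matrix(0, nrow = nLags, ncol = length(chroms))
  wts <- numeric(length(chroms))
  for (i in seq_along(chroms)) {
    idx <- which(chr == chroms[i])
    z <- v[idx] - mean(v[idx], na.rm = TRUE)
    n <- length(z)
    denom <- mean(z^2, na.rm = TRUE)
    wts[i] <- n
    for (k in seq_len(min(nLags, n - 1L))) {
      p <- z[1:(n - k)] * z[(k + 1):n]
      acc[k, i] <- mean(p, na.rm = TRUE) / denom
    }
  }
  as.numeric(acc %*% wts / sum(wts))
}

#' Call RT-variant regions between two groups of rawRT tracks
#'
#' Tiles the genome in fixed `window`-bp bins, pools each replicate's 1-kb
#' rawRT values inside a bin (or uses replicate means), tests each bin by
#' one-way ANOVA between groups, applies Bonferroni control over all tested
#' bins, merges strictly adjacent significant bins, and calls merged runs
#' whose genomic span strictly exceeds `minRegion` bp as variant.
#'
#' @param groupA,groupB lists of rawRT [DepthTrack-class] objects (or
#'   [RTProfile-class]s) on one shared grid; a single track per group is
#'   allowed with a warning
#' @param window bin size in bp (default 50 kb)
#' @param alpha significance level on the Bonferroni-adjusted p (strict `<`)
#' @param minRegion minimum genomic span of a variant region, strict `>`
#' @param observations `"windows"` (default: pooled 1-kb values) or
#'   `"replicate_means"`
#' @param minObs minimum observations per group per bin (default 3; bins
#'   below it are skipped and recorded)
#' @return a [VariantTable-class]
#' @export
callVariants <- function(groupA, groupB, window = 50e3, alpha = 0.01,
                         minRegion = 200e3,
                         observations = c("windows", "replicate_means"),
                         minObs = 3L) {
  observations <- match.arg(observations)
  if (!is.list(groupA)) groupA <- list(groupA)
  if (!is.list(groupB)) groupB <- list(groupB)
  groupA <- lapply(groupA, trackFrom, on = "rawRT")
  groupB <- lapply(groupB, trackFrom, on = "rawRT")
  if (length(groupA) < 2L || length(groupB) < 2L)
    warning("fewer than 2 replicates in a group; the ANOVA has no ",
            "between-replicate error term")
  grid <- windowGrid(groupA[[1L]])
  for (t in c(groupA, groupB)) {
    g2 <- windowGrid(t)
    if (length(g2) != length(grid) ||
        !identical(as.character(seqnames(g2)), as.character(seqnames(grid))) ||
        !identical(start(g2), start(grid)))
      stop("tracks are not on the same grid; offending chromosomes: ",
           paste(union(setdiff(seqlevelsInUse(g2), seqlevelsInUse(grid)),
                       setdiff(seqlevelsInUse(grid), seqlevelsInUse(g2))),
                 collapse = ", "))
  }
  chr <- as.character(seqnames(grid))
  mid <- (start(grid) + end(grid)) / 2
  rows <- list(); skipped <- 0L
  for (ch in unique(chr)) {
    idx <- which(chr == ch)
    lim <- max(end(grid)[idx])
    binStart <- seq(0, lim - 1, by = window)
    bin <- findInterval(mid[idx], binStart)
    for (b in unique(bin)) {
      wIdx <- idx[bin == b]
      ya <- lapply(groupA, function(t) trackValues(t)[wIdx])
      yb <- lapply(groupB, function(t) trackValues(t)[wIdx])
      if (observations == "replicate_means") {
        ya <- lapply(ya, function(v) mean(v, na.rm = TRUE))
        yb <- lapply(yb, function(v) mean(v, na.rm = TRUE))
      }
      ya <- unlist(ya); yb <- unlist(yb)
      ya <- ya[!is.na(ya)]; yb <- yb[!is.na(yb)]
      if (length(ya) < minObs || length(yb) < minObs) {
        skipped <- skipped + 1L
        next
      }
      y <- c(ya, yb)
      g <- factor(rep(c("A", "B"), c(length(ya), length(yb))))
      Fv <- NA_real_; pv <- NA_real_
      if (sd(y) > 0) {
        tst <- tryCatch(oneway.test(y ~ g, var.equal = TRUE),
                        error = function(e) NULL)
        if (!is.null(tst)) { Fv <- unname(tst$statistic); pv <- tst$p.value }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = binStart[b], end = min(binStart[b] + window, lim),
        meanA = mean(ya), meanB = mean(yb), nA = length(ya), nB = length(yb),
        F = Fv, p = pv, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      meanA = numeric(), meanB = numeric(), nA = integer(),
                      nB = integer(), F = numeric(), p = numeric())
  p <- tab$p
  p[is.na(p)] <- 1                       # zero-variance bins: not significant
  tab$p_adj <- p.adjust(p, method = "bonferroni")
  tab$significant <- tab$p_adj < alpha
  regions <- GRanges()
  if (any(tab$significant)) {
    sig <- tab[tab$significant, , drop = FALSE]
    gr <- GRanges(sig$chrom, IRanges(start = sig$start + 1, end = sig$end))
    merged <- reduce(sort(gr), min.gapwidth = 1)   # strictly adjacent bins
    regions <- merged[width(merged) > minRegion]
    if (length(regions)) regions$label <- "variant"
  }
  new("VariantTable", table = tab, regions = regions,
      params = list(window = window, alpha = alpha, minRegion = minRegion,
                    observations = observations, tested = nrow(tab),
                    skipped = skipped))
}

#' Per-quartile feature percentages
#'
#' Assigns each feature to the quartile of the window that covers at least
#' `minFraction` of the feature's span (bedtools `intersect -f 0.5`
#' semantics; longest overlap breaks ties), and reports the percentage of
#' features per quartile. Features covered by no window at the required
#' fraction stay unassigned, so the percentages may sum to less than 100.
#'
#' @param profile an [RTProfile-class] (or a list with `quartile` and a
#'   [WindowGrid-class] under `grid`)
#' @param features `GRanges` of features
#' @param minFraction required overlap fraction (default 0.5)
#' @param of apply the fraction to the `feature` span (default, matching
#'   bedtools `intersect -f`) or to the `window` span
#' @return named numeric: percentage of features in Q1..Q4 (and `unassigned`)
#' @export
quartileFeatureOverlap <- function(profile, features, minFraction = 0.5,
                                   of = c("feature", "window")) {
  of <- match.arg(of)
  if (!length(features)) stop("empty feature set")
  if (is(profile, "RTProfile")) {
    grid <- windowGrid(profile); q <- quartiles(profile)
  } else { grid <- profile$grid; q <- profile$quartile }
  hits <- findOverlaps(features, grid)
  assigned <- rep(NA_character_, length(features))
  if (length(hits)) {
    ov <- width(pintersect(features[queryHits(hits)], grid[subjectHits(hits)]))
    ref <- if (of == "feature") width(features)[queryHits(hits)]
           else width(grid)[subjectHits(hits)]
    okq <- !is.na(q[subjectHits(hits)])
    keep <- ov / ref >= minFraction & okq
    if (any(keep)) {
      qh <- queryHits(hits)[keep]; sh <- subjectHits(hits)[keep]; ovk <- ov[keep]
      o <- order(qh, -ovk)           # longest overlap first per feature
      first <- !duplicated(qh[o])
      assigned[qh[o][first]] <- as.character(q[sh[o][first]])
    }
  }
  lv <- paste0("Q", 1:4)
  pct <- 100 * tabulate(factor(assigned, levels = lv), nbins = 4L) /
    length(features)
  names(pct) <- lv
  c(pct, unassigned = 100 - sum(pct))
}

#' Per-quartile expression distributions
#'
#' For every window, the mean FPKM of the transcripts overlapping it (a
#' transcript counts when at least `minFraction` of its span lies in the
#' window); per quartile, the distribution of `log2(1 + mean FPKM)` over
#' windows with at least one transcript, summarized by its median.
#'
#' @param profile an [RTProfile-class]
#' @param transcripts `GRanges` with a non-negative `score` column (FPKM)
#' @param minFraction required overlap fraction of the transcript span
#' @return list with `values` (per-quartile numeric vectors of
#'   `log2(1 + mean FPKM)`) and `medians`
#' @export
quartileExpression <- function(profile, transcripts, minFraction = 0.5) {
  grid <- windowGrid(profile)
  q <- quartiles(profile)
  lv <- paste0("Q", 1:4)
  vals <- setNames(vector("list", 4L), lv)
  if (length(transcripts)) {
    if (is.null(transcripts$score) || any(transcripts$score < 0))
      stop("transcripts need a non-negative 'score' (FPKM) column")
    hits <- findOverlaps(transcripts, grid)
    if (length(hits)) {
      ov <- width(pintersect(transcripts[queryHits(hits)],
                             grid[subjectHits(hits)]))
      keep <- ov / width(transcripts)[queryHits(hits)] >= minFraction
      qh <- queryHits(hits)[keep]; sh <- subjectHits(hits)[keep]
      if (length(sh)) {
        mfpkm <- tapply(transcripts$score[qh], sh, mean)
        wIdx <- as.integer(names(mfpkm))
        lg <- log2(1 + as.numeric(mfpkm))
        for (i in seq_len(4L)) {
          inQ <- !is.na(q[wIdx]) & q[wIdx] == lv[i]
          vals[[i]] <- lg[inQ]
        }
      }
    }
  }
  vals[vapply(vals, is.null, logical(1))] <- list(numeric(0))
  list(values = vals,
       medians = vapply(vals, function(v)
         if (length(v)) median(v) else NA_real_, numeric(1)))
}

#' @importFrom stats setNames
NULL
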