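test_that("profile correlation obeys its exact contracts", {
  p <- smallProfile()
  expect_equal(rtCorrelation(p, p)$r, 1, tolerance = 1e-12)
  neg <- smoothedRT(p)
  trackValues(neg) <- -trackValues(neg)
  expect_equal(rtCorrelation(smoothedRT(p), neg)$r, -1, tolerance = 1e-12)
  tiny <- DepthTrack(uniformGrid(20), c(rnorm(5), rep(NA, 15)),
                     stage = "rawRT")
  expect_error(rtCorrelation(tiny, tiny), "fewer than 10")
})

test_that("autocorrelation separates domain structure from noise", {
  set.seed(19)
  n <- 6000
  grid <- uniformGrid(n)
  white <- DepthTrack(grid, rnorm(n), stage = "rawRT")
  ac <- rtAutocorrelation(white, nLags = 300L)
  expect_gte(mean(abs(ac) < 3 / sqrt(n)), 0.95)

  ## pipeline rawRT: strong lag-1, decaying over the first 50 lags
  rw <- rawRT(smallProfile())
  acR <- rtAutocorrelation(rw, nLags = 100L)
  expect_gt(acR[1], 0.5)
  expect_lt(acR[50], acR[1])
  fit <- lm(acR[1:50] ~ seq_len(50))
  expect_lt(coef(fit)[2], 0)       # monotone decay in trend

  ## permutation destroys structure
  perm <- rw
  set.seed(4)
  trackValues(perm) <- sample(trackValues(rw))
  acP <- rtAutocorrelation(perm, nLags = 100L)
  expect_gte(mean(abs(acP) < 3 / sqrt(length(rw))), 0.95)

  expect_warning(rtAutocorrelation(white, nLags = 6001L), "shorter")
})

test_that("variant calling is null-safe, symmetric and oracle-merged", {
  tr <- smallTruth()
  sim <- smallSim()
  p1 <- buildRTProfile(sim$track, ph = phRegions(tr))
  sim2 <- simulateDepth(tr, grid = sim$grid, seed = 18)
  p2 <- buildRTProfile(sim2$track, ph = phRegions(tr))

  ## identical groups: zero significant windows
  vt0 <- suppressWarnings(callVariants(list(p1), list(p1)))
  expect_identical(sum(variantStats(vt0)$significant), 0L)
  expect_identical(length(variantRegions(vt0)), 0L)

  ## Bonferroni arithmetic exact, strict threshold
  vt <- suppressWarnings(callVariants(list(p1), list(p2)))
  tab <- variantStats(vt)
  p <- tab$p; p[is.na(p)] <- 1
  expect_equal(tab$p_adj, pmin(1, p * nrow(tab)), tolerance = 1e-12)
  expect_identical(tab$significant, tab$p_adj < 0.01)

  ## symmetry in group order
  vtBA <- suppressWarnings(callVariants(list(p2), list(p1)))
  expect_identical(granges(variantRegions(vt)), granges(variantRegions(vtBA)))
  expect_equal(variantStats(vtBA)$F, tab$F, tolerance = 1e-12)

  ## merging is a pure function of the significant set: brute-force oracle
  sig <- tab[tab$significant, , drop = FALSE]
  if (nrow(sig)) {
    oracle <- list(); cur <- NULL
    for (i in seq_len(nrow(sig))) {
      if (!is.null(cur) && sig$chrom[i] == cur$chrom &&
          sig$start[i] == cur$end) cur$end <- sig$end[i]
      else { if (!is.null(cur)) oracle <- c(oracle, list(cur))
             cur <- list(chrom = sig$chrom[i], start = sig$start[i],
                         end = sig$end[i]) }
    }
    oracle <- c(oracle, list(cur))
    keep <- Filter(function(r) r$end - r$start > 200e3, oracle)
    expect_identical(length(variantRegions(vt)), length(keep))
  }

  ## mismatched grids error names the offending chromosome
  other <- DepthTrack(uniformGrid(length(p1@rawRT), chrom = "chrZ"),
                      trackValues(rawRT(p1)), stage = "rawRT")
  expect_error(suppressWarnings(callVariants(list(rawRT(p1)), list(other))),
               "chrZ")
})

test_that("an injected rawRT shift is detected and grows with magnitude", {
  tr <- smallTruth()
  sim <- smallSim()
  g <- sim$grid
  lab <- labelWindows(g, urRegions(tr), phRegions(tr))
  mkRaw <- function(seed) {
    s <- simulateDepth(tr, grid = g, seed = seed)
    gcc <- gcCorrect(s$track, exclude = suppressWarnings(
      c(granges(urRegions(tr)), granges(phRegions(tr)))))
    dualNormalize(gcc, labels = lab)
  }
  reps <- lapply(1:8, function(k) mkRaw(200 + k))
  reg <- GRanges("chr1", IRanges(1.5e6 + 1, 1.9e6))
  hit <- overlapsAny(g, reg)
  shiftBy <- function(t, d) { v <- trackValues(t); v[hit] <- v[hit] + d
                              trackValues(t) <- v; t }
  counts <- vapply(c(0, 0.25, 0.5, 1), function(d) {
    shifted <- lapply(reps[5:8], shiftBy, d = d)
    vt <- callVariants(reps[1:4], shifted)
    as.numeric(length(variantRegions(vt)))
  }, numeric(1))
  ## power grows with the shift; a 1-SD shift is found, zero shift is clean
  expect_identical(counts[1], 0)
  expect_true(all(diff(counts) >= 0))
  expect_gte(counts[4], 1)
  vt1 <- callVariants(reps[1:4], lapply(reps[5:8], shiftBy, d = 1))
  expect_gte(regionJaccard(variantRegions(vt1), reg), 0.5)
})

test_that("feature-quartile assignment matches a brute-force oracle", {
  p <- smallProfile()
  g <- windowGrid(p)
  q <- quartiles(p)

  ## features tiling Q1 windows land 100% in Q1
  q1win <- g[!is.na(q) & q == "Q1"][1:20]
  pct <- quartileFeatureOverlap(p, granges(q1win))
  expect_equal(unname(pct["Q1"]), 100, tolerance = 1e-9)

  ## 60/40 straddle goes to the 60% side
  w <- g[101:102]
  f <- GRanges(as.character(seqnames(w))[1],
               IRanges(start(w)[1] + round(width(w)[1] * 0.4),
                       start(w)[2] + round(width(w)[2] * 0.6) - 1))
  pct2 <- quartileFeatureOverlap(p, f)
  side <- as.character(q[102])
  expect_equal(unname(pct2[side]), 100, tolerance = 1e-9)

  ## random features vs an interval-arithmetic oracle
  set.seed(55)
  n <- 200
  st <- sample.int(3.5e6, n)
  feats <- GRanges("chr1", IRanges(st, width = sample(200:3000, n, TRUE)))
  pct3 <- quartileFeatureOverlap(p, feats)
  oracle <- vapply(seq_len(n), function(i) {
    hits <- which(start(g) <= end(feats)[i] & end(g) >= start(feats)[i])
    if (!length(hits)) return(NA_character_)
    ov <- pmin(end(g)[hits], end(feats)[i]) -
      pmax(start(g)[hits], start(feats)[i]) + 1
    okq <- !is.na(q[hits])
    keep <- ov / width(feats)[i] >= 0.5 & okq
    if (!any(keep)) return(NA_character_)
    as.character(q[hits[keep][which.max(ov[keep])]])
  }, character(1))
  want <- 100 * table(factor(oracle, paste0("Q", 1:4))) / n
  expect_equal(unname(pct3[paste0("Q", 1:4)]), as.numeric(want),
               tolerance = 1e-9)
  expect_error(quartileFeatureOverlap(p, GRanges()), "empty")
})

test_that("expression by quartile reflects RT-dependent transcription", {
  p <- smallProfile()
  g <- windowGrid(p)

  ## single transcript of FPKM 3 in one window: value log2(4) = 2
  i50 <- which(!is.na(quartiles(p)))[50]
  w <- g[i50]
  tx <- granges(w)
  tx$score <- 3
  qe <- quartileExpression(p, tx)
  qw <- as.character(quartiles(p)[i50])
  expect_equal(unname(qe$values[[qw]]), 2, tolerance = 1e-12)

  ## no transcripts: empty distributions
  qe0 <- quartileExpression(p, GRanges())
  expect_true(all(vapply(qe0$values, length, 0L) == 0L))

  ## expression drawn monotone in true RT: Q1 median above Q4 median
  tr <- smallTruth()
  rtg <- truthRTOnGrid(tr, g)
  set.seed(66)
  idx <- sample(which(!is.na(quartiles(p))), 1500)
  tx2 <- granges(g[idx])
  tx2$score <- rgamma(1500, shape = 2, scale = 5) * (0.2 + rtg[idx])
  qe2 <- quartileExpression(p, tx2)
  expect_gt(qe2$medians[["Q1"]], qe2$medians[["Q4"]])
})
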