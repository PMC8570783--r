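test_that("GC correction removes injected bias but preserves UR dips", {
  tr <- smallTruth()
  sim <- smallSim()
  g <- sim$grid
  gc <- mcols(g)$gc
  excl <- suppressWarnings(c(granges(urRegions(tr)), granges(phRegions(tr))))
  lab <- labelWindows(g, urRegions(tr), phRegions(tr))
  arm <- lab == "arm"

  ## injected bias (generator default, amplitude 8) is detectable raw and
  ## gone after correction
  bias <- exp(-8 * (gc - 0.4)^2)
  v <- trackValues(sim$track)
  corrected <- trackValues(gcCorrect(sim$track, exclude = excl))
  expect_gt(abs(cor(v[arm], bias[arm])), 0.3)
  expect_lt(abs(cor(corrected[arm], bias[arm])), 0.1)

  ## no bias to correct: relative change under 1 percent. The S-phase
  ## fraction is set negligible so the depth carries no RT structure —
  ## with RT signal present, the fit legitimately absorbs the chance
  ## conditional dependence E[RT | GC] of one finite genome realization.
  tr0 <- simulateTruth(nChrom = 2L, chromLength = 10e6, gcBiasAmplitude = 0,
                       sFraction = 1e-6, urPerChrom = 0L, phFraction = 0,
                       seed = 12)
  sim0 <- simulateDepth(tr0, seed = 13)
  v0 <- trackValues(sim0$track)
  c0 <- trackValues(gcCorrect(sim0$track))
  rel <- v0 / mean(v0)
  expect_lt(median(abs(c0 - rel) / rel), 0.01)

  ## dip depth preserved within 10% of truth u
  inUR <- as.character(lab) == "eUR"
  dip <- mean(corrected[inUR]) / mean(corrected[arm])
  ## expected depth: u adjusted by the dip's S-phase factor
  rtg <- truthRTOnGrid(tr, g)
  want <- 0.3 * mean(0.85 + 0.15 * (1 + rtg[inUR])) /
               mean(0.85 + 0.15 * (1 + rtg[arm]))
  expect_lt(abs(dip - want) / want, 0.10)

  expect_error(gcCorrect(DepthTrack(uniformGrid(50), rpois(50, 100))),
               "usable windows")
})

test_that("dual normalization anchors on arms and shields them from UR", {
  grid <- uniformGrid(1000)
  set.seed(31)
  v <- rnorm(1000, 10, 2)
  lab <- rep("arm", 1000)
  lab[301:400] <- "eUR"
  v[301:400] <- v[301:400] - 6
  tk <- DepthTrack(grid, v, label = lab, stage = "gc_corrected")
  z <- dualNormalize(tk)
  arm <- lab == "arm"
  expect_equal(mean(trackValues(z)[arm]), 0, tolerance = 1e-9)
  expect_equal(sd(trackValues(z)[arm]), 1, tolerance = 1e-9)
  expect_identical(trackStage(z), "rawRT")

  ## affine contract: a window at mean - 3 SD maps to exactly -3
  mu <- mean(v[arm]); sg <- sd(v[arm])
  v2 <- v; v2[500] <- mu - 3 * sg
  z2 <- dualNormalize(DepthTrack(grid, v2, label = lab, stage = "gc_corrected"))
  ## window 500 is arm, so arm mean/SD change slightly; use an eUR window
  v3 <- v; v3[350] <- mu - 3 * sg
  z3 <- dualNormalize(DepthTrack(grid, v3, label = lab, stage = "gc_corrected"))
  expect_equal(trackValues(z3)[350], -3, tolerance = 1e-12)

  ## arm-only track: plain z-scores
  zAll <- dualNormalize(DepthTrack(grid, v, stage = "gc_corrected"))
  expect_equal(trackValues(zAll), (v - mean(v)) / sd(v), tolerance = 1e-12)

  ## bitwise shielding: any change inside eUR windows leaves arm untouched
  vDeep <- v; vDeep[301:400] <- vDeep[301:400] - 100
  zDeep <- dualNormalize(DepthTrack(grid, vDeep, label = lab,
                                    stage = "gc_corrected"))
  expect_identical(trackValues(zDeep)[arm], trackValues(z)[arm])

  expect_error(dualNormalize(DepthTrack(grid, rep(1, 1000),
                                        stage = "gc_corrected")),
               "zero arm variance")
})

test_that("scaling raw counts by a constant leaves rawRT unchanged", {
  tr <- smallTruth()
  sim <- smallSim()
  p1 <- buildRTProfile(sim$track, ph = phRegions(tr))
  scaled <- sim$track
  trackValues(scaled) <- trackValues(scaled) * 2.5
  p2 <- buildRTProfile(scaled, ph = phRegions(tr))
  expect_equal(trackValues(rawRT(p1)), trackValues(rawRT(p2)),
               tolerance = 1e-9)
})

test_that("spline smoothing reproduces lines, honors zone rules", {
  ## straight line: the spline's null space
  grid <- uniformGrid(100)
  x <- (start(grid) + end(grid)) / 2
  line <- 2 + 3e-6 * x
  tk <- DepthTrack(grid, line, stage = "rawRT")
  sm <- smoothRT(tk)
  ## per-chromosome standardization makes any affine image of x identical
  expect_equal(trackValues(sm), (line - mean(line)) / sd(line),
               tolerance = 1e-6)

  ## zone of exactly 20 windows dropped, 21 kept
  v <- rep(NA_real_, 100)
  v[1:20] <- rnorm(20)
  v[41:61] <- rnorm(21)
  tk2 <- DepthTrack(grid, v, stage = "rawRT")
  sm2 <- trackValues(smoothRT(tk2, minZone = 21L))
  expect_true(all(is.na(sm2[1:20])))
  expect_true(all(!is.na(sm2[41:61])))

  ## gaps over 5 kb split zones; shorter gaps are bridged
  v3 <- rnorm(100)
  v3[30:36] <- NA          # 7-kb gap: splits 29- and 64-window pieces
  sm3 <- trackValues(smoothRT(DepthTrack(grid, v3, stage = "rawRT")))
  expect_true(all(!is.na(sm3[1:29])))
  expect_true(all(is.na(sm3[30:36])))
  expect_true(all(!is.na(sm3[37:100])))
  v4 <- rnorm(100)
  v4[30:33] <- NA          # 4-kb gap: bridged, one zone
  sm4 <- trackValues(smoothRT(DepthTrack(grid, v4, stage = "rawRT")))
  expect_true(all(!is.na(sm4[c(1:29, 34:100)])))

  expect_error(smoothRT(tk, p = 0), "p must be")
  expect_error(smoothRT(DepthTrack(grid, line, stage = "raw")), "rawRT")
})

test_that("spline tracks a noisy sinusoid like a dense penalized oracle", {
  set.seed(6)
  n <- 4000
  grid <- uniformGrid(n)
  x <- (start(grid) + end(grid)) / 2
  clean <- sin(2 * pi * x / 1e6)
  y <- clean + rnorm(n, 0, 0.5)
  sm <- trackValues(smoothRT(DepthTrack(grid, y, stage = "rawRT")))
  expect_gt(cor(sm, clean), 0.99)

  ## oracle: second-difference penalized least squares on the same grid
  p <- 1e-15
  lam <- ((1 - p) / p) / diff(range(x))^3
  u <- (x - min(x)) / diff(range(x))
  h <- diff(u)[1]
  D <- diff(diag(n), differences = 2) / h^2
  f <- solve(diag(n) + lam * h * crossprod(D), y)
  ## the package fit equals the oracle operator up to the per-chromosome
  ## standardization: standardized curves agree pointwise within 2% of the
  ## signal amplitude
  expect_gt(cor(sm, f), 0.999)
  fStd <- (f - mean(f)) / sd(f)
  amp <- diff(range(fStd))
  expect_lt(max(abs(sm - fStd)), 0.02 * amp)
})

test_that("quartiles are rank-exact with order-statistic cutoffs", {
  q <- assignQuartiles(c(4, 3, 2, 1))
  expect_identical(as.character(q$quartile), c("Q1", "Q2", "Q3", "Q4"))

  ## ties: deterministic by order, occupancy n/4 +- 1
  qt <- assignQuartiles(rep(1, 10))
  occ <- table(qt$quartile)
  expect_true(all(abs(occ - 2.5) <= 0.5))
  expect_identical(as.character(qt$quartile)[1], "Q1")
  expect_identical(as.character(qt$quartile)[10], "Q4")

  ## large Gaussian: cutoffs equal the sort-based oracle
  set.seed(10)
  v <- rnorm(1e5)
  v[sample(1e5, 500)] <- NA
  qg <- assignQuartiles(v)
  s <- sort(v)                      # sort drops NA
  m <- length(s)
  oracle <- vapply(c(0.75, 0.5, 0.25), function(p) {
    hh <- (m - 1) * p + 1           # R type-7 interpolation
    lo <- floor(hh)
    s[lo] + (hh - lo) * (s[lo + 1] - s[lo])
  }, numeric(1))
  expect_equal(unname(qg$cutoffs), oracle, tolerance = 1e-9)
  occ <- table(qg$quartile)
  expect_true(all(abs(occ - sum(!is.na(v)) / 4) <= 1))
  ## Q1 holds the highest values
  expect_gte(min(v[qg$quartile == "Q1"], na.rm = TRUE),
             max(v[qg$quartile == "Q4"], na.rm = TRUE))
  expect_true(all(is.na(qg$quartile[is.na(v)])))

  expect_error(assignQuartiles(c(1, 2, NA, NA)), "at least 4")
})

test_that("full profile meets its structural invariants", {
  p <- smallProfile()
  sm <- smoothedRT(p)
  g <- windowGrid(p)
  chr <- as.character(seqnames(g))
  for (ch in unique(chr)) {
    v <- trackValues(sm)[chr == ch]
    expect_equal(mean(v, na.rm = TRUE), 0, tolerance = 1e-6)
    expect_equal(sd(v, na.rm = TRUE), 1, tolerance = 1e-6)
  }
  occ <- table(quartiles(p))
  n <- sum(occ)
  expect_true(all(abs(occ - n / 4) <= 1))
  ## rawRT arm windows: exactly standardized
  rw <- rawRT(p)
  arm <- trackLabels(rw) == "arm" & !is.na(trackValues(rw)) &
    !mcols(g)$is_short
  expect_equal(mean(trackValues(rw)[arm]), 0, tolerance = 1e-9)
  expect_equal(sd(trackValues(rw)[arm]), 1, tolerance = 1e-9)
})

test_that("UR windows sit deep in rawRT yet keep relative RT order", {
  tr <- smallTruth()
  p <- smallProfile()
  rw <- rawRT(p)
  lab <- trackLabels(rw)
  v <- trackValues(rw)
  ## UR rawRT below the lowest arm quartile cutoff
  armQ25 <- quantile(v[lab == "arm"], 0.25, na.rm = TRUE)
  expect_lt(mean(v[lab == "eUR"], na.rm = TRUE), armQ25)
  ## within UR, smoothed ordering follows true RT (Spearman)
  sm <- trackValues(smoothedRT(p))
  rtg <- truthRTOnGrid(tr, windowGrid(p))
  inUR <- lab == "eUR" & !is.na(sm)
  expect_gte(cor(sm[inUR], rtg[inUR], method = "spearman"), 0.5)
})
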