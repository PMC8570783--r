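test_that("genome generation is deterministic and respects its contracts", {
  g1 <- generateGenome(nChrom = 2L, chromLength = 2e6, grid = 1000,
                       gcSmoothness = 2e5, alignableFraction = 1, seed = 1)
  expect_identical(length(g1@gc[[1]]), 2000L)
  expect_true(all(vapply(g1@alignability, function(a)
    sum(runLength(a) * as.numeric(runValue(a))), 0) == 2e6))
  ## mean GC near 0.42
  expect_lt(abs(mean(unlist(g1@gc)) - 0.42), 0.03)

  ## partial alignability lands near the requested fraction
  g2 <- generateGenome(nChrom = 1L, chromLength = 1e6, grid = 1000,
                       gcSmoothness = 1e5, alignableFraction = 0.8, seed = 1)
  frac <- sum(runLength(g2@alignability[[1]]) *
              as.numeric(runValue(g2@alignability[[1]]))) / 1e6
  expect_gte(frac, 0.78)
  expect_lte(frac, 0.82)

  ## byte-identical repetition under one seed
  a <- generateGenome(nChrom = 1L, chromLength = 1e6, seed = 7)
  b <- generateGenome(nChrom = 1L, chromLength = 1e6, seed = 7)
  expect_identical(a@gc, b@gc)
  expect_identical(lapply(a@alignability, as.logical),
                   lapply(b@alignability, as.logical))

  expect_error(generateGenome(chromLength = -5, seed = 1), "positive")
  expect_error(generateGenome(chromLength = 1e6 + 1, grid = 1000, seed = 1))
  expect_error(generateGenome(alignableFraction = 0, seed = 1), "\\(0, 1]")
})

test_that("RT landscape is smooth, domain-structured and seed-stable", {
  g <- generateGenome(nChrom = 1L, chromLength = 20e6, seed = 3)
  rt1 <- simulateRTLandscape(g, domainScale = 5e5, seed = 5)
  rt2 <- simulateRTLandscape(g, domainScale = 5e5, seed = 5)
  expect_identical(rt1@rt, rt2@rt)
  v <- rt1@rt[[1]]
  expect_gte(min(v), 0); expect_lte(max(v), 1)
  expect_equal(range(v), c(0, 1))
  expect_lt(max(abs(diff(v))), 0.2)          # continuity

  ## local maxima count on 20 Mb at 500 kb domains
  nmax <- sum(diff(sign(diff(v))) == -2)
  expect_gte(nmax, 10); expect_lte(nmax, 60)

  ## lag-1 autocorrelation: structured vs shuffled
  ac <- function(x) cor(x[-1], x[-length(x)])
  expect_gt(ac(v), 0.9)
  set.seed(1)
  expect_lt(abs(ac(sample(v))), 0.05)

  expect_error(simulateRTLandscape(g, domainScale = 500, seed = 1))
})

test_that("expected copy follows the closed-form copy equation", {
  ## s = 0, no UR, no GC bias: expected copy constant
  tr <- simulateTruth(nChrom = 1L, chromLength = 1e6, sFraction = 1e-9,
                      urPerChrom = 0L, phFraction = 0, gcBiasAmplitude = 0,
                      alignableFraction = 1, seed = 2)
  cp <- expectedCopy(tr)[[1]]
  expect_lt(diff(range(cp)), 1e-6)

  ## rt = 1 vs rt = 0 at s = 0.2: ratio (1 + 0.2) / 1
  tr2 <- simulateTruth(nChrom = 1L, chromLength = 1e6, sFraction = 0.2,
                       urPerChrom = 0L, phFraction = 0, gcBiasAmplitude = 0,
                       alignableFraction = 1, seed = 2)
  tr2@rt@rt[[1]][] <- 1
  early <- expectedCopy(tr2)[[1]][1]
  tr2@rt@rt[[1]][] <- 0
  late <- expectedCopy(tr2)[[1]][1]
  expect_equal(early / late, 1.2, tolerance = 1e-12)

  ## monotonicity: expected copy never decreases in rt
  tr3 <- tr2
  tr3@rt@rt[[1]] <- seq(0, 1, length.out = 1000)
  cp3 <- expectedCopy(tr3)[[1]]
  expect_true(all(diff(cp3) >= 0))
})

test_that("sampled counts match the closed-form expectation in a UR dip", {
  ## u = 0.3 over 100 kb, s = 0.15: region/outside count ratio matches the
  ## closed form within 3 standard errors
  tr <- simulateTruth(nChrom = 1L, chromLength = 2e6, sFraction = 0.15,
                      urPerChrom = 0L, phFraction = 0, gcBiasAmplitude = 0,
                      alignableFraction = 1, seed = 4)
  ur <- GRanges("chr1", IRanges(1000001, 1100000), label = "eUR", u = 0.3)
  tr@urRegions <- ur
  sim <- simulateDepth(tr, seed = 9)
  g <- sim$grid
  inUR <- overlapsAny(g, ur, type = "within")
  v <- trackValues(sim$track)
  cp <- expectedCopy(tr)[[1]]
  mid <- (start(g) + end(g)) / 2
  cpw <- cp[ceiling(mid / 1000)]
  expRatio <- mean(cpw[inUR]) / mean(cpw[!inUR])
  obsRatio <- mean(v[inUR]) / mean(v[!inUR])
  se <- expRatio * sqrt(1 / sum(v[inUR]) + 1 / sum(v[!inUR]))
  expect_lt(abs(obsRatio - expRatio), 3 * se)
  ## and the closed form itself is 0.3 x the within-S factor
  rtUR <- mean(tr@rt@rt[[1]][1001:1100])
  rtArm <- mean(tr@rt@rt[[1]][-(1001:1100)])
  closed <- 0.3 * (0.85 + 0.15 * (1 + rtUR)) / (0.85 + 0.15 * (1 + rtArm))
  expect_equal(expRatio, closed, tolerance = 1e-10)
})

test_that("Poisson sampling matches its mean within 4 SE over many draws", {
  tr <- smallTruth()
  grid <- smallSim()$grid
  exp1 <- simulateDepth(tr, grid = grid, seed = 1)$expected
  tot <- numeric(length(exp1))
  nrep <- 40L
  for (k in seq_len(nrep))
    tot <- tot + trackValues(simulateDepth(tr, grid = grid, seed = 100 + k)$track)
  ## aggregate over windows: >= 1e4 effective draws
  i <- which(!mcols(grid)$is_short)[1:250]
  m <- sum(tot[i]) / nrep
  mu <- sum(exp1[i])
  se <- sqrt(mu / nrep)
  expect_lt(abs(m - mu), 4 * se)
})

test_that("condition perturbation shifts rt and removes UR as specified", {
  tr <- smallTruth()
  same <- perturbCondition(tr)
  expect_identical(trueRT(same)@rt, trueRT(tr)@rt)
  expect_identical(urRegions(same), urRegions(tr))

  noUR <- perturbCondition(tr, urRemoved = TRUE)
  expect_true(all(c(urRegions(noUR)$u, phRegions(noUR)$u) == 1))
  ## with u == 1 everywhere (and gc bias off) every locus has >= 1 copy
  tr0 <- noUR; tr0@gcBias[["amplitude"]] <- 0
  expect_gte(min(expectedCopy(tr0)[[1]]), 1 - 1e-9)

  sh <- GRanges("chr1", IRanges(2e6 + 1, 2.3e6), delta = +0.4)
  up <- perturbCondition(tr, rtShifts = sh)
  cells <- 2001:2300
  before <- trueRT(tr)@rt[[1]][cells]
  after <- trueRT(up)@rt[[1]][cells]
  expect_equal(after, pmin(1, before + 0.4), tolerance = 1e-12)
  ## outside the region nothing changes
  expect_identical(trueRT(up)@rt[[1]][-cells], trueRT(tr)@rt[[1]][-cells])

  expect_error(perturbCondition(tr, rtShifts = GRanges("chr1", IRanges(1, 2))),
               "delta")
})

test_that("replicate tracks from distinct seeds agree after the pipeline", {
  p1 <- smallProfile()
  sim2 <- simulateDepth(smallTruth(), grid = smallSim()$grid, seed = 18)
  p2 <- buildRTProfile(sim2$track, ph = phRegions(smallTruth()))
  expect_gt(rtCorrelation(p1, p2, on = "smoothed")$r, 0.95)
  ## identical seed reproduces counts exactly
  sim1b <- simulateDepth(smallTruth(), grid = smallSim()$grid, seed = 17)
  expect_identical(trackValues(sim1b$track), trackValues(smallSim()$track))
})
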