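## Exhaustive least-squares change-point oracles for short series,
## shared by the segmentation unit tests and the acceptance checks.

oracleCost0 <- function(v) {
  ok <- !is.na(v)
  sum((v[ok] - mean(v[ok]))^2)
}
segCost <- function(v, cuts) {
  bounds <- c(0, cuts, length(v))
  tot <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    seg <- v[(bounds[i] + 1L):bounds[i + 1L]]
    tot <- tot + oracleCost0(seg)
  }
  tot
}
oracleBest <- function(v, maxBreaks, beta, minSeg = 5L) {
  n <- length(v)
  cnt <- cumsum(!is.na(v))
  okSeg <- function(a, b) (cnt[b] - if (a > 0) cnt[a] else 0) >= minSeg
  best <- list(cost = oracleCost0(v) + beta, cuts = integer(0))
  if (maxBreaks >= 1L) for (b1 in 1:(n - 1L)) {
    if (!okSeg(0L, b1) || !okSeg(b1, n)) next
    cost <- segCost(v, b1) + 2 * beta
    if (cost < best$cost) best <- list(cost = cost, cuts = b1)
  }
  if (maxBreaks >= 2L) for (b1 in 1:(n - 2L)) for (b2 in (b1 + 1L):(n - 1L)) {
    if (!okSeg(0L, b1) || !okSeg(b1, b2) || !okSeg(b2, n)) next
    cost <- segCost(v, c(b1, b2)) + 3 * beta
    if (cost < best$cost) best <- list(cost = cost, cuts = c(b1, b2))
  }
  best
}
modelCost <- function(m, v) {
  segCost(v, breakpoints(m)) + length(segmentMeans(m)) * m@penalty
}

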