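# Independent oracles, deliberately written against different data
# structures than the implementation they check.

# Stationary activity of one population under constant input, by bisection
# on the stationarity equation -(A - baseline) + (1 - A) * F(I + w*A) = 0.
bisectFixedPoint <- function(input, selfWeight = 0, baseline = 0,
                             gain = 4, threshold = 0.5, lower = 0, upper = 1) {
  f <- function(a)
    -(a - baseline) + (1 - a) * wcSigmoid(input + selfWeight * a,
                                          gain, threshold)
  lo <- lower; hi <- upper
  stopifnot(f(lo) >= 0)
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# From-scratch replay of the boundary-entropy decisions for a single
# symbol stream: at each position recompute the transition counts of the
# whole prefix by tabulation and apply the same pre-update dH > 0 test.
replayChunkBoundaries <- function(syms) {
  n <- length(syms)
  bounds <- integer(0)
  rowEntropy <- function(pairsA, pairsB, ctx, alphabet) {
    succ <- pairsB[pairsA == ctx]
    counts <- table(factor(succ, levels = alphabet))
    p <- (as.numeric(counts) + 1) / (sum(counts) + length(alphabet))
    -sum(p * log2(p))
  }
  for (t in 2:n) {
    alphabet <- unique(syms[1:t])
    pa <- syms[seq_len(t - 2)]          # transition pairs of the prefix,
    pb <- syms[seq_len(t - 2) + 1L]     # before (s_{t-1}, s_t) is counted
    dH <- rowEntropy(pa, pb, syms[t], alphabet) -
      rowEntropy(pa, pb, syms[t - 1], alphabet)
    if (dH > 1e-12) bounds <- c(bounds, t)
  }
  bounds
}

# Boundary F1 against ground truth, ignoring everything up to burnIn.
boundaryF1 <- function(found, truth, burnIn = 0) {
  f <- found[found > burnIn]; t <- truth[truth > burnIn]
  tp <- length(intersect(f, t))
  if (!length(f) || !length(t) || tp == 0) return(0)
  p <- tp / length(f); r <- tp / length(t)
  2 * p * r / (p + r)
}

# Observe a plain symbol stream under one viewpoint.
feedStream <- function(mem, syms, vp = "x") {
  for (s in syms) observeEvent(mem, list(vp = stats::setNames(list(s), vp)))
  mem
}

# Interval-wise profile summary used by the activity-profile checks: for
# each inter-onset interval, the rise over the first 50 ms and the largest
# drop below the interval's running peak after that peak.
profileByInterval <- function(trace, onsets) {
  tot <- totalActivity(trace)
  tm <- trace@time
  out <- data.frame(word = seq_along(onsets), rise50 = NA_real_,
                    declineAfterPeak = NA_real_)
  for (k in seq_along(onsets)) {
    a <- onsets[k]
    b <- if (k < length(onsets)) onsets[k + 1] else max(tm)
    w <- which(tm >= a & tm <= b)
    tw <- tot[w]
    out$rise50[k] <- tot[which.min(abs(tm - (a + 50)))] -
      tot[which.min(abs(tm - a))]
    im <- which.max(tw)
    out$declineAfterPeak[k] <-
      if (im < length(tw)) max(tw[im] - tw[im:length(tw)]) else 0
  }
  out
}

# Access to a level's internal environment (sequences, links, counts).
.getLevelEnv <- function(mem, vp, lev) conceptboard:::.getLevel(mem, vp, lev)

# Smallest working networks for dynamics tests.
singlePop <- function(...) {
  net <- RateNetwork()
  addPopulation(net, "p", ...)
  net
}
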