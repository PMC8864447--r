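# Independent oracles and small fixture builders used across the suite.

# Naive simulation of the iterative nearest-pair merge: considers every pair
# each round, picks the globally closest pair no further apart than the gap
# (ties broken by the pair with the smallest values), and replaces it by the
# floor of its mean. Independent of the package's sorted-adjacency version.
mergeOracle <- function(bins, mergeGap = 5) {
  vals <- sort(as.numeric(bins))
  repeat {
    n <- length(vals)
    if (n < 2L) break
    best <- NULL
    bestDist <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d <- abs(vals[j] - vals[i])
        if (d < bestDist) {
          bestDist <- d
          best <- c(i, j)
        }
      }
    }
    if (bestDist > mergeGap) break
    merged <- floor((vals[best[1]] + vals[best[2]]) / 2)
    vals <- sort(c(vals[-best], merged))
  }
  vals
}

# Brute-force minimum start->goal path weight on a Z x B grid with the
# 8-neighbour moves, no vertex revisits. Path weight = w(entry vertex) + sum
# of w over each subsequent vertex entered (goal edges cost 0). Pruning on
# partial weight is sound because all weights are positive.
shortestPathOracle <- function(w) {
  Z <- nrow(w)
  B <- ncol(w)
  best <- Inf
  visited <- matrix(FALSE, Z, B)
  moves <- rbind(
    c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, -1L), c(0L, 1L),
    c(1L, -1L), c(1L, 0L), c(1L, 1L)
  )
  dfs <- function(z, t, acc) {
    if (acc >= best) return(invisible())
    if (z == Z) {
      best <<- min(best, acc)
      return(invisible())
    }
    visited[z, t] <<- TRUE
    for (m in seq_len(nrow(moves))) {
      nz <- z + moves[m, 1L]
      nt <- t + moves[m, 2L]
      if (nz >= 1L && nz <= Z && nt >= 1L && nt <= B && !visited[nz, nt])
        dfs(nz, nt, acc + w[nz, nt])
    }
    visited[z, t] <<- FALSE
    invisible()
  }
  for (t0 in seq_len(B)) dfs(1L, t0, w[1L, t0])
  best
}

# PSTHMatrix with given rate matrix and unit trial counts.
ratePSTH <- function(rates, unitId = "u", nTrials = 20L, binMs = 1,
                     layer = "IV", condition = "sham", stimulus = "contact") {
  rates <- as.matrix(rates)
  psthMatrix(unitId, layer, condition, stimulus, rates,
             nTrials = rep(nTrials, nrow(rates)), binMs = binMs,
             windowMs = ncol(rates) * binMs)
}

# Single-row helper: a 50-bin PSTH row with spikes at given bins/rates.
rowWithPeaks <- function(bins, rates, B = 50) {
  row <- numeric(B)
  row[bins] <- rates
  row
}

# Noiseless multi-intensity PSTH from programmed component bins: rate `amp` at
# the given bin per intensity.
noiselessPSTH <- function(binsPerIntensity, amp = 100, B = 50, ...) {
  Z <- length(binsPerIntensity)
  rates <- matrix(0, Z, B)
  for (z in seq_len(Z)) rates[z, binsPerIntensity[[z]]] <- amp
  ratePSTH(rates, ...)
}

# Random raster with spikes uniform over the window.
randomRaster <- function(nSpikes = 200, Z = 5, nTrials = 10L, windowMs = 50,
                         seed = 1) {
  set.seed(seed)
  spikeRaster("u_rand", "II", "sham", "basic",
    events = data.frame(
      intensity = sample.int(Z, nSpikes, replace = TRUE),
      trial = sample.int(nTrials, nSpikes, replace = TRUE),
      time_ms = runif(nSpikes, 0, windowMs)
    ),
    nTrials = rep(nTrials, Z), windowMs = windowMs
  )
}
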