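#' Extract the 11-bin validation segment around a component
#'
#' Takes the intensity-pooled mean firing rates at the 5 bins immediately
#' before and after the identified component time. Together with the component
#' bin itself this is an 11-ms segment in which the component bin is nominally
#' 6th; near the window edges the segment is truncated (never zero-padded,
#' which would bias the segment minimum towards 0) and the bins lost on each
#' side are recorded.
#'
#' @param pooledRates numeric vector of B intensity-pooled rates (from
#'   [pooledMeanRates()]).
#' @param componentBin integer component time bin in 1..B.
#' @return A `PeakinessSegment`: a list with elements `bins` (the bin indices
#'   covered), `rates`, `center` (position of the component bin within the
#'   segment), `gi` (component-bin rate), `gk` (minimum rate within the
#'   segment), `leftTruncated`, `rightTruncated`.
#' @export
extractSegment <- function(pooledRates, componentBin) {
  B <- length(pooledRates)
  componentBin <- as.integer(componentBin)
  stopifnot(componentBin >= 1L, componentBin <= B)
  lo <- max(1L, componentBin - 5L)
  hi <- min(B, componentBin + 5L)
  bins <- lo:hi
  seg <- list(
    bins = bins,
    rates = as.numeric(pooledRates[bins]),
    center = componentBin - lo + 1L,
    gi = as.numeric(pooledRates[componentBin]),
    gk = min(pooledRates[bins]),
    leftTruncated = (componentBin - 5L) - lo,
    rightTruncated = hi - (componentBin + 5L)
  )
  seg$leftTruncated <- abs(seg$leftTruncated)
  seg$rightTruncated <- abs(seg$rightTruncated)
  class(seg) <- "PeakinessSegment"
  seg
}

#' Peakiness of a response component
#'
#' Scores how much the component bin's mean firing rate `g_i` exceeds the
#' minimum mean firing rate `g_k` within the surrounding 11-ms segment. The
#' default `"literal"` form is `(g_i + 1) / (g_k + 1)`: it equals 1 when the
#' component bin rate equals the segment minimum, and (at high rates) 1.25
#' when the component rate is 25% above the minimum, 1.5 at 50% above, and so
#' on. The `"normalized"` form `(g_i + 1) / ((g_i + g_k)/2 + 1)` is bounded in
#' (0, 2) with the same fixed point at 1; it is offered because a bounded
#' 0-to-2 scale is sometimes the intended reading, but it is never substituted
#' silently.
#'
#' @param seg a `PeakinessSegment` from [extractSegment()], or a list with
#'   elements `gi` and `gk`.
#' @param variant `"literal"` (default) or `"normalized"`.
#' @return numeric(1) peakiness value, >= 1 for literal when `gk` is the
#'   segment minimum (since `gk <= gi`).
#' @examples
#' peakiness(list(gi = 4, gk = 1)) # (4+1)/(1+1) = 2.5
#' peakiness(list(gi = 12500, gk = 10000)) # ~1.25: 25% above the minimum
#' @export
peakiness <- function(seg, variant = c("literal", "normalized")) {
  variant <- match.arg(variant)
  gi <- seg$gi
  gk <- seg$gk
  stopifnot(is.numeric(gi), is.numeric(gk), gi >= 0, gk >= 0)
  switch(variant,
    literal = (gi + 1) / (gk + 1),
    normalized = (gi + 1) / ((gi + gk) / 2 + 1)
  )
}

#' One-tailed two-sample t test of a component against its surroundings
#'
#' Splits the 11-bin segment into the "component segment" — the 3 bins centred
#' on the component time (nominal segment positions 5-7), clipped by any edge
#' truncation — and the remaining (nominally 8) bins, then tests whether the
#' component bins' mean firing rate exceeds the surround with a one-tailed
#' two-sample t test (pooled variance by default, Welch optionally).
#'
#' When both groups have zero variance the t statistic is degenerate: equal
#' means return `t = 0, p = 0.5` (no evidence either way); unequal means
#' return an infinite t with p of 0 or 1 according to direction, and the
#' result is flagged `degenerate`. A group with fewer than 2 bins (extreme
#' edge truncation) makes the test not computable.
#'
#' @param seg a `PeakinessSegment` from [extractSegment()].
#' @param varEqual logical; `TRUE` (default) pools the variance, `FALSE` uses
#'   Welch's approximation.
#' @return list with elements `t`, `p`, `computable`, `degenerate`.
#' @export
componentTTest <- function(seg, varEqual = TRUE) {
  componentBin <- seg$bins[seg$center]
  inComp <- seg$bins >= componentBin - 1L & seg$bins <= componentBin + 1L
  comp <- seg$rates[inComp]
  rest <- seg$rates[!inComp]
  if (length(comp) < 2L || length(rest) < 2L)
    return(list(t = NA_real_, p = NA_real_, computable = FALSE, degenerate = FALSE))
  vC <- stats::var(comp)
  vR <- stats::var(rest)
  if (vC == 0 && vR == 0) {
    d <- mean(comp) - mean(rest)
    if (d == 0) {
      return(list(t = 0, p = 0.5, computable = TRUE, degenerate = FALSE))
    }
    return(list(t = sign(d) * Inf, p = if (d > 0) 0 else 1,
                computable = TRUE, degenerate = TRUE))
  }
  ht <- stats::t.test(comp, rest, alternative = "greater", var.equal = varEqual)
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       computable = TRUE, degenerate = FALSE)
}

#' Validate every detected component of a unit
#'
#' For each unit-level component time, extracts the 11-bin segment from the
#' intensity-pooled PSTH, computes both peakiness variants and the one-tailed
#' component t test.
#'
#' @param psth a [PSTHMatrix-class].
#' @param componentSet the unit's [ComponentSet-class].
#' @param varEqual passed to [componentTTest()].
#' @return data.frame with one row per component: `unit_id`,
#'   `component_time_ms`, `peakiness_literal`, `peakiness_normalized`, `t`,
#'   `p`, `computable_flag`. Zero rows for a non-responder.
#' @export
validateComponents <- function(psth, componentSet, varEqual = TRUE) {
  stopifnot(is(psth, "PSTHMatrix"), is(componentSet, "ComponentSet"))
  pooled <- pooledMeanRates(psth)
  times <- componentSet@componentTimes
  out <- lapply(times, function(b) {
    seg <- extractSegment(pooled, b)
    tt <- componentTTest(seg, varEqual = varEqual)
    data.frame(
      unit_id = psth@unitId,
      component_time_ms = b,
      peakiness_literal = peakiness(seg, "literal"),
      peakiness_normalized = peakiness(seg, "normalized"),
      t = tt$t, p = tt$p, computable_flag = tt$computable,
      stringsAsFactors = FALSE
    )
  })
  if (length(out) == 0L) {
    return(data.frame(
      unit_id = character(), component_time_ms = numeric(),
      peakiness_literal = numeric(), peakiness_normalized = numeric(),
      t = numeric(), p = numeric(), computable_flag = logical(),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, out)
}
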