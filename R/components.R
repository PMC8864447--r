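#' Local maxima of a PSTH row
#'
#' An interior bin b (2 <= b <= B-1) is a local maximum when its rate strictly
#' exceeds both neighbours. A plateau of equal rates strictly above both of its
#' flanks yields a single maximum at the plateau's median bin (lower median for
#' an even-length plateau). Endpoint bins are never maxima: a local maximum
#' needs two neighbours, and the downstream filter rule references both.
#'
#' @param rates numeric vector of B >= 3 mean firing rates.
#' @return integer vector of local-maximum time bins (possibly empty), sorted.
#' @examples
#' localMaxima(c(0, 0, 5, 0, 0)) # 3
#' localMaxima(c(0, 4, 4, 4, 0)) # plateau -> 3
#' @export
localMaxima <- function(rates) {
  stopifnot(is.numeric(rates), length(rates) >= 3L)
  r <- rle(rates)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer()
  if (k >= 3L) {
    for (i in 2:(k - 1L)) {
      if (r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L])
        out <- c(out, as.integer(floor((starts[i] + ends[i]) / 2)))
    }
  }
  out
}

#' Filter weak, isolated local maxima
#'
#' A local maximum at bin b is discarded iff its rate is below 25% of the
#' maximum firing rate AND both neighbouring 1-ms bins carry no spikes (rate
#' 0). Both conditions must hold (conjunction): a weak maximum flanked by any
#' activity is kept.
#'
#' @param bins integer vector of candidate local-maximum bins (a subset of
#'   `localMaxima(rates)`).
#' @param rates the same PSTH row the maxima came from.
#' @param maxRate the reference maximum firing rate; defaults to `max(rates)`
#'   of this row. Pass the unit-wide maximum to apply the threshold globally.
#' @param threshold fraction of `maxRate` below which an isolated maximum is
#'   discarded (default 0.25).
#' @return the retained bins, sorted.
#' @export
filterMaxima <- function(bins, rates, maxRate = max(rates), threshold = 0.25) {
  if (length(bins) == 0L) return(integer())
  keep <- vapply(bins, function(b) {
    !(rates[b] < threshold * maxRate && rates[b - 1L] == 0 && rates[b + 1L] == 0)
  }, logical(1))
  sort(as.integer(bins[keep]))
}

# Iterative nearest-pair merging with provenance tracking. Each cluster keeps
# the identities (e.g. intensity labels) of the maxima merged into it; the
# representative time of a merged pair is floor of the mean, which keeps times
# on the 1-ms lattice. Ties on separation are broken by the left-most pair.
.mergeClusters <- function(times, ids, mergeGap) {
  n <- length(times)
  if (n == 0L) return(list(times = numeric(), members = list()))
  ord <- order(times)
  times <- times[ord]
  members <- lapply(ids[ord], function(x) x)
  while (length(times) > 1L) {
    gaps <- diff(times)
    i <- which.min(gaps) # earliest pair on ties
    if (gaps[i] > mergeGap) break
    merged <- .floorMeanPair(times[i], times[i + 1L])
    newMembers <- c(members[[i]], members[[i + 1L]])
    times <- c(times[seq_len(i - 1L)], merged,
               times[seq(i + 2L, length.out = length(times) - i - 1L)])
    members <- c(members[seq_len(i - 1L)], list(newMembers),
                 members[seq(i + 2L, length.out = length(members) - i - 1L)])
    ord <- order(times)
    times <- times[ord]
    members <- members[ord]
  }
  list(times = times, members = members)
}

#' Iteratively merge nearby local maxima
#'
#' Local maxima within `mergeGap` ms of each other are combined, starting with
#' the two maxima nearest each other: the pair with the smallest separation
#' (<= `mergeGap`; ties broken by the earliest pair) is replaced by the median
#' 1-ms bin between them (floor of the mean), and the procedure repeats until
#' all pairwise separations exceed `mergeGap`.
#'
#' @param bins numeric vector of local-maximum time bins (any order).
#' @param mergeGap maximum separation in ms at which two maxima are combined
#'   (default 5, inclusive).
#' @return merged time bins, sorted ascending.
#' @examples
#' mergeMaxima(c(10, 12, 30)) # 11, 30
#' mergeMaxima(c(10, 13, 15)) # (13,15)->14, then (10,14)->12
#' @export
mergeMaxima <- function(bins, mergeGap = 5) {
  res <- .mergeClusters(as.numeric(bins), as.list(seq_along(bins)), mergeGap)
  res$times
}

#' Detect unit-level response components
#'
#' Runs the full extended local-maxima analysis on one unit: per intensity,
#' `mergeMaxima(filterMaxima(localMaxima(row)))`; then pools the per-intensity
#' maxima times across intensities and applies the same iterative merge. Each
#' resulting cluster is one candidate response component; clusters supported by
#' fewer than `minSupport` distinct intensities are dropped. The surviving
#' component times determine the unit's category: 0, 1, 2 or 3plus.
#'
#' @param psth a [PSTHMatrix-class].
#' @param mergeGap merge gap in ms (default 5).
#' @param minSupport minimum number of distinct intensities whose maxima must
#'   contribute to a cluster (default 1, the literal single-intensity reading;
#'   3 is recommended for 10-intensity data — see the package vignette).
#' @param unitWideMax logical; if `TRUE` the 25%-of-max filter threshold uses
#'   the unit-wide maximum rate instead of each row's own maximum.
#' @param threshold filter threshold fraction (default 0.25).
#' @return A [ComponentSet-class].
#' @export
unitComponents <- function(psth, mergeGap = 5, minSupport = 1L,
                           unitWideMax = FALSE, threshold = 0.25) {
  stopifnot(is(psth, "PSTHMatrix"))
  rates <- psth@rates
  Z <- nrow(rates)
  globalMax <- if (length(rates)) max(rates) else 0
  perIntensity <- vector("list", Z)
  for (z in seq_len(Z)) {
    row <- rates[z, ]
    lm <- localMaxima(row)
    refMax <- if (unitWideMax) globalMax else max(row)
    fm <- filterMaxima(lm, row, maxRate = refMax, threshold = threshold)
    perIntensity[[z]] <- as.integer(mergeMaxima(fm, mergeGap = mergeGap))
  }
  pooledTimes <- unlist(perIntensity, use.names = FALSE)
  pooledIds <- rep(seq_len(Z), vapply(perIntensity, length, integer(1)))
  merged <- .mergeClusters(as.numeric(pooledTimes), as.list(pooledIds), mergeGap)
  support <- vapply(merged$members, function(m) length(unique(unlist(m))), integer(1))
  keep <- support >= minSupport
  times <- merged$times[keep]
  support <- support[keep]
  n <- length(times)
  new("ComponentSet",
    unitId = psth@unitId,
    perIntensityMaxima = perIntensity,
    componentTimes = as.numeric(times),
    support = as.integer(support),
    category = if (n >= 3L) "3plus" else as.character(n)
  )
}

#' Response category of a component count
#'
#' Units are partitioned into four categories by their number of detected
#' response components: `"0"` (non-responder), `"1"`, `"2"`, or `"3plus"`.
#'
#' @param x a [ComponentSet-class] or a non-negative integer component count.
#' @return character(1) category label.
#' @export
classifyComponents <- function(x) {
  n <- if (is(x, "ComponentSet")) length(x@componentTimes) else as.integer(x)
  stopifnot(length(n) == 1L, n >= 0L)
  if (n >= 3L) "3plus" else as.character(n)
}

#' Tabulate detected components across units
#'
#' @param componentSets list of [ComponentSet-class] objects.
#' @param psths matching list of [PSTHMatrix-class] objects supplying unit
#'   metadata (matched by unit id).
#' @return data.frame with one row per detected component (plus one row per
#'   non-responder with `component_index = NA`): columns `unit_id`, `layer`,
#'   `condition`, `stimulus`, `category`, `component_index`,
#'   `component_time_ms`, `supporting_intensities`.
#' @export
componentsTable <- function(componentSets, psths) {
  meta <- lapply(psths, function(p) {
    data.frame(unit_id = p@unitId, layer = p@layer, condition = p@condition,
               stimulus = p@stimulus, stringsAsFactors = FALSE)
  })
  meta <- do.call(rbind, meta)
  rows <- lapply(componentSets, function(cs) {
    m <- meta[match(cs@unitId, meta$unit_id), , drop = FALSE]
    n <- length(cs@componentTimes)
    if (n == 0L) {
      cbind(m, data.frame(category = cs@category, component_index = NA_integer_,
                          component_time_ms = NA_real_,
                          supporting_intensities = NA_integer_))
    } else {
      cbind(m[rep(1L, n), , drop = FALSE],
            data.frame(category = cs@category, component_index = seq_len(n),
                       component_time_ms = cs@componentTimes,
                       supporting_intensities = cs@support))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
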