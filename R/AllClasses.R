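#' @import methods
NULL

.LAYERS <- c("II", "IV")
.CONDITIONS <- c("sham", "tbi_4d", "tbi_2w", "tbi_8w")
.STIMULI <- c("basic", "contact")
.CATEGORIES <- c("0", "1", "2", "3plus")

#' SpikeRaster: trial-resolved spike times for one unit
#'
#' Container for the raw, stimulus-aligned spike times of a single online-sorted
#' unit, recorded across a contiguous range of stimulus intensities (on-ramp
#' velocities for the trapezoid "basic" stimulus, peak amplitudes for the
#' naturalistic "contact" stimulus) with one or more repeated trials per
#' intensity.
#'
#' @slot unitId character(1) unit identifier.
#' @slot layer character(1), `"II"` or `"IV"` (cortical layer).
#' @slot condition character(1), one of `"sham"`, `"tbi_4d"`, `"tbi_2w"`,
#'   `"tbi_8w"`.
#' @slot stimulus character(1), `"basic"` or `"contact"`.
#' @slot events data.frame with columns `intensity` (integer, 1..Z),
#'   `trial` (integer, 1..nTrials\[z\]) and `time_ms` (numeric, >= 0 ms from
#'   stimulus onset). One row per spike; may have zero rows.
#' @slot nTrials integer vector of trial counts, one per intensity; its length
#'   defines Z, the number of intensities.
#' @slot windowMs numeric(1) analysis window length in ms (spikes at or beyond
#'   it are tolerated here and dropped at PSTH build time).
#'
#' @seealso [spikeRaster()], [buildPSTH()]
#' @export
setClass("SpikeRaster",
  representation(
    unitId = "character",
    layer = "character",
    condition = "character",
    stimulus = "character",
    events = "data.frame",
    nTrials = "integer",
    windowMs = "numeric"
  )
)

setValidity("SpikeRaster", function(object) {
  msg <- character()
  if (length(object@unitId) != 1L) msg <- c(msg, "unitId must be a single string")
  if (!object@layer %in% .LAYERS) msg <- c(msg, "layer must be 'II' or 'IV'")
  if (!object@condition %in% .CONDITIONS)
    msg <- c(msg, sprintf("condition must be one of %s", paste(.CONDITIONS, collapse = ", ")))
  if (!object@stimulus %in% .STIMULI) msg <- c(msg, "stimulus must be 'basic' or 'contact'")
  if (length(object@nTrials) < 1L || any(object@nTrials < 1L))
    msg <- c(msg, "nTrials must have >= 1 trial per intensity")
  if (length(object@windowMs) != 1L || object@windowMs <= 0)
    msg <- c(msg, "windowMs must be a single positive number")
  ev <- object@events
  need <- c("intensity", "trial", "time_ms")
  if (!all(need %in% names(ev))) {
    msg <- c(msg, "events must have columns intensity, trial, time_ms")
  } else if (nrow(ev) > 0L) {
    Z <- length(object@nTrials)
    if (any(ev$intensity < 1L | ev$intensity > Z))
      msg <- c(msg, sprintf("event intensity outside 1..%d", Z))
    if (any(ev$trial < 1L) ||
        any(ev$trial > object@nTrials[pmin(pmax(ev$intensity, 1L), Z)]))
      msg <- c(msg, "event trial index exceeds declared nTrials")
    if (any(ev$time_ms < 0)) msg <- c(msg, "negative spike times")
  }
  if (length(msg)) msg else TRUE
})

#' PSTHMatrix: intensity-by-time mean firing rates for one unit
#'
#' The peristimulus time histogram of a unit, one row per stimulus intensity
#' and one column per time bin, holding trial-mean firing rates in Hz. This is
#' the object every downstream analysis consumes.
#'
#' @slot unitId,layer,condition,stimulus unit metadata, as in
#'   [SpikeRaster-class].
#' @slot rates numeric Z x B matrix of mean firing rates (Hz), all >= 0.
#'   Column b covers the half-open interval \[b-1, b) x binMs ms.
#' @slot nTrials integer vector of trial counts per intensity (length Z).
#' @slot binMs numeric(1) bin width in ms (default 1).
#' @slot windowMs numeric(1) window length in ms (default 50); B = windowMs /
#'   binMs exactly.
#'
#' @details Rates are recoverable spike counts:
#' `count(z, b) = rates[z, b] * nTrials[z] * binMs / 1000`, so total in-window
#' spike count is conserved by construction.
#'
#' @seealso [buildPSTH()], [psthMatrix()], [unitComponents()], [buildGraph()]
#' @export
setClass("PSTHMatrix",
  representation(
    unitId = "character",
    layer = "character",
    condition = "character",
    stimulus = "character",
    rates = "matrix",
    nTrials = "integer",
    binMs = "numeric",
    windowMs = "numeric"
  )
)

setValidity("PSTHMatrix", function(object) {
  msg <- character()
  if (!object@layer %in% .LAYERS) msg <- c(msg, "layer must be 'II' or 'IV'")
  if (!object@condition %in% .CONDITIONS) msg <- c(msg, "invalid condition")
  if (!object@stimulus %in% .STIMULI) msg <- c(msg, "invalid stimulus")
  if (!is.numeric(object@rates)) msg <- c(msg, "rates must be numeric")
  if (any(object@rates < 0)) msg <- c(msg, "rates must be >= 0")
  if (length(object@binMs) != 1L || object@binMs <= 0) msg <- c(msg, "binMs must be positive")
  B <- object@windowMs / object@binMs
  if (abs(B - round(B)) > 1e-9) msg <- c(msg, "windowMs must be an integer multiple of binMs")
  if (ncol(object@rates) != round(B))
    msg <- c(msg, sprintf("rates must have %d columns (windowMs/binMs)", round(B)))
  if (nrow(object@rates) != length(object@nTrials))
    msg <- c(msg, "nTrials length must equal nrow(rates)")
  if (length(msg)) msg else TRUE
})

#' ComponentSet: detected response components of one unit
#'
#' Result of the extended local-maxima response-component analysis: the
#' per-intensity (post-filter, post-merge) local maxima, the unit-level
#' component times obtained by pooling and re-merging those maxima across
#' intensities, and the unit's response category.
#'
#' @slot unitId character(1).
#' @slot perIntensityMaxima list of integer vectors, element z holding the
#'   merged local-maxima time bins of intensity z's PSTH row.
#' @slot componentTimes numeric vector of unit-level component time bins (ms on
#'   the 1-ms lattice), sorted, pairwise separated by more than the merge gap.
#' @slot support integer vector, per component, of how many distinct
#'   intensities contributed maxima to it.
#' @slot category character(1), `"0"`, `"1"`, `"2"` or `"3plus"` =
#'   `min(length(componentTimes), 3)`.
#'
#' @seealso [unitComponents()], [classifyComponents()]
#' @export
setClass("ComponentSet",
  representation(
    unitId = "character",
    perIntensityMaxima = "list",
    componentTimes = "numeric",
    support = "integer",
    category = "character"
  )
)

setValidity("ComponentSet", function(object) {
  msg <- character()
  if (!object@category %in% .CATEGORIES) msg <- c(msg, "invalid category")
  n <- length(object@componentTimes)
  if (length(object@support) != n) msg <- c(msg, "support length must match componentTimes")
  expected <- if (n >= 3L) "3plus" else as.character(n)
  if (object@category != expected)
    msg <- c(msg, sprintf("category '%s' inconsistent with %d components", object@category, n))
  if (is.unsorted(object@componentTimes, strictly = TRUE) && n > 1L)
    msg <- c(msg, "componentTimes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' ComponentPath: one shortest path through a PSTH grid graph
#'
#' A single intensity-ordered path extracted from the weighted directed grid
#' graph of a PSTH matrix, together with its summary features.
#'
#' @slot rank integer(1), 1 for the primary (shortest) path, 2 for the
#'   secondary, etc.
#' @slot vertices data.frame with columns `z`, `t`, `rate`: the grid vertices
#'   visited, in path order (start/goal pseudo-vertices stripped).
#' @slot totalWeight numeric(1) sum of edge weights along start -> goal.
#' @slot medianTime numeric(1) lower median of all visited time bins (ms).
#' @slot perRow data.frame with columns `z`, `time`, `rate`: per intensity row,
#'   the lower-median time bin visited and the mean firing rate over that row's
#'   path vertices.
#' @slot nonstationarityMs numeric(1) max - min of per-row times: how far the
#'   tracked component shifts across stimulus intensities.
#'
#' @seealso [kDisjointShortestPaths()], [pathFeatures()]
#' @export
setClass("ComponentPath",
  representation(
    rank = "integer",
    vertices = "data.frame",
    totalWeight = "numeric",
    medianTime = "numeric",
    perRow = "data.frame",
    nonstationarityMs = "numeric"
  )
)

setValidity("ComponentPath", function(object) {
  msg <- character()
  if (nrow(object@vertices) < 1L) msg <- c(msg, "path must visit at least one vertex")
  if (object@nonstationarityMs < 0) msg <- c(msg, "nonstationarityMs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' StimulusWaveform: a whisker-deflection stimulus trace
#'
#' Deflection amplitude over time for one stimulus variant: the trapezoid
#' "basic" stimulus parameterized by on-ramp velocity, or the 100-ms
#' naturalistic "contact" proxy parameterized by peak amplitude.
#'
#' @slot kind character(1), `"basic"` or `"contact"`.
#' @slot parameter numeric(1), on-ramp velocity in mm/s (basic) or peak
#'   amplitude in mm (contact).
#' @slot samples data.frame with columns `time_ms`, `amplitude_mm`.
#'
#' @seealso [basicWaveform()], [contactWaveform()]
#' @export
setClass("StimulusWaveform",
  representation(
    kind = "character",
    parameter = "numeric",
    samples = "data.frame"
  )
)

setValidity("StimulusWaveform", function(object) {
  msg <- character()
  if (!object@kind %in% .STIMULI) msg <- c(msg, "kind must be 'basic' or 'contact'")
  if (object@parameter <= 0) msg <- c(msg, "parameter must be positive")
  if (any(object@samples$amplitude_mm < -1e-12)) msg <- c(msg, "amplitudes must be >= 0")
  if (length(msg)) msg else TRUE
})
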