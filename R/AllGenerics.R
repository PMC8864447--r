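#' @title Accessor generics
#' @description Accessors for the core classes; slot access from user code is
#'   discouraged.
#' @param object a `SpikeRaster`, `PSTHMatrix`, `ComponentSet` or
#'   `ComponentPath`.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("unitId", function(object) standardGeneric("unitId"))

#' @rdname accessors
#' @export
setGeneric("psthRates", function(object) standardGeneric("psthRates"))

#' @rdname accessors
#' @export
setGeneric("nIntensities", function(object) standardGeneric("nIntensities"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("componentTimes", function(object) standardGeneric("componentTimes"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("componentCategory", function(object) standardGeneric("componentCategory"))

#' @rdname accessors
#' @export
setGeneric("componentSupport", function(object) standardGeneric("componentSupport"))

#' @rdname accessors
#' @export
setGeneric("pathRank", function(object) standardGeneric("pathRank"))

#' @rdname accessors
#' @export
setGeneric("pathVertices", function(object) standardGeneric("pathVertices"))

#' @rdname accessors
#' @export
setGeneric("totalWeight", function(object) standardGeneric("totalWeight"))

#' @rdname accessors
#' @export
setGeneric("perRowSummary", function(object) standardGeneric("perRowSummary"))

#' @rdname accessors
#' @export
setGeneric("nonstationarity", function(object) standardGeneric("nonstationarity"))

setMethod("unitId", "SpikeRaster", function(object) object@unitId)
setMethod("unitId", "PSTHMatrix", function(object) object@unitId)
setMethod("unitId", "ComponentSet", function(object) object@unitId)

setMethod("psthRates", "PSTHMatrix", function(object) object@rates)

setMethod("nIntensities", "SpikeRaster", function(object) length(object@nTrials))
setMethod("nIntensities", "PSTHMatrix", function(object) nrow(object@rates))

setMethod("nTrials", "SpikeRaster", function(object) object@nTrials)
setMethod("nTrials", "PSTHMatrix", function(object) object@nTrials)

setMethod("componentTimes", "ComponentSet", function(object) object@componentTimes)
setMethod("nComponents", "ComponentSet", function(object) length(object@componentTimes))
setMethod("componentCategory", "ComponentSet", function(object) object@category)
setMethod("componentSupport", "ComponentSet", function(object) object@support)

setMethod("pathRank", "ComponentPath", function(object) object@rank)
setMethod("pathVertices", "ComponentPath", function(object) object@vertices)
setMethod("totalWeight", "ComponentPath", function(object) object@totalWeight)
setMethod("perRowSummary", "ComponentPath", function(object) object@perRow)
setMethod("nonstationarity", "ComponentPath", function(object) object@nonstationarityMs)

setMethod("show", "SpikeRaster", function(object) {
  cat(sprintf(
    "SpikeRaster '%s' | layer %s | %s | %s\n  %d intensities, trials per intensity: %s\n  %d spikes, window %g ms\n",
    object@unitId, object@layer, object@condition, object@stimulus,
    length(object@nTrials), paste(object@nTrials, collapse = ","),
    nrow(object@events), object@windowMs
  ))
})

setMethod("show", "PSTHMatrix", function(object) {
  cat(sprintf(
    "PSTHMatrix '%s' | layer %s | %s | %s\n  %d intensities x %d bins (%g ms bins, %g ms window)\n  max rate %.1f Hz\n",
    object@unitId, object@layer, object@condition, object@stimulus,
    nrow(object@rates), ncol(object@rates), object@binMs, object@windowMs,
    if (length(object@rates)) max(object@rates) else 0
  ))
})

setMethod("show", "ComponentSet", function(object) {
  cat(sprintf(
    "ComponentSet '%s': category %s\n  component times (ms): %s\n  support (intensities): %s\n",
    object@unitId, object@category,
    if (length(object@componentTimes)) paste(object@componentTimes, collapse = ", ") else "none",
    if (length(object@support)) paste(object@support, collapse = ", ") else "-"
  ))
})

setMethod("show", "ComponentPath", function(object) {
  cat(sprintf(
    "ComponentPath rank %d: %d vertices, total weight %.3f\n  median time %g ms, non-stationarity %g ms\n",
    object@rank, nrow(object@vertices), object@totalWeight,
    object@medianTime, object@nonstationarityMs
  ))
})

setMethod("show", "StimulusWaveform", function(object) {
  cat(sprintf(
    "StimulusWaveform '%s' (parameter %g): %d samples over %g ms, peak %.3g mm\n",
    object@kind, object@parameter, nrow(object@samples),
    max(object@samples$time_ms), max(object@samples$amplitude_mm)
  ))
})
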