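#' Trapezoid "basic" whisker stimulus waveform
#'
#' On-ramp at the given velocity to a deflection of 3.6 mm, a 20-ms hold, then
#' a linear 40-ms off-ramp back to rest. The on-ramp duration is
#' `3.6 mm / velocity` (9 ms at 400 mm/s, 120 ms at 30 mm/s — slower ramps
#' extend past the 50-ms analysis window and the waveform is still emitted in
#' full).
#'
#' @param velocity on-ramp velocity in mm/s (> 0); the study's variants are
#'   30, 60, 150, 250 and 400 mm/s.
#' @param dtMs sample spacing in ms (default 0.5).
#' @return A [StimulusWaveform-class].
#' @export
basicWaveform <- function(velocity, dtMs = 0.5) {
  .assertScalarNumber(velocity, "velocity", positive = TRUE)
  peak <- 3.6
  rampMs <- peak / velocity * 1000
  holdEnd <- rampMs + 20
  totalMs <- holdEnd + 40
  times <- sort(unique(c(seq(0, totalMs, by = dtMs), rampMs, holdEnd, totalMs)))
  amp <- ifelse(times <= rampMs, velocity * times / 1000,
         ifelse(times <= holdEnd, peak,
                peak * (1 - (times - holdEnd) / 40)))
  amp <- pmax(amp, 0)
  new("StimulusWaveform", kind = "basic", parameter = velocity,
      samples = data.frame(time_ms = times, amplitude_mm = amp))
}

#' Synthetic proxy of the naturalistic "contact" stimulus waveform
#'
#' A deterministic 100-ms stand-in for the object-contact deflection trace
#' (the original was reconstructed from high-speed video and is not
#' reproduced here): an initial deflection peaking near 10 ms, a secondary
#' bump near 25 ms, and a dip near 40 ms, scaled linearly so the maximum
#' equals `peakAmplitude`. It starts at 0 mm and influences nothing downstream
#' except documentation and plots.
#'
#' @param peakAmplitude peak deflection in mm (> 0).
#' @param dtMs sample spacing in ms (default 0.5).
#' @return A [StimulusWaveform-class] spanning exactly 100 ms.
#' @export
contactWaveform <- function(peakAmplitude, dtMs = 0.5) {
  .assertScalarNumber(peakAmplitude, "peakAmplitude", positive = TRUE)
  times <- seq(0, 100, by = dtMs)
  bump <- function(mu, sd) exp(-(times - mu)^2 / (2 * sd^2))
  shape <- pmin(times / 5, 1) *
    (bump(10, 3) + 0.45 * bump(25, 4) - 0.25 * bump(40, 5) + 0.05)
  shape <- pmax(shape, 0)
  shape <- shape / max(shape)
  new("StimulusWaveform", kind = "contact", parameter = peakAmplitude,
      samples = data.frame(time_ms = times,
                           amplitude_mm = peakAmplitude * shape))
}

#' Specification of one synthetic unit
#'
#' Describes the programmed firing-rate model of a synthetic unit: a constant
#' Poisson baseline plus up to three Gaussian rate bumps ("components") whose
#' amplitudes grow or shrink linearly with stimulus intensity and whose times
#' shift earlier with intensity (the programmed non-stationarity).
#'
#' The expected rate at intensity z (1..Z) and time t (ms) is
#' `lambda(z, t) = baseline + sum_c max(A_c + slope_c (z-1), 0) *
#' exp(-(t - (tau_c - s_c (z-1)))^2 / (2 width^2))`, clipped at 0.
#'
#' @param unitId,layer,condition,stimulus unit metadata.
#' @param componentTimes numeric vector of component times tau_c in ms at
#'   intensity 1 (length = number of components; may be empty).
#' @param peakRates peak rates A_c in Hz at intensity 1 (> 0).
#' @param rateSlopes amplitude change per intensity step in Hz (may be
#'   negative, emulating opposing components; amplitudes clip at 0).
#' @param latencyShifts earliness shift s_c in ms per intensity step (>= 0);
#'   `tau_c - s_c (Z-1)` must stay >= 0.
#' @param componentWidth Gaussian sd of each component in ms (default 1, i.e.
#'   sharp 1-3 ms components).
#' @param baselineRate baseline rate in Hz (>= 0).
#' @param nIntensities number of intensities Z (5 basic / 10 contact).
#' @param nTrials trials per intensity (default 20).
#' @param seed integer RNG seed for spike generation.
#' @return A `SyntheticUnitSpec` (validated list).
#' @export
syntheticUnitSpec <- function(unitId, layer = "IV", condition = "sham",
                              stimulus = "contact",
                              componentTimes = numeric(),
                              peakRates = numeric(),
                              rateSlopes = numeric(),
                              latencyShifts = numeric(),
                              componentWidth = 1, baselineRate = 0,
                              nIntensities = 10L, nTrials = 20L, seed = 1L) {
  nC <- length(componentTimes)
  if (length(peakRates) != nC || length(rateSlopes) != nC ||
      length(latencyShifts) != nC)
    stop("componentTimes, peakRates, rateSlopes, latencyShifts must have equal length")
  if (nC > 0L) {
    if (any(peakRates <= 0)) stop("peakRates must be > 0")
    if (any(latencyShifts < 0)) stop("latencyShifts must be >= 0")
    if (any(componentTimes - latencyShifts * (nIntensities - 1L) < 0))
      stop("components must not shift before stimulus onset")
  }
  if (baselineRate < 0) stop("baselineRate must be >= 0")
  structure(
    list(unitId = as.character(unitId), layer = layer, condition = condition,
         stimulus = stimulus, nComponents = nC,
         componentTimes = componentTimes, peakRates = peakRates,
         rateSlopes = rateSlopes, latencyShifts = latencyShifts,
         componentWidth = componentWidth, baselineRate = baselineRate,
         nIntensities = as.integer(nIntensities), nTrials = as.integer(nTrials),
         seed = as.integer(seed)),
    class = "SyntheticUnitSpec"
  )
}

#' Expected-rate surface of a synthetic unit
#'
#' @param spec a `SyntheticUnitSpec`.
#' @param windowMs,binMs analysis window and bin width in ms; rates are
#'   evaluated at bin centres.
#' @return numeric Z x B matrix of expected rates lambda(z, t) in Hz.
#' @export
unitLambda <- function(spec, windowMs = 50, binMs = 1) {
  B <- as.integer(round(windowMs / binMs))
  Z <- spec$nIntensities
  centers <- (seq_len(B) - 0.5) * binMs
  lam <- matrix(spec$baselineRate, nrow = Z, ncol = B)
  for (c in seq_len(spec$nComponents)) {
    for (z in seq_len(Z)) {
      A <- max(spec$peakRates[c] + spec$rateSlopes[c] * (z - 1L), 0)
      mu <- spec$componentTimes[c] - spec$latencyShifts[c] * (z - 1L)
      lam[z, ] <- lam[z, ] +
        A * exp(-(centers - mu)^2 / (2 * spec$componentWidth^2))
    }
  }
  pmax(lam, 0)
}

#' Generate one synthetic unit's spike raster and ground truth
#'
#' Draws per-trial spike counts for every (intensity, bin) cell as
#' `Poisson(lambda(z, t) * binMs / 1000)` and places spikes uniformly within
#' their bins. Fully reproducible for a fixed `spec$seed`; the caller's RNG
#' state is left untouched.
#'
#' @param spec a `SyntheticUnitSpec`.
#' @param windowMs,binMs window and bin width in ms (defaults 50 and 1).
#' @return list with `raster` (a [SpikeRaster-class]) and `groundTruth` (a
#'   data.frame in long format: `unit_id`, `category`, `component_index`,
#'   `intensity`, `true_time_ms`, `true_nonstationarity_ms`; one NA-component
#'   row for a non-responder).
#' @export
generateUnit <- function(spec, windowMs = 50, binMs = 1) {
  stopifnot(inherits(spec, "SyntheticUnitSpec"))
  lam <- unitLambda(spec, windowMs = windowMs, binMs = binMs)
  Z <- spec$nIntensities
  B <- ncol(lam)
  nT <- spec$nTrials
  events <- .withSeed(spec$seed, {
    mu <- lam * binMs / 1000 # expected count per trial per bin
    counts <- stats::rpois(Z * B * nT, rep(as.vector(mu), times = nT))
    dim(counts) <- c(Z * B, nT)
    idx <- which(counts > 0L, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      data.frame(intensity = integer(), trial = integer(), time_ms = numeric())
    } else {
      nrep <- counts[idx]
      z <- ((idx[, 1L] - 1L) %% Z) + 1L
      b <- ((idx[, 1L] - 1L) %/% Z) + 1L
      ev <- data.frame(
        intensity = rep(z, nrep),
        trial = rep(idx[, 2L], nrep),
        time_ms = NA_real_
      )
      ev$time_ms <- (rep(b, nrep) - 1L) * binMs + stats::runif(nrow(ev)) * binMs
      ev
    }
  })
  raster <- spikeRaster(spec$unitId, spec$layer, spec$condition, spec$stimulus,
                        events = events, nTrials = rep(nT, Z),
                        windowMs = windowMs)
  gt <- if (spec$nComponents == 0L) {
    data.frame(unit_id = spec$unitId, category = "0",
               component_index = NA_integer_, intensity = NA_integer_,
               true_time_ms = NA_real_, true_nonstationarity_ms = NA_real_,
               stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(component_index = seq_len(spec$nComponents),
                        intensity = seq_len(Z))
    data.frame(
      unit_id = spec$unitId,
      category = classifyComponents(spec$nComponents),
      component_index = grid$component_index,
      intensity = grid$intensity,
      true_time_ms = spec$componentTimes[grid$component_index] -
        spec$latencyShifts[grid$component_index] * (grid$intensity - 1L),
      true_nonstationarity_ms = spec$latencyShifts[grid$component_index] * (Z - 1L),
      stringsAsFactors = FALSE
    )
  }
  list(raster = raster, groundTruth = gt)
}

#' Deterministic largest-remainder allocation of category counts
#'
#' @param proportions numeric vector summing to 1.
#' @param n total count to allocate.
#' @return integer vector of counts summing to `n`; remainders are awarded to
#'   the largest fractional parts (ties by index order).
#' @export
largestRemainder <- function(proportions, n) {
  stopifnot(abs(sum(proportions) - 1) < 1e-9, n >= 0)
  raw <- proportions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    frac <- raw - base
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Specification of a synthetic population
#'
#' Defines, per (layer, condition, stimulus) cell, how many units to generate
#' and the proportions of units with 0/1/2/3 programmed components, plus the
#' timing model linking first and second components
#' (`second = a + b * first + Normal(0, sigma)`) and the sampling ranges of
#' all unit-level parameters. Category counts are realized by deterministic
#' largest-remainder allocation, not multinomial sampling, so recovery tests
#' carry no generator-level sampling noise.
#'
#' @param cells data.frame with columns `layer`, `condition`, `stimulus`,
#'   `nUnits`, `p0`, `p1`, `p2`, `p3` (proportions summing to 1 per row);
#'   optional columns `a`, `b`, `sigma` override `timing` per cell.
#' @param timing list with `a` (ms), `b`, `sigma` (ms) for the
#'   second-component timing model.
#' @param nIntensities,nTrials,baselineRate,componentWidth as in
#'   [syntheticUnitSpec()].
#' @param peakRange range (Hz) of component peak rates at intensity 1.
#' @param slopeRange range (Hz per intensity step) of amplitude slopes.
#' @param shiftChoices,shiftProbs discrete distribution of per-step latency
#'   shifts (ms); over Z-1 steps these realize the programmed 0-5 ms
#'   non-stationarity.
#' @param firstTimeRange range (ms) of first-component times.
#' @param thirdGapRange range (ms) of the gap between second and third
#'   components.
#' @param minSeparation minimum separation (ms) enforced between programmed
#'   component times, so the 5-ms merge rule cannot fuse distinct programmed
#'   components.
#' @param sharedShift logical; if `TRUE` (default) all components of a unit
#'   share one latency shift (the whole response profile shifts coherently
#'   with intensity, so programmed component separations are preserved at
#'   every intensity); if `FALSE` shifts are drawn independently per
#'   component.
#' @param masterSeed master RNG seed; all unit seeds derive from it.
#' @return A `PopulationSpec` (validated list).
#' @export
populationSpec <- function(cells = data.frame(
                             layer = "IV", condition = "sham",
                             stimulus = "contact", nUnits = 200L,
                             p0 = 0.25, p1 = 0.30, p2 = 0.30, p3 = 0.15
                           ),
                           timing = list(a = 10, b = 1, sigma = 1.5),
                           nIntensities = 10L, nTrials = 20L,
                           baselineRate = 5, componentWidth = 1,
                           peakRange = c(150, 300), slopeRange = c(-5, 10),
                           shiftChoices = seq(0, 0.5, by = 0.1),
                           shiftProbs = c(0.10, 0.15, 0.25, 0.25, 0.15, 0.10),
                           firstTimeRange = c(8, 20),
                           thirdGapRange = c(10, 15),
                           minSeparation = 8,
                           sharedShift = TRUE,
                           masterSeed = 1L) {
  props <- as.matrix(cells[, c("p0", "p1", "p2", "p3")])
  if (any(abs(rowSums(props) - 1) > 1e-9))
    stop("category proportions must sum to 1 in every cell")
  if (any(cells$nUnits < 0)) stop("nUnits must be >= 0")
  if (sum(cells$nUnits) == 0) stop("population is empty")
  stopifnot(length(shiftChoices) == length(shiftProbs))
  structure(
    list(cells = cells, timing = timing, nIntensities = as.integer(nIntensities),
         nTrials = as.integer(nTrials), baselineRate = baselineRate,
         componentWidth = componentWidth, peakRange = peakRange,
         slopeRange = slopeRange, shiftChoices = shiftChoices,
         shiftProbs = shiftProbs / sum(shiftProbs),
         firstTimeRange = firstTimeRange, thirdGapRange = thirdGapRange,
         minSeparation = minSeparation, sharedShift = isTRUE(sharedShift),
         masterSeed = as.integer(masterSeed)),
    class = "PopulationSpec"
  )
}

# Deterministic 32-bit sub-seed for unit i under a master seed.
.unitSeed <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) * 7919 + i * 104729) %% 2147483647)
}

#' Generate a synthetic population
#'
#' Realizes every cell of a [populationSpec()]: category counts by largest
#' remainder, unit parameters drawn from the spec's ranges under the master
#' seed, second-component times from the linear timing model, and spike
#' rasters from [generateUnit()] under per-unit derived seeds. Every emitted
#' raster has matching ground-truth rows.
#'
#' @param pop a `PopulationSpec`.
#' @param windowMs,binMs window and bin width in ms.
#' @return list with `rasters` (named list of [SpikeRaster-class]), `specs`
#'   (the per-unit `SyntheticUnitSpec`s) and `groundTruth` (long data.frame,
#'   one row per unit x component x intensity).
#' @export
generatePopulation <- function(pop, windowMs = 50, binMs = 1) {
  stopifnot(inherits(pop, "PopulationSpec"))
  Z <- pop$nIntensities
  rasters <- list()
  specs <- list()
  gts <- list()
  unitCounter <- 0L
  .withSeed(pop$masterSeed, {
    for (ci in seq_len(nrow(pop$cells))) {
      cell <- pop$cells[ci, ]
      counts <- largestRemainder(
        as.numeric(cell[c("p0", "p1", "p2", "p3")]), cell$nUnits)
      a <- if (!is.null(cell$a) && !is.na(cell$a)) cell$a else pop$timing$a
      b <- if (!is.null(cell$b) && !is.na(cell$b)) cell$b else pop$timing$b
      sg <- if (!is.null(cell$sigma) && !is.na(cell$sigma)) cell$sigma else pop$timing$sigma
      for (nComp in 0:3) {
        for (u in seq_len(counts[nComp + 1L])) {
          unitCounter <- unitCounter + 1L
          uid <- sprintf("%s_%s_%s_u%04d", cell$layer, cell$condition,
                         cell$stimulus, unitCounter)
          times <- numeric()
          if (nComp >= 1L)
            times <- stats::runif(1, pop$firstTimeRange[1], pop$firstTimeRange[2])
          if (nComp >= 2L) {
            repeat {
              second <- a + b * times[1] + stats::rnorm(1, 0, sg)
              if (second - times[1] >= pop$minSeparation &&
                  second <= windowMs - 3) break
            }
            times <- c(times, second)
          }
          if (nComp >= 3L) {
            third <- times[2] +
              stats::runif(1, pop$thirdGapRange[1], pop$thirdGapRange[2])
            times <- c(times, min(third, windowMs - 2))
          }
          peaks <- stats::runif(nComp, pop$peakRange[1], pop$peakRange[2])
          slopes <- stats::runif(nComp, pop$slopeRange[1], pop$slopeRange[2])
          shifts <- if (isTRUE(pop$sharedShift) && nComp > 0L) {
            rep(sample(pop$shiftChoices, 1L, prob = pop$shiftProbs), nComp)
          } else {
            sample(pop$shiftChoices, nComp, replace = TRUE,
                   prob = pop$shiftProbs)
          }
          spec <- syntheticUnitSpec(
            uid, layer = cell$layer, condition = cell$condition,
            stimulus = cell$stimulus, componentTimes = times,
            peakRates = peaks, rateSlopes = slopes, latencyShifts = shifts,
            componentWidth = pop$componentWidth,
            baselineRate = pop$baselineRate, nIntensities = Z,
            nTrials = pop$nTrials,
            seed = .unitSeed(pop$masterSeed, unitCounter)
          )
          gen <- generateUnit(spec, windowMs = windowMs, binMs = binMs)
          rasters[[uid]] <- gen$raster
          specs[[uid]] <- spec
          gts[[uid]] <- gen$groundTruth
        }
      }
    }
  })
  list(rasters = rasters, specs = specs,
       groundTruth = do.call(rbind, c(gts, list(make.row.names = FALSE))))
}
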