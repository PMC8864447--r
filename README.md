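# psthComponents

Detection, validation and tracking of **temporal response components** in
peristimulus time histograms (PSTHs) of sensory-cortex units recorded across
graded stimulus intensities — e.g. whisker-deflection responses in rodent
barrel cortex at several on-ramp velocities or contact amplitudes.

A *response component* is a brief period of elevated firing, separated by
silence from other such periods, within the first 50 ms post-stimulus. Units
are categorized by how many components they express (0 = non-responder, 1,
2, 3+), each component is scored for statistical validity, and a
graph-theoretic method tracks components across stimulus intensities to
measure their *non-stationarity* — how far a component's time shifts as
intensity grows.

## What the package computes

Given spike rasters (unit × intensity × trial × spike time), or pre-binned
intensity × time rate matrices:

1. **PSTHs** — spikes counted in 1-ms half-open bins to 50 ms, as trial-mean
   rates in Hz (`buildPSTH()`).
2. **Components** — per-intensity local maxima, filtered by the
   25%-of-max-with-silent-neighbours rule, merged iteratively (nearest pair
   first, ≤ 5 ms, replaced by the median bin), then pooled and re-merged
   across intensities (`unitComponents()`).
3. **Validation** — for each component, over the intensity-pooled 11-bin
   segment centred on it: the peakiness ratio
   `(g_i + 1) / (g_k + 1)` (component-bin rate vs segment minimum; 1 =
   equal, 1.25 = 25% above) and a one-tailed two-sample *t* test of the 3
   component bins against the remaining 8 (`validateComponents()`).
4. **Component paths** — the PSTH matrix as a weighted directed grid graph
   (edges into each vertex weighted `unit max rate / vertex rate`), up to 3
   vertex-disjoint Dijkstra shortest paths from the lowest- to the
   highest-intensity row, each with median time, per-row rates, and
   non-stationarity = max − min of per-row times (`graphComponents()`).
5. **Population statistics** — category-proportion tables with pairwise KS
   comparisons, first-vs-second component timing regressions
   (`second = a + b·first`, intercept ± SE), and binned non-stationarity
   distributions (`categoryProportions()`, `timingRegressionTable()`,
   `nonstationarityDistribution()`).
6. **Synthetic populations** — a seeded Poisson spike-raster generator with
   programmable components, amplitude slopes, latency shifts and a
   ground-truth table, for parameter-recovery testing
   (`generatePopulation()`).

A file-mediated pipeline (`runPipeline()`, or
`inst/scripts/psth-pipeline.R` from a shell) chains all stages with a YAML
config and deterministic seeding.

## Worked example

```r
library(psthComponents)

spec <- syntheticUnitSpec("demo", layer = "IV", condition = "sham",
  stimulus = "contact",
  componentTimes = c(12.4, 24.8),  # two components, ~12 ms apart
  peakRates   = c(220, 180),       # Hz at the lowest intensity
  rateSlopes  = c(6, -4),          # amplitudes drift oppositely with intensity
  latencyShifts = c(0.3, 0.3),     # 0.3 ms earlier per intensity step
  baselineRate = 5, nIntensities = 10, nTrials = 20, seed = 42)

psth <- buildPSTH(generateUnit(spec)$raster)
psth
#> PSTHMatrix 'demo' | layer IV | sham | contact
#>   10 intensities x 50 bins (1 ms bins, 50 ms window)
#>   max rate 350.0 Hz

unitComponents(psth, minSupport = 9, unitWideMax = TRUE)
#> ComponentSet 'demo': category 2
#>   component times (ms): 12, 23
#>   support (intensities): 10, 10
```

Both programmed components are recovered (the detected times sit ~1 ms below
the programmed 12.4 and 24.8 ms because pooling across intensities averages
in the programmed earliness shift). Validation and path tracking:

```r
validateComponents(psth, unitComponents(psth, minSupport = 9, unitWideMax = TRUE))
#>   unit_id component_time_ms peakiness_literal peakiness_normalized    t       p
#> 1    demo                12               201                 1.99 4.19 0.00117
#> 2    demo                23                91                 1.98 2.66 0.01308

graphComponents(psth, k = 2)$paths[[1]]
#> ComponentPath rank 1: 10 vertices, total weight 13.567
#>   median time 12 ms, non-stationarity 4 ms
```

Both components are strongly peaked (rates hundreds of times the local
minimum; significant at α = 0.05, the first also at 0.01). The primary path
tracks the first component and measures 4 ms of non-stationarity against a
programmed 0.3 × 9 = 2.7 ms — within the ±1 ms resolution of an integer
max-minus-min measurement on the 1-ms lattice.

The full pipeline over a simulated population:

```r
runPipeline(defaultPipelineConfig(seed = 1), "out/")
# out/: rasters.tsv, ground_truth.tsv, psth.tsv, components.tsv,
#       validation.tsv, paths.tsv, path_correlations.tsv,
#       stats_report.json, report.md, run_manifest.json
```

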