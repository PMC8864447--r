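#' Default pipeline configuration
#'
#' Every analysis parameter defaults to the study's convention: a 50-ms window
#' of 1-ms bins, a 5-ms merge gap, single-intensity component support, the
#' literal peakiness formula, pooled-variance t test, 3 disjoint paths, a
#' 1e-3 Hz rate floor, and significance echoed at alpha = 0.05 and 0.01.
#'
#' @param seed master seed for the simulate stage.
#' @return nested list understood by [runPipeline()].
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      cells = list(
        list(layer = "IV", condition = "sham", stimulus = "contact",
             nUnits = 12L, p0 = 0.25, p1 = 0.25, p2 = 0.25, p3 = 0.25)
      ),
      timing = list(a = 10, b = 1, sigma = 1.5),
      n_intensities = 10L, n_trials = 20L, baseline_rate = 5
    ),
    analysis = list(
      window_ms = 50, bin_ms = 1, merge_gap = 5, min_support = 1L,
      unit_wide_max = FALSE, peakiness_variant = "literal",
      t_test_variant = "pooled", k_paths = 3L, epsilon = 1e-3,
      alpha = c(0.05, 0.01)
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [defaultPipelineConfig()] values.
#'
#' @param path a YAML config file.
#' @return nested config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  def <- defaultPipelineConfig()
  cfg$seed <- if (is.null(cfg$seed)) def$seed else as.integer(cfg$seed)
  cfg$analysis <- utils::modifyList(def$analysis, cfg$analysis %||% list())
  if (is.null(cfg$simulate) && is.null(cfg$rasters) && is.null(cfg$psth))
    cfg$simulate <- def$simulate
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.popSpecFromConfig <- function(sim, seed) {
  cells <- do.call(rbind, lapply(sim$cells, function(cl) {
    data.frame(layer = cl$layer, condition = cl$condition,
               stimulus = cl$stimulus, nUnits = as.integer(cl$nUnits),
               p0 = cl$p0, p1 = cl$p1, p2 = cl$p2, p3 = cl$p3,
               a = cl$a %||% NA_real_, b = cl$b %||% NA_real_,
               sigma = cl$sigma %||% NA_real_, stringsAsFactors = FALSE)
  }))
  args <- list(cells = cells, masterSeed = seed)
  if (!is.null(sim$timing)) args$timing <- sim$timing
  if (!is.null(sim$n_intensities)) args$nIntensities <- as.integer(sim$n_intensities)
  if (!is.null(sim$n_trials)) args$nTrials <- as.integer(sim$n_trials)
  if (!is.null(sim$baseline_rate)) args$baselineRate <- sim$baseline_rate
  if (!is.null(sim$peak_range)) args$peakRange <- as.numeric(sim$peak_range)
  if (!is.null(sim$slope_range)) args$slopeRange <- as.numeric(sim$slope_range)
  if (!is.null(sim$shift_choices)) args$shiftChoices <- as.numeric(sim$shift_choices)
  if (!is.null(sim$shift_probs)) args$shiftProbs <- as.numeric(sim$shift_probs)
  do.call(populationSpec, args)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.stageSimulate <- function(cfg, outDir) {
  pop <- .popSpecFromConfig(cfg$simulate, cfg$seed)
  gen <- generatePopulation(pop, windowMs = cfg$analysis$window_ms,
                            binMs = cfg$analysis$bin_ms)
  writeRaster(gen$rasters, file.path(outDir, "rasters.tsv"))
  .writeTSV(gen$groundTruth, file.path(outDir, "ground_truth.tsv"))
  yaml::write_yaml(cfg$simulate, file.path(outDir, "population_config.yaml"))
  invisible(gen)
}

.stagePSTH <- function(cfg, outDir) {
  rasters <- readRasterSet(file.path(outDir, "rasters.tsv"))
  psths <- lapply(rasters, buildPSTH, windowMs = cfg$analysis$window_ms,
                  binMs = cfg$analysis$bin_ms)
  writePSTH(psths, file.path(outDir, "psth.tsv"))
  invisible(psths)
}

.stageComponents <- function(cfg, outDir) {
  psths <- readPSTHSet(file.path(outDir, "psth.tsv"))
  sets <- lapply(psths, unitComponents,
                 mergeGap = cfg$analysis$merge_gap,
                 minSupport = cfg$analysis$min_support,
                 unitWideMax = isTRUE(cfg$analysis$unit_wide_max))
  .writeTSV(componentsTable(sets, psths), file.path(outDir, "components.tsv"))
  invisible(sets)
}

# Rebuild per-unit ComponentSet objects from a components.tsv table.
.componentSetsFromTable <- function(tab) {
  out <- list()
  for (uid in unique(tab$unit_id)) {
    rows <- tab[tab$unit_id == uid & !is.na(tab$component_index), , drop = FALSE]
    rows <- rows[order(rows$component_index), , drop = FALSE]
    n <- nrow(rows)
    out[[uid]] <- new("ComponentSet",
      unitId = uid, perIntensityMaxima = list(),
      componentTimes = as.numeric(rows$component_time_ms),
      support = as.integer(rows$supporting_intensities),
      category = if (n >= 3L) "3plus" else as.character(n)
    )
  }
  out
}

.stageValidate <- function(cfg, outDir) {
  psths <- readPSTHSet(file.path(outDir, "psth.tsv"))
  tab <- utils::read.delim(file.path(outDir, "components.tsv"),
                           stringsAsFactors = FALSE)
  sets <- .componentSetsFromTable(tab)
  rows <- lapply(names(sets), function(uid) {
    validateComponents(psths[[uid]], sets[[uid]],
                       varEqual = cfg$analysis$t_test_variant != "welch")
  })
  val <- do.call(rbind, rows)
  if (is.null(val) || nrow(val) == 0L)
    val <- validateComponents(psths[[1]], .emptyComponentSet(psths[[1]]@unitId))
  .writeTSV(val, file.path(outDir, "validation.tsv"))
  invisible(val)
}

.emptyComponentSet <- function(uid) {
  new("ComponentSet", unitId = uid, perIntensityMaxima = list(),
      componentTimes = numeric(), support = integer(), category = "0")
}

.stageGraphPaths <- function(cfg, outDir) {
  psths <- readPSTHSet(file.path(outDir, "psth.tsv"))
  res <- lapply(psths, graphComponents, k = cfg$analysis$k_paths,
                epsilon = cfg$analysis$epsilon)
  pathTab <- do.call(rbind, c(lapply(res, `[[`, "pathTable"),
                              list(make.row.names = FALSE)))
  corTab <- do.call(rbind, c(lapply(res, `[[`, "correlations"),
                             list(make.row.names = FALSE)))
  meta <- do.call(rbind, lapply(psths, function(p) {
    data.frame(unit_id = p@unitId, layer = p@layer, condition = p@condition,
               stimulus = p@stimulus, stringsAsFactors = FALSE)
  }))
  pathTab <- merge(meta, pathTab, by = "unit_id", sort = TRUE)
  .writeTSV(pathTab[order(pathTab$unit_id, pathTab$path_rank, pathTab$row), ],
            file.path(outDir, "paths.tsv"))
  .writeTSV(corTab, file.path(outDir, "path_correlations.tsv"))
  invisible(res)
}

.stageStats <- function(cfg, outDir) {
  comp <- utils::read.delim(file.path(outDir, "components.tsv"),
                            stringsAsFactors = FALSE)
  paths <- utils::read.delim(file.path(outDir, "paths.tsv"),
                             stringsAsFactors = FALSE)
  val <- utils::read.delim(file.path(outDir, "validation.tsv"),
                           stringsAsFactors = FALSE)
  units <- unique(comp[, c("unit_id", "layer", "condition", "stimulus", "category")])
  units$category <- as.character(units$category)
  props <- categoryProportions(units)
  compCmp <- categoryComparisons(units)
  regs <- timingRegressionTable(comp)
  primary <- paths[paths$path_rank == 1, , drop = FALSE]
  primary <- unique(primary[, c("unit_id", "layer", "condition",
                                "nonstationarity_ms")])
  ns <- if (nrow(primary)) nonstationarityDistribution(primary) else
    list(histogram = data.frame(), comparisons = data.frame())
  alphas <- cfg$analysis$alpha
  valSummary <- if (nrow(val)) {
    s <- list(
      n_components = nrow(val),
      frac_peakiness_ge_1.25 = mean(val$peakiness_literal >= 1.25),
      frac_peakiness_ge_1.5 = mean(val$peakiness_literal >= 1.5)
    )
    for (a in alphas)
      s[[sprintf("frac_t_p_lt_%g", a)]] <-
        mean(val$p < a, na.rm = TRUE)
    s
  } else list(n_components = 0L)
  report <- list(
    proportions = props,
    proportion_comparisons = compCmp,
    timing_regressions = regs,
    nonstationarity_histogram = ns$histogram,
    nonstationarity_comparisons = ns$comparisons,
    validation_summary = valSummary
  )
  jsonlite::write_json(report, file.path(outDir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, na = "null")
  invisible(report)
}

.stageReport <- function(cfg, outDir) {
  rep <- jsonlite::read_json(file.path(outDir, "stats_report.json"),
                             simplifyVector = TRUE)
  lines <- c(
    "# Temporal response component analysis report", "",
    "## Category proportions (0 / 1 / 2 / 3+ components)", "",
    utils::capture.output(print(rep$proportions)), "",
    "## Pairwise proportion comparisons (KS on per-unit component counts)", "",
    utils::capture.output(print(rep$proportion_comparisons)), "",
    "## First-vs-second component timing regressions (intercept +/- SE; '#' = insignificant)", "",
    utils::capture.output(print(rep$timing_regressions)), "",
    "## Non-stationarity of primary component paths (ms)", "",
    utils::capture.output(print(rep$nonstationarity_histogram)), "",
    utils::capture.output(print(rep$nonstationarity_comparisons)), "",
    "## Component validation summary", "",
    vapply(names(rep$validation_summary), function(k)
      sprintf("- %s: %s", k, format(rep$validation_summary[[k]])), character(1))
  )
  writeLines(lines, file.path(outDir, "report.md"))
  invisible(file.path(outDir, "report.md"))
}

.ALL_STAGES <- c("simulate", "psth", "components", "validate", "graphpaths",
                 "stats", "report")

#' Run the analysis pipeline
#'
#' Orchestrates simulate -> psth -> components -> validate -> graphpaths ->
#' stats -> report over a shared output directory. Stages communicate through
#' files only (rasters.tsv, psth.tsv, components.tsv, validation.tsv,
#' paths.tsv, path_correlations.tsv, stats_report.json, report.md), so any
#' stage can be re-run in isolation against existing upstream outputs, and a
#' re-run under the same seed is byte-identical. A `run_manifest.json`
#' (config echo, seed, package version, output checksums) is written at the
#' end.
#'
#' @param config a config list (see [defaultPipelineConfig()]) or path to a
#'   YAML file for [readPipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param stages character vector, a subset of
#'   `c("simulate", "psth", "components", "validate", "graphpaths", "stats",
#'   "report")`, run in pipeline order.
#' @return `outDir`, invisibly.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outDir,
                        stages = .ALL_STAGES) {
  if (is.character(config) && length(config) == 1L)
    config <- readPipelineConfig(config)
  bad <- setdiff(stages, .ALL_STAGES)
  if (length(bad))
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  stages <- .ALL_STAGES[.ALL_STAGES %in% stages]
  for (st in stages) {
    switch(st,
      simulate = .stageSimulate(config, outDir),
      psth = .stagePSTH(config, outDir),
      components = .stageComponents(config, outDir),
      validate = .stageValidate(config, outDir),
      graphpaths = .stageGraphPaths(config, outDir),
      stats = .stageStats(config, outDir),
      report = .stageReport(config, outDir)
    )
  }
  outs <- list.files(outDir, full.names = TRUE)
  outs <- outs[!grepl("run_manifest.json$", outs)]
  manifest <- list(
    config = config,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("psthComponents")),
    stages = stages,
    checksums = as.list(tools::md5sum(sort(outs)))
  )
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}
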