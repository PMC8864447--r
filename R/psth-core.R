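#' Construct a SpikeRaster
#'
#' @param unitId character(1) unit identifier.
#' @param layer `"II"` or `"IV"`.
#' @param condition one of `"sham"`, `"tbi_4d"`, `"tbi_2w"`, `"tbi_8w"`.
#' @param stimulus `"basic"` or `"contact"`.
#' @param events data.frame with columns `intensity`, `trial`, `time_ms`
#'   (one row per spike; may be empty).
#' @param nTrials integer vector of trial counts per intensity; its length
#'   defines the number of intensities Z.
#' @param windowMs analysis window in ms (default 50).
#' @return A [SpikeRaster-class] object.
#' @examples
#' r <- spikeRaster("u1", "IV", "sham", "contact",
#'   events = data.frame(intensity = 1L, trial = 1L, time_ms = 12.3),
#'   nTrials = rep(20L, 10)
#' )
#' nIntensities(r)
#' @export
spikeRaster <- function(unitId, layer, condition, stimulus,
                        events = data.frame(
                          intensity = integer(), trial = integer(),
                          time_ms = numeric()
                        ),
                        nTrials, windowMs = 50) {
  events$intensity <- as.integer(events$intensity)
  events$trial <- as.integer(events$trial)
  events$time_ms <- as.numeric(events$time_ms)
  new("SpikeRaster",
    unitId = as.character(unitId), layer = layer, condition = condition,
    stimulus = stimulus, events = events, nTrials = as.integer(nTrials),
    windowMs = windowMs
  )
}

#' Construct a PSTHMatrix directly from a rate matrix
#'
#' @inheritParams spikeRaster
#' @param rates numeric Z x B matrix of mean firing rates in Hz.
#' @param nTrials integer trial counts per intensity (length Z).
#' @param binMs bin width in ms.
#' @param windowMs window length in ms; `ncol(rates)` must equal
#'   `windowMs / binMs`.
#' @return A [PSTHMatrix-class] object.
#' @export
psthMatrix <- function(unitId, layer, condition, stimulus, rates, nTrials,
                       binMs = 1, windowMs = 50) {
  rates <- as.matrix(rates)
  dimnames(rates) <- NULL
  storage.mode(rates) <- "double"
  new("PSTHMatrix",
    unitId = as.character(unitId), layer = layer, condition = condition,
    stimulus = stimulus, rates = rates,
    nTrials = as.integer(nTrials), binMs = binMs, windowMs = windowMs
  )
}

#' Build a PSTH matrix from a spike raster
#'
#' Counts spikes in `binMs`-wide bins up to `windowMs` post-stimulus onset,
#' separately per stimulus intensity, and converts counts to trial-mean firing
#' rates in Hz: `rate(z, b) = count(z, b) / (nTrials[z] * binMs / 1000)`.
#'
#' Bins are 1-based and half-open: bin b covers \[(b-1), b) x binMs ms, so a
#' spike exactly at `windowMs` falls outside the window and is excluded (a
#' note is emitted when `options(psthComponents.verbose = TRUE)`).
#'
#' @param raster a [SpikeRaster-class].
#' @param windowMs analysis window in ms (default 50).
#' @param binMs bin width in ms (default 1); `windowMs` must be an integer
#'   multiple of it.
#' @return A [PSTHMatrix-class] with Z rows and `windowMs / binMs` columns.
#' @examples
#' r <- spikeRaster("u1", "IV", "sham", "basic",
#'   events = data.frame(intensity = 1L, trial = 1:10, time_ms = 12.5),
#'   nTrials = rep(10L, 5)
#' )
#' p <- buildPSTH(r)
#' psthRates(p)[1, 13] # 10 spikes / (10 trials * 1 ms) = 1000 Hz
#' @export
buildPSTH <- function(raster, windowMs = 50, binMs = 1) {
  stopifnot(is(raster, "SpikeRaster"))
  .assertScalarNumber(windowMs, "windowMs", positive = TRUE)
  .assertScalarNumber(binMs, "binMs", positive = TRUE)
  B <- windowMs / binMs
  if (abs(B - round(B)) > 1e-9)
    stop("windowMs must be an integer multiple of binMs")
  B <- as.integer(round(B))
  Z <- length(raster@nTrials)
  counts <- matrix(0L, nrow = Z, ncol = B)
  ev <- raster@events
  if (nrow(ev) > 0L) {
    inWin <- ev$time_ms >= 0 & ev$time_ms < windowMs
    nOut <- sum(!inWin)
    if (nOut > 0L && isTRUE(getOption("psthComponents.verbose", FALSE)))
      message(sprintf("buildPSTH: excluded %d spike(s) at or beyond %g ms", nOut, windowMs))
    ev <- ev[inWin, , drop = FALSE]
    if (nrow(ev) > 0L) {
      bin <- as.integer(floor(ev$time_ms / binMs)) + 1L
      tab <- table(factor(ev$intensity, levels = seq_len(Z)),
                   factor(bin, levels = seq_len(B)))
      counts <- matrix(as.integer(tab), nrow = Z, ncol = B)
    }
  }
  rates <- counts / (raster@nTrials * binMs / 1000)
  psthMatrix(raster@unitId, raster@layer, raster@condition, raster@stimulus,
             rates, raster@nTrials, binMs = binMs, windowMs = windowMs)
}

#' Intensity-pooled mean firing rates
#'
#' Per time bin, the unweighted mean of the per-intensity mean firing rates —
#' the "averaged across all velocities or amplitudes" trace that the component
#' validation operates on.
#'
#' @param psth a [PSTHMatrix-class].
#' @return numeric vector of B rates (Hz).
#' @export
pooledMeanRates <- function(psth) {
  stopifnot(is(psth, "PSTHMatrix"))
  colMeans(psth@rates)
}

# ---------------------------------------------------------------------------
# TSV I/O.
#
# Raster dialect: '#meta' comment lines (one per unit) carrying the trial
# counts and window, a header line
#   unit_id layer condition stimulus intensity trial spike_time_ms
# then one spike per row. PSTH dialect: '#meta bin_ms=... window_ms=...', a
# header
#   unit_id layer condition stimulus intensity n_trials bin_1 ... bin_B
# then one row per intensity. Tab-separated, UTF-8, '.' decimal.
# ---------------------------------------------------------------------------

.rasterHeader <- c("unit_id", "layer", "condition", "stimulus", "intensity",
                   "trial", "spike_time_ms")

.metaLine <- function(raster) {
  sprintf("#meta unit_id=%s n_trials=%s window_ms=%g",
          raster@unitId, paste(raster@nTrials, collapse = ","), raster@windowMs)
}

.parseMetaLines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    kv <- regmatches(ln, gregexpr("[A-Za-z_]+=[^ ]+", ln))[[1]]
    rec <- list()
    for (item in kv) {
      p <- strsplit(item, "=", fixed = TRUE)[[1]]
      rec[[p[1]]] <- p[2]
    }
    if (!is.null(rec$unit_id)) meta[[rec$unit_id]] <- rec
  }
  meta
}

#' Write spike rasters to TSV
#'
#' @param rasters a [SpikeRaster-class] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(rasters, path) {
  if (is(rasters, "SpikeRaster")) rasters <- list(rasters)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (r in rasters) writeLines(.metaLine(r), con)
  writeLines(paste(.rasterHeader, collapse = "\t"), con)
  for (r in rasters) {
    ev <- r@events
    if (nrow(ev) == 0L) next
    df <- data.frame(
      unit_id = r@unitId, layer = r@layer, condition = r@condition,
      stimulus = r@stimulus, intensity = ev$intensity, trial = ev$trial,
      spike_time_ms = ev$time_ms
    )
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

.checkRasterTable <- function(tab) {
  for (i in seq_len(nrow(tab))) {
    if (tab$spike_time_ms[i] < 0)
      stop(sprintf("row %d (unit %s): negative spike time %g",
                   i, tab$unit_id[i], tab$spike_time_ms[i]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read spike rasters from TSV
#'
#' `readRasterSet()` returns a named list of [SpikeRaster-class] objects;
#' `readRaster()` expects the file to hold exactly one unit and returns it.
#' Files with a malformed header, non-contiguous intensity indices, or negative
#' spike times are rejected with a message naming the offending row or gap.
#'
#' @param path a raster TSV written by [writeRaster()].
#' @return A [SpikeRaster-class] (`readRaster`) or named list (`readRasterSet`).
#' @export
readRasterSet <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  isMeta <- startsWith(lines, "#")
  meta <- .parseMetaLines(lines[isMeta])
  body <- lines[!isMeta]
  if (length(body) == 0L) stop("raster file has no header line")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, .rasterHeader))
    stop(sprintf("malformed raster header: '%s'", body[1]))
  tab <- if (length(body) > 1L) {
    utils::read.delim(text = body, header = TRUE, stringsAsFactors = FALSE)
  } else {
    stats::setNames(
      data.frame(character(), character(), character(), character(),
                 integer(), integer(), numeric()), .rasterHeader)
  }
  if (nrow(tab) > 0L) .checkRasterTable(tab)
  unitIds <- union(names(meta), unique(tab$unit_id))
  if (length(unitIds) == 0L) stop("raster file declares no units")
  out <- list()
  for (uid in unitIds) {
    rows <- tab[tab$unit_id == uid, , drop = FALSE]
    m <- meta[[uid]]
    if (is.null(m)) {
      nT <- tapply(rows$trial, factor(rows$intensity,
                                      levels = seq_len(max(rows$intensity))),
                   max)
      nT[is.na(nT)] <- 1L
      nT <- as.integer(nT)
      windowMs <- 50
    } else {
      nT <- as.integer(strsplit(m$n_trials, ",", fixed = TRUE)[[1]])
      windowMs <- as.numeric(m$window_ms)
    }
    if (nrow(rows) > 0L) {
      zs <- sort(unique(rows$intensity))
      gaps <- setdiff(seq_len(max(zs)), zs)
      # spikes need not occur at every intensity when trial counts are
      # declared in metadata; without metadata a gap is unrecoverable
      if (is.null(m) && length(gaps))
        stop(sprintf("unit %s: non-contiguous intensity indices, missing %s",
                     uid, paste(gaps, collapse = ",")), call. = FALSE)
      if (max(zs) > length(nT))
        stop(sprintf("unit %s: intensity %d exceeds declared count %d",
                     uid, max(zs), length(nT)), call. = FALSE)
    }
    lay <- if (nrow(rows)) rows$layer[1] else "II"
    cond <- if (nrow(rows)) rows$condition[1] else "sham"
    stim <- if (nrow(rows)) rows$stimulus[1] else "basic"
    if (!is.null(m)) {
      if (!is.null(m$layer)) lay <- m$layer
      if (!is.null(m$condition)) cond <- m$condition
      if (!is.null(m$stimulus)) stim <- m$stimulus
    }
    out[[uid]] <- spikeRaster(
      uid, lay, cond, stim,
      events = data.frame(intensity = rows$intensity, trial = rows$trial,
                          time_ms = rows$spike_time_ms),
      nTrials = nT, windowMs = windowMs
    )
  }
  out
}

#' @rdname readRasterSet
#' @export
readRaster <- function(path) {
  rs <- readRasterSet(path)
  if (length(rs) != 1L)
    stop(sprintf("expected one unit, found %d; use readRasterSet()", length(rs)))
  rs[[1]]
}

#' Write PSTH matrices to TSV
#'
#' @param psths a [PSTHMatrix-class] or list of them (same bin/window).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePSTH <- function(psths, path) {
  if (is(psths, "PSTHMatrix")) psths <- list(psths)
  binMs <- psths[[1]]@binMs
  windowMs <- psths[[1]]@windowMs
  B <- ncol(psths[[1]]@rates)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("#meta bin_ms=%g window_ms=%g", binMs, windowMs), con)
  writeLines(paste(c("unit_id", "layer", "condition", "stimulus", "intensity",
                     "n_trials", sprintf("bin_%d", seq_len(B))),
                   collapse = "\t"), con)
  for (p in psths) {
    for (z in seq_len(nrow(p@rates))) {
      writeLines(paste(c(p@unitId, p@layer, p@condition, p@stimulus, z,
                         p@nTrials[z],
                         format(p@rates[z, ], digits = 15, trim = TRUE,
                                scientific = FALSE)),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read PSTH matrices from TSV
#'
#' `readPSTHSet()` returns a named list of [PSTHMatrix-class] objects;
#' `readPSTH()` expects exactly one unit.
#'
#' @param path a PSTH TSV written by [writePSTH()].
#' @return A [PSTHMatrix-class] or named list of them.
#' @export
readPSTHSet <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  isMeta <- startsWith(lines, "#")
  binMs <- 1
  windowMs <- 50
  for (ln in lines[isMeta]) {
    kv <- .parseMetaLines(ln)
    m <- regmatches(ln, regexec("bin_ms=([0-9.]+) window_ms=([0-9.]+)", ln))[[1]]
    if (length(m) == 3L) {
      binMs <- as.numeric(m[2])
      windowMs <- as.numeric(m[3])
    }
  }
  body <- lines[!isMeta]
  if (length(body) < 1L) stop("PSTH file has no header line")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 7L || !identical(header[1:6],
      c("unit_id", "layer", "condition", "stimulus", "intensity", "n_trials")))
    stop(sprintf("malformed PSTH header: '%s'", body[1]))
  tab <- utils::read.delim(text = body, header = TRUE, stringsAsFactors = FALSE)
  binCols <- grep("^bin_", names(tab))
  out <- list()
  for (uid in unique(tab$unit_id)) {
    rows <- tab[tab$unit_id == uid, , drop = FALSE]
    rows <- rows[order(rows$intensity), , drop = FALSE]
    zs <- rows$intensity
    if (!identical(as.integer(zs), seq_len(nrow(rows))))
      stop(sprintf("unit %s: intensity indices {%s} are not contiguous 1..Z",
                   uid, paste(zs, collapse = ",")), call. = FALSE)
    out[[uid]] <- psthMatrix(
      uid, rows$layer[1], rows$condition[1], rows$stimulus[1],
      as.matrix(rows[, binCols, drop = FALSE]), rows$n_trials,
      binMs = binMs, windowMs = windowMs
    )
  }
  out
}

#' @rdname readPSTHSet
#' @export
readPSTH <- function(path) {
  ps <- readPSTHSet(path)
  if (length(ps) != 1L)
    stop(sprintf("expected one unit, found %d; use readPSTHSet()", length(ps)))
  ps[[1]]
}
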