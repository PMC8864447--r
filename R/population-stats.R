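#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around the two-sided two-sample KS test used for comparing
#' component-timing distributions, per-unit component-count distributions and
#' non-stationarity distributions across layers and conditions. Ties (frequent
#' on the 1-ms lattice and on integer counts) make the asymptotic p
#' approximate; the tie warning is suppressed and the asymptotic p reported,
#' with the exact p available for small samples.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact logical or `NULL` (default: exact when both n < 30 and no
#'   ties, following `stats::ks.test`'s own rule when `NULL`).
#' @return list with `D`, `p`, `nA`, `nB`.
#' @export
ksTwoSample <- function(a, b, exact = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(D = unname(kt$statistic), p = unname(kt$p.value),
       nA = length(a), nB = length(b))
}

#' Linear regression between first- and second-component times
#'
#' Ordinary least squares of the second-component time on the first, for
#' multi-component units: `second = intercept + slope * first`. Mirrors the
#' reporting style of intercept +/- SE with an insignificance flag for fits
#' whose slope p-value is >= 0.05.
#'
#' @param first,second numeric vectors of first- and second-component times
#'   (ms), paired by unit; n >= 3 required for a computable fit.
#' @return list with `n`, `slope`, `slopeSE`, `intercept`, `interceptSE`, `p`
#'   (slope != 0), `rSquared`, `significant`, `computable`.
#' @export
timingRegression <- function(first, second) {
  stopifnot(length(first) == length(second))
  n <- length(first)
  if (n < 3L)
    return(list(n = n, slope = NA_real_, slopeSE = NA_real_,
                intercept = NA_real_, interceptSE = NA_real_, p = NA_real_,
                rSquared = NA_real_, significant = NA, computable = FALSE))
  fit <- stats::lm(second ~ first)
  # exact collinearity (noiseless inputs) triggers a "perfect fit" warning;
  # that case is legitimate here and reported with zero SEs
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  # exact collinearity leaves a zero residual: SEs are 0 and the slope test
  # degenerates; report p = 0 for a non-degenerate perfect fit
  slopeP <- if (nrow(co) < 2L) NA_real_ else co["first", "Pr(>|t|)"]
  if (!is.na(slopeP) && is.nan(slopeP))
    slopeP <- if (co["first", "Estimate"] != 0) 0 else 1
  list(
    n = n,
    slope = unname(co["first", "Estimate"]),
    slopeSE = unname(co["first", "Std. Error"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    interceptSE = unname(co["(Intercept)", "Std. Error"]),
    p = unname(slopeP),
    rSquared = sm$r.squared,
    significant = !is.na(slopeP) && slopeP < 0.05,
    computable = TRUE
  )
}

#' First- and second-component times per multi-component unit
#'
#' @param components a components table from [componentsTable()].
#' @return data.frame with one row per unit having >= 2 components: `unit_id`,
#'   `layer`, `condition`, `stimulus`, `first`, `second`.
#' @export
firstSecondTimes <- function(components) {
  cc <- components[!is.na(components$component_index), , drop = FALSE]
  out <- lapply(split(cc, cc$unit_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    d <- d[order(d$component_index), , drop = FALSE]
    data.frame(unit_id = d$unit_id[1], layer = d$layer[1],
               condition = d$condition[1], stimulus = d$stimulus[1],
               first = d$component_time_ms[1], second = d$component_time_ms[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(unit_id = character(), layer = character(),
                      condition = character(), stimulus = character(),
                      first = numeric(), second = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Timing regressions per (layer, condition, stimulus) group
#'
#' @param components a components table from [componentsTable()].
#' @return data.frame with one row per group: group labels, `n`,
#'   `intercept`, `intercept_se`, `slope`, `slope_se`, `p`, `r_squared`,
#'   `significant`.
#' @export
timingRegressionTable <- function(components) {
  fs <- firstSecondTimes(components)
  groups <- unique(fs[, c("layer", "condition", "stimulus")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- fs$layer == g$layer & fs$condition == g$condition &
      fs$stimulus == g$stimulus
    tr <- timingRegression(fs$first[sel], fs$second[sel])
    data.frame(layer = g$layer, condition = g$condition, stimulus = g$stimulus,
               n = tr$n, intercept = tr$intercept, intercept_se = tr$interceptSE,
               slope = tr$slope, slope_se = tr$slopeSE, p = tr$p,
               r_squared = tr$rSquared, significant = tr$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(layer = character(), condition = character(),
                      stimulus = character(), n = integer(),
                      intercept = numeric(), intercept_se = numeric(),
                      slope = numeric(), slope_se = numeric(), p = numeric(),
                      r_squared = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.categoryToCount <- function(category) {
  counts <- c("0" = 0L, "1" = 1L, "2" = 2L, "3plus" = 3L)
  unname(counts[as.character(category)])
}

#' Category proportions per (layer, condition, stimulus) cell
#'
#' Proportions of units with 0, 1, 2 or 3+ detected response components
#' (non-responders = 0 components), per cell, each row summing to 1.
#'
#' @param units data.frame with one row per unit and columns `layer`,
#'   `condition`, `stimulus`, `category` (e.g. the unique unit rows of a
#'   [componentsTable()]).
#' @return data.frame: group labels, `n`, `prop_0`, `prop_1`, `prop_2`,
#'   `prop_3plus`.
#' @export
categoryProportions <- function(units) {
  stopifnot(all(c("layer", "condition", "stimulus", "category") %in% names(units)))
  groups <- unique(units[, c("layer", "condition", "stimulus")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- units$layer == g$layer & units$condition == g$condition &
      units$stimulus == g$stimulus
    tab <- table(factor(units$category[sel], levels = .CATEGORIES))
    props <- as.numeric(tab) / sum(tab)
    data.frame(layer = g$layer, condition = g$condition, stimulus = g$stimulus,
               n = sum(tab), prop_0 = props[1], prop_1 = props[2],
               prop_2 = props[3], prop_3plus = props[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise comparisons of per-unit component-count distributions
#'
#' For every pair of cells sharing a stimulus and differing in layer (same
#' condition) or condition (same layer), compares the per-unit component-count
#' samples (0, 1, 2, 3 per unit) with a two-sample KS test. A KS test on a
#' four-valued integer sample is an unusual but serviceable comparison of
#' proportion profiles; a chi-square test on the contingency table is emitted
#' alongside for reference. No multiple-comparison correction is applied; raw
#' p-values are reported.
#'
#' @param units as in [categoryProportions()].
#' @return data.frame: `stimulus`, `group_a`, `group_b`, `D`, `p_ks`,
#'   `p_chisq`, `n_a`, `n_b`.
#' @export
categoryComparisons <- function(units) {
  groups <- unique(units[, c("layer", "condition", "stimulus")])
  key <- function(g) paste(g$layer, g$condition, sep = "/")
  rows <- list()
  if (nrow(groups) >= 2L) {
    for (i in seq_len(nrow(groups) - 1L)) {
      for (j in seq(i + 1L, nrow(groups))) {
        gi <- groups[i, ]
        gj <- groups[j, ]
        if (gi$stimulus != gj$stimulus) next
        sameLayer <- gi$layer == gj$layer
        sameCond <- gi$condition == gj$condition
        if (!(sameLayer || sameCond)) next # compare across one factor at a time
        si <- units$layer == gi$layer & units$condition == gi$condition &
          units$stimulus == gi$stimulus
        sj <- units$layer == gj$layer & units$condition == gj$condition &
          units$stimulus == gj$stimulus
        ca <- .categoryToCount(units$category[si])
        cb <- .categoryToCount(units$category[sj])
        ks <- ksTwoSample(ca, cb)
        tab <- rbind(table(factor(ca, levels = 0:3)),
                     table(factor(cb, levels = 0:3)))
        tab <- tab[, colSums(tab) > 0, drop = FALSE]
        pChi <- tryCatch(
          suppressWarnings(stats::chisq.test(tab)$p.value),
          error = function(e) NA_real_
        )
        rows[[length(rows) + 1L]] <- data.frame(
          stimulus = gi$stimulus, group_a = key(gi), group_b = key(gj),
          D = ks$D, p_ks = ks$p, p_chisq = pChi, n_a = ks$nA, n_b = ks$nB,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(stimulus = character(), group_a = character(),
                      group_b = character(), D = numeric(), p_ks = numeric(),
                      p_chisq = numeric(), n_a = integer(), n_b = integer(),
                      stringsAsFactors = FALSE)
  out
}

#' Non-stationarity distribution per (layer, condition) group
#'
#' Bins each unit's primary (rank-1) path non-stationarity into 0, 1, 2, 3, 4
#' or 5+ ms, reports per-group proportions, and compares groups pairwise with
#' two-sample KS tests on the raw per-unit values.
#'
#' @param paths data.frame with one row per unit and columns `layer`,
#'   `condition`, `nonstationarity_ms` (primary-path values).
#' @return list with `histogram` (data.frame: group labels, `n`, `prop_0` ..
#'   `prop_5plus`) and `comparisons` (data.frame: `group_a`, `group_b`, `D`,
#'   `p`).
#' @export
nonstationarityDistribution <- function(paths) {
  stopifnot(all(c("layer", "condition", "nonstationarity_ms") %in% names(paths)))
  lev <- c("0", "1", "2", "3", "4", "5plus")
  binned <- pmin(floor(paths$nonstationarity_ms), 5)
  binLab <- ifelse(binned >= 5, "5plus", as.character(binned))
  groups <- unique(paths[, c("layer", "condition")])
  hist <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- paths$layer == g$layer & paths$condition == g$condition
    tab <- table(factor(binLab[sel], levels = lev))
    props <- as.numeric(tab) / sum(tab)
    cbind(data.frame(layer = g$layer, condition = g$condition, n = sum(tab),
                     stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(t(props)), paste0("prop_", lev)))
  }))
  rownames(hist) <- NULL
  comps <- list()
  if (nrow(groups) >= 2L) {
    for (i in seq_len(nrow(groups) - 1L)) {
      for (j in seq(i + 1L, nrow(groups))) {
        gi <- groups[i, ]
        gj <- groups[j, ]
        si <- paths$layer == gi$layer & paths$condition == gi$condition
        sj <- paths$layer == gj$layer & paths$condition == gj$condition
        ks <- ksTwoSample(paths$nonstationarity_ms[si],
                          paths$nonstationarity_ms[sj])
        comps[[length(comps) + 1L]] <- data.frame(
          group_a = paste(gi$layer, gi$condition, sep = "/"),
          group_b = paste(gj$layer, gj$condition, sep = "/"),
          D = ks$D, p = ks$p, stringsAsFactors = FALSE
        )
      }
    }
  }
  comparisons <- do.call(rbind, comps)
  if (is.null(comparisons))
    comparisons <- data.frame(group_a = character(), group_b = character(),
                              D = numeric(), p = numeric(),
                              stringsAsFactors = FALSE)
  list(histogram = hist, comparisons = comparisons)
}
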