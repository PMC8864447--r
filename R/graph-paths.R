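#' Convert a PSTH matrix into a weighted directed grid graph
#'
#' Each intensity-time bin (z, t) of the PSTH becomes a vertex. Every vertex
#' receives directed edges from its existing grid neighbours at (z+/-1, t),
#' (z, t+/-1) and (z+/-1, t+/-1); all edges into (z, t) carry the same weight
#' `w(z, t) = Rmax / max(rate(z, t), epsilon)`, where `Rmax` is the unit's
#' maximum mean firing rate. High-rate bins therefore attract paths (low
#' incoming weight). A start pseudo-vertex feeds every row-1 vertex (edge
#' weight = that vertex's w) and every row-Z vertex feeds a goal pseudo-vertex
#' (weight 0).
#'
#' The literal weight is infinite at zero-rate bins; the `epsilon` floor keeps
#' all weights finite so Dijkstra applies, without changing weight ratios
#' among positive-rate bins. An all-zero PSTH (Rmax = 0) yields a valid graph
#' flagged so that path extraction short-circuits to "no paths".
#'
#' @param psth a [PSTHMatrix-class] with Z >= 2 intensities and B >= 2 bins.
#' @param epsilon positive rate floor in Hz (default 1e-3).
#' @return A `PSTHGraph`: a list with the igraph object (`graph`), the vertex
#'   weight matrix (`w`), dimensions `Z`, `B`, `Rmax`, `epsilon`, vertex-id
#'   helpers and the `allZero` flag.
#' @export
buildGraph <- function(psth, epsilon = 1e-3) {
  stopifnot(is(psth, "PSTHMatrix"))
  .assertScalarNumber(epsilon, "epsilon", positive = TRUE)
  rates <- psth@rates
  Z <- nrow(rates)
  B <- ncol(rates)
  stopifnot(Z >= 2L, B >= 2L)
  Rmax <- max(rates)
  w <- Rmax / pmax(rates, epsilon)
  startId <- Z * B + 1L
  goalId <- Z * B + 2L
  vid <- function(z, t) (z - 1L) * B + t

  # ordered pairs (source -> target) over the 8-neighbourhood, vectorized
  offs <- rbind(
    c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, -1L), c(0L, 1L),
    c(1L, -1L), c(1L, 0L), c(1L, 1L)
  )
  tz <- rep(seq_len(Z), times = B)
  tt <- rep(seq_len(B), each = Z)
  from <- integer()
  to <- integer()
  wt <- numeric()
  for (i in seq_len(nrow(offs))) {
    sz <- tz + offs[i, 1L]
    st <- tt + offs[i, 2L]
    ok <- sz >= 1L & sz <= Z & st >= 1L & st <= B
    from <- c(from, vid(sz[ok], st[ok]))
    to <- c(to, vid(tz[ok], tt[ok]))
    wt <- c(wt, w[cbind(tz[ok], tt[ok])])
  }
  # start -> row 1; row Z -> goal
  from <- c(from, rep(startId, B), vid(rep(Z, B), seq_len(B)))
  to <- c(to, vid(rep(1L, B), seq_len(B)), rep(goalId, B))
  wt <- c(wt, w[1L, ], rep(0, B))

  g <- igraph::make_empty_graph(n = Z * B + 2L, directed = TRUE)
  g <- igraph::add_edges(g, rbind(from, to), weight = wt)
  structure(
    list(
      graph = g, w = w, Z = Z, B = B, Rmax = Rmax, epsilon = epsilon,
      startId = startId, goalId = goalId, rates = rates,
      allZero = (Rmax == 0)
    ),
    class = "PSTHGraph"
  )
}

#' Extract up to k vertex-disjoint shortest paths
#'
#' The primary path is the Dijkstra shortest path from the start to the goal
#' pseudo-vertex. Before each subsequent run, every edge leading into a vertex
#' already used by an earlier path is re-weighted to an arbitrarily large
#' value `Wbig = 10 * |V| * max(finite edge weight)`, so later paths cannot
#' revisit those vertices unless the grid is exhausted; a candidate path whose
#' total weight reaches `Wbig` is discarded, so fewer than `k` paths may be
#' returned. All returned paths are pairwise vertex-disjoint.
#'
#' @param g a `PSTHGraph` from [buildGraph()].
#' @param k maximum number of paths (default 3).
#' @return list of [ComponentPath-class] objects, rank 1..length.
#' @export
kDisjointShortestPaths <- function(g, k = 3L) {
  stopifnot(inherits(g, "PSTHGraph"))
  if (g$allZero) return(list())
  graph <- g$graph
  wts <- igraph::E(graph)$weight
  Wbig <- 10 * (g$Z * g$B + 2) * max(wts)
  paths <- list()
  heads <- igraph::head_of(graph, igraph::E(graph))
  for (rank in seq_len(k)) {
    sp <- suppressWarnings(igraph::shortest_paths(
      graph, from = g$startId, to = g$goalId,
      weights = wts, mode = "out", output = "both"
    ))
    if (length(sp$vpath[[1]]) == 0L) break
    eids <- sp$epath[[1]]
    total <- sum(wts[as.integer(eids)])
    if (total >= Wbig) break
    vids <- as.integer(sp$vpath[[1]])
    vids <- vids[!(vids %in% c(g$startId, g$goalId))]
    zs <- ((vids - 1L) %/% g$B) + 1L
    ts <- ((vids - 1L) %% g$B) + 1L
    verts <- data.frame(z = zs, t = ts, rate = g$rates[cbind(zs, ts)])
    feat <- pathFeatures(verts)
    paths[[rank]] <- new("ComponentPath",
      rank = as.integer(rank), vertices = verts, totalWeight = total,
      medianTime = feat$medianTime, perRow = feat$perRow,
      nonstationarityMs = feat$nonstationarityMs
    )
    wts[as.integer(heads) %in% vids] <- Wbig
  }
  paths
}

#' Summary features of a component path
#'
#' Computes (i) the median time bin over all path vertices (lower median for
#' even counts), (ii) per intensity row, the (lower-)median time bin visited
#' and the mean firing rate over that row's path vertices, and (iii) the
#' non-stationarity: max minus min of the per-row times, i.e. how far the
#' tracked component shifts across stimulus intensities.
#'
#' @param vertices data.frame with columns `z`, `t`, `rate` (path order), or a
#'   [ComponentPath-class].
#' @return list with `medianTime`, `perRow` (data.frame `z`, `time`, `rate`)
#'   and `nonstationarityMs`.
#' @export
pathFeatures <- function(vertices) {
  if (is(vertices, "ComponentPath")) vertices <- vertices@vertices
  stopifnot(nrow(vertices) >= 1L)
  zs <- sort(unique(vertices$z))
  perRow <- do.call(rbind, lapply(zs, function(z) {
    sel <- vertices$z == z
    data.frame(z = z, time = .lowerMedian(vertices$t[sel]),
               rate = mean(vertices$rate[sel]))
  }))
  list(
    medianTime = .lowerMedian(vertices$t),
    perRow = perRow,
    nonstationarityMs = max(perRow$time) - min(perRow$time)
  )
}

#' Correlation between two paths' per-row firing rates
#'
#' Pearson correlation, across shared intensity rows, of the mean firing rates
#' along two component paths of the same unit. A significant positive
#' correlation suggests the paths trace components modulated alike by stimulus
#' intensity; a negative one suggests opposing components (one waxing while
#' the other wanes).
#'
#' @param a,b [ComponentPath-class] objects from the same unit.
#' @return list with `r`, `p` (two-tailed), `nRows`, `computable`. Fewer than
#'   3 shared rows, or zero variance in either rate profile, is flagged not
#'   computable.
#' @export
pathRateCorrelation <- function(a, b) {
  stopifnot(is(a, "ComponentPath"), is(b, "ComponentPath"))
  shared <- intersect(a@perRow$z, b@perRow$z)
  if (length(shared) < 3L)
    return(list(r = NA_real_, p = NA_real_, nRows = length(shared), computable = FALSE))
  ra <- a@perRow$rate[match(shared, a@perRow$z)]
  rb <- b@perRow$rate[match(shared, b@perRow$z)]
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    return(list(r = NA_real_, p = NA_real_, nRows = length(shared), computable = FALSE))
  ct <- stats::cor.test(ra, rb, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = unname(ct$p.value),
       nRows = length(shared), computable = TRUE)
}

#' Run the graph analysis for one unit
#'
#' Convenience wrapper: build the graph, extract up to `k` disjoint shortest
#' paths, and tabulate path features and pairwise rate correlations.
#'
#' @param psth a [PSTHMatrix-class].
#' @param k maximum number of paths (default 3).
#' @param epsilon rate floor in Hz (default 1e-3).
#' @return list with `paths` (list of [ComponentPath-class]), `pathTable`
#'   (long-format data.frame: unit_id, path_rank, total_weight,
#'   median_time_ms, nonstationarity_ms, row, time_ms, rate_hz) and
#'   `correlations` (data.frame: unit_id, rank_a, rank_b, r, p, computable).
#' @export
graphComponents <- function(psth, k = 3L, epsilon = 1e-3) {
  g <- buildGraph(psth, epsilon = epsilon)
  paths <- kDisjointShortestPaths(g, k = k)
  pathTable <- do.call(rbind, lapply(paths, function(p) {
    data.frame(
      unit_id = psth@unitId, path_rank = p@rank, total_weight = p@totalWeight,
      median_time_ms = p@medianTime, nonstationarity_ms = p@nonstationarityMs,
      row = p@perRow$z, time_ms = p@perRow$time, rate_hz = p@perRow$rate,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(pathTable)) {
    pathTable <- data.frame(
      unit_id = character(), path_rank = integer(), total_weight = numeric(),
      median_time_ms = numeric(), nonstationarity_ms = numeric(),
      row = integer(), time_ms = numeric(), rate_hz = numeric(),
      stringsAsFactors = FALSE
    )
  }
  cors <- list()
  if (length(paths) >= 2L) {
    combos <- utils::combn(length(paths), 2L)
    cors <- lapply(seq_len(ncol(combos)), function(i) {
      pa <- paths[[combos[1L, i]]]
      pb <- paths[[combos[2L, i]]]
      pc <- pathRateCorrelation(pa, pb)
      data.frame(unit_id = psth@unitId, rank_a = pa@rank, rank_b = pb@rank,
                 r = pc$r, p = pc$p, computable = pc$computable,
                 stringsAsFactors = FALSE)
    })
  }
  correlations <- if (length(cors)) do.call(rbind, cors) else data.frame(
    unit_id = character(), rank_a = integer(), rank_b = integer(),
    r = numeric(), p = numeric(), computable = logical(),
    stringsAsFactors = FALSE
  )
  list(paths = paths, pathTable = pathTable, correlations = correlations)
}
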