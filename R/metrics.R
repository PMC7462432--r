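#' Degree centrality
#'
#' Number of edges attached to each node ("hubness"); the row sums of the
#' binary adjacency matrix. The degrees sum to twice the edge count.
#'
#' @param g A [BinaryGraph-class].
#' @return Named integer vector of nodal degrees.
#' @export
degreeCentrality <- function(g) {
  stopifnot(is(g, "BinaryGraph"))
  d <- as.integer(rowSums(adjacencyMatrix(g)))
  names(d) <- roiLabels(g)
  d
}

#' Clustering coefficient
#'
#' Fraction of realized triangles around each node:
#' `C_i = 2 L_i / (K_i (K_i - 1))`, with `L_i` the number of triangles
#' through node i and `K_i` its degree; nodes with degree < 2 score 0
#' (the formula is 0/0 there). Triangles come from the diagonal of the
#' cubed adjacency matrix.
#'
#' @param g A [BinaryGraph-class].
#' @return List with `nodal` (named numeric C_i) and `mean` (mean over all
#'   n nodes).
#' @export
#' @examples
#' a <- matrix(0L, 4, 4); a[1,2] <- a[1,3] <- a[2,3] <- a[3,4] <- 1L
#' a <- a + t(a)
#' clusteringCoefficient(BinaryGraph(a))$mean  # 7/12
clusteringCoefficient <- function(g) {
  stopifnot(is(g, "BinaryGraph"))
  a <- adjacencyMatrix(g)
  storage.mode(a) <- "double"
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  names(ci) <- roiLabels(g)
  list(nodal = ci, mean = mean(ci))
}

#' Geodesic (hop-count) distance matrix
#'
#' Unweighted shortest-path lengths between all node pairs via
#' breadth-first search; disconnected pairs are `Inf` and the diagonal 0.
#'
#' @param g A [BinaryGraph-class].
#' @return Numeric matrix of hop counts with ROI dimnames.
#' @export
geodesicDistances <- function(g) {
  stopifnot(is(g, "BinaryGraph"))
  a <- adjacencyMatrix(g)
  storage.mode(a) <- "integer"
  d <- bfs_distances(a)
  dimnames(d) <- list(roiLabels(g), roiLabels(g))
  d
}

# Efficiency of a plain adjacency matrix (internal; 1/Inf counts as 0 so
# fragmented graphs stay defined).
effFromAdjacency <- function(a) {
  n <- nrow(a)
  if (n < 2L) return(0)
  d <- bfs_distances(a)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs,
#' `E_glob = 1/(n(n-1)) * sum_{i != j} 1/L_ij`, a measure of the network's
#' capacity for parallel information transfer. Disconnected pairs
#' contribute 0 (`1/Inf`), which keeps the measure defined when stringent
#' thresholds fragment the graph.
#'
#' @param g A [BinaryGraph-class].
#' @return A single number in [0, 1].
#' @export
#' @examples
#' a <- matrix(0L, 3, 3); a[1,2] <- a[2,3] <- 1L; a <- a + t(a)
#' globalEfficiency(BinaryGraph(a))  # path a-b-c: 5/6
globalEfficiency <- function(g) {
  stopifnot(is(g, "BinaryGraph"))
  a <- adjacencyMatrix(g)
  if (nrow(a) < 2L)
    adhStop("tooFewNodes", "global efficiency requires at least 2 nodes")
  storage.mode(a) <- "integer"
  effFromAdjacency(a)
}

#' Local efficiency
#'
#' For each node i, the global efficiency of the subgraph induced by its
#' neighbors (node i excluded): how efficiently the local neighborhood can
#' exchange information when the node is removed. Nodes with degree < 2
#' score 0.
#'
#' @param g A [BinaryGraph-class].
#' @return List with `nodal` (named numeric Eloc_i) and `mean`.
#' @export
localEfficiency <- function(g) {
  stopifnot(is(g, "BinaryGraph"))
  a <- adjacencyMatrix(g)
  storage.mode(a) <- "integer"
  e <- local_efficiency_nodal(a)
  names(e) <- roiLabels(g)
  list(nodal = e, mean = mean(e))
}

#' Louvain modularity, averaged over repetitions
#'
#' Runs Louvain community detection `reps` times with distinct seeds
#' derived from `seed`, scores each partition with the Newman-Girvan
#' modularity `Q = 1/(2m) * sum_ij (A_ij - k_i k_j / (2m)) delta(c_i, c_j)`,
#' and reports the individual and mean Q. Partitions themselves are
#' discarded; only the quality statistic enters the analysis. An edgeless
#' graph yields Q = 0 with a warning rather than an error so threshold
#' sweeps never crash at extreme T.
#'
#' @param g A [BinaryGraph-class].
#' @param reps Number of repetitions (reference protocol: 150).
#' @param seed Run seed; repetition seeds are derived from it.
#' @return List with `qValues` (length `reps`) and `meanQ`.
#' @export
modularityLouvain <- function(g, reps = 150L, seed = 1L) {
  stopifnot(is(g, "BinaryGraph"))
  if (reps < 1L) adhStop("badReps", "reps must be >= 1")
  a <- adjacencyMatrix(g)
  if (sum(a) == 0L) {
    adhWarn("edgelessGraph", "graph has no edges; Q defined as 0")
    return(list(qValues = rep(0, reps), meanQ = 0))
  }
  gi <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  q <- vapply(seq_len(reps), function(r) {
    set.seed(deriveSeed(seed, 211L, r))
    part <- igraph::cluster_louvain(gi)
    igraph::modularity(gi, igraph::membership(part))
  }, numeric(1))
  list(qValues = q, meanQ = mean(q))
}

#' Binarized system segregation
#'
#' Density-based segregation of predefined subnetworks:
#' `z_binw` is the realized within-subnetwork edge count divided by the
#' possible within count, averaged over subnetworks; `z_binb` is the
#' between-subnetwork edge count divided by the possible between count
#' (pooled over all between pairs by default, or averaged per subnetwork
#' pair with `between = "pairwise"`). Segregation is
#' `S = (z_binw - z_binb) / z_binw`; it is undefined (classed error) when
#' no within edges exist.
#'
#' @param g A [BinaryGraph-class].
#' @param aff An [AffiliationVector-class] covering all nodes; every
#'   subnetwork needs at least 2 nodes.
#' @param between "pooled" (default) or "pairwise".
#' @return List with `withinDensity`, `betweenDensity`, `segregation`.
#' @export
#' @examples
#' a <- matrix(0L, 6, 6)
#' a[1,2] <- a[1,3] <- a[2,3] <- 1L  # complete triad 1
#' a[4,5] <- a[4,6] <- a[5,6] <- 1L  # complete triad 2
#' a[1,4] <- 1L                      # one between edge
#' a <- a + t(a); dimnames(a) <- list(paste0("n", 1:6), paste0("n", 1:6))
#' aff <- AffiliationVector(structure(rep(c("A", "B"), each = 3),
#'                                    names = paste0("n", 1:6)))
#' systemSegregation(BinaryGraph(a), aff)$segregation  # 8/9
systemSegregation <- function(g, aff, between = c("pooled", "pairwise")) {
  stopifnot(is(g, "BinaryGraph"), is(aff, "AffiliationVector"))
  between <- match.arg(between)
  a <- adjacencyMatrix(g)
  labs <- roiLabels(g)
  map <- affiliations(aff)
  uncovered <- setdiff(labs, names(map))
  if (length(uncovered))
    adhStop("unaffiliatedRoi", "no affiliation for node(s): %s",
            paste(utils::head(uncovered, 5), collapse = ", "))
  memb <- map[labs]
  sizes <- table(memb)
  if (any(sizes < 2L))
    adhStop("singletonNetwork", "subnetwork(s) with < 2 nodes: %s",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
  nets <- names(sizes)
  withinDens <- vapply(nets, function(s) {
    idx <- which(memb == s)
    ns <- length(idx)
    sum(a[idx, idx]) / 2 / (ns * (ns - 1) / 2)
  }, numeric(1))
  zw <- mean(withinDens)
  if (between == "pooled") {
    n <- nrow(a)
    withinEdges <- sum(vapply(nets, function(s) {
      idx <- which(memb == s); sum(a[idx, idx]) / 2
    }, numeric(1)))
    betweenEdges <- sum(a) / 2 - withinEdges
    possBetween <- n * (n - 1) / 2 - sum(sizes * (sizes - 1) / 2)
    zb <- betweenEdges / possBetween
  } else {
    pairDens <- c()
    for (i in seq_along(nets)) for (j in seq_len(i - 1L)) {
      ii <- which(memb == nets[i]); jj <- which(memb == nets[j])
      pairDens <- c(pairDens, sum(a[ii, jj]) / (length(ii) * length(jj)))
    }
    zb <- mean(pairDens)
  }
  if (zw == 0)
    adhStop("undefinedSegregation",
            "no within-subnetwork edges: segregation undefined")
  list(withinDensity = zw, betweenDensity = zb,
       segregation = (zw - zb) / zw)
}

#' Global metric set of one binary graph
#'
#' Mean clustering, global efficiency, mean local efficiency, binarized
#' system segregation, and (optionally) mean Louvain Q, keyed by the
#' graph's threshold. Undefined segregation is recorded as `NA` rather
#' than an error so sweeps stay rectangular.
#'
#' @param g A [BinaryGraph-class].
#' @param aff An [AffiliationVector-class].
#' @param louvainReps Louvain repetitions; 0 skips modularity.
#' @param seed Seed for the Louvain repetitions.
#' @param between Segregation between-density mode, see
#'   [systemSegregation()].
#' @return One-row data.frame of global metrics.
#' @export
globalMetrics <- function(g, aff, louvainReps = 150L, seed = 1L,
                          between = "pooled") {
  cl <- clusteringCoefficient(g)
  le <- localEfficiency(g)
  seg <- tryCatch(systemSegregation(g, aff, between)$segregation,
                  adh_undefinedSegregation = function(e) NA_real_)
  q <- if (louvainReps >= 1L)
    suppressWarnings(modularityLouvain(g, louvainReps, seed)$meanQ)
  else NA_real_
  data.frame(
    threshold = thresholdOf(g),
    mean_clustering = cl$mean,
    global_efficiency = globalEfficiency(g),
    mean_local_efficiency = le$mean,
    system_segregation = seg,
    modularity = q
  )
}

#' Metric table over a participant's threshold sweep
#'
#' Long-format table keyed by (participant, threshold, scope, metric):
#' scope is either a node label (nodal clustering, local efficiency,
#' degree) or `"GLOBAL"` (mean clustering, global efficiency, mean local
#' efficiency, system segregation, and mean Louvain Q when requested).
#' Undefined segregation is recorded as missing, not zero.
#'
#' @param graphs List of [BinaryGraph-class] from one participant's sweep.
#' @param aff An [AffiliationVector-class].
#' @param metrics Which metric families to compute: any subset of
#'   "clustering", "local_efficiency", "degree" (nodal + their global
#'   means), "global_efficiency", "system_segregation", "modularity".
#'   Restricting the set skips the corresponding computations entirely,
#'   which matters for large scan simulations.
#' @param louvainReps Louvain repetitions per graph; 0 skips modularity
#'   (the expensive metric) even when requested.
#' @param seed Seed for Louvain repetitions.
#' @param between Segregation mode, see [systemSegregation()].
#' @return data.frame with columns participant_id, threshold, scope,
#'   metric, value.
#' @export
metricsOverSweep <- function(graphs, aff,
                             metrics = c("clustering", "local_efficiency",
                                         "degree", "global_efficiency",
                                         "system_segregation", "modularity"),
                             louvainReps = 150L, seed = 1L,
                             between = "pooled") {
  stopifnot(length(graphs) >= 1L)
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- vector("list", length(graphs))
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    id <- participantId(g)
    t <- thresholdOf(g)
    labs <- roiLabels(g)
    nodalScope <- character(0); nodalMetric <- character(0)
    nodalValue <- numeric(0)
    globMetric <- character(0); globValue <- numeric(0)
    addNodal <- function(name, v) {
      nodalScope <<- c(nodalScope, labs)
      nodalMetric <<- c(nodalMetric, rep(name, length(labs)))
      nodalValue <<- c(nodalValue, as.numeric(v))
    }
    addGlob <- function(name, v) {
      globMetric <<- c(globMetric, name)
      globValue <<- c(globValue, v)
    }
    if ("clustering" %in% metrics) {
      cl <- clusteringCoefficient(g)
      addNodal("clustering", cl$nodal)
      addGlob("mean_clustering", cl$mean)
    }
    if ("local_efficiency" %in% metrics) {
      le <- localEfficiency(g)
      addNodal("local_efficiency", le$nodal)
      addGlob("mean_local_efficiency", le$mean)
    }
    if ("degree" %in% metrics)
      addNodal("degree", degreeCentrality(g))
    if ("global_efficiency" %in% metrics)
      addGlob("global_efficiency", globalEfficiency(g))
    if ("system_segregation" %in% metrics)
      addGlob("system_segregation",
              tryCatch(systemSegregation(g, aff, between)$segregation,
                       adh_undefinedSegregation = function(e) NA_real_))
    if ("modularity" %in% metrics && louvainReps >= 1L)
      addGlob("modularity",
              suppressWarnings(modularityLouvain(g, louvainReps,
                                                 deriveSeed(seed, 97L, k))$meanQ))
    out[[k]] <- rbind(
      if (length(nodalScope))
        data.frame(participant_id = id, threshold = t, scope = nodalScope,
                   metric = nodalMetric, value = nodalValue),
      if (length(globMetric))
        data.frame(participant_id = id, threshold = t, scope = "GLOBAL",
                   metric = globMetric, value = globValue)
    )
  }
  do.call(rbind, out)
}

#' Metric table for a whole cohort
#'
#' Convenience wrapper: Pearson connectome, threshold sweep and
#' [metricsOverSweep()] for every participant, bound into one long table.
#'
#' @param series List of [RoiTimeSeriesSet-class].
#' @param aff An [AffiliationVector-class].
#' @param cfg A [RunConfig-class]; supplies the grid, binarization mode and
#'   Louvain repetitions.
#' @param metrics Metric families to compute, see [metricsOverSweep()].
#' @param louvainReps Override of `cfg@louvainReps` (0 skips modularity).
#' @param seed Run seed for the Louvain repetitions.
#' @return Long metric data.frame as in [metricsOverSweep()].
#' @export
cohortMetrics <- function(series, aff, cfg = runConfig(),
                          metrics = c("clustering", "local_efficiency",
                                      "degree", "global_efficiency",
                                      "system_segregation", "modularity"),
                          louvainReps = cfg@louvainReps, seed = 1L) {
  tabs <- lapply(seq_along(series), function(i) {
    w <- pearsonConnectome(series[[i]])
    graphs <- suppressWarnings(
      thresholdSweep(w, cfg@thresholdGrid, absolute = cfg@absoluteThreshold))
    metricsOverSweep(graphs, aff, metrics = metrics,
                     louvainReps = louvainReps,
                     seed = deriveSeed(seed, 31L, i),
                     between = cfg@segregationBetween)
  })
  do.call(rbind, tabs)
}
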