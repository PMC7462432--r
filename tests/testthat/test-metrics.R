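mkGraph <- function(edges, n) {
  a <- matrix(0L, n, n)
  for (e in edges) { a[e[1], e[2]] <- 1L; a[e[2], e[1]] <- 1L }
  BinaryGraph(a)
}

test_that("clustering coefficient matches hand-enumerated triangle fractions", {
  tri <- mkGraph(list(c(1, 2), c(1, 3), c(2, 3)), 3)
  expect_equal(clusteringCoefficient(tri)$nodal, setNames(rep(1, 3), roiLabels(tri)))
  expect_equal(clusteringCoefficient(tri)$mean, 1)

  path <- mkGraph(list(c(1, 2), c(2, 3)), 3)
  expect_equal(unname(clusteringCoefficient(path)$nodal), rep(0, 3))

  # edges {ab, ac, bc, cd}: C = (1, 1, 1/3, 0), mean 7/12
  g <- mkGraph(list(c(1, 2), c(1, 3), c(2, 3), c(3, 4)), 4)
  expect_equal(unname(clusteringCoefficient(g)$nodal), c(1, 1, 1 / 3, 0))
  expect_equal(clusteringCoefficient(g)$mean, 7 / 12)
  expect_equal(unname(degreeCentrality(g)), c(2L, 2L, 3L, 1L))
  expect_identical(sum(degreeCentrality(g)), 8L)
})

test_that("geodesic distances and efficiencies agree with hand values", {
  k5 <- BinaryGraph(matrix(1L, 5, 5) - diag(5L))
  d <- geodesicDistances(k5)
  expect_true(all(d[upper.tri(d)] == 1))
  expect_equal(globalEfficiency(k5), 1)
  expect_equal(unname(degreeCentrality(k5)), rep(4L, 5))

  path <- mkGraph(list(c(1, 2), c(2, 3)), 3)
  expect_equal(geodesicDistances(path)[1, 3], 2)
  expect_equal(globalEfficiency(path), 5 / 6)

  empty <- BinaryGraph(matrix(0L, 4, 4))
  expect_equal(globalEfficiency(empty), 0)
  expect_true(all(is.infinite(geodesicDistances(empty)[upper.tri(diag(4))])))

  k3 <- mkGraph(list(c(1, 2), c(1, 3), c(2, 3)), 3)
  expect_equal(unname(localEfficiency(k3)$nodal), rep(1, 3))
  star <- mkGraph(list(c(1, 2), c(1, 3), c(1, 4)), 4)
  expect_equal(localEfficiency(star)$nodal[[1]], 0)
})

test_that("every metric equals its brute-force oracle on random graphs", {
  set.seed(301)
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    g <- randomBinaryGraph(n, stats::runif(1, 0.15, 0.6))
    a <- adjacencyMatrix(g)
    expect_equal(unname(clusteringCoefficient(g)$nodal), oracleClustering(a),
                 tolerance = 1e-12)
    expect_equal(unname(degreeCentrality(g)), as.integer(oracleDegree(a)))
    expect_equal(unname(geodesicDistances(g)), oracleFloydWarshall(a))
    expect_equal(globalEfficiency(g), oracleGlobalEfficiency(a),
                 tolerance = 1e-12)
    expect_equal(unname(localEfficiency(g)$nodal), oracleLocalEfficiency(a),
                 tolerance = 1e-12)
  }
})

test_that("local efficiency of a node equals global efficiency of its neighbor subgraph", {
  set.seed(302)
  for (rep in 1:10) {
    g <- randomBinaryGraph(10, 0.4)
    a <- adjacencyMatrix(g)
    eloc <- localEfficiency(g)$nodal
    for (i in 1:10) {
      nb <- which(a[i, ] == 1)
      expected <- if (length(nb) < 2) 0 else
        globalEfficiency(BinaryGraph(a[nb, nb, drop = FALSE]))
      expect_equal(eloc[[i]], expected, tolerance = 1e-12)
    }
  }
})

test_that("Louvain modularity hits exact optima on structured graphs", {
  two <- mkGraph(list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)), 6)
  res <- modularityLouvain(two, reps = 20, seed = 1)
  expect_length(res$qValues, 20L)
  expect_equal(res$meanQ, 0.5)
  expect_equal(oracleOptimalModularity(adjacencyMatrix(two)), 0.5)

  k4 <- BinaryGraph(matrix(1L, 4, 4) - diag(4L))
  expect_equal(modularityLouvain(k4, reps = 10, seed = 1)$meanQ, 0)
  expect_lte(oracleOptimalModularity(adjacencyMatrix(k4)), 1e-12)

  expect_length(modularityLouvain(two, reps = 150, seed = 2)$qValues, 150L)
  expect_error(modularityLouvain(two, reps = 0), class = "adh_badReps")
  expect_warning(q0 <- modularityLouvain(BinaryGraph(matrix(0L, 3, 3)), reps = 5),
                 class = "adh_edgelessGraph")
  expect_equal(q0$meanQ, 0)
})

test_that("reported Q never exceeds the exhaustive-partition optimum", {
  set.seed(303)
  for (rep in 1:12) {
    g <- randomBinaryGraph(sample(4:8, 1), stats::runif(1, 0.25, 0.6))
    if (sum(adjacencyMatrix(g)) == 0) next
    res <- modularityLouvain(g, reps = 10, seed = rep)
    opt <- oracleOptimalModularity(adjacencyMatrix(g))
    expect_lte(max(res$qValues), opt + 1e-12)
  }
})

test_that("system segregation reproduces direct edge-count values", {
  aff2 <- AffiliationVector(structure(rep(c("A", "B"), each = 3),
                                      names = sprintf("n%02d", 1:6)))
  # two complete triads, no between edges: perfect segregation
  sep <- mkGraph(list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)), 6)
  expect_equal(systemSegregation(sep, aff2)$segregation, 1)
  # ... plus exactly one of the nine possible between edges: S = 8/9
  mixed <- mkGraph(list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                        c(1, 4)), 6)
  res <- systemSegregation(mixed, aff2)
  expect_equal(res$withinDensity, 1)
  expect_equal(res$betweenDensity, 1 / 9)
  expect_equal(res$segregation, 8 / 9)
  # equal within and between density: definitional zero
  flat <- mkGraph(list(c(1, 2), c(1, 3), c(4, 5), c(4, 6),
                       c(1, 4), c(1, 5), c(1, 6), c(2, 4), c(3, 4), c(2, 5)), 6)
  resFlat <- systemSegregation(flat, aff2)
  expect_equal(resFlat$withinDensity, resFlat$betweenDensity)
  expect_equal(resFlat$segregation, 0)
})

test_that("segregation agrees with its counting oracle and handles degenerate input", {
  set.seed(304)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    g <- randomBinaryGraph(n, stats::runif(1, 0.3, 0.7))
    memb <- sample(rep(c("A", "B", "C"), length.out = n))
    names(memb) <- roiLabels(g)
    aff <- AffiliationVector(memb)
    if (min(table(memb)) < 2) next
    res <- tryCatch(systemSegregation(g, aff),
                    adh_undefinedSegregation = function(e) NULL)
    if (is.null(res)) next
    expect_equal(res$segregation,
                 oracleSegregation(adjacencyMatrix(g), memb[roiLabels(g)]),
                 tolerance = 1e-12)
  }
  aff2 <- AffiliationVector(structure(rep(c("A", "B"), each = 3),
                                      names = sprintf("n%02d", 1:6)))
  onlyBetween <- mkGraph(list(c(1, 4), c(2, 5)), 6)
  expect_error(systemSegregation(onlyBetween, aff2),
               class = "adh_undefinedSegregation")
  affSingleton <- AffiliationVector(structure(c("A", rep("B", 5)),
                                              names = sprintf("n%02d", 1:6)))
  expect_error(systemSegregation(mkGraph(list(c(2, 3)), 6), affSingleton),
               class = "adh_singletonNetwork")
})

test_that("pairwise between-density mode averages over network pairs", {
  # unequal network sizes (3/2/2) so pooled and pairwise differ:
  # within all complete (zw = 1); A-B between saturated (6/6), A-C and B-C empty
  memb <- structure(rep(c("A", "B", "C"), c(3, 2, 2)),
                    names = sprintf("n%02d", 1:7))
  aff <- AffiliationVector(memb)
  g <- mkGraph(list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(6, 7),
                    c(1, 4), c(1, 5), c(2, 4), c(2, 5), c(3, 4), c(3, 5)), 7)
  pooled <- systemSegregation(g, aff, between = "pooled")
  pairwise <- systemSegregation(g, aff, between = "pairwise")
  expect_equal(pooled$betweenDensity, 6 / 16)
  expect_equal(pairwise$betweenDensity, mean(c(1, 0, 0)))
  expect_equal(pooled$segregation, 1 - 6 / 16)
  expect_equal(pairwise$segregation, 1 - 1 / 3)
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(305)
  g <- randomBinaryGraph(9, 0.4)
  a <- adjacencyMatrix(g)
  perm <- sample(9)
  gp <- BinaryGraph(a[perm, perm], roiLabels = roiLabels(g)[perm])
  expect_equal(unname(clusteringCoefficient(gp)$nodal),
               unname(clusteringCoefficient(g)$nodal[perm]))
  expect_equal(unname(localEfficiency(gp)$nodal),
               unname(localEfficiency(g)$nodal[perm]))
  expect_equal(unname(degreeCentrality(gp)), unname(degreeCentrality(g)[perm]))
  expect_equal(clusteringCoefficient(gp)$mean, clusteringCoefficient(g)$mean)
  expect_equal(globalEfficiency(gp), globalEfficiency(g))
})

test_that("the sweep metric table has the documented shape and limits", {
  # complete graph at every threshold: all three efficiency-type means are 1
  n <- 8
  r <- matrix(0.9, n, n); diag(r) <- 0
  labs <- sprintf("n%02d", 1:n)
  dimnames(r) <- list(labs, labs)
  w <- new("WeightedConnectome", r = r, roiLabels = labs, participantId = "p")
  aff <- AffiliationVector(structure(rep(c("A", "B"), each = 4), names = labs))
  graphs <- thresholdSweep(w)
  tab <- metricsOverSweep(graphs, aff, louvainReps = 0)
  glob <- tab[tab$scope == "GLOBAL", ]
  for (m in c("mean_clustering", "global_efficiency", "mean_local_efficiency"))
    expect_true(all(glob$value[glob$metric == m] == 1))
  one <- globalMetrics(graphs[[1]], aff, louvainReps = 5, seed = 1)
  expect_equal(one$mean_clustering, 1)
  expect_equal(one$global_efficiency, 1)
  expect_equal(one$modularity, 0)      # complete graph: one community
  expect_equal(one$threshold, 0.05)

  # one full-scale participant: 131 nodal rows x 10 thresholds per nodal metric
  coh <- simulateCohort(simParams(seed = 31, nParticipants = 3,
                                  groupSizes = c(meditation = 2, writing = 1)))
  sweep <- suppressWarnings(thresholdSweep(pearsonConnectome(coh$series[[1]])))
  full <- metricsOverSweep(sweep, coh$affiliation, louvainReps = 0)
  nodal <- full[full$metric == "clustering" & full$scope != "GLOBAL", ]
  expect_identical(nrow(nodal), 1310L)
  expect_identical(nrow(full[full$metric == "mean_clustering", ]), 10L)
  # segregation is non-decreasing along the grid on modular cohorts
  segs <- full$value[full$metric == "system_segregation"]
  expect_false(anyNA(segs))
  expect_true(all(diff(segs) >= -1e-9))
  # values stay in their analytic ranges
  expect_true(all(full$value[full$metric %in%
    c("clustering", "local_efficiency", "mean_clustering",
      "global_efficiency", "mean_local_efficiency")] >= 0))
  expect_true(all(full$value[full$metric %in%
    c("clustering", "local_efficiency", "mean_clustering",
      "global_efficiency", "mean_local_efficiency")] <= 1))
})
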