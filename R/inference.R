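# Vectorized permutation Pearson test; assumes inputs already validated.
# All nPerm permutations are drawn in one shot by ranking iid uniform keys
# within columns, then correlated against x with a single BLAS call.
.permCorOne <- function(x, y, nPerm, seed) {
  r <- stats::cor(x, y)
  set.seed(seed)
  n <- length(y)
  keys <- stats::runif(n * nPerm)
  o <- order(rep.int(seq_len(nPerm), rep.int(n, nPerm)), keys)
  Y <- matrix(y[((o - 1L) %% n) + 1L], n, nPerm)
  rp <- as.vector(stats::cor(x, Y))
  p <- (1 + sum(abs(rp) >= abs(r))) / (nPerm + 1)
  list(r = r, p = p)
}

#' Permutation test of a Pearson correlation
#'
#' Two-sided permutation test: the observed r is compared with the |r| of
#' `nPerm` random permutations of `y`, and the p-value uses the add-one
#' estimator `p = (1 + #{|r_perm| >= |r|}) / (nPerm + 1)`. The attainable
#' floor is therefore `1/(nPerm + 1)` (9.99E-04 at 1,000 permutations) and
#' p = 0 is never reported. Deterministic given `seed`.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), neither constant.
#' @param nPerm Number of permutations (default 1,000).
#' @param seed Seed for the permutation draws.
#' @return List with `r` (observed Pearson coefficient) and `p`.
#' @export
#' @examples
#' x <- rnorm(29)
#' permutationCorrelation(x, x, nPerm = 1000, seed = 1)$p  # the floor, 1/1001
permutationCorrelation <- function(x, y, nPerm = 1000L, seed = 1L) {
  if (length(x) != length(y))
    adhStop("lengthMismatch", "x and y must have equal length")
  if (length(x) < 3L)
    adhStop("tooFewObservations", "need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    adhStop("constantVector", "correlation undefined for a constant vector")
  if (nPerm < 1L) adhStop("badNPerm", "nPerm must be >= 1")
  .permCorOne(x, y, as.integer(nPerm), seed)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control: q-values are the BH-adjusted
#' p-values and the significance mask marks every test whose q-value is at
#' or below `q` (equivalently, all ordered p up to the largest i with
#' `p_(i) <= (i/m) q`).
#'
#' @param p Vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return List with `q` (adjusted values) and `significant` (logical mask).
#' @export
#' @examples
#' fdrBH(c(0.01, 0.02, 0.03, 0.04))$significant  # all TRUE at q = 0.05
fdrBH <- function(p, q = 0.05) {
  if (length(p) == 0L) adhStop("emptyInput", "no p-values supplied")
  if (any(p <= 0 | p > 1)) adhStop("badPValues", "p-values must lie in (0, 1]")
  qv <- stats::p.adjust(p, method = "BH")
  list(q = qv, significant = qv <= q)
}

# Subset the adherence table to a group and validate the outcome vector.
.scanCohort <- function(adherence, group, outcome) {
  stopifnot(group %in% c("all", "meditation", "writing"),
            outcome %in% c("homework", "attendance"))
  rows <- if (group == "all") seq_len(nrow(adherence))
          else which(adherence$group == group)
  if (length(rows) < 3L)
    adhStop("tooFewParticipants",
            "group '%s' has %d participants; scans need >= 3", group, length(rows))
  list(ids = adherence$participant_id[rows],
       y = as.numeric(adherence[[outcome]][rows]))
}

# Wide participant x node matrix of one metric at one threshold.
.metricMatrix <- function(tab, ids, nodes) {
  m <- matrix(NA_real_, length(ids), length(nodes),
              dimnames = list(ids, nodes))
  m[cbind(match(tab$participant_id, ids), match(tab$scope, nodes))] <- tab$value
  m
}

#' Nodal association scan
#'
#' For one nodal metric, one participant group, and one adherence outcome:
#' at every threshold of the grid, a permutation correlation per node, then
#' Benjamini-Hochberg FDR across the nodes within that threshold. Nodes
#' significant at `minSigThresholds` or more thresholds form the robust
#' set. Nodes whose metric is constant across participants at a threshold
#' (e.g. clustering identically zero in a fragmented graph) are recorded
#' with missing r/p and excluded from the FDR family.
#'
#' @param metricTable Long metric table from [cohortMetrics()] /
#'   [metricsOverSweep()].
#' @param adherence Adherence data.frame.
#' @param cfg A [RunConfig-class].
#' @param group "all", "meditation" or "writing".
#' @param outcome "homework" or "attendance".
#' @param metric Nodal metric name ("clustering", "degree" or
#'   "local_efficiency").
#' @param seed Run seed; each test draws its permutations from a seed
#'   derived from it.
#' @return List with `associations` (one row per node x threshold:
#'   scope, metric, threshold, group, outcome, r, p, q, significant) and
#'   `robustNodes` (node, nSignificant for nodes meeting the robust rule).
#' @export
nodalScan <- function(metricTable, adherence, cfg = runConfig(),
                      group = "all", outcome = "homework",
                      metric = "clustering", seed = 1L) {
  sc <- .scanCohort(adherence, group, outcome)
  if (stats::sd(sc$y) == 0)
    adhStop("constantVector", "outcome '%s' is constant in group '%s'",
            outcome, group)
  tab <- metricTable[metricTable$metric == metric &
                     metricTable$scope != "GLOBAL" &
                     metricTable$participant_id %in% sc$ids, ]
  if (nrow(tab) == 0L)
    adhStop("emptyInput", "metric '%s' not present in the metric table", metric)
  thresholds <- sort(unique(tab$threshold))
  nodes <- unique(tab$scope)
  res <- vector("list", length(thresholds))
  for (ti in seq_along(thresholds)) {
    sub <- tab[tab$threshold == thresholds[ti], ]
    m <- .metricMatrix(sub, sc$ids, nodes)
    r <- rep(NA_real_, length(nodes))
    p <- rep(NA_real_, length(nodes))
    for (j in seq_along(nodes)) {
      x <- m[, j]
      if (anyNA(x) || stats::sd(x) == 0) next
      out <- .permCorOne(x, sc$y, cfg@nPerm, deriveSeed(seed, 7L, ti, j))
      r[j] <- out$r
      p[j] <- out$p
    }
    qv <- rep(NA_real_, length(nodes))
    sig <- rep(FALSE, length(nodes))
    ok <- !is.na(p)
    if (any(ok)) {
      bh <- fdrBH(p[ok], cfg@fdrQ)
      qv[ok] <- bh$q
      sig[ok] <- bh$significant
    }
    res[[ti]] <- data.frame(
      scope = nodes, metric = metric, threshold = thresholds[ti],
      group = group, outcome = outcome, r = r, p = p, q = qv,
      significant = sig
    )
  }
  assoc <- do.call(rbind, res)
  if (cfg@minSigThresholds > length(thresholds))
    adhWarn("impossibleCriterion",
            "minSigThresholds = %d exceeds the %d thresholds tested: robust set is provably empty",
            cfg@minSigThresholds, length(thresholds))
  counts <- tapply(assoc$significant, assoc$scope, sum)
  robust <- data.frame(node = names(counts),
                       nSignificant = as.integer(counts))
  robust <- robust[robust$nSignificant >= cfg@minSigThresholds, , drop = FALSE]
  robust <- robust[order(-robust$nSignificant, robust$node), , drop = FALSE]
  rownames(robust) <- NULL
  list(associations = assoc, robustNodes = robust)
}

#' Global association scan
#'
#' Permutation correlation between every global metric and the adherence
#' outcome at every threshold, with Benjamini-Hochberg FDR across the whole
#' family (all global metrics x thresholds within this group/outcome).
#' Cells with a missing metric value (e.g. undefined segregation) are
#' excluded from the family.
#'
#' @inheritParams nodalScan
#' @param metrics Which global metrics to test; defaults to every global
#'   metric present in the table.
#' @return data.frame of association results (scope = "GLOBAL").
#' @export
globalScan <- function(metricTable, adherence, cfg = runConfig(),
                       group = "all", outcome = "homework",
                       metrics = NULL, seed = 1L) {
  sc <- .scanCohort(adherence, group, outcome)
  if (stats::sd(sc$y) == 0)
    adhStop("constantVector", "outcome '%s' is constant in group '%s'",
            outcome, group)
  tab <- metricTable[metricTable$scope == "GLOBAL" &
                     metricTable$participant_id %in% sc$ids, ]
  if (!is.null(metrics)) tab <- tab[tab$metric %in% metrics, ]
  if (nrow(tab) == 0L)
    adhStop("emptyInput", "no global metrics found in the metric table")
  mets <- unique(tab$metric)
  thresholds <- sort(unique(tab$threshold))
  grid <- expand.grid(metric = mets, threshold = thresholds,
                      stringsAsFactors = FALSE)
  r <- rep(NA_real_, nrow(grid))
  p <- rep(NA_real_, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    sub <- tab[tab$metric == grid$metric[k] &
               tab$threshold == grid$threshold[k], ]
    x <- sub$value[match(sc$ids, sub$participant_id)]
    if (anyNA(x) || stats::sd(x) == 0) next
    out <- .permCorOne(x, sc$y, cfg@nPerm,
                       deriveSeed(seed, 13L, match(grid$metric[k], mets),
                                  match(grid$threshold[k], thresholds)))
    r[k] <- out$r
    p[k] <- out$p
  }
  qv <- rep(NA_real_, nrow(grid))
  sig <- rep(FALSE, nrow(grid))
  ok <- !is.na(p)
  if (any(ok)) {
    bh <- fdrBH(p[ok], cfg@fdrQ)
    qv[ok] <- bh$q
    sig[ok] <- bh$significant
  }
  data.frame(
    scope = "GLOBAL", metric = grid$metric, threshold = grid$threshold,
    group = group, outcome = outcome, r = r, p = p, q = qv,
    significant = sig
  )
}

#' Robust-node counts per resting-state network
#'
#' Tallies the robust nodes of a scan by the resting-state network they
#' belong to (the bar-graph summary of which systems carry the adherence
#' association).
#'
#' @param robustNodes The `robustNodes` data.frame from [nodalScan()].
#' @param aff An [AffiliationVector-class] covering all robust nodes.
#' @return data.frame with columns `network` and `count` (all networks,
#'   zeros included); counts sum to the robust-set size.
#' @export
networkSummary <- function(robustNodes, aff) {
  stopifnot(is(aff, "AffiliationVector"))
  map <- affiliations(aff)
  nets <- networkNames(aff)
  if (nrow(robustNodes) == 0L)
    return(data.frame(network = nets, count = 0L))
  missing <- setdiff(robustNodes$node, names(map))
  if (length(missing))
    adhStop("unaffiliatedRoi", "no affiliation for node(s): %s",
            paste(utils::head(missing, 5), collapse = ", "))
  counts <- table(factor(map[robustNodes$node], levels = nets))
  data.frame(network = nets, count = as.integer(counts))
}
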