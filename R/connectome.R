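#' Pairwise Pearson connectome of one participant
#'
#' Computes the full matrix of pairwise Pearson correlation coefficients
#' between ROI time series and zeroes the diagonal, yielding the weighted
#' connectivity graph that the threshold sweep binarizes.
#'
#' @param ts A [RoiTimeSeriesSet-class].
#' @return A [WeightedConnectome-class].
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 4, 3), c = c(4, 3, 2, 1))
#' connectivityMatrix(pearsonConnectome(RoiTimeSeriesSet("s1", m)))
pearsonConnectome <- function(ts) {
  stopifnot(is(ts, "RoiTimeSeriesSet"))
  m <- seriesMatrix(ts)
  if (nrow(m) < 3L)
    adhStop("tooFewTimepoints",
            "correlation undefined with %d timepoints (need >= 3)", nrow(m))
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    adhStop("zeroVariance", "constant time series for ROI(s): %s",
            paste(roiLabels(ts)[sds == 0], collapse = ", "))
  r <- stats::cor(m)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  new("WeightedConnectome", r = r, roiLabels = roiLabels(ts),
      participantId = participantId(ts))
}

#' Binarize a weighted connectome at a threshold
#'
#' Keeps an edge wherever the correlation strictly exceeds T (`r > T`);
#' ties and all negative correlations are dropped. With
#' `absolute = TRUE` the rule becomes `|r| > T`. Thresholds above 0.5 risk
#' keeping noisy or physiologically weak connections and trigger a warning,
#' as do thresholds below 0.05.
#'
#' @param w A [WeightedConnectome-class].
#' @param threshold Correlation threshold T in (0, 1).
#' @param absolute Binarize on `|r|` instead of signed r.
#' @return A [BinaryGraph-class].
#' @export
#' @examples
#' m <- matrix(rnorm(300), 30, 10)
#' g <- binarize(pearsonConnectome(RoiTimeSeriesSet("s1", m)), 0.3)
#' sum(adjacencyMatrix(g)) / 2  # edge count
binarize <- function(w, threshold, absolute = FALSE) {
  stopifnot(is(w, "WeightedConnectome"))
  if (threshold <= 0 || threshold >= 1)
    adhStop("badThreshold", "threshold must lie in (0, 1), got %s",
            format(threshold))
  if (threshold > 0.5)
    adhWarn("thresholdRange",
            "threshold %s exceeds 0.5: risk of keeping noisy or weak connections",
            format(threshold))
  if (threshold < 0.05)
    adhWarn("thresholdRange",
            "threshold %s is below 0.05: graphs may saturate", format(threshold))
  r <- connectivityMatrix(w)
  a <- if (absolute) abs(r) > threshold else r > threshold
  storage.mode(a) <- "integer"
  diag(a) <- 0L
  new("BinaryGraph", adjacency = a, threshold = threshold,
      roiLabels = roiLabels(w), participantId = participantId(w))
}

#' Binarize over a threshold grid
#'
#' One [BinaryGraph-class] per grid value, in grid order. Because the edge
#' rule is a strict cut on the same correlations, the graphs are nested:
#' every edge present at a higher threshold is present at every lower one,
#' so edge counts are non-increasing along the grid.
#'
#' @param w A [WeightedConnectome-class].
#' @param grid Strictly increasing thresholds; default 0.05 to 0.5 in steps
#'   of 0.05.
#' @param absolute Passed to [binarize()].
#' @return List of [BinaryGraph-class] objects.
#' @export
thresholdSweep <- function(w, grid = seq(0.05, 0.5, by = 0.05),
                           absolute = FALSE) {
  if (length(grid) == 0L) adhStop("emptyGrid", "threshold grid is empty")
  grid <- round(grid, 10)   # collapse seq() floating-point dust
  if (any(diff(grid) <= 0))
    adhStop("badGrid", "threshold grid must be strictly increasing")
  lapply(grid, function(t) binarize(w, t, absolute = absolute))
}
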