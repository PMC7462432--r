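#' Per-participant ROI time-series container
#'
#' Holds one participant's parcellated BOLD-like signal: a numeric matrix
#' with timepoints in rows and regions of interest (ROIs) in columns, plus
#' the ordered ROI labels. The reference study extracted 131 ROI-averaged
#' time series per participant from a 5-minute resting-state scan.
#'
#' @slot participantId Single participant identifier.
#' @slot series Numeric matrix, timepoints x ROIs, no missing values.
#' @slot roiLabels Character vector of unique ROI labels, one per column.
#' @export
setClass("RoiTimeSeriesSet",
  representation(
    participantId = "character",
    series        = "matrix",
    roiLabels     = "character"
  )
)

setValidity("RoiTimeSeriesSet", function(object) {
  s <- object@series
  if (length(object@participantId) != 1L) return("participantId must be a single string")
  if (!is.numeric(s)) return("series must be numeric")
  if (nrow(s) < 3L) return("series needs at least 3 timepoints")
  if (ncol(s) < 2L) return("series needs at least 2 ROIs")
  if (anyNA(s) || any(!is.finite(s))) return("series contains missing or non-finite values")
  if (length(object@roiLabels) != ncol(s)) return("one ROI label per series column required")
  if (anyDuplicated(object@roiLabels)) return("roiLabels must be unique")
  TRUE
})

#' Construct a [RoiTimeSeriesSet-class]
#'
#' @param participantId Participant identifier.
#' @param series Numeric matrix, timepoints x ROIs.
#' @param roiLabels ROI labels; defaults to the column names of `series`.
#' @return A validated `RoiTimeSeriesSet`.
#' @export
#' @examples
#' m <- matrix(rnorm(40), nrow = 10, dimnames = list(NULL, paste0("R", 1:4)))
#' RoiTimeSeriesSet("sub01", m)
RoiTimeSeriesSet <- function(participantId, series, roiLabels = colnames(series)) {
  if (is.null(roiLabels)) roiLabels <- sprintf("ROI%03d", seq_len(ncol(series)))
  colnames(series) <- roiLabels
  new("RoiTimeSeriesSet",
      participantId = as.character(participantId),
      series = series, roiLabels = as.character(roiLabels))
}

#' Node-to-network affiliation vector
#'
#' Maps every ROI label to the resting-state network it belongs to. The
#' canonical parcellation uses five networks (subcortical, sensory, default
#' mode, attention/executive, language/memory); other counts are accepted
#' with a warning unless strict loading is requested.
#'
#' @slot affiliations Named character vector: names are ROI labels, values
#'   network names.
#' @export
setClass("AffiliationVector",
  representation(affiliations = "character")
)

setValidity("AffiliationVector", function(object) {
  a <- object@affiliations
  if (length(a) == 0L) return("affiliation vector is empty")
  if (is.null(names(a)) || any(names(a) == "")) return("every ROI needs a label")
  if (anyDuplicated(names(a))) return("duplicated ROI labels")
  if (anyNA(a) || any(a == "")) return("every ROI needs a network name")
  TRUE
})

#' Construct an [AffiliationVector-class]
#'
#' @param affiliations Named character vector mapping ROI label to network.
#' @return A validated `AffiliationVector`.
#' @export
#' @examples
#' AffiliationVector(c(R1 = "subcortical", R2 = "sensory"))
AffiliationVector <- function(affiliations) {
  new("AffiliationVector", affiliations = affiliations)
}

#' Weighted Pearson connectome
#'
#' Symmetric matrix of pairwise Pearson correlation coefficients between all
#' ROI time series of one participant, with the diagonal fixed at zero.
#'
#' @slot r Numeric n x n symmetric matrix, zero diagonal, entries in [-1, 1].
#' @slot roiLabels ROI labels in matrix order.
#' @slot participantId Participant the connectome belongs to.
#' @export
setClass("WeightedConnectome",
  representation(
    r             = "matrix",
    roiLabels     = "character",
    participantId = "character"
  )
)

setValidity("WeightedConnectome", function(object) {
  r <- object@r
  if (nrow(r) != ncol(r)) return("connectome must be square")
  if (length(object@roiLabels) != nrow(r)) return("one label per node required")
  if (max(abs(r - t(r))) > 1e-12) return("connectome must be symmetric")
  if (any(abs(diag(r)) > 0)) return("diagonal must be zero")
  off <- r[upper.tri(r)]
  if (any(off < -1 - 1e-12 | off > 1 + 1e-12)) return("correlations must lie in [-1, 1]")
  TRUE
})

#' Binary graph at a correlation threshold
#'
#' Undirected, unweighted adjacency obtained by keeping the edges whose
#' correlation strictly exceeds the threshold T; ties and negative
#' correlations carry no edge.
#'
#' @slot adjacency Integer n x n symmetric 0/1 matrix with zero diagonal.
#' @slot threshold The correlation threshold T used.
#' @slot roiLabels Node labels in matrix order.
#' @slot participantId Participant the graph belongs to.
#' @export
setClass("BinaryGraph",
  representation(
    adjacency     = "matrix",
    threshold     = "numeric",
    roiLabels     = "character",
    participantId = "character"
  )
)

setValidity("BinaryGraph", function(object) {
  a <- object@adjacency
  if (nrow(a) != ncol(a)) return("adjacency must be square")
  if (!all(a %in% c(0L, 1L))) return("adjacency entries must be 0/1")
  if (any(a != t(a))) return("adjacency must be symmetric")
  if (any(diag(a) != 0L)) return("diagonal must be zero")
  if (length(object@roiLabels) != nrow(a)) return("one label per node required")
  if (length(object@threshold) != 1L) return("threshold must be a single value")
  TRUE
})

#' Construct a [BinaryGraph-class] from an adjacency matrix
#'
#' Mostly useful in examples and tests; analysis graphs come from
#' [binarize()].
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param threshold Threshold annotation (default `NA`).
#' @param roiLabels Node labels.
#' @param participantId Participant annotation.
#' @return A validated `BinaryGraph`.
#' @export
BinaryGraph <- function(adjacency, threshold = NA_real_,
                        roiLabels = colnames(adjacency),
                        participantId = NA_character_) {
  if (is.null(roiLabels)) roiLabels <- sprintf("n%02d", seq_len(nrow(adjacency)))
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(roiLabels, roiLabels)
  new("BinaryGraph", adjacency = adjacency, threshold = threshold,
      roiLabels = as.character(roiLabels),
      participantId = as.character(participantId))
}

#' Analysis run configuration
#'
#' Bundles the tunable constants of the analysis protocol. Defaults follow
#' the reference protocol: a sparsity threshold grid from 0.05 to 0.5 in
#' steps of 0.05, 1,000 permutations per test, FDR at 0.05, a robust-node
#' rule of at least 3 significant thresholds, a high-adherence cutoff of
#' more than 10 completed assignments, a stratified hold-out of a quarter of
#' participants, five cross-validation seeds, and 150 Louvain repetitions.
#'
#' @slot thresholdGrid Strictly increasing correlation thresholds in (0, 1).
#' @slot nPerm Number of permutations per correlation test.
#' @slot fdrQ FDR level for Benjamini-Hochberg correction.
#' @slot minSigThresholds Minimum number of FDR-significant thresholds for a
#'   node to count as robust.
#' @slot homeworkCutoff Completed assignments strictly above this value
#'   define the high-adherence class.
#' @slot holdoutFraction Fraction of participants held out for testing.
#' @slot seeds Integer seeds for classifier cross-validation repeats.
#' @slot louvainReps Louvain repetitions averaged into mean Q.
#' @slot absoluteThreshold If `TRUE`, binarize on |r| > T instead of r > T.
#' @slot segregationBetween Either "pooled" (between-network edges treated
#'   as one class) or "pairwise" (density averaged over network pairs).
#' @slot referenceThreshold Threshold at which classifier features are read.
#' @export
setClass("RunConfig",
  representation(
    thresholdGrid      = "numeric",
    nPerm              = "integer",
    fdrQ               = "numeric",
    minSigThresholds   = "integer",
    homeworkCutoff     = "integer",
    holdoutFraction    = "numeric",
    seeds              = "integer",
    louvainReps        = "integer",
    absoluteThreshold  = "logical",
    segregationBetween = "character",
    referenceThreshold = "numeric"
  )
)

setValidity("RunConfig", function(object) {
  g <- object@thresholdGrid
  if (length(g) == 0L) return("threshold grid is empty")
  if (any(diff(g) <= 0)) return("threshold grid must be strictly increasing")
  if (any(g <= 0 | g >= 1)) return("thresholds must lie in (0, 1)")
  if (object@nPerm < 1L) return("nPerm must be positive")
  if (object@fdrQ <= 0 || object@fdrQ >= 1) return("fdrQ must lie in (0, 1)")
  if (object@minSigThresholds < 1L) return("minSigThresholds must be positive")
  if (object@holdoutFraction <= 0 || object@holdoutFraction >= 1)
    return("holdoutFraction must lie in (0, 1)")
  if (length(object@seeds) < 1L) return("at least one seed required")
  if (object@louvainReps < 1L) return("louvainReps must be positive")
  if (!object@segregationBetween %in% c("pooled", "pairwise"))
    return("segregationBetween must be 'pooled' or 'pairwise'")
  TRUE
})

#' Construct a [RunConfig-class]
#'
#' @param thresholdGrid,nPerm,fdrQ,minSigThresholds,homeworkCutoff,holdoutFraction,seeds,louvainReps,absoluteThreshold,segregationBetween,referenceThreshold
#'   See the class documentation; defaults are the reference protocol.
#' @return A validated `RunConfig`.
#' @export
#' @examples
#' runConfig()
#' runConfig(nPerm = 200, thresholdGrid = c(0.1, 0.2, 0.3))
runConfig <- function(thresholdGrid = seq(0.05, 0.5, by = 0.05),
                      nPerm = 1000L,
                      fdrQ = 0.05,
                      minSigThresholds = 3L,
                      homeworkCutoff = 10L,
                      holdoutFraction = 0.25,
                      seeds = 1:5,
                      louvainReps = 150L,
                      absoluteThreshold = FALSE,
                      segregationBetween = "pooled",
                      referenceThreshold = 0.35) {
  new("RunConfig",
      # round away seq() floating-point dust so grid values compare equal
      # to literals like 0.35
      thresholdGrid = round(as.numeric(thresholdGrid), 10),
      nPerm = as.integer(nPerm),
      fdrQ = as.numeric(fdrQ),
      minSigThresholds = as.integer(minSigThresholds),
      homeworkCutoff = as.integer(homeworkCutoff),
      holdoutFraction = as.numeric(holdoutFraction),
      seeds = as.integer(seeds),
      louvainReps = as.integer(louvainReps),
      absoluteThreshold = isTRUE(absoluteThreshold),
      segregationBetween = match.arg(segregationBetween, c("pooled", "pairwise")),
      referenceThreshold = as.numeric(referenceThreshold))
}

#' Synthetic cohort generator parameters
#'
#' Parameters of the latent-factor cohort simulator. Each participant p
#' draws a within-network coupling weight w_p ~ Normal(couplingMean,
#' couplingSd^2) truncated at zero; ROI i in network s then follows
#' `w_p * latent_s + globalWeight * global + noise`, where `latent_s` and
#' `global` are independent standard Gaussian series over timepoints.
#' Adherence scores are linear in w_p with Gaussian noise, rounded and
#' clipped to their questionnaire ranges, so the analysis can be asked to
#' recover a planted coupling-adherence association (or, with
#' `effectSlope = 0`, its absence).
#'
#' @slot nParticipants Cohort size (reference cohort: 51).
#' @slot groupSizes Named integer split across the two programs
#'   (meditation 29, writing 22).
#' @slot nRoi Number of ROIs (131).
#' @slot nTimepoints Retained scan volumes (145).
#' @slot networkSizes Five network sizes summing to `nRoi`.
#' @slot couplingMean,couplingSd Mean and SD of the within-network signal
#'   weight w_p.
#' @slot globalWeight Weight of the shared global signal.
#' @slot noiseSd SD of the per-timepoint observation noise.
#' @slot effectSlope Homework units gained per unit of coupling (b).
#' @slot effectNoiseSd SD of the homework noise.
#' @slot attendanceSlope,attendanceNoiseSd Analogous slope and noise for
#'   class attendance.
#' @slot effectSlopeByGroup Optional named per-group overrides of
#'   `effectSlope` (names among "meditation", "writing").
#' @slot homeworkMax,attendanceMax Questionnaire maxima (20 and 4).
#' @slot seed Master seed of the cohort.
#' @export
setClass("SimParams",
  representation(
    nParticipants      = "integer",
    groupSizes         = "integer",
    nRoi               = "integer",
    nTimepoints        = "integer",
    networkSizes       = "integer",
    couplingMean       = "numeric",
    couplingSd         = "numeric",
    globalWeight       = "numeric",
    noiseSd            = "numeric",
    effectSlope        = "numeric",
    effectNoiseSd      = "numeric",
    attendanceSlope    = "numeric",
    attendanceNoiseSd  = "numeric",
    effectSlopeByGroup = "numeric",
    homeworkMax        = "integer",
    attendanceMax      = "integer",
    seed               = "integer"
  )
)

setValidity("SimParams", function(object) {
  if (object@nParticipants < 3L) return("inference requires at least 3 participants")
  if (sum(object@groupSizes) != object@nParticipants)
    return("group sizes must sum to nParticipants")
  if (length(object@networkSizes) != 5L) return("exactly 5 network sizes required")
  if (any(object@networkSizes < 2L)) return("every network needs at least 2 ROIs")
  if (sum(object@networkSizes) != object@nRoi)
    return("network sizes must sum to nRoi")
  if (object@nTimepoints < 3L) return("at least 3 timepoints required")
  if (object@couplingSd < 0 || object@noiseSd < 0 ||
      object@effectNoiseSd < 0 || object@attendanceNoiseSd < 0)
    return("standard deviations must be non-negative")
  if (object@noiseSd == 0 && object@couplingSd == 0)
    return("noiseSd = 0 with couplingSd = 0 makes all series collinear")
  if (length(object@effectSlopeByGroup) &&
      !all(names(object@effectSlopeByGroup) %in% c("meditation", "writing")))
    return("effectSlopeByGroup names must be 'meditation'/'writing'")
  TRUE
})
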