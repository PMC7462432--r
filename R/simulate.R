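#' Construct [SimParams-class] with study-scale defaults
#'
#' Defaults emulate the reference cohort: 51 participants split 29/22
#' across meditation and writing programs, 131 ROIs over five resting-state
#' networks, 145 retained volumes, homework on a 0-20 scale and attendance
#' on 0-4. The generative constants (coupling distribution, global signal,
#' noise, effect slopes) are a calibration choice documented in the methods
#' vignette: they place the pooled correlation between mean clustering and
#' homework near 0.3, the order of magnitude the nodal/global scans are
#' expected to detect.
#'
#' @param nParticipants,groupSizes,nRoi,nTimepoints,networkSizes,couplingMean,couplingSd,globalWeight,noiseSd,effectSlope,effectNoiseSd,attendanceSlope,attendanceNoiseSd,effectSlopeByGroup,homeworkMax,attendanceMax,seed
#'   See [SimParams-class].
#' @return A validated `SimParams` object.
#' @export
#' @examples
#' simParams(nParticipants = 10, groupSizes = c(meditation = 6, writing = 4),
#'           nRoi = 20, networkSizes = c(4, 4, 4, 4, 4), seed = 1)
simParams <- function(nParticipants = 51L,
                      groupSizes = c(meditation = 29L, writing = 22L),
                      nRoi = 131L,
                      nTimepoints = 145L,
                      networkSizes = c(27L, 26L, 26L, 26L, 26L),
                      couplingMean = 1,
                      couplingSd = 0.3,
                      globalWeight = 0.3,
                      noiseSd = 1,
                      effectSlope = 10,
                      effectNoiseSd = 3,
                      attendanceSlope = 2.4,
                      attendanceNoiseSd = 0.8,
                      effectSlopeByGroup = numeric(0),
                      homeworkMax = 20L,
                      attendanceMax = 4L,
                      seed = 1L) {
  if (nParticipants < 3L)
    adhStop("tooFewParticipants", "inference requires at least 3 participants")
  if (noiseSd == 0 && couplingSd == 0)
    adhStop("degenerateParams",
            "noiseSd = 0 with couplingSd = 0 makes all series collinear")
  new("SimParams",
      nParticipants = as.integer(nParticipants),
      groupSizes = structure(as.integer(groupSizes), names = names(groupSizes)),
      nRoi = as.integer(nRoi),
      nTimepoints = as.integer(nTimepoints),
      networkSizes = as.integer(networkSizes),
      couplingMean = as.numeric(couplingMean),
      couplingSd = as.numeric(couplingSd),
      globalWeight = as.numeric(globalWeight),
      noiseSd = as.numeric(noiseSd),
      effectSlope = as.numeric(effectSlope),
      effectNoiseSd = as.numeric(effectNoiseSd),
      attendanceSlope = as.numeric(attendanceSlope),
      attendanceNoiseSd = as.numeric(attendanceNoiseSd),
      effectSlopeByGroup = effectSlopeByGroup,
      homeworkMax = as.integer(homeworkMax),
      attendanceMax = as.integer(attendanceMax),
      seed = as.integer(seed))
}

# Truncated-at-zero normal draw by rejection; couplingSd is small relative
# to couplingMean at defaults, so rejection is rare.
rtruncnorm0 <- function(n, mean, sd) {
  out <- rnorm(n, mean, sd)
  while (any(bad <- out < 0)) out[bad] <- rnorm(sum(bad), mean, sd)
  out
}

#' Simulate a cohort with planted modular structure
#'
#' Latent-factor generator: each of five networks has one latent Gaussian
#' series per participant, plus a shared global series. ROI i in network s
#' follows `w_p * latent_s + globalWeight * global + noise`, where the
#' participant-level coupling `w_p ~ N(couplingMean, couplingSd^2)`
#' truncated at zero is the single scalar the analysis should recover:
#' within-network correlation rises with `w_p` while between-network
#' correlation falls, so clustering and system segregation increase and
#' global efficiency decreases with `w_p` in the thresholded graphs.
#' Homework is `round(clip(a + effectSlope * w_p + noise, 0, homeworkMax))`
#' with the intercept chosen so the expected mean sits near
#' `homeworkMax / 2`; attendance is generated analogously. Everything is
#' deterministic given `params@seed`.
#'
#' @param params A [SimParams-class] object.
#' @return A list with `series` (list of [RoiTimeSeriesSet-class]),
#'   `adherence` (data.frame), `affiliation` ([AffiliationVector-class]),
#'   `coupling` (the true w_p vector, named by participant), and `params`
#'   (provenance, with the effect slopes actually used).
#' @seealso [simulateNullCohort()] for the matched no-effect variant.
#' @export
#' @examples
#' p <- simParams(nParticipants = 6, groupSizes = c(meditation = 3, writing = 3),
#'                nRoi = 15, networkSizes = rep(3L, 5), nTimepoints = 40, seed = 7)
#' coh <- simulateCohort(p)
#' coh$adherence
simulateCohort <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  set.seed(params@seed)
  n  <- params@nParticipants
  tp <- params@nTimepoints
  nets <- rep(CANONICAL_NETWORKS, params@networkSizes)
  roi <- sprintf("ROI%03d", seq_len(params@nRoi))
  groups <- rep(names(params@groupSizes), params@groupSizes)
  ids <- sprintf("sub%03d", seq_len(n))

  w <- rtruncnorm0(n, params@couplingMean, params@couplingSd)
  names(w) <- ids

  slope <- rep(params@effectSlope, n)
  if (length(params@effectSlopeByGroup)) {
    for (g in names(params@effectSlopeByGroup))
      slope[groups == g] <- params@effectSlopeByGroup[[g]]
  }

  series <- vector("list", n)
  netIdx <- match(nets, CANONICAL_NETWORKS)
  for (p in seq_len(n)) {
    latent <- matrix(rnorm(tp * 5L), tp, 5L)
    global <- rnorm(tp)
    noise <- matrix(rnorm(tp * params@nRoi, sd = params@noiseSd), tp, params@nRoi)
    m <- w[p] * latent[, netIdx] + params@globalWeight * global + noise
    colnames(m) <- roi
    series[[p]] <- RoiTimeSeriesSet(ids[p], m)
  }

  aHw <- params@homeworkMax / 2 - mean(slope) * params@couplingMean
  homework <- round(clip(aHw + slope * w + rnorm(n, sd = params@effectNoiseSd),
                         0, params@homeworkMax))
  aAtt <- params@attendanceMax / 2 - params@attendanceSlope * params@couplingMean
  attendance <- round(clip(aAtt + params@attendanceSlope * w +
                             rnorm(n, sd = params@attendanceNoiseSd),
                           0, params@attendanceMax))

  adherence <- data.frame(
    participant_id = ids,
    group = groups,
    homework = as.integer(homework),
    attendance = as.integer(attendance),
    stringsAsFactors = FALSE
  )
  affiliation <- AffiliationVector(structure(nets, names = roi))
  list(series = series, adherence = adherence, affiliation = affiliation,
       coupling = w, params = params)
}

#' Simulate a null cohort (no coupling-adherence effect)
#'
#' Convenience wrapper around [simulateCohort()] that forces both effect
#' slopes to zero, so adherence is pure noise with respect to the planted
#' network structure. Used for type-I-error and false-discovery checks.
#'
#' @param params A [SimParams-class] object; its slopes are overridden.
#' @return As [simulateCohort()]; `params` in the result records the zero
#'   slopes actually used.
#' @export
simulateNullCohort <- function(params) {
  stopifnot(is(params, "SimParams"))
  params@effectSlope <- 0
  params@attendanceSlope <- 0
  params@effectSlopeByGroup <- numeric(0)
  simulateCohort(params)
}
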