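#' Run the full adherence-prediction pipeline
#'
#' End-to-end orchestration: load (or simulate) a cohort, build per-
#' participant Pearson connectomes, binarize over the threshold grid,
#' compute the metric table, run the global and nodal permutation scans
#' for the requested groups and outcomes, summarize robust nodes by
#' resting-state network, and classify high/low adherence from nodal
#' features at the reference threshold. All result tables are written to
#' `outDir` as TSV, together with a machine-readable `run.json` recording
#' the configuration, seeds and input digests needed to re-execute the
#' run.
#'
#' @param input Either a [SimParams-class] (a synthetic cohort is
#'   generated and written under `outDir/cohort`) or the path to a cohort
#'   manifest readable by [readCohort()].
#' @param cfg A [RunConfig-class].
#' @param outDir Output directory for result tables and the run record.
#' @param affiliationPath Affiliation file when `input` is a manifest path
#'   (defaults to `affiliations.tsv` next to the manifest).
#' @param groups Participant groups to scan.
#' @param outcomes Adherence outcomes to scan.
#' @param seed Run seed; all stochastic stages derive their seeds from it.
#' @param classify Run the classification stage (needs a non-empty robust
#'   set and both label classes).
#' @return Invisibly, a list with the cohort, metric table, scan results,
#'   network summaries and classifier report.
#' @export
runPipeline <- function(input, cfg = runConfig(), outDir,
                        affiliationPath = NULL,
                        groups = "all",
                        outcomes = c("homework", "attendance"),
                        seed = 1L, classify = TRUE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is(input, "SimParams")) {
    cohort <- simulateCohort(input)
    manifestPath <- writeCohort(cohort$series, cohort$adherence,
                                cohort$affiliation, file.path(outDir, "cohort"))
    aff <- cohort$affiliation
    adherence <- cohort$adherence
    series <- cohort$series
  } else {
    manifestPath <- input
    loaded <- readCohort(manifestPath)
    series <- loaded$series
    adherence <- loaded$adherence
    if (is.null(affiliationPath))
      affiliationPath <- file.path(dirname(manifestPath), "affiliations.tsv")
    aff <- readAffiliations(affiliationPath, roiLabels(series[[1L]]))
  }

  metricTable <- cohortMetrics(series, aff, cfg, seed = deriveSeed(seed, 1L))
  utils::write.table(metricTable, file.path(outDir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  globalRes <- list()
  nodalRes <- list()
  netSummaries <- list()
  for (g in groups) for (oc in outcomes) {
    key <- paste(g, oc, sep = ".")
    globalRes[[key]] <- globalScan(metricTable, adherence, cfg, g, oc,
                                   seed = deriveSeed(seed, 2L))
    for (met in c("clustering", "degree")) {
      nk <- paste(key, met, sep = ".")
      nodalRes[[nk]] <- nodalScan(metricTable, adherence, cfg, g, oc, met,
                                  seed = deriveSeed(seed, 3L))
      netSummaries[[nk]] <- networkSummary(nodalRes[[nk]]$robustNodes, aff)
    }
  }
  writeScan <- function(lst, getter, file) {
    rows <- do.call(rbind, lapply(names(lst), function(k) {
      d <- getter(lst[[k]])
      if (is.null(d) || nrow(d) == 0L) return(NULL)
      cbind(scan = k, d)
    }))
    if (!is.null(rows))
      utils::write.table(rows, file.path(outDir, file), sep = "\t",
                         row.names = FALSE, quote = FALSE)
  }
  writeScan(globalRes, identity, "global_associations.tsv")
  writeScan(nodalRes, function(x) x$associations, "nodal_associations.tsv")
  writeScan(nodalRes, function(x) x$robustNodes, "robust_nodes.tsv")
  writeScan(netSummaries, identity, "network_summary.tsv")

  classifierReport <- NULL
  if (classify) {
    labels <- labelBinarize(adherence, cfg@homeworkCutoff)
    robust <- list(
      clustering = nodalRes[["all.homework.clustering"]]$robustNodes,
      degree = nodalRes[["all.homework.degree"]]$robustNodes
    )
    nFeatures <- sum(vapply(robust, function(r)
      if (is.null(r)) 0L else nrow(r), integer(1)))
    if (nFeatures == 0L) {
      message("classification skipped: no robust nodes")
    } else if (min(table(labels$label)) < 2L) {
      message("classification skipped: a label class has < 2 members")
    } else {
      x <- buildFeatureTable(metricTable, robust, cfg@referenceThreshold)
      y <- labels$label[match(rownames(x), labels$participant_id)]
      split <- holdoutSplit(y, cfg@holdoutFraction, deriveSeed(seed, 4L))
      xTrain <- x[split$train, , drop = FALSE]
      yTrain <- y[split$train]
      keep <- if (ncol(x) >= 2L)
        backwardElimination(xTrain, yTrain, deriveSeed(seed, 5L))$features
      else colnames(x)
      classifierReport <- trainAndEvaluate(
        xTrain[, keep, drop = FALSE], yTrain,
        x[split$heldout, keep, drop = FALSE], y[split$heldout], cfg)
      aucTab <- data.frame(
        classifier = names(classifierReport$classifiers),
        cvMean = vapply(classifierReport$classifiers, `[[`, 0, "cvMean"),
        cvHalfWidth = vapply(classifierReport$classifiers, `[[`, 0, "cvHalfWidth"),
        heldoutAccuracy = vapply(classifierReport$classifiers, `[[`, 0,
                                 "heldoutAccuracy"),
        auc = vapply(classifierReport$classifiers, `[[`, 0, "auc")
      )
      utils::write.table(aucTab, file.path(outDir, "classifier_report.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  cfgList <- sapply(slotNames(cfg), function(s) methods::slot(cfg, s),
                    simplify = FALSE)
  digests <- list()
  if (file.exists(manifestPath))
    digests$manifest <- unname(tools::md5sum(manifestPath))
  if (!is.null(affiliationPath) && file.exists(affiliationPath))
    digests$affiliations <- unname(tools::md5sum(affiliationPath))
  record <- list(
    package = "AdhereNet",
    version = as.character(utils::packageVersion("AdhereNet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = cfgList,
    groups = groups,
    outcomes = outcomes,
    inputs = digests
  )
  jsonlite::write_json(record, file.path(outDir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    series = series, adherence = adherence, affiliation = aff,
    metricTable = metricTable, globalScans = globalRes,
    nodalScans = nodalRes, networkSummaries = netSummaries,
    classifierReport = classifierReport,
    runRecord = record
  ))
}
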