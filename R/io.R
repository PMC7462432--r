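#' Canonical resting-state network names
#'
#' The five networks used to partition the 131-ROI parcellation.
#' @export
CANONICAL_NETWORKS <- c("subcortical", "sensory", "default_mode",
                        "attention_executive", "language_memory")

# Parse a delimited numeric matrix file (comma or tab, sniffed from the
# first line; an optional header row carries the ROI labels). Errors are
# classed: adh_emptyFile, adh_raggedRows, adh_nonNumericCell,
# adh_missingValue.
parseSeriesFile <- function(path) {
  sep <- sniffSep(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    adhStop("raggedRows", "file '%s': rows have %s fields",
            path, paste(unique(widths), collapse = "/"))
  first <- suppressWarnings(as.numeric(cells[[1L]]))
  hasHeader <- anyNA(first)
  labels <- if (hasHeader) trimws(cells[[1L]]) else NULL
  body <- if (hasHeader) cells[-1L] else cells
  if (length(body) == 0L)
    adhStop("emptyFile", "file '%s' has a header but no data rows", path)
  num <- lapply(body, function(x) suppressWarnings(as.numeric(x)))
  for (i in seq_along(num)) {
    bad <- which(is.na(num[[i]]))
    for (j in bad) {
      raw <- trimws(body[[i]][j])
      if (toupper(raw) %in% c("NA", "NAN", ""))
        adhStop("missingValue", "file '%s': missing value at row %d, column %d",
                path, i, j)
      adhStop("nonNumericCell", "file '%s': non-numeric cell '%s' at row %d, column %d",
              path, raw, i, j)
    }
  }
  m <- do.call(rbind, num)
  if (!is.null(labels)) colnames(m) <- labels
  m
}

#' Read a full cohort from a manifest
#'
#' The manifest is a comma- or tab-delimited table with columns
#' `participant_id`, `group`, `homework`, `attendance`, `timeseries_path`;
#' each time-series path points to a delimited timepoints x ROIs matrix
#' (relative paths are resolved against the manifest's directory). The first
#' file fixes the ROI label order; all other files must match it exactly.
#'
#' @param manifestPath Path to the manifest file.
#' @return A list with `series` (list of [RoiTimeSeriesSet-class], one per
#'   manifest row) and `adherence` (data.frame with columns participant_id,
#'   group, homework, attendance).
#' @seealso [writeCohort()] for the inverse operation, [readAffiliations()].
#' @export
readCohort <- function(manifestPath) {
  if (!file.exists(manifestPath))
    adhStop("missingFile", "manifest '%s' does not exist", manifestPath)
  sep <- sniffSep(manifestPath)
  man <- utils::read.table(manifestPath, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("participant_id", "group", "homework", "attendance", "timeseries_path")
  missing <- setdiff(need, names(man))
  if (length(missing))
    adhStop("badManifest", "manifest lacks column(s): %s",
            paste(missing, collapse = ", "))
  if (anyDuplicated(man$participant_id))
    adhStop("duplicateParticipant", "duplicated participant_id: %s",
            paste(unique(man$participant_id[duplicated(man$participant_id)]),
                  collapse = ", "))
  if (!all(man$group %in% c("meditation", "writing")))
    adhStop("badGroup", "group must be 'meditation' or 'writing'")
  if (any(man$homework < 0 | man$homework > 20))
    adhStop("invalidAdherence", "homework must lie in [0, 20]")
  if (any(man$attendance < 0 | man$attendance > 4))
    adhStop("invalidAdherence", "attendance must lie in [0, 4]")

  base <- dirname(normalizePath(manifestPath))
  refLabels <- NULL
  series <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$timeseries_path[i]
    if (!file.exists(p)) p <- file.path(base, man$timeseries_path[i])
    if (!file.exists(p))
      adhStop("missingFile", "time-series file '%s' (participant %s) does not exist",
              man$timeseries_path[i], man$participant_id[i])
    m <- parseSeriesFile(p)
    if (is.null(refLabels)) {
      if (is.null(colnames(m))) colnames(m) <- sprintf("ROI%03d", seq_len(ncol(m)))
      refLabels <- colnames(m)
    } else {
      if (ncol(m) != length(refLabels))
        adhStop("roiCountMismatch",
                "participant %s has %d ROIs, expected %d",
                man$participant_id[i], ncol(m), length(refLabels))
      if (is.null(colnames(m))) {
        colnames(m) <- refLabels
      } else if (!identical(colnames(m), refLabels)) {
        adhStop("roiLabelMismatch",
                "participant %s: ROI labels differ from the first file",
                man$participant_id[i])
      }
    }
    series[[i]] <- RoiTimeSeriesSet(man$participant_id[i], m)
  }
  adherence <- data.frame(
    participant_id = as.character(man$participant_id),
    group = man$group,
    homework = as.integer(man$homework),
    attendance = as.integer(man$attendance),
    stringsAsFactors = FALSE
  )
  list(series = series, adherence = adherence)
}

#' Read a node-to-network affiliation table
#'
#' Two-column delimited file (`roi_label`, `network_name`), with or without
#' a header. Coverage of `roiLabels` is mandatory; the canonical layout has
#' exactly five networks, and any other count triggers a warning (or an
#' error when `strict = TRUE`).
#'
#' @param path Path to the affiliation file.
#' @param roiLabels ROI labels that must all be covered.
#' @param strict Error (instead of warn) when the network count is not 5.
#' @return An [AffiliationVector-class].
#' @export
readAffiliations <- function(path, roiLabels, strict = FALSE) {
  if (!file.exists(path))
    adhStop("missingFile", "affiliation file '%s' does not exist", path)
  sep <- sniffSep(path)
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(tab) != 2L)
    adhStop("badAffiliationFile", "expected 2 columns, found %d", ncol(tab))
  if (identical(tolower(unlist(tab[1, ])), c("roi_label", "network_name")))
    tab <- tab[-1, , drop = FALSE]
  map <- as.character(tab[[2]])
  names(map) <- as.character(tab[[1]])
  if (anyDuplicated(names(map)))
    adhStop("duplicateRoi", "duplicated ROI label(s) in affiliation file")
  uncovered <- setdiff(roiLabels, names(map))
  if (length(uncovered))
    adhStop("unaffiliatedRoi", "no affiliation for ROI(s): %s",
            paste(utils::head(uncovered, 5), collapse = ", "))
  unknown <- setdiff(names(map), roiLabels)
  if (length(unknown))
    adhStop("unknownRoi", "affiliation file names unknown ROI(s): %s",
            paste(utils::head(unknown, 5), collapse = ", "))
  map <- map[roiLabels]
  k <- length(unique(map))
  if (k != 5L) {
    if (strict)
      adhStop("networkCount", "expected 5 networks, found %d", k)
    adhWarn("networkCount", "expected 5 networks, found %d", k)
  }
  AffiliationVector(map)
}

#' Write a cohort to disk in the pipeline's exchange format
#'
#' Writes one delimited time-series file per participant (with a ROI-label
#' header), an affiliation table, and a manifest that [readCohort()] can
#' load back; the round trip reproduces the in-memory cohort exactly.
#'
#' @param series List of [RoiTimeSeriesSet-class].
#' @param adherence Adherence data.frame (participant_id, group, homework,
#'   attendance).
#' @param affiliation An [AffiliationVector-class].
#' @param dir Output directory (created if needed).
#' @param sep Field separator, tab by default.
#' @return The manifest path, invisibly.
#' @export
writeCohort <- function(series, adherence, affiliation, dir, sep = "\t") {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(series))
  for (i in seq_along(series)) {
    id <- participantId(series[[i]])
    paths[i] <- file.path("timeseries", paste0(id, ".tsv"))
    m <- seriesMatrix(series[[i]])
    # %.17g survives the text round trip bit-exactly
    fm <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
    utils::write.table(fm, file.path(dir, paths[i]), sep = sep,
                       row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  man <- cbind(adherence, timeseries_path = paths)
  manifestPath <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifestPath, sep = sep,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  aff <- affiliations(affiliation)
  utils::write.table(
    data.frame(roi_label = names(aff), network_name = unname(aff)),
    file.path(dir, "affiliations.tsv"), sep = sep,
    row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(manifestPath)
}
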