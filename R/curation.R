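# Record-level curation of FAERS-like report tables into weighted CMM-ADR
# associations: case-version deduplication, non-ADR term exclusion,
# pair aggregation, and union with literature-curated pairs.

#' Keep the most recent version of each case
#'
#' Spontaneous-report databases resubmit cases under increasing version
#' numbers; only the latest version of each case should contribute to
#' signal counts. Retains, per `case_id`, the record with the maximum
#' `case_version`, preserving input order otherwise. Duplicate
#' (`case_id`, `case_version`) pairs violate the record contract and raise
#' an error; multiple records tied at the same maximum version (possible in
#' messy exports where versions are unreliable) keep the last-seen record
#' after a warning.
#'
#' @param records `data.frame` with at least columns `case_id`,
#'   `case_version`.
#' @return the deduplicated `data.frame`.
#' @examples
#' r <- data.frame(case_id = c("c1", "c1", "c2"), case_version = c(1, 2, 1),
#'                 cmm_id = "h", pt = "Nausea")
#' dedupLatestVersion(r)
#' @export
dedupLatestVersion <- function(records) {
  if (nrow(records) == 0) return(records)
  key <- paste(records$case_id, records$case_version, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (case_id, case_version) record(s) in input", call. = FALSE)
  }
  maxVer <- tapply(records$case_version, records$case_id, max)
  isMax <- records$case_version == maxVer[as.character(records$case_id)]
  cand <- records[isMax, , drop = FALSE]
  if (anyDuplicated(cand$case_id)) {
    warning("ties at maximum case_version; keeping last-seen record per case",
      call. = FALSE
    )
    keep <- !duplicated(cand$case_id, fromLast = TRUE)
    cand <- cand[keep, , drop = FALSE]
  }
  cand
}

#' Remove records mapped to non-ADR Preferred Terms
#'
#' Excludes administrative or otherwise non-medical MedDRA Preferred Terms
#' (e.g. "Product issues") using a user-supplied blacklist of exact PT
#' strings.
#'
#' @param records `data.frame` with a `pt` column.
#' @param blacklist character vector of exact PT strings to drop.
#' @return list with `records` (the filtered table) and `removed` (count of
#'   dropped records).
#' @export
filterNonAdr <- function(records, blacklist) {
  drop <- records$pt %in% blacklist
  list(records = records[!drop, , drop = FALSE], removed = sum(drop))
}

#' Aggregate curated records to CMM-ADR pair counts
#'
#' Collapses deduplicated, filtered report records to one association per
#' distinct (`cmm_id`, `pt`) with `report_count` equal to the number of
#' contributing records and provenance `"faers"`.
#'
#' @param records `data.frame` with columns `cmm_id`, `pt`.
#' @return `data.frame` with columns `cmm_id`, `pt`, `report_count`,
#'   `provenance`.
#' @export
aggregatePairs <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(
      cmm_id = character(0), pt = character(0),
      report_count = integer(0), provenance = character(0),
      stringsAsFactors = FALSE
    ))
  }
  agg <- stats::aggregate(
    list(report_count = rep(1L, nrow(records))),
    by = list(cmm_id = records$cmm_id, pt = records$pt), FUN = sum
  )
  agg <- agg[order(agg$cmm_id, agg$pt), , drop = FALSE]
  rownames(agg) <- NULL
  agg$provenance <- "faers"
  agg
}

#' Union FAERS-derived and literature-curated associations
#'
#' Set union keyed on (`cmm_id`, `pt`). On overlap the FAERS record wins --
#' its report count feeds the evidence features, so it must survive -- and
#' the pair keeps provenance `"faers"`. Literature-only pairs enter with
#' `report_count = 0` and provenance `"literature"`.
#'
#' @param faersPairs `data.frame` as from [aggregatePairs()].
#' @param literaturePairs `data.frame` with columns `cmm_id`, `pt`
#'   (`report_count`/`provenance` filled if absent).
#' @return the combined association `data.frame`.
#' @export
unionWithLiterature <- function(faersPairs, literaturePairs) {
  if (nrow(literaturePairs) > 0) {
    literaturePairs$report_count <- 0L
    literaturePairs$provenance <- "literature"
  } else {
    literaturePairs <- data.frame(
      cmm_id = character(0), pt = character(0),
      report_count = integer(0), provenance = character(0),
      stringsAsFactors = FALSE
    )
  }
  cols <- c("cmm_id", "pt", "report_count", "provenance")
  if (nrow(faersPairs) == 0) {
    return(literaturePairs[, cols, drop = FALSE])
  }
  fKey <- paste(faersPairs$cmm_id, faersPairs$pt, sep = "\r")
  lKey <- paste(literaturePairs$cmm_id, literaturePairs$pt, sep = "\r")
  litOnly <- literaturePairs[!(lKey %in% fKey), cols, drop = FALSE]
  out <- rbind(faersPairs[, cols, drop = FALSE], litOnly)
  rownames(out) <- NULL
  out
}

#' Restrict to monotherapy reports
#'
#' Sensitivity-analysis filter keeping only records from reports with
#' exactly one unique drug, a proxy for monotherapy exposure.
#'
#' @param records `data.frame` with an `n_drugs_in_report` column.
#' @return filtered `data.frame`.
#' @export
monotherapySubset <- function(records) {
  records[records$n_drugs_in_report == 1L, , drop = FALSE]
}

#' Run the full report-level curation workflow
#'
#' Convenience wrapper: deduplicate case versions, drop blacklisted
#' non-ADR terms, aggregate to pair counts, and union with literature
#' associations.
#'
#' @param records report `data.frame` (columns `case_id`, `case_version`,
#'   `cmm_id`, `pt`, optionally `n_drugs_in_report`).
#' @param blacklist character vector of non-ADR Preferred Terms.
#' @param literaturePairs optional literature association table
#'   (columns `cmm_id`, `pt`).
#' @return list with `associations` (the curated pair table), `removed`
#'   (blacklisted record count) and `nRecords` (records after dedup).
#' @export
curateReports <- function(records, blacklist = character(0),
                          literaturePairs = NULL) {
  dd <- dedupLatestVersion(records)
  fl <- filterNonAdr(dd, blacklist)
  pairs <- aggregatePairs(fl$records)
  if (!is.null(literaturePairs)) {
    pairs <- unionWithLiterature(pairs, literaturePairs)
  }
  list(associations = pairs, removed = fl$removed, nRecords = nrow(fl$records))
}

#' Read a report table / blacklist from disk
#'
#' @param path TSV with header columns `case_id`, `case_version`, `cmm_id`,
#'   `pt`, `n_drugs_in_report`.
#' @return `data.frame` of report records.
#' @export
readReportTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("case_id", "case_version", "cmm_id", "pt")
  .check(all(need %in% names(df)), "report table must have columns %s",
         paste(need, collapse = ", "))
  df
}

#' @rdname readReportTable
#' @param blacklistPath text file with one Preferred Term per line (UTF-8).
#' @export
readBlacklist <- function(blacklistPath) {
  x <- readLines(blacklistPath, encoding = "UTF-8", warn = FALSE)
  x[nzchar(x)]
}

#' Write an association table
#'
#' @param associations `data.frame` with columns `cmm_id`, `pt`,
#'   `report_count`, `provenance`.
#' @param path output TSV path.
#' @export
writeAssociations <- function(associations, path) {
  utils::write.table(associations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
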