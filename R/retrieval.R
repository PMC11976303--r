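#' Faceted name retrieval
#'
#' Browse-style lookup over the indexed summary records. The query text is
#' split into tokens; a record matches when every query token is a
#' case-folded prefix of some token of its scientificName (so `"Acer
#' integr"` finds both `"Acer integrum"` and `"Acer integrifolium"`, while
#' the full token `"integrum"` finds only the former). Filters on publication
#' year, rank, status and dataset apply conjunctively; records with an empty
#' year are excluded while a year filter is active; vernacular records are
#' excluded unless requested. Hits are sorted ascending by name length, then
#' name, and paginated; facet counts over rank, status, year and dataset are
#' computed on the full filtered hit set, so each facet dimension sums to
#' `totalHits`.
#'
#' @param query query text (raw; normalized internally). An empty query with
#'   no active filter returns an empty page rather than the full table.
#' @param index a [build_index()] object.
#' @param year optional single year or length-2 closed range (numeric or
#'   character).
#' @param rank,status,datasets optional character vectors of accepted
#'   taxonRank / taxonomicStatus / datasetID values.
#' @param include_vernacular include vernacular records (default `FALSE`).
#' @param page,page_size pagination (page is 1-based; `page_size` is capped
#'   at `config$max_page_size`).
#' @param config a [tn_config()] object.
#' @return a `result_page`: list with `hits` (record tibble page),
#'   `totalHits`, `page`, `pageSize` and `facets` (named list of count
#'   tables for `taxonRank`, `taxonomicStatus`, `namePublishedInYear`,
#'   `datasetID`).
#' @export
retrieve_names <- function(query, index, year = NULL, rank = NULL,
                           status = NULL, datasets = NULL,
                           include_vernacular = FALSE, page = 1L,
                           page_size = NULL, config = default_config()) {
  stopifnot(inherits(index, "name_index"), page >= 1)
  if (is.null(page_size)) page_size <- config$page_size
  page_size <- min(as.integer(page_size), config$max_page_size)
  stopifnot(page_size >= 1)
  q <- normalize_name(if (is.null(query) || is.na(query)) "" else query, config)
  no_filter <- is.null(year) && is.null(rank) && is.null(status) &&
    is.null(datasets)
  recs <- index$records
  if (!nzchar(q) && no_filter) {
    recs <- recs[0, , drop = FALSE]
  } else {
    if (!include_vernacular) recs <- recs[!recs$isVernacular, , drop = FALSE]
    if (nzchar(q)) {
      qtok <- tolower(strsplit(q, " ", fixed = TRUE)[[1]])
      rtok <- strsplit(tolower(recs$scientificName), " ", fixed = TRUE)
      hit <- vapply(rtok, function(tk) {
        all(vapply(qtok, function(qt) any(startsWith(tk, qt)), logical(1)))
      }, logical(1))
      recs <- recs[hit, , drop = FALSE]
    }
    if (!is.null(year)) {
      yr <- suppressWarnings(as.integer(recs$namePublishedInYear))
      rng <- range(as.integer(year))
      recs <- recs[!is.na(yr) & yr >= rng[1] & yr <= rng[2], , drop = FALSE]
    }
    if (!is.null(rank)) recs <- recs[recs$taxonRank %in% rank, , drop = FALSE]
    if (!is.null(status)) {
      recs <- recs[recs$taxonomicStatus %in% status, , drop = FALSE]
    }
    if (!is.null(datasets)) {
      recs <- recs[recs$datasetID %in% datasets, , drop = FALSE]
    }
  }
  recs <- recs[order(nchar(recs$scientificName), recs$scientificName,
                     recs$recordID), , drop = FALSE]
  total <- nrow(recs)
  facets <- lapply(
    c(taxonRank = "taxonRank", taxonomicStatus = "taxonomicStatus",
      namePublishedInYear = "namePublishedInYear", datasetID = "datasetID"),
    function(col) {
      v <- recs[[col]]
      v[!nzchar(v)] <- "(none)"
      tab <- table(v)
      tibble::tibble(value = names(tab), count = as.integer(tab))
    })
  lo <- (as.integer(page) - 1L) * page_size + 1L
  hi <- min(total, lo + page_size - 1L)
  hits <- if (lo > total) recs[0, , drop = FALSE] else recs[lo:hi, , drop = FALSE]
  structure(list(hits = hits, totalHits = total, page = as.integer(page),
                 pageSize = page_size, facets = facets),
            class = "result_page")
}

#' @export
print.result_page <- function(x, ...) {
  cat("<result_page>", x$totalHits, "hit(s), page", x$page, "of size",
      x$pageSize, "\n")
  if (nrow(x$hits)) print(x$hits[, c("scientificName", "taxonRank",
                                     "taxonomicStatus", "datasetID")])
  invisible(x)
}

#' Autocomplete suggestions for a name prefix
#'
#' Names whose case-folded form starts with the case-folded prefix, sorted
#' ascending by length then lexicographically, truncated to `limit`.
#' Duplicate spellings across datasets are suggested once.
#'
#' @param prefix the typed prefix; an empty prefix suggests nothing.
#' @param index a [build_index()] object.
#' @param limit maximum number of suggestions (default 10).
#' @param include_vernacular include vernacular names (default `FALSE`).
#' @return character vector of suggested names.
#' @export
suggest_names <- function(prefix, index, limit = 10L,
                          include_vernacular = FALSE) {
  stopifnot(inherits(index, "name_index"), limit >= 1)
  if (is.null(prefix) || is.na(prefix) || !nzchar(prefix)) return(character(0))
  recs <- index$records
  if (!include_vernacular) recs <- recs[!recs$isVernacular, , drop = FALSE]
  nm <- unique(recs$scientificName)
  hit <- nm[startsWith(tolower(nm), tolower(prefix))]
  hit <- hit[order(nchar(hit), hit)]
  utils::head(hit, limit)
}

#' Detailed view of one record
#'
#' Resolves the record's accepted name by following `acceptedNameUsageID`
#' (within the same dataset) and assembles its lineage: the
#' `higherClassification` string when present, otherwise the
#' `parentNameUsageID` chain from root to record. Link-following is
#' cycle-safe; a dangling accepted link is reported in `warning` rather than
#' raised.
#'
#' @param record_id a recordID present in the store.
#' @param records the summary-record tibble (or a [record_store()] /
#'   `name_index`).
#' @return a list with `record` (one-row tibble), `acceptedName`,
#'   `acceptedRecord` (one-row tibble or `NULL`), `lineage` (character
#'   vector, root first) and `warning` (`NA` or a message).
#' @export
record_detail <- function(record_id, records) {
  if (inherits(records, "record_store")) records <- store_records(records)
  if (inherits(records, "name_index")) records <- records$records
  stopifnot(is.data.frame(records))
  row <- records[records$recordID == record_id, , drop = FALSE]
  if (!nrow(row)) stop("record not found: ", record_id)
  warning_msg <- NA_character_

  accepted <- row
  if (nzchar(row$acceptedNameUsageID) &&
      !identical(row$acceptedNameUsageID, row$taxonID)) {
    tgt <- records[records$datasetID == row$datasetID &
                     records$taxonID == row$acceptedNameUsageID &
                     !records$isVernacular, , drop = FALSE]
    if (nrow(tgt)) {
      accepted <- tgt[1, , drop = FALSE]
    } else {
      accepted <- NULL
      warning_msg <- paste0("dangling acceptedNameUsageID: ",
                            row$acceptedNameUsageID)
    }
  }

  if (nzchar(row$higherClassification)) {
    lineage <- strsplit(row$higherClassification, "|", fixed = TRUE)[[1]]
    lineage <- trimws(lineage)
  } else {
    lineage <- character(0)
    seen <- character(0)
    cur <- row
    while (nzchar(cur$parentNameUsageID) &&
           !cur$parentNameUsageID %in% seen) {
      seen <- c(seen, cur$taxonID)
      par <- records[records$datasetID == row$datasetID &
                       records$taxonID == cur$parentNameUsageID, ,
                     drop = FALSE]
      if (!nrow(par)) break
      cur <- par[1, , drop = FALSE]
      lineage <- c(cur$scientificName, lineage)
    }
  }
  list(record = row,
       acceptedName = if (is.null(accepted)) NA_character_
                      else accepted$scientificName,
       acceptedRecord = accepted,
       lineage = lineage,
       warning = warning_msg)
}
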