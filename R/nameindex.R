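#' An in-memory record store for the integrated name summary table
#'
#' The summary table integrates one row per name usage across datasets, with
#' Darwin Core core terms plus dataset provenance. Records accumulate in the
#' store as files are ingested with [ingest_records()]; [build_index()] then
#' derives the lookup structures from a snapshot of the store.
#'
#' @return an empty record store (class `record_store`).
#' @export
record_store <- function() {
  st <- new.env(parent = emptyenv())
  st$records <- empty_records()
  st$next_id <- 1L
  st$skip_log <- character(0)
  class(st) <- "record_store"
  st
}

record_columns <- c("taxonID", "scientificName", "scientificNameAuthorship",
                    "taxonRank", "taxonomicStatus", "acceptedNameUsageID",
                    "parentNameUsageID", "namePublishedInYear",
                    "higherClassification")

empty_records <- function() {
  cols <- c(list(recordID = integer(0)),
            stats::setNames(rep(list(character(0)), length(record_columns) + 1),
                            c(record_columns, "datasetID")),
            list(isVernacular = logical(0)))
  tibble::as_tibble(cols[c("recordID", "taxonID", "datasetID",
                           setdiff(record_columns, "taxonID"),
                           "isVernacular")])
}

#' @export
print.record_store <- function(x, ...) {
  cat("<record_store>", nrow(x$records), "records,",
      length(unique(x$records$datasetID)), "dataset(s),",
      length(x$skip_log), "skipped row(s)\n")
  invisible(x)
}

#' Records currently held in a store
#' @param store a [record_store()].
#' @return the summary-record tibble.
#' @export
store_records <- function(store) {
  stopifnot(inherits(store, "record_store"))
  store$records
}

#' Ingest a Darwin-Core-style taxon table into a record store
#'
#' Reads a TSV or CSV taxon table (UTF-8, header row using Darwin Core term
#' names) and appends its rows to the store as summary records tagged with
#' `datasetID`. Only the recognized columns are kept; unknown columns are
#' ignored; missing optional columns are filled with empty strings. Names are
#' normalized on ingest. Rows without a scientificName are skipped and
#' recorded in the store's skip log.
#'
#' @param store a [record_store()].
#' @param path path to a `.tsv`/`.txt` (tab-delimited) or `.csv` file with a
#'   header row containing at least `scientificName`.
#' @param datasetID dataset code recorded as provenance for every row.
#' @param config a [tn_config()] object.
#' @return integer: the number of records created, with attribute `skipped`
#'   giving the number of rows skipped for lacking a scientificName.
#' @export
ingest_records <- function(store, path, datasetID, config = default_config()) {
  stopifnot(inherits(store, "record_store"), is.character(datasetID))
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), encoding = "UTF-8")
  if (!"scientificName" %in% names(df)) {
    stop("missing required column: scientificName")
  }
  n_in <- nrow(df)
  for (col in record_columns) {
    if (!col %in% names(df)) df[[col]] <- rep("", n_in)
  }
  vern <- if ("isVernacular" %in% names(df)) {
    tolower(trimws(df$isVernacular)) %in% c("true", "t", "1", "yes")
  } else rep(FALSE, n_in)

  sci <- normalize_name(df$scientificName, config)
  keep <- !is.na(sci) & nzchar(sci)
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    store$skip_log <- c(store$skip_log,
                        sprintf("%s: row %d skipped (empty scientificName)",
                                basename(path), which(!keep)))
  }
  df <- df[keep, , drop = FALSE]
  sci <- sci[keep]
  vern <- vern[keep]
  n <- nrow(df)
  if (n > 0) {
    ids <- seq.int(store$next_id, length.out = n)
    new <- tibble::tibble(
      recordID = as.integer(ids),
      taxonID = trimws(df$taxonID),
      datasetID = datasetID,
      scientificName = sci,
      scientificNameAuthorship = trimws(df$scientificNameAuthorship),
      taxonRank = trimws(df$taxonRank),
      taxonomicStatus = trimws(df$taxonomicStatus),
      acceptedNameUsageID = trimws(df$acceptedNameUsageID),
      parentNameUsageID = trimws(df$parentNameUsageID),
      namePublishedInYear = trimws(df$namePublishedInYear),
      higherClassification = trimws(df$higherClassification),
      isVernacular = vern
    )
    store$records <- rbind(store$records, new)
    store$next_id <- store$next_id + n
  }
  structure(as.integer(n), skipped = as.integer(n_skip))
}

#' Build the name index over a set of summary records
#'
#' Derives, from the record tibble, the structures every query path uses: a
#' case-folded exact-name table, a token-prefix count table answering "how
#' many indexed names start with this token sequence" (case-sensitive on the
#' genus initial, case-folded elsewhere), and per-token-count buckets holding
#' aligned token columns with their lengths for complete fuzzy lookup.
#' Fuzzy buckets cover scientific-name records only; vernacular records are
#' reachable through the exact and prefix tables.
#'
#' @param records a summary-record tibble (from [store_records()] or
#'   [generate_taxonomy()]), or a [record_store()].
#' @param config a [tn_config()] object.
#' @return a `name_index` object.
#' @export
build_index <- function(records, config = default_config()) {
  if (inherits(records, "record_store")) records <- store_records(records)
  stopifnot(is.data.frame(records))
  records <- tibble::as_tibble(records)
  if (!"recordID" %in% names(records)) {
    records$recordID <- seq_len(nrow(records))
  }
  exact <- new.env(parent = emptyenv(), hash = TRUE)
  prefix <- new.env(parent = emptyenv(), hash = TRUE)
  toks_raw <- strsplit(records$scientificName, " ", fixed = TRUE)
  for (i in seq_len(nrow(records))) {
    key <- tolower(records$scientificName[i])
    exact[[key]] <- c(exact[[key]], records$recordID[i])
    tk <- toks_raw[[i]]
    for (j in seq_along(tk)) {
      pk <- prefix_key(tk[seq_len(j)])
      cnt <- prefix[[pk]]
      prefix[[pk]] <- if (is.null(cnt)) 1L else cnt + 1L
    }
  }
  # length-bucketed token columns for fuzzy lookup, scientific names only
  sci_idx <- which(!records$isVernacular)
  kcount <- lengths(toks_raw[sci_idx])
  buckets <- list()
  for (k in unique(kcount)) {
    rows <- sci_idx[kcount == k]
    tok_cols <- lapply(seq_len(k), function(p) {
      tolower(vapply(toks_raw[rows], `[[`, character(1), p))
    })
    buckets[[as.character(k)]] <- list(
      ids = records$recordID[rows],
      tok = tok_cols,
      len = lapply(tok_cols, nchar)
    )
  }
  structure(list(records = records, exact = exact, prefix = prefix,
                 buckets = buckets, n_names = nrow(records),
                 fuzzy_mode = config$fuzzy_mode),
            class = "name_index")
}

#' @export
print.name_index <- function(x, ...) {
  cat("<name_index>", x$n_names, "records (",
      sum(x$records$isVernacular), "vernacular ),",
      length(x$buckets), "token-count bucket(s)\n")
  invisible(x)
}

# prefix keys case-fold everything except the initial character of the
# leading (genus) token
prefix_key <- function(tokens) {
  folded <- tolower(tokens)
  substr(folded[1], 1, 1) <- substr(tokens[1], 1, 1)
  paste(folded, collapse = "\x1f")
}

#' Exact name lookup
#'
#' Case-insensitive comparison of the full normalized name string against the
#' indexed names (vernacular records included; callers that need scientific
#' names only filter on `isVernacular`).
#'
#' @param index a [build_index()] object.
#' @param name a normalized name string.
#' @return integer vector of matching recordIDs (possibly empty).
#' @export
lookup_exact <- function(index, name) {
  stopifnot(inherits(index, "name_index"))
  if (is.na(name) || !nzchar(name)) return(integer(0))
  ids <- index$exact[[tolower(name)]]
  if (is.null(ids)) integer(0) else ids
}

#' Fuzzy name lookup by per-token edit distance
#'
#' Returns exactly the indexed scientific names with the same number of
#' space-separated tokens as the query whose every aligned token is within
#' Levenshtein distance `d` of the corresponding query token. Candidate
#' pruning is by token-length bucketing (a token at distance `d` differs in
#' length by at most `d`); the surviving candidates are verified with exact
#' edit distances, so the result is complete. With
#' `mode = "whole_string"` the constraint is instead a Levenshtein distance
#' of at most `d` on the whole case-folded string.
#'
#' @param index a [build_index()] object.
#' @param name a normalized name string.
#' @param d maximum per-token distance, 1 or 2.
#' @param mode `"per_token"` (default, taken from the index's configuration)
#'   or `"whole_string"`.
#' @return a tibble with columns `recordID`, `tokenDistances` (list column of
#'   integer vectors; a single total for whole-string mode) and
#'   `totalDistance`, sorted by `totalDistance` then `recordID`.
#' @export
lookup_fuzzy <- function(index, name, d = 1L, mode = index$fuzzy_mode) {
  stopifnot(inherits(index, "name_index"), d %in% c(1L, 2L))
  mode <- match.arg(mode, c("per_token", "whole_string"))
  no_hit <- tibble::tibble(recordID = integer(0),
                           tokenDistances = list(),
                           totalDistance = integer(0))
  if (is.na(name) || !nzchar(name)) return(no_hit)
  q <- tolower(name)
  if (mode == "whole_string") {
    recs <- index$records[!index$records$isVernacular, ]
    lens <- nchar(tolower(recs$scientificName))
    cand <- which(abs(lens - nchar(q)) <= d)
    if (!length(cand)) return(no_hit)
    dist <- as.integer(utils::adist(q, tolower(recs$scientificName[cand])))
    keep <- dist <= d
    out <- tibble::tibble(recordID = recs$recordID[cand][keep],
                          tokenDistances = lapply(dist[keep], identity),
                          totalDistance = dist[keep])
    return(out[order(out$totalDistance, out$recordID), ])
  }
  qtok <- strsplit(q, " ", fixed = TRUE)[[1]]
  bucket <- index$buckets[[as.character(length(qtok))]]
  if (is.null(bucket)) return(no_hit)
  cand <- seq_along(bucket$ids)
  dists <- matrix(0L, nrow = length(cand), ncol = length(qtok))
  for (p in seq_along(qtok)) {
    if (!length(cand)) break
    ok_len <- abs(bucket$len[[p]][cand] - nchar(qtok[p])) <= d
    cand <- cand[ok_len]
    dists <- dists[ok_len, , drop = FALSE]
    if (!length(cand)) break
    dp <- as.integer(utils::adist(qtok[p], bucket$tok[[p]][cand]))
    ok <- dp <= d
    cand <- cand[ok]
    dists <- dists[ok, , drop = FALSE]
    dists[, p] <- dp[ok]
  }
  if (!length(cand)) return(no_hit)
  out <- tibble::tibble(
    recordID = bucket$ids[cand],
    tokenDistances = lapply(seq_along(cand), function(i) dists[i, ]),
    totalDistance = as.integer(rowSums(dists))
  )
  out[order(out$totalDistance, out$recordID), ]
}

#' Count indexed names starting with a token sequence
#'
#' Answers, in constant time, how many indexed names begin with the given
#' tokens — the primitive behind whole-name finding in free text. Comparison
#' is case-sensitive on the first character of the leading token (a genus
#' must be capitalized as written) and case-folded elsewhere.
#'
#' @param index a [build_index()] object.
#' @param tokens character vector of tokens; the empty sequence counts every
#'   indexed name.
#' @return a non-negative integer.
#' @export
phrase_prefix_count <- function(index, tokens) {
  stopifnot(inherits(index, "name_index"))
  if (!length(tokens)) return(index$n_names)
  cnt <- index$prefix[[prefix_key(tokens)]]
  if (is.null(cnt)) 0L else cnt
}

# records for a vector of recordIDs, in the given order
records_by_id <- function(index, ids) {
  index$records[match(ids, index$records$recordID), , drop = FALSE]
}
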