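#' Read a one-column name list in the match-template shape
#'
#' The template is a UTF-8 CSV whose first relevant column is headed
#' `scientificName` (matched case-insensitively). Blank rows are skipped and
#' counted.
#'
#' @param path path to the CSV file.
#' @param limit optional maximum number of names (e.g. the matching service's
#'   batch limit); exceeding it is an error.
#' @return character vector of names, with integer attribute `skipped`.
#' @export
read_name_csv <- function(path, limit = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = character(0), encoding = "UTF-8",
                        blank.lines.skip = FALSE)
  col <- which(tolower(trimws(names(df))) == "scientificname")
  if (!length(col)) stop("missing required column: scientificName")
  vals <- trimws(df[[col[1]]])
  keep <- nzchar(vals)
  out <- vals[keep]
  if (!is.null(limit) && length(out) > limit) {
    stop("batch limit exceeded: ", length(out), " names submitted, at most ",
         limit, " allowed per submission")
  }
  structure(out, skipped = sum(!keep))
}

#' Dispatch a JSON service request to the toolkit
#'
#' An in-process service layer mirroring the five classic name-service
#' routes: `retrieval`, `match`, `search`, `parse` and `detail`. Each route
#' delegates to the corresponding package function and wraps the result in a
#' JSON envelope with a `status` field (`ok` or `error`), a `version` stamp
#' and machine-readable error codes (`bad_request`, `batch_limit`,
#' `not_found`, `internal`). Field names reuse the Darwin Core terms used
#' throughout the package. No stack traces are ever leaked into responses.
#'
#' Payload fields by route:
#' \describe{
#'   \item{retrieval}{`query`, optional `year`, `rank`, `status`,
#'     `datasets`, `includeVernacular`, `page`, `pageSize`.}
#'   \item{match}{`names` (character vector, at most the configured batch
#'     limit), optional `datasets`.}
#'   \item{search}{`text` — returns the found-name array with offsets.}
#'   \item{parse}{`name` or `names`.}
#'   \item{detail}{`recordID`.}
#' }
#'
#' @param route one of `"retrieval"`, `"match"`, `"search"`, `"parse"`,
#'   `"detail"`.
#' @param payload named list of route parameters.
#' @param index a [build_index()] object.
#' @param config a [tn_config()] object.
#' @return a JSON string (class `json`).
#' @export
#' @examples
#' tax <- generate_taxonomy(n_genera = 2, species_per_genus = 2, seed = 1)
#' idx <- build_index(tax$records)
#' api_handle("parse", list(name = "Acer palmatum Thunb."), idx)
api_handle <- function(route, payload, index, config = default_config()) {
  respond <- function(body) {
    jsonlite::toJSON(c(list(status = "ok",
                            version = as.character(
                              utils::packageVersion("taxres"))),
                       body),
                     auto_unbox = TRUE, null = "null", digits = NA)
  }
  fail <- function(code, message, http = 400L) {
    jsonlite::toJSON(list(status = "error", code = code, httpStatus = http,
                          message = message),
                     auto_unbox = TRUE)
  }
  if (!is.character(route) || length(route) != 1 ||
      !route %in% c("retrieval", "match", "search", "parse", "detail")) {
    return(fail("bad_request", "unknown route"))
  }
  if (!is.list(payload)) return(fail("bad_request", "payload must be a list"))
  out <- tryCatch({
    switch(route,
      retrieval = {
        pg <- retrieve_names(
          query = payload$query %||% "", index = index,
          year = payload$year, rank = payload$rank, status = payload$status,
          datasets = payload$datasets,
          include_vernacular = isTRUE(payload$includeVernacular),
          page = payload$page %||% 1L,
          page_size = payload$pageSize, config = config)
        respond(list(totalHits = pg$totalHits, page = pg$page,
                     pageSize = pg$pageSize, hits = drop_listcols(pg$hits),
                     facets = pg$facets))
      },
      match = {
        nms <- as.character(payload$names %||% character(0))
        if (length(nms) > config$batch_limit) {
          fail("batch_limit",
               paste0("at most ", config$batch_limit,
                      " names per submission"), 413L)
        } else {
          res <- match_batch(nms, index, datasets = payload$datasets,
                             config = config)
          respond(list(results = match_report(res)))
        }
      },
      search = {
        txt <- payload$text %||% ""
        m <- find_names(txt, index, config)
        respond(list(matches = drop_listcols(m)))
      },
      parse = {
        nms <- as.character(payload$names %||% payload$name %||% character(0))
        respond(list(results = parse_name(nms, config)))
      },
      detail = {
        rid <- payload$recordID
        if (is.null(rid)) {
          fail("bad_request", "recordID is required")
        } else if (!rid %in% index$records$recordID) {
          fail("not_found", paste0("record not found: ", rid), 404L)
        } else {
          d <- record_detail(rid, index)
          respond(list(record = d$record, acceptedName = d$acceptedName,
                       lineage = d$lineage,
                       warning = d$warning))
        }
      })
  }, error = function(e) fail("internal", "internal error", 500L))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# list columns (recordIDs etc.) serialize poorly row-wise; expose them as
# comma-joined strings
drop_listcols <- function(df) {
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], function(v) paste(v, collapse = ","),
                          character(1))
    }
  }
  df
}
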