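#' Normalized edit similarity between two name strings
#'
#' `1 - Lev(a, b) / max(nchar(a), nchar(b))` on case-folded whole strings:
#' symmetric, 1 exactly when the case-folded strings are equal (two empty
#' strings count as equal), 0 when one string is empty and the other is not.
#'
#' @param a,b character vectors (recycled to a common length).
#' @return numeric vector of similarities in `[0, 1]`.
#' @export
#' @examples
#' name_similarity("Acer palmatum", "Acer palmatun")
name_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(tolower(a), n)
  b <- rep_len(tolower(b), n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    la <- nchar(a[i]); lb <- nchar(b[i])
    if (la == 0 && lb == 0) { out[i] <- 1; next }
    out[i] <- 1 - as.integer(utils::adist(a[i], b[i])) / max(la, lb)
  }
  out
}

#' Match one name against the index with the cascading strategy
#'
#' The cascade runs stage by stage and stops at the first stage with at least
#' one hit: exact match on scientific names, exact match on vernacular names,
#' fuzzy match at distance 1, fuzzy match at distance 2; then, if the parser
#' detects an authorship in the query, the authorship is stripped and the
#' whole cascade repeats on the name part. An exact hit (with or without
#' authorship stripping) is labelled `Match`, a vernacular hit `Vernacular`,
#' a fuzzy hit `Recorrect` and an empty cascade `Unmatch`.
#'
#' Candidates carry the normalized edit similarity between the query form
#' used at the terminating stage and the candidate name, and are sorted by
#' similarity (descending), then name length, then name, then the dataset
#' registry order.
#'
#' @param name a raw name string (normalized internally).
#' @param index a [build_index()] object.
#' @param datasets optional character vector of datasetIDs; when given, a
#'   stage only counts hits from these datasets.
#' @param config a [tn_config()] object.
#' @return a `match_result`: list with elements `query` (normalized),
#'   `status` (`Match`, `Recorrect`, `Vernacular`, `Unmatch`), `stageUsed`
#'   (`exact`, `vernacular`, `fuzzy1`, `fuzzy2`,
#'   `authorship_stripped_exact`, `authorship_stripped_fuzzy1`,
#'   `authorship_stripped_fuzzy2`, `none`) and `candidates`, a tibble of the
#'   matched records with `totalDistance` and `similarity` columns.
#' @export
#' @examples
#' tax <- generate_taxonomy(n_genera = 3, species_per_genus = 2, seed = 1)
#' idx <- build_index(tax$records)
#' match_name(tax$records$scientificName[1], idx)$status
match_name <- function(name, index, datasets = NULL,
                       config = default_config()) {
  stopifnot(inherits(index, "name_index"))
  query <- normalize_name(if (is.na(name)) "" else name, config)
  res <- list(query = query, status = "Unmatch", stageUsed = "none",
              candidates = empty_candidates(index))
  class(res) <- "match_result"
  if (!nzchar(query)) return(res)

  run <- run_cascade(query, index, datasets, stage_prefix = "")
  if (is.null(run)) {
    parsed <- parse_name(query, config)
    if (has_authorship(parsed) && nzchar(parsed$scientificName[1]) &&
        parsed$scientificName[1] != query) {
      run <- run_cascade(parsed$scientificName[1], index, datasets,
                         stage_prefix = "authorship_stripped_")
    }
  }
  if (is.null(run)) return(res)
  res$status <- run$status
  res$stageUsed <- run$stage
  res$candidates <- sort_candidates(run$candidates, index, config)
  res
}

# one pass of the exact -> vernacular -> fuzzy1 -> fuzzy2 cascade; NULL when
# every stage is empty
run_cascade <- function(query, index, datasets, stage_prefix) {
  in_sets <- function(recs) {
    if (is.null(datasets)) rep(TRUE, nrow(recs)) else recs$datasetID %in% datasets
  }
  ids <- lookup_exact(index, query)
  if (length(ids)) {
    recs <- records_by_id(index, ids)
    keep <- in_sets(recs)
    sci <- keep & !recs$isVernacular
    if (any(sci)) {
      return(list(status = "Match", stage = paste0(stage_prefix, "exact"),
                  candidates = with_scores(recs[sci, ], 0L, query)))
    }
    if (nzchar(stage_prefix) == FALSE && any(keep & recs$isVernacular)) {
      vrecs <- recs[keep & recs$isVernacular, ]
      return(list(status = "Vernacular", stage = "vernacular",
                  candidates = with_scores(vrecs, 0L, query)))
    }
  }
  for (d in c(1L, 2L)) {
    hits <- lookup_fuzzy(index, query, d = d)
    if (nrow(hits)) {
      recs <- records_by_id(index, hits$recordID)
      keep <- in_sets(recs)
      if (any(keep)) {
        return(list(status = "Recorrect",
                    stage = paste0(stage_prefix, "fuzzy", d),
                    candidates = with_scores(recs[keep, ],
                                             hits$totalDistance[keep], query)))
      }
    }
  }
  NULL
}

with_scores <- function(recs, total_distance, query) {
  recs$totalDistance <- as.integer(total_distance)
  recs$similarity <- name_similarity(query, recs$scientificName)
  recs
}

empty_candidates <- function(index) {
  recs <- index$records[0, , drop = FALSE]
  recs$totalDistance <- integer(0)
  recs$similarity <- numeric(0)
  recs
}

sort_candidates <- function(cands, index, config) {
  ds_order <- match(cands$datasetID, config$datasets$datasetID)
  ds_order[is.na(ds_order)] <- nrow(config$datasets) + 1L
  ord <- order(-cands$similarity, nchar(cands$scientificName),
               cands$scientificName, ds_order, cands$recordID)
  cands[ord, , drop = FALSE]
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> \"", x$query, "\": ", x$status,
      " (stage ", x$stageUsed, ", ", nrow(x$candidates), " candidate(s))\n",
      sep = "")
  if (nrow(x$candidates)) {
    top <- x$candidates[1, ]
    cat("  top: ", top$scientificName, " [", top$datasetID, "] similarity ",
        sprintf("%.4f", top$similarity), "\n", sep = "")
  }
  invisible(x)
}

#' Match a batch of names
#'
#' Element-wise [match_name()] with the submission limit of the matching
#' service enforced: at most `config$batch_limit` (default 1000) names per
#' call.
#'
#' @param names character vector of raw names (1 to `batch_limit` elements;
#'   an empty vector returns an empty list).
#' @inheritParams match_name
#' @return a list of `match_result` objects, in input order.
#' @export
match_batch <- function(names, index, datasets = NULL,
                        config = default_config()) {
  if (length(names) > config$batch_limit) {
    stop("batch limit exceeded: ", length(names), " names submitted, at most ",
         config$batch_limit, " allowed per submission")
  }
  lapply(names, match_name, index = index, datasets = datasets,
         config = config)
}

#' Tabulate batch match results as a report
#'
#' Flattens a list of `match_result`s into the downloadable-report shape:
#' one row per query with its best candidate (or empty fields for
#' `Unmatch`).
#'
#' @param results a list of `match_result` objects from [match_batch()].
#' @return a tibble with columns `query`, `status`, `matchedName`,
#'   `matchedAuthorship`, `similarity`, `totalDistance`, `datasetID`,
#'   `taxonID`, `stageUsed`.
#' @export
match_report <- function(results) {
  rows <- lapply(results, function(r) {
    if (nrow(r$candidates)) {
      top <- r$candidates[1, ]
      tibble::tibble(query = r$query, status = r$status,
                     matchedName = top$scientificName,
                     matchedAuthorship = top$scientificNameAuthorship,
                     similarity = top$similarity,
                     totalDistance = top$totalDistance,
                     datasetID = top$datasetID, taxonID = top$taxonID,
                     stageUsed = r$stageUsed)
    } else {
      tibble::tibble(query = r$query, status = r$status, matchedName = "",
                     matchedAuthorship = "", similarity = NA_real_,
                     totalDistance = NA_integer_, datasetID = "",
                     taxonID = "", stageUsed = r$stageUsed)
    }
  })
  do.call(rbind, rows)
}
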