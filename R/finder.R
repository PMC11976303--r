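#' Tokenize free text into words with character offsets
#'
#' Tokens are maximal runs of letters, hyphen-minus, period, apostrophe or
#' the hybrid sign `×`. Offsets are 0-based character (not byte) positions
#' into the original text, half-open: the slice `[start, end)` reproduces the
#' token exactly.
#'
#' @param text a single character string.
#' @return a tibble with columns `token`, `start`, `end` (integer offsets).
#' @export
#' @examples
#' tokenize_text("Camellia sinensis.")
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(0), start = integer(0),
                          end = integer(0)))
  }
  m <- gregexpr("[\\p{L}×.'’-]+", text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(0), start = integer(0),
                          end = integer(0)))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tibble::tibble(token = regmatches(text, list(m))[[1]],
                 start = start, end = start + as.integer(len))
}

# trailing sentence punctuation that may cling to the last word of a phrase
strip_terminal <- function(tok) sub("[.,;:!?'’]+$", "", tok)

# a token opens a name candidate when it starts with an uppercase letter or
# the hybrid sign
opens_candidate <- function(tok) grepl("^[×\\p{Lu}]", tok, perl = TRUE)

#' Find whole scientific names in free text
#'
#' Scans the text left to right. A token starting with an uppercase letter or
#' `×` opens a candidate phrase, which is extended token by token while some
#' indexed name still starts with the accumulated tokens
#' ([phrase_prefix_count()] > 0). When extension stops, the longest prefix of
#' the accumulated phrase that is a *complete* indexed name (exact lookup
#' non-empty) is emitted; a phrase that is merely a viable prefix is never
#' emitted. This is what makes combinations absent from the index — a valid
#' genus with a valid epithet that never co-occur as a binomial — invisible
#' to the finder. Scanning resumes after the emitted match, so matches are
#' non-overlapping and leftmost-longest.
#'
#' Terminal sentence punctuation clinging to the last word of a phrase is
#' stripped before index queries, and excluded from the emitted offsets.
#'
#' @param text a single character string.
#' @param index a [build_index()] object.
#' @param config a [tn_config()] object.
#' @return a tibble of matches sorted by `start`: columns `scientificName`
#'   (the normalized text slice), `start`, `end` (0-based, half-open
#'   character offsets), `taxonRank`, `taxonomicStatus` (from the best-ranked
#'   matching record) and `recordIDs` (list column of matching record IDs).
#' @export
#' @examples
#' tax <- generate_taxonomy(n_genera = 2, species_per_genus = 2, seed = 4)
#' idx <- build_index(tax$records)
#' nm <- tax$records$scientificName[tax$records$taxonRank == "species"][1]
#' find_names(paste("We saw", nm, "yesterday."), idx)
find_names <- function(text, index, config = default_config()) {
  stopifnot(inherits(index, "name_index"))
  toks <- tokenize_text(text)
  out <- list()
  i <- 1L
  n <- nrow(toks)
  while (i <= n) {
    if (!opens_candidate(toks$token[i])) { i <- i + 1L; next }
    best <- NULL   # longest complete name seen for this opening
    j <- i
    while (j <= n) {
      phrase <- toks$token[i:j]
      probe <- phrase_variants(phrase)
      hit <- NULL
      viable <- FALSE
      for (v in probe) {
        if (is.null(hit)) {
          ids <- lookup_exact(index, paste(v$tokens, collapse = " "))
          if (length(ids)) hit <- list(v = v, ids = ids)
        }
        if (!viable && phrase_prefix_count(index, v$tokens) > 0) viable <- TRUE
      }
      if (!is.null(hit)) {
        end <- toks$end[j] - hit$v$stripped
        best <- list(ids = hit$ids, j = j, end = end)
      }
      if (!viable) break
      j <- j + 1L
    }
    if (!is.null(best)) {
      slice <- substr(text, toks$start[i] + 1L, best$end)
      recs <- records_by_id(index, best$ids)
      top <- recs[order(recs$isVernacular, recs$taxonRank,
                        recs$recordID), ][1, ]
      out[[length(out) + 1L]] <- tibble::tibble(
        scientificName = normalize_name(slice, config),
        start = toks$start[i], end = as.integer(best$end),
        taxonRank = top$taxonRank, taxonomicStatus = top$taxonomicStatus,
        recordIDs = list(sort(best$ids))
      )
      i <- best$j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(tibble::tibble(scientificName = character(0), start = integer(0),
                          end = integer(0), taxonRank = character(0),
                          taxonomicStatus = character(0), recordIDs = list()))
  }
  do.call(rbind, out)
}

# the raw phrase plus, when the last token carries terminal punctuation, the
# stripped variant; `stripped` counts characters removed from the last token
phrase_variants <- function(tokens) {
  k <- length(tokens)
  variants <- list(list(tokens = tokens, stripped = 0L))
  bare <- strip_terminal(tokens[k])
  if (bare != tokens[k] && nzchar(bare)) {
    t2 <- tokens
    t2[k] <- bare
    variants[[2]] <- list(tokens = t2,
                          stripped = nchar(tokens[k]) - nchar(bare))
  }
  variants
}

#' Render found names as highlighted HTML
#'
#' Wraps every match from [find_names()] in `<mark>` tags — a portable,
#' plain-text rendering of "highlight the found names in the document".
#'
#' @param text the text passed to [find_names()].
#' @param matches the tibble returned by [find_names()] on that text.
#' @return a single HTML string.
#' @export
render_highlighted <- function(text, matches) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  if (!nrow(matches)) return(paste0("<p>", esc(text), "</p>"))
  pieces <- character(0)
  pos <- 0L
  for (r in seq_len(nrow(matches))) {
    s <- matches$start[r]; e <- matches$end[r]
    pieces <- c(pieces, esc(substr(text, pos + 1L, s)),
                paste0("<mark>", esc(substr(text, s + 1L, e)), "</mark>"))
    pos <- e
  }
  pieces <- c(pieces, esc(substr(text, pos + 1L, nchar(text))))
  paste0("<p>", paste(pieces, collapse = ""), "</p>")
}
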