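#' Parse scientific names into their nomenclatural parts
#'
#' Decomposes each name string into the parts defined by binomial
#' nomenclature: `genusOrAbove`, `specificEpithet`, an optional rank marker
#' with `infraspecificEpithet`, the `scientificNameAuthorship` and, when the
#' authorship carries one, the `namePublishedInYear`.
#'
#' The walk is left to right over space-separated tokens. The first token must
#' be a capitalized (optionally hybrid-sign-prefixed) word and becomes
#' `genusOrAbove`; a single-word name is a genus-or-above name and nothing
#' else. Lowercase tokens then fill `specificEpithet` and
#' `infraspecificEpithet`, the latter optionally introduced by a rank marker
#' (`var.`, `subsp.`, `ssp.`, `f.`, `subvar.`, `subf.`, `cv.`). `f.` is read
#' as a rank marker only when a lowercase epithet follows; otherwise it is the
#' author abbreviation for *filius*. The authorship begins at the first token
#' after the name part that is capitalized, parenthesized, an abbreviation
#' containing a period, or a bare year; everything from there is authorship
#' and the last standalone four-digit year token in `[year_min, current
#' year]` is split off as `namePublishedInYear`. Hybrid markers written
#' `_x` (flat-file style) or as a detached `×` are canonicalized onto the
#' following word before parsing.
#'
#' Names whose trailing tokens fit neither the epithet grammar nor the
#' authorship grammar parse partially: the consumed part is returned and the
#' remainder is preserved in `unparsedTail` with `parseRemark =
#' "parsed_partial"`. The parser never errors on any printable input; an
#' empty or non-name string yields `parseRemark = "unparsable"`.
#'
#' @param x character vector of names (normalized with [normalize_name()]
#'   first; parsing normalizes again, which is a no-op on normalized input).
#' @param config a [tn_config()] object.
#' @return a tibble with one row per input and columns `verbatim`,
#'   `parseRemark` (`parsed`, `parsed_partial` or `unparsable`),
#'   `scientificName` (canonical name without authorship), `genusOrAbove`,
#'   `specificEpithet`, `rankMarker`, `infraspecificEpithet`,
#'   `scientificNameAuthorship`, `namePublishedInYear`, `unparsedTail`.
#'   All columns are character; absent parts are empty strings.
#' @export
#' @examples
#' parse_name("Acer palmatum Thunb.")
#' parse_name("Poa annua var. annua L. 1753")
parse_name <- function(x, config = default_config()) {
  stopifnot(is.character(x))
  rows <- lapply(x, parse_one, config = config)
  out <- tibble::as_tibble(do.call(rbind, rows))
  out
}

rank_markers <- c("var.", "subsp.", "ssp.", "f.", "subvar.", "subf.", "cv.")

parse_one <- function(name, config) {
  empty <- c(verbatim = if (is.na(name)) "" else name,
             parseRemark = "unparsable", scientificName = "",
             genusOrAbove = "", specificEpithet = "", rankMarker = "",
             infraspecificEpithet = "", scientificNameAuthorship = "",
             namePublishedInYear = "", unparsedTail = "")
  if (is.na(name)) return(empty)
  norm <- normalize_name(name, config)
  empty["verbatim"] <- norm
  if (!nzchar(norm)) return(empty)

  toks <- canonicalize_hybrid(strsplit(norm, " ", fixed = TRUE)[[1]])
  if (!length(toks) || !is_genus_token(toks[1])) {
    empty["unparsedTail"] <- paste(toks, collapse = " ")
    return(empty)
  }

  genus <- toks[1]
  sp <- ""; marker <- ""; infra <- ""; auth <- ""; tail <- ""
  i <- 2L; n <- length(toks)
  while (i <= n) {
    tok <- toks[i]
    if (tok %in% rank_markers && nzchar(sp) && !nzchar(infra) &&
        i < n && is_epithet_token(toks[i + 1]) &&
        !(tok == "f." && !is_epithet_token(toks[i + 1]))) {
      marker <- tok
      infra <- toks[i + 1]
      i <- i + 2L
    } else if (is_epithet_token(tok)) {
      if (!nzchar(sp)) sp <- tok
      else if (!nzchar(infra)) infra <- tok  # autonym-style trinomial, no marker
      else { tail <- paste(toks[i:n], collapse = " "); break }
      i <- i + 1L
    } else if (is_author_start(tok)) {
      auth <- paste(toks[i:n], collapse = " ")
      i <- n + 1L
    } else {
      tail <- paste(toks[i:n], collapse = " ")
      break
    }
  }

  sci <- paste(c(genus,
                 if (nzchar(sp)) sp,
                 if (nzchar(marker)) marker,
                 if (nzchar(infra)) infra), collapse = " ")
  ay <- split_authorship_year(auth, config)
  c(verbatim = norm,
    parseRemark = if (nzchar(tail)) "parsed_partial" else "parsed",
    scientificName = sci, genusOrAbove = genus, specificEpithet = sp,
    rankMarker = marker, infraspecificEpithet = infra,
    scientificNameAuthorship = ay$author[1],
    namePublishedInYear = ay$year[1], unparsedTail = tail)
}

# "_x" (flat-file hybrid marker) and a detached hybrid sign both attach to the
# following word as the canonical "×" prefix
canonicalize_hybrid <- function(toks) {
  toks <- sub("^_x(?=\\p{L})", "×", toks, perl = TRUE)
  lone <- toks %in% c("_x", "×", "x", "X") &
    c(rep(TRUE, max(length(toks) - 1, 0)), FALSE)
  # only the explicit markers are attached; a bare x/X is left alone
  lone <- lone & toks %in% c("_x", "×")
  if (any(lone)) {
    keep <- rep(TRUE, length(toks))
    for (j in which(lone)) {
      toks[j + 1] <- paste0("×", toks[j + 1])
      keep[j] <- FALSE
    }
    toks <- toks[keep]
  }
  toks
}

is_genus_token <- function(tok) {
  grepl("^×?\\p{Lu}[\\p{L}'-]*$", tok, perl = TRUE)
}

is_epithet_token <- function(tok) {
  grepl("^×?\\p{Ll}[\\p{L}'-]*$", tok, perl = TRUE) &&
    !tok %in% rank_markers
}

is_author_start <- function(tok) {
  startsWith(tok, "(") ||
    grepl("^\\p{Lu}", tok, perl = TRUE) ||
    (grepl("\\.", tok, fixed = FALSE) && grepl("\\p{L}", tok, perl = TRUE)) ||
    grepl("^\\(?\\d{4}\\)?[.,]?$", tok)
}

#' Split an authorship string into author and publication year
#'
#' The year is the last standalone four-digit token within the configured
#' range (1700 to the current year by default), optionally parenthesized or
#' carrying trailing punctuation; the author is the remainder with normalized
#' spacing. When no such token exists the year is empty.
#'
#' @param authorship character vector of authorship strings (as detected by
#'   [parse_name()]).
#' @param config a [tn_config()] object.
#' @return a tibble with character columns `author` and `year`, one row per
#'   input.
#' @export
#' @examples
#' split_authorship_year("(Thunb.) Siebold & Zucc. 1845")
split_authorship_year <- function(authorship, config = default_config()) {
  stopifnot(is.character(authorship))
  year_max <- as.integer(format(Sys.Date(), "%Y"))
  res <- lapply(authorship, function(a) {
    if (is.na(a) || !nzchar(a)) return(c(author = "", year = ""))
    toks <- strsplit(a, " ", fixed = TRUE)[[1]]
    m <- regmatches(toks, regexec("^\\(?(\\d{4})\\)?[.,]?$", toks))
    yr_val <- vapply(m, function(g) if (length(g)) as.integer(g[2]) else NA_integer_,
                     integer(1))
    ok <- which(!is.na(yr_val) & yr_val >= config$year_min & yr_val <= year_max)
    if (!length(ok)) return(c(author = trimws(a), year = ""))
    pick <- ok[length(ok)]
    author <- paste(toks[-pick], collapse = " ")
    author <- sub(",$", "", trimws(author))
    c(author = author, year = as.character(yr_val[pick]))
  })
  tibble::as_tibble(do.call(rbind, res))
}

# TRUE where a parsed name row carries authorship information
has_authorship <- function(parsed) {
  nzchar(parsed$scientificNameAuthorship) | nzchar(parsed$namePublishedInYear)
}
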