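#' Normalize the writing form of scientific name strings
#'
#' Canonicalizes raw name strings so that every downstream operation (parsing,
#' indexing, matching, finding) sees one standardized writing of each name.
#' Normalization is purely orthographic: it unifies special characters and
#' whitespace but never changes letters, case or diacritics (spelling
#' differences are the matcher's concern).
#'
#' The steps, in order:
#' \enumerate{
#'   \item Unicode compatibility composition (NFKC), so fullwidth and other
#'     compatibility variants collapse to their canonical codepoints;
#'   \item the configured special-character mapping (typographic quotes to
#'     straight ASCII, dashes to hyphen-minus, multiplication-sign lookalikes
#'     to the canonical hybrid sign `×`);
#'   \item insert a space after each character that must keep one (by default
#'     the period) when none follows;
#'   \item convert all whitespace runs to a single space;
#'   \item remove the space before `)` and `,` and after `(`;
#'   \item trim leading and trailing space.
#' }
#'
#' A standalone `x` between words is deliberately never rewritten to the
#' hybrid sign: that inference is wrong too often to automate.
#'
#' @param x character vector of raw name strings. `NA` stays `NA`.
#' @param config a [tn_config()] object.
#' @return character vector of the same length, each element satisfying the
#'   normalized-form invariants (no double spaces, no leading/trailing space,
#'   no space before `)` or `,`, a space after every period unless the next
#'   character is end-of-string or a strip-before character, no characters
#'   from the mapping's source set). Idempotent: normalizing a normalized
#'   string returns it unchanged.
#' @export
#' @examples
#' normalize_name("Acer   palmatum")
#' normalize_name("Quercus robur ( L. )")
normalize_name <- function(x, config = default_config()) {
  if (length(x) == 0) return(character(0))
  stopifnot(is.character(x))
  out <- x
  ok <- !is.na(out)
  if (!any(ok)) return(out)
  s <- stringi::stri_trans_nfkc(out[ok])
  cm <- config$charmap
  if (length(cm)) {
    s <- stringi::stri_replace_all_fixed(s, names(cm), unname(cm),
                                         vectorize_all = FALSE)
  }
  keep <- paste0(escape_rx(config$space_after), collapse = "")
  s <- gsub(paste0("([", keep, "])(?=\\S)"), "\\1 ", s, perl = TRUE)
  s <- gsub("\\s+", " ", s, perl = TRUE)
  before <- paste0(escape_rx(config$strip_before), collapse = "")
  s <- gsub(paste0(" +(?=[", before, "])"), "", s, perl = TRUE)
  after <- paste0(escape_rx(config$strip_after), collapse = "")
  s <- gsub(paste0("([", after, "]) +"), "\\1", s, perl = TRUE)
  out[ok] <- trimws(s)
  out
}

# escape characters for use inside a [] character class
escape_rx <- function(chars) gsub("([][\\^-])", "\\\\\\1", chars)

#' Test whether strings are already in normalized form
#'
#' @param x character vector.
#' @param config a [tn_config()] object.
#' @return logical vector: `TRUE` where `normalize_name(x)` equals `x`.
#' @export
is_normalized <- function(x, config = default_config()) {
  !is.na(x) & normalize_name(x, config) == x
}
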