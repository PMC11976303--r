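#' Toolkit configuration
#'
#' All tunable limits and tables used across the toolkit live in one
#' configuration object: the batch-submission limit, pagination bounds, the
#' fuzzy-matching semantic, the special-character mapping table, the writing
#' convention character sets used by the normalizer, and the dataset registry.
#' Nothing else in the package hard-codes these values.
#'
#' @param file optional path to a `key = value` text file overriding scalar
#'   settings (`batch_limit`, `page_size`, `max_page_size`, `fuzzy_mode`,
#'   `charmap_path`, `datasets_path`). Lines starting with `#` are ignored.
#' @param ... named scalar overrides applied after `file`.
#'
#' @return an object of class `tn_config`: a named list with elements
#'   `batch_limit` (maximum names per match submission, default 1000),
#'   `page_size` / `max_page_size` (retrieval pagination), `fuzzy_mode`
#'   (`"per_token"` or `"whole_string"`), `year_min` (earliest acceptable
#'   publication year, default 1700), `space_after` (characters that must keep
#'   a following space), `strip_before` / `strip_after` (characters whose
#'   neighbouring space is removed), `charmap` (named character vector,
#'   source character -> canonical character) and `datasets` (tibble with
#'   `datasetID`, `datasetName`).
#' @export
#' @examples
#' cfg <- tn_config()
#' cfg$batch_limit
tn_config <- function(file = NULL, ...) {
  cfg <- list(
    batch_limit   = 1000L,
    page_size     = 20L,
    max_page_size = 500L,
    fuzzy_mode    = "per_token",
    year_min      = 1700L,
    space_after   = ".",
    strip_before  = c(")", ","),
    strip_after   = "(",
    charmap_path  = system.file("extdata", "charmap.tsv", package = "taxres"),
    datasets_path = system.file("extdata", "datasets.tsv", package = "taxres")
  )
  if (!is.null(file)) {
    stopifnot(file.exists(file))
    lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) next
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (key %in% c("batch_limit", "page_size", "max_page_size", "year_min")) {
        cfg[[key]] <- as.integer(val)
      } else if (key %in% names(cfg)) {
        cfg[[key]] <- val
      }
    }
  }
  dots <- list(...)
  for (key in names(dots)) cfg[[key]] <- dots[[key]]
  cfg$fuzzy_mode <- match.arg(cfg$fuzzy_mode, c("per_token", "whole_string"))

  cm <- utils::read.delim(cfg$charmap_path, header = TRUE, sep = "\t",
                          quote = "", comment.char = "", encoding = "UTF-8",
                          colClasses = "character")
  cfg$charmap <- stats::setNames(cm$target, cm$source)
  ds <- utils::read.delim(cfg$datasets_path, header = TRUE, sep = "\t",
                          quote = "", encoding = "UTF-8",
                          colClasses = "character")
  cfg$datasets <- tibble::as_tibble(ds)
  structure(cfg, class = "tn_config")
}

#' @export
print.tn_config <- function(x, ...) {
  cat("<tn_config>\n")
  cat("  batch_limit:", x$batch_limit, "| page_size:", x$page_size,
      "| fuzzy_mode:", x$fuzzy_mode, "\n")
  cat("  charmap:", length(x$charmap), "mapped characters |",
      nrow(x$datasets), "registered datasets\n")
  invisible(x)
}

# default config, built once per session on first use
the <- new.env(parent = emptyenv())

default_config <- function() {
  if (is.null(the$config)) the$config <- tn_config()
  the$config
}
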