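# Independent oracles: straightforward, structure-free re-computations used
# to check the indexed/incremental implementations.

# textbook dynamic-programming Levenshtein distance
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  if (n == 0) return(m)
  if (m == 0) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, integer(m))
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[m + 1]
}

# full-scan per-token fuzzy lookup over a record tibble (no buckets, no
# pruning); returns recordID and totalDistance, sorted
brute_fuzzy <- function(records, name, d) {
  recs <- records[!records$isVernacular, , drop = FALSE]
  qtok <- strsplit(tolower(name), " ", fixed = TRUE)[[1]]
  out_id <- integer(0); out_total <- integer(0)
  for (i in seq_len(nrow(recs))) {
    rtok <- strsplit(tolower(recs$scientificName[i]), " ", fixed = TRUE)[[1]]
    if (length(rtok) != length(qtok)) next
    dists <- mapply(function(q, r) as.integer(utils::adist(q, r)), qtok, rtok)
    if (all(dists <= d)) {
      out_id <- c(out_id, recs$recordID[i])
      out_total <- c(out_total, sum(dists))
    }
  }
  ord <- order(out_total, out_id)
  list(recordID = out_id[ord], totalDistance = as.integer(out_total[ord]))
}

# brute-force prefix count with the index's case semantics (first character
# of the leading token compared as written, everything else case-folded)
brute_prefix_count <- function(names, tokens) {
  if (!length(tokens)) return(length(names))
  hits <- 0L
  for (nm in names) {
    nt <- strsplit(nm, " ", fixed = TRUE)[[1]]
    if (length(nt) < length(tokens)) next
    nt <- nt[seq_along(tokens)]
    same_initial <- substr(nt[1], 1, 1) == substr(tokens[1], 1, 1)
    if (same_initial && all(tolower(nt) == tolower(tokens)))
      hits <- hits + 1L
  }
  hits
}

# slide every indexed name over every token position of the text, then
# resolve overlaps leftmost-longest. Matching semantics: the occurrence must
# open with an uppercase letter or the hybrid sign, the genus initial must
# agree as written, other characters case-folded; the last word of the
# occurrence may carry trailing sentence punctuation (excluded from the end
# offset).
brute_find <- function(text, records) {
  toks <- taxres::tokenize_text(text)
  n <- nrow(toks)
  if (!n) return(data.frame(scientificName = character(0),
                            start = integer(0), end = integer(0)))
  names_tok <- strsplit(records$scientificName, " ", fixed = TRUE)
  cand <- list()
  for (i in seq_len(n)) {
    if (!grepl("^[×[:upper:]]", toks$token[i], perl = TRUE)) next
    for (w in seq_along(names_tok)) {
      nt <- names_tok[[w]]
      k <- length(nt)
      if (i + k - 1 > n) next
      ok <- TRUE
      stripped <- 0L
      for (p in seq_len(k)) {
        tt <- toks$token[i + p - 1]
        if (p == k) {
          bare <- sub("[.,;:!?'’]+$", "", tt)
          if (tolower(tt) == tolower(nt[p])) {
            stripped <- 0L
          } else if (nzchar(bare) && tolower(bare) == tolower(nt[p])) {
            stripped <- nchar(tt) - nchar(bare)
          } else { ok <- FALSE; break }
        } else if (tolower(tt) != tolower(nt[p])) { ok <- FALSE; break }
        if (p == 1 && substr(tt, 1, 1) != substr(nt[1], 1, 1)) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        cand[[length(cand) + 1]] <- data.frame(
          tok_start = i, tok_end = i + k - 1,
          start = toks$start[i], end = toks$end[i + k - 1] - stripped)
      }
    }
  }
  if (!length(cand)) return(data.frame(scientificName = character(0),
                                       start = integer(0), end = integer(0)))
  cand <- do.call(rbind, cand)
  # leftmost-longest, non-overlapping (in token space, as the scanner resumes
  # after the emitted match)
  cand <- cand[order(cand$tok_start, -cand$tok_end), ]
  out <- list()
  next_tok <- 1L
  for (r in seq_len(nrow(cand))) {
    if (cand$tok_start[r] < next_tok) next
    # longest candidate at this start position comes first in the ordering
    if (length(out) && cand$tok_start[r] == out[[length(out)]]$tok_start) next
    out[[length(out) + 1]] <- cand[r, ]
    next_tok <- cand$tok_end[r] + 1L
  }
  res <- do.call(rbind, out)
  data.frame(
    scientificName = taxres::normalize_name(
      substr(rep(text, nrow(res)), res$start + 1L, res$end)),
    start = res$start, end = res$end)
}

# random printable strings for fuzz/property tests
random_strings <- function(n, max_len = 30) {
  pool <- c(letters, LETTERS, " ", ".", "(", ")", "×", "-", "'", "0":"9")
  vapply(seq_len(n), function(i) {
    paste(sample(pool, sample.int(max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}
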