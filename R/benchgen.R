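#' Generate a reproducible synthetic name backbone
#'
#' Builds a multi-rank, Darwin-Core-shaped summary table emulating the
#' structure of an integrated name backbone: genera, binomials, a fraction of
#' infraspecific names with rank markers, hybrid-sign names, authorship
#' strings (some with publication years), synonym-to-accepted links and
#' vernacular names linked to accepted species. Words are pseudo-Latin
#' syllable strings, so every generated scientific name is well-formed under
#' the parser's grammar (an invariant the test suite relies on). Generation
#' is fully deterministic for a given seed and parameter set.
#'
#' @param n_genera number of genera.
#' @param species_per_genus accepted+synonym species per genus.
#' @param infraspecific_fraction fraction of accepted species that carry one
#'   infraspecific name (`var.`, `subsp.` or `f.`).
#' @param synonym_fraction fraction of species that are synonyms linked to an
#'   accepted congener.
#' @param vernacular_fraction fraction of accepted species with one
#'   vernacular-name record.
#' @param authorship_fraction fraction of species/infraspecific names with an
#'   authorship string.
#' @param year_fraction fraction of authored names whose record carries a
#'   publication year.
#' @param hybrid_fraction fraction of species written as hybrids
#'   (`Genus ×epithet`).
#' @param dataset_id dataset code stamped on every record.
#' @param seed integer seed; same seed and parameters give identical records.
#' @return an object of class `synthetic_taxonomy`: list with `records` (a
#'   summary-record tibble accepted by [build_index()]) and `params`.
#' @export
#' @examples
#' tax <- generate_taxonomy(n_genera = 5, species_per_genus = 3, seed = 42)
#' nrow(tax$records)
generate_taxonomy <- function(n_genera = 40, species_per_genus = 8,
                              infraspecific_fraction = 0.15,
                              synonym_fraction = 0.2,
                              vernacular_fraction = 0.1,
                              authorship_fraction = 0.8,
                              year_fraction = 0.5,
                              hybrid_fraction = 0.05,
                              dataset_id = "SYN", seed = 1L) {
  stopifnot(n_genera >= 0, species_per_genus >= 0,
            infraspecific_fraction >= 0, infraspecific_fraction <= 1,
            synonym_fraction >= 0, synonym_fraction <= 1,
            vernacular_fraction >= 0, vernacular_fraction <= 1)
  params <- list(n_genera = n_genera, species_per_genus = species_per_genus,
                 infraspecific_fraction = infraspecific_fraction,
                 synonym_fraction = synonym_fraction,
                 vernacular_fraction = vernacular_fraction,
                 authorship_fraction = authorship_fraction,
                 year_fraction = year_fraction,
                 hybrid_fraction = hybrid_fraction,
                 dataset_id = dataset_id, seed = seed)
  recs <- withr::with_seed(as.integer(seed), gen_records(params))
  structure(list(records = recs, params = params),
            class = "synthetic_taxonomy")
}

#' @export
print.synthetic_taxonomy <- function(x, ...) {
  cat("<synthetic_taxonomy>", nrow(x$records), "records | seed",
      x$params$seed, "\n")
  print(table(x$records$taxonRank))
  invisible(x)
}

author_pool <- c("L.", "Mill.", "Thunb.", "DC.", "Benth.", "Hook. f.",
                 "(L.) Kuntze", "Siebold & Zucc.", "(Thunb.) Steud.",
                 "A. Gray", "Sm.", "Lam.")

vern_first <- c("Misty", "Golden", "Dwarf", "Silver", "Creeping", "Mountain",
                "Weeping", "Crimson", "Marsh", "Alpine")
vern_second <- c("oakleaf", "bellflower", "thornbush", "rockcress",
                 "milkwort", "firethorn", "spleenwort", "bladderpod",
                 "toadflax", "hartstongue")

rand_words <- function(n, min_syl, max_syl) {
  cons <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  out <- character(0)
  while (length(out) < n) {
    batch <- vapply(seq_len(max(2L * (n - length(out)), 16L)), function(i) {
      k <- sample(min_syl:max_syl, 1)
      paste0(paste0(sample(cons, k, replace = TRUE),
                    sample(vow, k, replace = TRUE), collapse = ""),
             sample(c("", "s", "m", "r"), 1))
    }, character(1))
    out <- unique(c(out, batch))
  }
  out[seq_len(n)]
}

cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

gen_records <- function(p) {
  if (p$n_genera == 0) return(empty_records())
  genera <- cap(rand_words(p$n_genera, 3, 4))
  n_sp_total <- p$n_genera * p$species_per_genus
  epithets <- rand_words(max(n_sp_total * 2, 10), 2, 4)

  rows <- list()
  rid <- 0L
  add <- function(taxonID, name, author = "", rank = "", status = "accepted",
                  accepted = "", parent = "", year = "", vern = FALSE) {
    rid <<- rid + 1L
    rows[[rid]] <<- tibble::tibble(
      recordID = rid, taxonID = taxonID, datasetID = p$dataset_id,
      scientificName = name, scientificNameAuthorship = author,
      taxonRank = rank, taxonomicStatus = status,
      acceptedNameUsageID = accepted, parentNameUsageID = parent,
      namePublishedInYear = year, higherClassification = "",
      isVernacular = vern)
    rid
  }
  maybe_author <- function() {
    if (stats::runif(1) < p$authorship_fraction) sample(author_pool, 1) else ""
  }
  maybe_year <- function(author) {
    if (nzchar(author) && stats::runif(1) < p$year_fraction) {
      as.character(sample(1753:2020, 1))
    } else ""
  }

  ei <- 0L
  next_epithet <- function() { ei <<- ei + 1L; epithets[ei] }
  markers <- c("var.", "subsp.", "f.")
  vi <- 0L

  for (g in seq_len(p$n_genera)) {
    gid <- sprintf("g%04d", g)
    add(gid, genera[g], rank = "genus")
    if (p$species_per_genus == 0) next
    n_syn <- round(p$species_per_genus * p$synonym_fraction)
    status <- c(rep("accepted", p$species_per_genus - n_syn),
                rep("synonym", n_syn))
    accepted_ids <- character(0)
    for (s in seq_len(p$species_per_genus)) {
      ep <- next_epithet()
      if (stats::runif(1) < p$hybrid_fraction) ep <- paste0("×", ep)
      sid <- sprintf("s%04d_%02d", g, s)
      au <- maybe_author()
      yr <- maybe_year(au)
      is_syn <- status[s] == "synonym" && length(accepted_ids) > 0
      add(sid, paste(genera[g], ep), author = au, rank = "species",
          status = if (is_syn) "synonym" else "accepted",
          accepted = if (is_syn) sample(accepted_ids, 1) else "",
          parent = gid, year = yr)
      if (!is_syn) {
        accepted_ids <- c(accepted_ids, sid)
        if (stats::runif(1) < p$infraspecific_fraction) {
          mk <- sample(markers, 1)
          iep <- next_epithet()
          au2 <- maybe_author()
          add(sprintf("i%04d_%02d", g, s),
              paste(genera[g], ep, mk, iep), author = au2,
              rank = c("var." = "variety", "subsp." = "subspecies",
                       "f." = "form")[[mk]],
              parent = sid, year = maybe_year(au2))
        }
        if (stats::runif(1) < p$vernacular_fraction) {
          vi <- vi + 1L
          add(sprintf("v%04d", vi),
              paste(sample(vern_first, 1), sample(vern_second, 1)),
              status = "", accepted = sid, vern = TRUE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a summary-record table as a Darwin-Core-style TSV
#'
#' The written file round-trips through [ingest_records()].
#'
#' @param records a summary-record tibble or a `synthetic_taxonomy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_dwc <- function(records, path) {
  if (inherits(records, "synthetic_taxonomy")) records <- records$records
  out <- records[, setdiff(names(records), "recordID"), drop = FALSE]
  out$isVernacular <- ifelse(out$isVernacular, "true", "false")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Corrupt a name by seeded random edits in every word
#'
#' Applies `edits_per_word` character edits to each whitespace-delimited word
#' of the name, emulating misspelled input at a controlled edit distance.
#' Substitutions (the default) replace a randomly chosen letter with a
#' different letter of the same case, so for words of length at least
#' `edits_per_word` the per-word Levenshtein distance from the source is
#' exactly `edits_per_word` (for at most 2 edits on equal-length words the
#' distance cannot collapse below the number of changed positions). Word
#' structure is never touched: spaces are preserved. Words shorter than
#' `edits_per_word` receive as many edits as they have letters; the total
#' shortfall is recorded in the `shortfall` attribute.
#'
#' @param name a non-empty normalized name string.
#' @param edits_per_word 0, 1 or 2 edits per word.
#' @param kind `"substitution"` (default) or `"mixed"` (each edit is a
#'   substitution, insertion or deletion, chosen at random, giving per-word
#'   distance at most `edits_per_word`).
#' @param seed optional integer seed for reproducibility.
#' @return the corrupted name, with integer attribute `shortfall`.
#' @export
#' @examples
#' perturb_name("Acer palmatum", edits_per_word = 1, seed = 7)
perturb_name <- function(name, edits_per_word = 1L,
                         kind = c("substitution", "mixed"), seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            edits_per_word >= 0)
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed),
                            perturb_name(name, edits_per_word, kind)))
  }
  words <- strsplit(name, " ", fixed = TRUE)[[1]]
  shortfall <- 0L
  out <- vapply(words, function(w) {
    chars <- strsplit(w, "")[[1]]
    letter_pos <- which(grepl("\\p{L}", chars, perl = TRUE))
    k <- min(edits_per_word, length(letter_pos))
    shortfall <<- shortfall + (edits_per_word - k)
    if (k == 0) return(w)
    pos <- sort(sample_vec(letter_pos, k))
    for (pi in rev(pos)) {
      op <- if (kind == "substitution") "sub" else
        sample(c("sub", "ins", "del"), 1)
      if (op == "sub") {
        cur <- chars[pi]
        pool <- if (grepl("\\p{Lu}", cur, perl = TRUE)) LETTERS else letters
        pool <- setdiff(pool, cur)
        chars[pi] <- sample(pool, 1)
      } else if (op == "ins") {
        chars <- append(chars, sample(letters, 1), after = pi)
      } else {
        chars <- chars[-pi]
      }
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  structure(paste(out, collapse = " "), shortfall = shortfall)
}

# sample() without the length-1 surprise
sample_vec <- function(x, k) x[sample.int(length(x), k)]

#' Corrupt a vector of names under one seed
#'
#' @param names character vector of names.
#' @inheritParams perturb_name
#' @param seed integer seed covering the whole vector.
#' @return character vector of corrupted names (attributes dropped).
#' @export
perturb_names <- function(names, edits_per_word = 1L,
                          kind = c("substitution", "mixed"), seed = 1L) {
  kind <- match.arg(kind)
  withr::with_seed(as.integer(seed), {
    vapply(names, function(nm) as.character(perturb_name(nm, edits_per_word,
                                                         kind)),
           character(1), USE.NAMES = FALSE)
  })
}

#' Run the name-corruption matching benchmark
#'
#' For each test category (typically correct names, names with one random
#' wrong character per word, and names with two), matches every name against
#' the index and counts it as recalled when the matcher returns `Match` or
#' `Recorrect` (vernacular hits do not count).
#'
#' @param test_sets named list of character vectors of test names.
#' @param index a [build_index()] object.
#' @param config a [tn_config()] object.
#' @return a tibble with columns `category`, `n`, `recalled`, `recall_pct`.
#' @export
run_match_benchmark <- function(test_sets, index, config = default_config()) {
  stopifnot(is.list(test_sets), !is.null(names(test_sets)))
  rows <- lapply(names(test_sets), function(cat) {
    nms <- test_sets[[cat]]
    status <- vapply(nms, function(nm) match_name(nm, index,
                                                  config = config)$status,
                     character(1), USE.NAMES = FALSE)
    rec <- sum(status %in% c("Match", "Recorrect"))
    tibble::tibble(category = cat, n = length(nms), recalled = rec,
                   recall_pct = if (length(nms)) 100 * rec / length(nms)
                                else NA_real_)
  })
  do.call(rbind, rows)
}

#' Build benchmark test sets from an indexed backbone
#'
#' Samples `n_per_category` indexed scientific names and derives the three
#' standard categories: the names as written, every word corrupted by one
#' random substitution, and every word corrupted by two.
#'
#' @param index a [build_index()] object.
#' @param n_per_category names per category (sampled with replacement if the
#'   index is smaller).
#' @param seed integer seed.
#' @param min_words only sample names with at least this many words
#'   (default 2, i.e. binomials and below).
#' @return named list with elements `correct`, `one_char`, `two_char`.
#' @export
make_benchmark_sets <- function(index, n_per_category = 2000L, seed = 1L,
                                min_words = 2L) {
  pool <- unique(index$records$scientificName[!index$records$isVernacular])
  pool <- pool[lengths(strsplit(pool, " ", fixed = TRUE)) >= min_words]
  stopifnot(length(pool) > 0)
  withr::with_seed(as.integer(seed), {
    base <- sample_vec(rep(pool, length.out = max(n_per_category,
                                                  length(pool))),
                       n_per_category)
    list(correct = base,
         one_char = perturb_names(base, 1L, seed = seed + 1L),
         two_char = perturb_names(base, 2L, seed = seed + 2L))
  })
}

#' Run the parsing benchmark
#'
#' Parses every name and tabulates the parse outcomes; names that do not
#' parse fully are listed verbatim.
#'
#' @param names character vector of names.
#' @param config a [tn_config()] object.
#' @return a list with `counts` (tibble of `parseRemark`, `n`), `failures`
#'   (character vector of names with remark other than `parsed`) and
#'   `success_pct`.
#' @export
run_parse_benchmark <- function(names, config = default_config()) {
  if (!length(names)) {
    return(list(counts = tibble::tibble(parseRemark = character(0),
                                        n = integer(0)),
                failures = character(0), success_pct = NA_real_))
  }
  parsed <- parse_name(names, config)
  tab <- table(parsed$parseRemark)
  list(counts = tibble::tibble(parseRemark = names(tab), n = as.integer(tab)),
       failures = parsed$verbatim[parsed$parseRemark != "parsed"],
       success_pct = 100 * mean(parsed$parseRemark == "parsed"))
}
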