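# fixture builders: small record tables and indexes assembled in code

make_records <- function(names, dataset = "FIX", rank = "species",
                         status = "accepted", authorship = "",
                         year = "", vernacular = FALSE, taxon_id = NULL) {
  n <- length(names)
  tibble::tibble(
    recordID = seq_len(n),
    taxonID = if (is.null(taxon_id)) sprintf("t%03d", seq_len(n)) else taxon_id,
    datasetID = rep_len(dataset, n),
    scientificName = names,
    scientificNameAuthorship = rep_len(authorship, n),
    taxonRank = rep_len(rank, n),
    taxonomicStatus = rep_len(status, n),
    acceptedNameUsageID = rep_len("", n),
    parentNameUsageID = rep_len("", n),
    namePublishedInYear = rep_len(year, n),
    higherClassification = rep_len("", n),
    isVernacular = rep_len(vernacular, n)
  )
}

small_index <- function(names, ...) taxres::build_index(make_records(names, ...))

# the classic three-name fixture: a genus, a binomial in it, and a binomial
# whose epithet is valid elsewhere — "Camellia henryi" is NOT in the index
camellia_index <- function() {
  recs <- make_records(c("Camellia", "Camellia sinensis", "Thea henryi"),
                       rank = c("genus", "species", "species"))
  taxres::build_index(recs)
}

# a text that embeds given names among noise words and absent combinations
make_text <- function(names, extra = character(0)) {
  noise <- c("We", "collected", "several", "specimens", "near", "the",
             "river", "and", "dried", "them.", "The", "site", "was", "wet.")
  parts <- c(sample(noise, 4), names[1],
             sample(noise, 3), extra,
             if (length(names) > 1) names[-1], sample(noise, 3))
  paste(parts, collapse = " ")
}

# an "absent binomial": genus of one indexed name + epithet of another,
# skipped if the combination happens to be indexed
absent_binomial <- function(index) {
  recs <- index$records[!index$records$isVernacular, ]
  sp <- recs$scientificName[lengths(strsplit(recs$scientificName, " ")) == 2]
  if (length(sp) < 2) return(NULL)
  for (i in seq_len(50)) {
    a <- strsplit(sample(sp, 1), " ")[[1]]
    b <- strsplit(sample(sp, 1), " ")[[1]]
    combo <- paste(a[1], b[2])
    if (!length(taxres::lookup_exact(index, combo))) return(combo)
  }
  NULL
}

write_fixture_tsv <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path, useBytes = FALSE)
  path
}
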