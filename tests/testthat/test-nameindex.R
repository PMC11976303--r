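fixture_tsv <- function() {
  write_fixture_tsv(c(
    "taxonID\tscientificName\ttaxonRank\ttaxonomicStatus",
    "t1\tAcer\tgenus\taccepted",
    "t2\tAcer palmatum\tspecies\taccepted",
    "t3\tAcer pseudoplatanus\tspecies\taccepted"),
    ext = ".tsv")
}

test_that("taxon tables ingest with counts, skips and schema errors", {
  st <- record_store()
  n <- ingest_records(st, fixture_tsv(), "COL")
  expect_equal(as.integer(n), 3L)
  expect_equal(attr(n, "skipped"), 0L)
  expect_equal(nrow(store_records(st)), 3)

  with_blank <- write_fixture_tsv(c(
    "taxonID\tscientificName\ttaxonRank\ttaxonomicStatus",
    "t1\tAcer\tgenus\taccepted",
    "t2\t\tspecies\taccepted",
    "t3\tAcer palmatum\tspecies\taccepted",
    "t4\tAcer pseudoplatanus\tspecies\taccepted"))
  st2 <- record_store()
  n2 <- ingest_records(st2, with_blank, "COL")
  expect_equal(as.integer(n2), 3L)
  expect_equal(attr(n2, "skipped"), 1L)
  expect_length(st2$skip_log, 1)

  header_only <- write_fixture_tsv("taxonID\tscientificName")
  expect_equal(as.integer(ingest_records(record_store(), header_only, "COL")),
               0L)

  bad <- write_fixture_tsv("taxonID\tname\nx\ty")
  expect_error(ingest_records(record_store(), bad, "COL"), "scientificName")
  expect_error(ingest_records(record_store(), "no-such-file.tsv", "COL"),
               "not found")
})

test_that("CSV ingests like TSV and names are normalized on ingest", {
  csv <- write_fixture_tsv(c("taxonID,scientificName",
                             "t1,Acer   palmatum"), ext = ".csv")
  st <- record_store()
  ingest_records(st, csv, "WFO")
  expect_equal(store_records(st)$scientificName, "Acer palmatum")
})

test_that("ingest is deterministic and per-dataset counts are conserved", {
  path <- fixture_tsv()
  st1 <- record_store(); ingest_records(st1, path, "COL")
  st2 <- record_store(); ingest_records(st2, path, "COL")
  expect_identical(store_records(st1), store_records(st2))

  ingest_records(st1, path, "WFO")
  recs <- store_records(st1)
  expect_equal(sum(table(recs$datasetID)), nrow(recs))
  # same name from two datasets resolves to two records
  idx <- build_index(recs)
  expect_length(lookup_exact(idx, "Acer palmatum"), 2)
})

test_that("exact lookup is case-insensitive on the full string", {
  idx <- small_index(c("Acer", "Acer palmatum"))
  ids <- lookup_exact(idx, "Acer palmatum")
  expect_length(ids, 1)
  expect_identical(lookup_exact(idx, "acer PALMATUM"), ids)
  expect_length(lookup_exact(idx, "Acer palmatun"), 0)
  expect_length(lookup_exact(idx, ""), 0)
})

test_that("token-prefix counts match the brute-force definition", {
  idx <- small_index(c("Acer", "Acer palmatum"))
  expect_equal(phrase_prefix_count(idx, "Acer"), 2L)
  expect_equal(phrase_prefix_count(idx, c("Acer", "palmatum")), 1L)
  expect_equal(phrase_prefix_count(idx, character(0)), 2L)
  expect_equal(phrase_prefix_count(idx, "Zea"), 0L)

  cam <- camellia_index()
  expect_equal(phrase_prefix_count(cam, "Camellia"), 2L)
  # the combination absent from the index counts zero
  expect_equal(phrase_prefix_count(cam, c("Camellia", "henryi")), 0L)

  # randomized agreement with the brute-force count
  tax <- generate_taxonomy(n_genera = 15, species_per_genus = 4, seed = 9)
  idx2 <- build_index(tax$records)
  nms <- tax$records$scientificName
  withr::local_seed(10)
  for (i in 1:50) {
    nm <- sample(nms, 1)
    tk <- strsplit(nm, " ", fixed = TRUE)[[1]]
    tk <- tk[seq_len(sample.int(length(tk), 1))]
    expect_equal(phrase_prefix_count(idx2, tk), brute_prefix_count(nms, tk),
                 info = paste(tk, collapse = " "))
  }
  # an empty index answers empty everywhere
  idx0 <- build_index(make_records(character(0)))
  expect_equal(phrase_prefix_count(idx0, "Acer"), 0L)
  expect_length(lookup_exact(idx0, "Acer"), 0)
  expect_equal(nrow(lookup_fuzzy(idx0, "Acer", 1)), 0)
})

test_that("the distance primitive agrees with a hand-written DP", {
  withr::local_seed(11)
  pool <- c("", "a", "acer", "palmatum", "palmatun", "×bora")
  pairs <- cbind(sample(c(pool, random_strings(40, 12)), 60, replace = TRUE),
                 sample(c(pool, random_strings(40, 12)), 60, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    expect_equal(as.integer(utils::adist(pairs[r, 1], pairs[r, 2])),
                 lev_dp(pairs[r, 1], pairs[r, 2]),
                 info = paste(pairs[r, ], collapse = " / "))
  }
})

test_that("fuzzy lookup returns per-token distances as specified", {
  idx <- small_index("Acer palmatum")
  h1 <- lookup_fuzzy(idx, "Acer palmatun", d = 1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$tokenDistances[[1]], c(0L, 1L))
  expect_equal(h1$totalDistance, 1L)

  h0 <- lookup_fuzzy(idx, "Acer palmatum", d = 1)
  expect_equal(h0$totalDistance, 0L)

  h2 <- lookup_fuzzy(idx, "Azer palmatun", d = 1)
  expect_equal(h2$tokenDistances[[1]], c(1L, 1L))
  expect_equal(h2$totalDistance, 2L)

  # token-count mismatch never matches in per-token mode
  expect_equal(nrow(lookup_fuzzy(idx, "Acer", d = 2)), 0)
  # but the whole-string mode can bridge it
  idxw <- small_index(c("Acer palmatum", "Acer palmata"))
  hw <- lookup_fuzzy(idxw, "Acer palmatum L", d = 2, mode = "whole_string")
  expect_true(1L %in% hw$recordID)
})

test_that("fuzzy lookup equals the full-scan oracle on random indexes", {
  withr::local_seed(12)
  for (trial in 1:4) {
    tax <- generate_taxonomy(n_genera = 10 + 5 * trial,
                             species_per_genus = 4, seed = 100 + trial)
    idx <- build_index(tax$records)
    pool <- tax$records$scientificName[!tax$records$isVernacular]
    queries <- c(
      sample(pool, 10),
      perturb_names(sample(pool, 15), 1, seed = trial),
      perturb_names(sample(pool, 15), 2, seed = trial + 50),
      random_strings(10, 20))
    for (q in queries) {
      for (d in c(1L, 2L)) {
        got <- lookup_fuzzy(idx, q, d)
        want <- brute_fuzzy(tax$records, q, d)
        expect_equal(got$recordID, want$recordID, info = paste(q, d))
        expect_equal(got$totalDistance, want$totalDistance,
                     info = paste(q, d))
      }
    }
  }
})
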