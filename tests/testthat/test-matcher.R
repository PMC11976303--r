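test_that("similarity is the normalized edit similarity", {
  expect_equal(name_similarity("Acer palmatum", "Acer palmatum"), 1.0)
  expect_equal(name_similarity("Acer palmatum", "Acer palmatun"), 1 - 1 / 13)
  expect_equal(name_similarity("", "Acer"), 0.0)
  expect_equal(name_similarity("", ""), 1.0)
  expect_equal(name_similarity("ACER", "acer"), 1.0)
  # symmetry
  withr::local_seed(21)
  a <- random_strings(25, 15); b <- random_strings(25, 15)
  expect_equal(name_similarity(a, b), name_similarity(b, a))
  expect_true(all(name_similarity(a, b) >= 0 & name_similarity(a, b) <= 1))
})

test_that("the cascade stops at the first stage with hits", {
  idx <- small_index(c("Acer palmatum", "Acer campestre"))

  m <- match_name("Acer palmatum", idx)
  expect_equal(m$status, "Match")
  expect_equal(m$stageUsed, "exact")
  expect_equal(m$candidates$similarity[1], 1.0)

  m1 <- match_name("Acer palmatun", idx)
  expect_equal(m1$status, "Recorrect")
  expect_equal(m1$stageUsed, "fuzzy1")
  expect_equal(m1$candidates$scientificName[1], "Acer palmatum")
  expect_equal(m1$candidates$totalDistance[1], 1L)

  m2 <- match_name("Azer palmatun", idx)
  expect_equal(m2$status, "Recorrect")
  expect_equal(m2$stageUsed, "fuzzy1")

  m3 <- match_name("Aper kalmatuq", idx)   # 2 per token
  expect_equal(m3$stageUsed, "fuzzy2")

  u <- match_name("Qqqq zzzz", idx)
  expect_equal(u$status, "Unmatch")
  expect_equal(u$stageUsed, "none")
  expect_equal(nrow(u$candidates), 0)

  blank <- match_name("   ", idx)
  expect_equal(blank$status, "Unmatch")
})

test_that("authorship is stripped and the cascade repeated", {
  idx <- small_index("Acer palmatum")
  m <- match_name("Acer palmatum Thunb.", idx)
  expect_equal(m$status, "Match")
  expect_equal(m$stageUsed, "authorship_stripped_exact")

  m1 <- match_name("Acer palmatun Thunb.", idx)
  expect_equal(m1$status, "Recorrect")
  expect_equal(m1$stageUsed, "authorship_stripped_fuzzy1")
  expect_equal(m1$candidates$scientificName[1], "Acer palmatum")
})

test_that("vernacular names match exactly and distinctly", {
  recs <- rbind(make_records("Camellia sinensis"),
                make_records("Tea plant", vernacular = TRUE, rank = "",
                             status = ""))
  recs$recordID <- 1:2
  recs$acceptedNameUsageID[2] <- recs$taxonID[1]
  idx <- build_index(recs)
  v <- match_name("Tea plant", idx)
  expect_equal(v$status, "Vernacular")
  expect_equal(v$stageUsed, "vernacular")
  # no fuzzy matching into vernacular names
  expect_equal(match_name("Tea plont", idx)$status, "Unmatch")
})

test_that("the dataset filter restricts candidates", {
  recs <- rbind(make_records("Acer palmatum", dataset = "COL"),
                make_records("Acer campestre", dataset = "WFO"))
  recs$recordID <- 1:2
  idx <- build_index(recs)
  m <- match_name("Acer palmatum", idx, datasets = "COL")
  expect_equal(m$status, "Match")
  expect_true(all(m$candidates$datasetID == "COL"))
  # the only exact hit lives outside the filter: the name falls through
  m2 <- match_name("Acer palmatum", idx, datasets = "WFO")
  expect_false(identical(m2$stageUsed, "exact") && m2$status == "Match" &&
                 any(m2$candidates$datasetID == "COL"))
  expect_true(all(m2$candidates$datasetID %in% "WFO"))
})

test_that("candidates are sorted by similarity with deterministic ties", {
  idx <- small_index(c("Bora mela", "Bora melas", "Bora melu"))
  m <- match_name("Bora mel", idx)
  expect_equal(m$status, "Recorrect")
  expect_true(all(diff(m$candidates$similarity) <= 1e-12))
  # equal similarity ties break by length then name
  tie <- m$candidates[m$candidates$similarity ==
                        max(m$candidates$similarity), ]
  if (nrow(tie) > 1) {
    expect_true(all(diff(nchar(tie$scientificName)) >= 0))
  }
})

test_that("batch matching enforces the submission limit", {
  idx <- small_index("Acer palmatum")
  two <- match_batch(c("Acer palmatum", "Qqqq"), idx)
  expect_length(two, 2)
  expect_equal(two[[1]]$status, "Match")
  expect_equal(two[[2]]$status, "Unmatch")
  expect_length(match_batch(character(0), idx), 0)

  thousand <- rep("Acer palmatum", 1000)
  expect_length(match_batch(thousand, idx), 1000)
  expect_error(match_batch(c(thousand, "x"), idx), "1000")

  rep_tbl <- match_report(two)
  expect_equal(rep_tbl$query, c("Acer palmatum", "Qqqq"))
  expect_equal(rep_tbl$matchedName, c("Acer palmatum", ""))
})

test_that("cascade stages are sound against the index primitives", {
  tax <- generate_taxonomy(n_genera = 12, species_per_genus = 4, seed = 31)
  idx <- build_index(tax$records)
  pool <- tax$records$scientificName[!tax$records$isVernacular]
  withr::local_seed(32)
  queries <- c(sample(pool, 10), perturb_names(sample(pool, 10), 1, seed = 3),
               perturb_names(sample(pool, 10), 2, seed = 4),
               random_strings(10))
  for (q in queries) {
    m <- match_name(q, idx)
    qn <- normalize_name(q)
    if (m$stageUsed == "exact") {
      expect_gt(length(lookup_exact(idx, qn)), 0)
    } else if (m$stageUsed == "fuzzy1") {
      expect_gt(nrow(lookup_fuzzy(idx, qn, 1)), 0)
      expect_true(all(m$candidates$totalDistance >= 1))
    } else if (m$stageUsed == "fuzzy2") {
      expect_equal(nrow(lookup_fuzzy(idx, qn, 1)), 0)
      expect_gt(nrow(lookup_fuzzy(idx, qn, 2)), 0)
    } else if (m$stageUsed == "none") {
      expect_equal(nrow(m$candidates), 0)
      expect_equal(m$status, "Unmatch")
    }
    expect_true(all(diff(m$candidates$similarity) <= 1e-12))
  }
})

test_that("one substitution per word is always recalled", {
  tax <- generate_taxonomy(n_genera = 15, species_per_genus = 5, seed = 41)
  idx <- build_index(tax$records)
  pool <- unique(tax$records$scientificName[
    tax$records$taxonRank == "species"])
  withr::local_seed(42)
  for (i in 1:150) {
    src <- sample(pool, 1)
    bad <- as.character(perturb_name(src, 1))
    m <- match_name(bad, idx)
    if (length(lookup_exact(idx, bad))) {
      # the corruption collided with another indexed spelling
      expect_equal(m$status, "Match")
    } else {
      expect_equal(m$status, "Recorrect", info = paste(src, "->", bad))
      expect_true(src %in% m$candidates$scientificName)
    }
  }
})
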