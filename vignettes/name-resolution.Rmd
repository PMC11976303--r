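---
title: "Resolving scientific names: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving scientific names: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxres)
```

`taxres` resolves scientific plant names against an integrated,
Darwin-Core-shaped name table. This vignette explains each operation's
model, the parameters that matter, the places where the design was genuinely
open and how they were decided, and what the test evidence does and does not
show about real data.

## The name table and its index

Every operation queries one container: a tibble of summary records with the
Darwin Core core terms (`taxonID`, `scientificName`,
`scientificNameAuthorship`, `taxonRank`, `taxonomicStatus`,
`acceptedNameUsageID`, `parentNameUsageID`, `namePublishedInYear`,
`higherClassification`), a `datasetID` provenance column and an
`isVernacular` flag. Records are kept in an in-memory store with a TSV
round-trip (`export_dwc()` / `ingest_records()`); at the scale this package
targets (up to a few hundred thousand rows) rebuilding the index from a flat
file on load is cheap, so no embedded database is used.

`build_index()` derives three structures:

- an **exact table**: case-folded full name → record IDs (a hashed
  environment, O(1) lookup);
- a **token-prefix table**: every leading token sequence of every indexed
  name → how many names start with it. Keys case-fold everything except the
  first character of the leading token, because a genus initial is a writing
  convention, not spelling variation: `camellia sinensis` should not open a
  name candidate in text, but `CAMELLIA SINENSIS` is just shouting.
- **per-token-count buckets** for fuzzy lookup: for each token count *k*,
  the aligned token columns of all *k*-token scientific names with their
  lengths.

## Fuzzy matching semantics

"Differs by one character" is ambiguous between whole-string and per-word
readings. `taxres` implements the **per-token** semantic as the default:
a query matches an indexed name at level *d* when both have the same number
of space-separated tokens and *every* aligned token pair is within
Levenshtein distance *d* (distances computed case-folded; `utils::adist`
provides the primitive). The per-token reading is what makes names corrupted
in *every* word still recallable — a binomial with one wrong character in
the genus *and* one in the epithet is whole-string distance 2 but per-token
distance 1, and a binomial with two wrong characters per word is per-token
distance 2 yet whole-string distance 4. A `whole_string` mode is available
through the configuration (`tn_config(fuzzy_mode = "whole_string")`) for
comparison.

Two consequences of the token alignment are worth stating. First, fuzzy
lookup never bridges different token counts, so a trinomial never fuzzily
matches a binomial; the authorship-stripping stage of the matcher handles
the common case (query with authorship vs. indexed canonical name) instead.
Second, completeness is a checkable contract: candidate pruning uses only
the length bound |len(a) − len(b)| ≤ Lev(a, b), so the pruned scan returns
exactly what a full scan returns. The test suite verifies this equivalence
against an independent full-scan oracle on hundreds of randomized queries,
and validates `adist` itself once against a hand-written dynamic program.

## The matching cascade

`match_name()` runs: exact → vernacular exact → fuzzy *d* = 1 → fuzzy
*d* = 2 → (if the parser detects an authorship) the same cascade on the
stripped name part. The first stage with a hit terminates the cascade.
Status labels: distance-0 hits are `Match` (also after authorship
stripping), fuzzy hits `Recorrect`, vernacular hits `Vernacular`, an empty
cascade `Unmatch`.

Candidates are scored with the normalized edit similarity
`1 − Lev(a,b)/max(|a|,|b|)` on case-folded whole strings — no similarity
formula is canonical here, and this one has the two properties the status
labels need: it is 1 exactly on a case-folded equal pair and 0 against an
empty string. Ties at equal similarity break by ascending name length, then
lexicographically, then dataset registry order, so output is deterministic.

Vernacular names participate in the exact stage only: fuzzy correction of
common names has no defensible distance semantics across languages, so a
misspelled vernacular is `Unmatch` rather than a guess.

The optional dataset filter restricts which records count as hits at every
stage, but does not reorder stages. A stage whose only hits lie outside the
filter does not terminate the cascade — otherwise a result could claim a
match status while carrying zero visible candidates.

The batch entry point `match_batch()` enforces the submission limit
(`tn_config()$batch_limit`, default 1000 names) as a hard error, mirroring
the service contract it models.

## Finding names in text

`tokenize_text()` splits text into maximal runs of letters, hyphen, period,
apostrophe and the hybrid sign, with 0-based half-open character offsets.
`find_names()` scans left to right: a token starting with an uppercase
letter or `×` opens a candidate; the phrase extends while the prefix table
says some indexed name starts with it; when extension stops, the longest
prefix of the phrase that is a **complete** indexed name is emitted, and
scanning resumes after it (non-overlapping, leftmost-longest).

The single most consequential design decision lives here. A literal
"emit the last viable intermediate phrase" rule would report phrases that
are prefixes of indexed names without being names — precisely the failure
mode of genus-and-epithet-independently-valid tools, where *Camellia
henryi* (a valid genus, an epithet valid in another genus, a combination in
no checklist) is reported as a binomial. `taxres` instead backtracks to the
longest complete name, so every emitted string has a non-empty exact
lookup; on that text it reports only `Camellia`. Genus-only matches are
emitted when a longer combination fails — defensible either way, and chosen
because a bare genus mention in text is still a name occurrence.

Terminal sentence punctuation clinging to a phrase's last word is stripped
for index queries and excluded from the emitted offsets; punctuation inside
a name (rank markers, author abbreviations) is untouched. Sentence-initial
capitalized ordinary words cost one failed prefix probe and nothing else;
no linguistic filtering is attempted.

The naive algorithm — slide every indexed name over every position — is
retained in the test suite as the oracle, and the incremental scanner must
agree with it exactly (names and offsets) on every generated fixture.

## Parsing

The parser walks tokens left to right. The first token must be a
capitalized, optionally hybrid-prefixed word (`genusOrAbove`); a single-word
name is genus-or-above and nothing else. Lowercase tokens fill
`specificEpithet`, then `infraspecificEpithet`, the latter optionally
introduced by a rank marker from {`var.`, `subsp.`, `ssp.`, `f.`,
`subvar.`, `subf.`, `cv.`}. The classic ambiguity of `f.` (forma vs.
*filius*) is resolved by lookahead: a rank marker only when a lowercase
epithet follows. Authorship detection has no canonical rule, so the package
centralizes one heuristic: the first token after the name part that is
capitalized, parenthesized, a period-bearing abbreviation or a bare year
starts the authorship, which is consumed to the end of the string. The
publication year is the last standalone four-digit token in
[1700, current year] — the floor keeps collector numbers and page numbers
out of the year field; both bounds sit in the configuration.

Inputs that fit neither grammar degrade rather than fail: the parsed part
is returned with the unconsumed tail preserved (`parsed_partial`), and only
empty or non-name strings are `unparsable`. The parser never raises, which
the suite checks by fuzzing. Known limitation: lowercase authorship
prefixes (`de`, `van`) directly after an epithet are mistaken for epithets;
avoiding that requires an author-name lexicon, which is out of scope.

## Normalization

Normalization unifies writing, never spelling: NFKC compatibility
composition, then a configurable single-character mapping (typographic
quotes and dashes to ASCII, multiplication-sign lookalikes to `×`), then
the space rules — insert a space after a period lacking one, collapse
whitespace runs, remove spaces before `)` and `,` and after `(`, trim. The
order matters and is what makes the function idempotent. Case and
diacritics are preserved: case conventions carry nomenclatural information
used elsewhere (genus initials, the finder's opening rule) and diacritic
differences are spelling differences, which the matcher's edit distance
already absorbs. A standalone `x` between words is never promoted to the
hybrid sign — too many legitimate strings contain a bare x — while `_x` and
a detached `×` are attached to the following word during parsing.

## The synthetic backbone and the benchmark

`generate_taxonomy()` builds the study fixture: pseudo-Latin genera and
epithets (consonant-vowel syllable strings, so every generated name is
well-formed under the parser's grammar), with defaults chosen to emulate a
realistic checklist slice — 80% of species carry authorship, half of those
a year, 20% synonymy with accepted congeners, 15% infraspecific names, 10%
vernaculars, 5% hybrid-sign names. Generation is deterministic per seed,
and exports round-trip through ingestion byte-for-byte.

`perturb_name()` implements the corruption protocol: each
whitespace-delimited word receives a fixed number of random edits;
substitutions (the default) replace a letter with a different letter of the
same case, never touching spaces. For at most two substitutions on a word
of sufficient length the per-word Levenshtein distance equals the number of
substitutions exactly — a single length-preserving edit is necessarily one
substitution, so two changed positions cannot collapse to distance 1 — and
the suite verifies this across hundreds of seeded samples. Words shorter
than the edit budget take as many edits as they have letters, with the
shortfall reported. Authorship words, when present in the input, are
corrupted like any other word.

`run_match_benchmark()` counts a name as recalled when its match status is
`Match` or `Recorrect`; vernacular hits do not count. Under per-token
matching, one substitution per word keeps every token at distance 1 and two
substitutions keep it at distance 2, so recall on the synthetic backbone is
100% in all three categories — the benchmark here demonstrates the
mechanism. One boundary case is acknowledged: a corrupted spelling can
collide with a *different* indexed name, in which case the exact stage
claims it (`Match`, still recalled) and the source appears only if the
cascade had continued; the tests state this precondition explicitly.

What the fixture does **not** emulate: real backbones have near-identical
names at scale (gender endings, one-letter epithet variants), heavy
cross-dataset duplication, abbreviated genera, and OCR-specific noise.
Passing tests show the algorithms are correct to their contracts, not that
recall on an eight-million-name production index would be 100% — on such an
index, equal-token-count alignment and the d ≤ 2 cap genuinely lose names,
and corrupted queries can be closer to a different name than to their
source.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely from generated data:
fuzzy-lookup equivalence on 20 random indexes (≤ 1000 names) × 200 queries,
finder equivalence on 5 indexes × 8 texts, recall on 1000 corrupted
binomials, parser round-trip on > 1000 names, and benchmark sizes of 2000
names per matching category and 6000 parsing names. These sizes keep a full
run in the low minutes on one CPU while leaving every property at or above
the sizes the protocol states. All randomness flows from explicit seeds;
there are no tolerances anywhere — every compared quantity (distances,
counts, offsets, statuses) is integer-exact, and similarity values are
compared as exact rationals of integer edit distances.
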