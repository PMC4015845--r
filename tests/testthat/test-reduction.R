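test_that("distinct-peptide dedupe matches a set-size oracle", {
  expect_setequal(distinct_peptides(c("AAK", "AAK", "AAR")), c("AAK", "AAR"))
  expect_equal(distinct_peptides(character()), character())
  withr::with_seed(5, {
    base <- unique(replicate(863, random_protein(10)))
    peps <- sample(c(base, base[sample(length(base), 1000 - length(base), replace = TRUE)]))
  })
  expect_equal(length(distinct_peptides(peps)), length(unique(peps)))
})

test_that("subset-peptide removal keeps maximal peptides only", {
  expect_setequal(remove_subset_peptides(c("PEPTIDER", "TIDE")), "PEPTIDER")
  # overlap without containment keeps both
  expect_setequal(
    remove_subset_peptides(c("ACDEFG", "CDEFGH")),
    c("ACDEFG", "CDEFGH")
  )
  withr::with_seed(13, peps <- random_string_set(500, 60, len_range = c(12, 30)))
  expect_setequal(remove_subset_peptides(peps), oracle_maximal_strings(unique(peps)))
})

test_that("peptide mapping is exhaustive, exact, and flags unmapped peptides", {
  lib <- merge_libraries(make_library("MKVLA", "P1"))
  hit <- map_peptides_to_library("KVL", lib)
  expect_equal(nrow(hit), 1)
  miss <- map_peptides_to_library("WWW", lib)
  expect_equal(nrow(miss), 0)
  expect_equal(attr(miss, "unmapped"), "WWW")
})

test_that("per-protein counters recover planted redundant/distinct/unique counts", {
  lib <- merge_libraries(make_library(
    c("AAAMKVLARBBBPEPTIDEK", "CCCPEPTIDEKDDDFGHIKW"),
    c("P1", "P2")
  ))
  obs <- tibble::tibble(
    peptide = c(rep("MKVLAR", 5), "PEPTIDEK", "FGHIKW"),
    study_id = "s1", reported_accession = NA_character_,
    spectral_count = c(rep(1L, 5), 3L, 2L)
  )
  store <- build_evidence_store(obs, lib)
  counts <- protein_counts(store)
  p1 <- counts[counts$accession == "P1", ]
  p2 <- counts[counts$accession == "P2", ]
  # P1: MKVLAR seen 5x (unique) + shared PEPTIDEK 3x
  expect_equal(p1$redundant_count, 8L)
  expect_equal(p1$distinct_peptide_count, 2L)
  expect_equal(p1$unique_peptide_count, 1L)
  # P2: shared PEPTIDEK 3x + unique FGHIKW 2x
  expect_equal(p2$redundant_count, 5L)
  expect_equal(p2$unique_peptide_count, 1L)
  # invariant
  expect_true(all(counts$redundant_count >= counts$distinct_peptide_count))
  expect_true(all(counts$distinct_peptide_count >= counts$unique_peptide_count))
})

test_that("one peptide seen five times gives (redundant 5, distinct 1)", {
  lib <- merge_libraries(make_library("AAAMKVLARBBB", "P1"))
  obs <- tibble::tibble(
    peptide = rep("MKVLAR", 5), study_id = paste0("s", 1:5),
    reported_accession = "P1", spectral_count = 1L
  )
  counts <- protein_counts(build_evidence_store(obs, lib))
  expect_equal(counts$redundant_count, 5L)
  expect_equal(counts$distinct_peptide_count, 1L)
})

test_that("peptide-to-protein distribution is a conservation-checked histogram", {
  lib <- merge_libraries(make_library(
    c("AAAMKVLARBBBPEPWIDEK", "CCCFGHIKWDDDTTTVVVNK"),
    c("P1", "P2")
  ))
  obs <- tibble::tibble(
    peptide = c("MKVLAR", "PEPWIDEK", "AAAMKV", "FGHIKW"),
    study_id = "s1", reported_accession = NA_character_, spectral_count = 1L
  )
  store <- build_evidence_store(obs, lib)
  dist <- peptide_protein_distribution(store, "distinct")
  expect_equal(sum(dist$n), nrow(protein_counts(store)))
  expect_equal(dist$bin[dist$n == 1], c(1, 3)) # P2 has 1 peptide, P1 has 3
  # empty store -> empty table
  empty <- build_evidence_store(tibble::tibble(), lib)
  expect_equal(nrow(peptide_protein_distribution(empty)), 0)
})

test_that("unique-peptide protein inventory honours the planted ground truth", {
  # peptide shared by exactly two proteins supports neither as unique
  lib <- merge_libraries(make_library(
    c("AAAPEPTIDEKBBB", "CCCPEPTIDEKDDD"),
    c("P1", "P2")
  ))
  obs <- tibble::tibble(
    peptide = "PEPTIDEK", study_id = "s1",
    reported_accession = NA_character_, spectral_count = 1L
  )
  expect_equal(nrow(unique_peptide_proteins(build_evidence_store(obs, lib))), 0)

  # one unique + two shared peptides: in the set, and in the >=3 tier
  lib2 <- merge_libraries(make_library(
    c("AAAMKVLARBBBPEPTIDEKCCCFGHIKW", "DDDPEPTIDEKEEEFGHIKWFFF"),
    c("Q1", "Q2")
  ))
  obs2 <- tibble::tibble(
    peptide = c("MKVLAR", "PEPTIDEK", "FGHIKW"),
    study_id = "s1", reported_accession = NA_character_, spectral_count = 1L
  )
  uniq <- unique_peptide_proteins(build_evidence_store(obs2, lib2))
  expect_equal(uniq$accession, "Q1")
  expect_true(uniq$high_confidence)
  # the >=3 tier is a subset of the unique-peptide set
  expect_true(all(uniq$accession[uniq$high_confidence] %in% uniq$accession))
})

test_that("duplicate observations never change distinct counts or the unique set", {
  fx <- generate_library(n_families = 3, variants_per_family = 2, seed = 21)
  red <- remove_subset_proteins(merge_libraries(fx$library))
  st <- generate_studies(fx$library, n_studies = 2, detection_prob = 0.8, seed = 21)
  store1 <- build_evidence_store(st$observations, red)
  doubled <- dplyr::bind_rows(st$observations, st$observations[1, ])
  store2 <- build_evidence_store(doubled, red)
  c1 <- protein_counts(store1)
  c2 <- protein_counts(store2)
  expect_equal(
    c1[order(c1$accession), c("accession", "distinct_peptide_count", "unique_peptide_count")],
    c2[order(c2$accession), c("accession", "distinct_peptide_count", "unique_peptide_count")]
  )
  expect_equal(
    sort(unique_peptide_proteins(store1)$accession),
    sort(unique_peptide_proteins(store2)$accession)
  )
})

test_that("confidence tiers encode the peptide-count false-positive heuristic", {
  expect_equal(as.character(confidence_tier(1)), "single")
  expect_equal(as.character(confidence_tier(2)), "double")
  expect_equal(as.character(confidence_tier(3)), "high")
  expect_equal(as.character(confidence_tier(250)), "high")
  expect_error(confidence_tier(0), class = "fedprot_domain_error")
  expect_equal(levels(confidence_tier(integer())), c("single", "double", "high"))
})

test_that("tidy() and glance() summarise the store", {
  fx <- generate_library(n_families = 2, variants_per_family = 2, seed = 4)
  red <- remove_subset_proteins(merge_libraries(fx$library))
  st <- generate_studies(fx$library, n_studies = 2, detection_prob = 1, seed = 4)
  store <- build_evidence_store(st$observations, red)
  td <- generics::tidy(store)
  expect_true(all(c("accession", "tier") %in% names(td)))
  gl <- generics::glance(store)
  expect_equal(gl$n_studies, 2)
  expect_equal(gl$n_proteins_detected, nrow(protein_counts(store)))
})
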