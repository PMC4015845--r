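test_that("self-alignment yields full identity with a run spanning the sequence", {
  r <- align_pair("MKVLA", "MKVLA")
  expect_equal(r$n_identities, 5L)
  expect_equal(r$mismatches, 0L)
  expect_equal(r$gap_openings, 0L)
  expect_equal(r$longest_perfect_run, 5L)
  expect_equal(r$alignment_length, 5L)
})

test_that("sequences over disjoint alphabets produce an empty local alignment", {
  r <- align_pair("WWWWW", "AAAAA")
  expect_equal(r$n_identities, 0L)
  expect_equal(r$alignment_length, 0L)
  expect_false(is_match(r))
})

test_that("a planted substitution splits the perfect run at the longer flank", {
  left <- "ACDEFGHIKLMNPQRSTVWY" # 20 residues
  right <- "ACDEFGHIK" # 9 residues
  a <- paste0(left, "A", right) # 30 residues
  b <- paste0(left, "W", right) # single substitution at position 21
  r <- align_pair(a, b)
  expect_equal(r$mismatches, 1L)
  expect_equal(r$longest_perfect_run, 20L)
  expect_equal(r$n_identities, 29L)
  # brute-force run scan over the (gap-free) aligned columns agrees
  expect_equal(r$longest_perfect_run, oracle_longest_run(a, b))
})

test_that("alignment scores agree with an affine-gap dynamic-programming oracle", {
  withr::with_seed(17, {
    pairs <- lapply(1:20, function(k) {
      a <- random_protein(sample(10:30, 1))
      b <- if (k %% 3 == 0) {
        # related pair: mutate / delete a few residues of a
        v <- strsplit(a, "")[[1]]
        v[sample(length(v), 2)] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 2)
        paste(v[-sample(length(v), 1)], collapse = "")
      } else {
        random_protein(sample(10:30, 1))
      }
      list(a = a, b = b)
    })
  })
  for (p in pairs) {
    got <- align_pair(p$a, p$b)$score
    want <- oracle_sw_score(p$a, p$b, blosum62, gap_open = 11, gap_ext = 1)
    expect_equal(got, want, info = paste(p$a, p$b))
  }
})

test_that("BLAST tabular import reconstructs identities field by field", {
  path <- withr::local_tempfile(fileext = ".tsv")
  lines <- c(
    "q1\ts1\t100.00\t50\t0\t0\t1\t50\t1\t50\t1e-30\t100",
    "q1\ts2\t80.00\t40\t8\t0\t1\t40\t5\t44\t1e-10\t60.5",
    "q2\ts1\t75.00\t100\t20\t5\t1\t95\t1\t99\t2.5e-200\t310",
    "q3\ts3\t66.67\t30\t10\t0\t1\t30\t1\t30\t0.001\t25"
  )
  writeLines(lines, path)
  got <- import_blast_tabular(path)
  expect_equal(nrow(got), 4)
  expect_equal(got$n_identities, c(50L, 32L, 75L, 20L))
  expect_equal(got$mismatches, c(0L, 8L, 20L, 10L))
  expect_equal(got$gap_openings, c(0L, 0L, 5L, 0L))
  expect_equal(got$e_value, c(1e-30, 1e-10, 2.5e-200, 0.001))
  expect_equal(got$bitscore, c(100, 60.5, 310, 25))
  expect_true(all(is.na(got$longest_perfect_run)))

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_equal(nrow(import_blast_tabular(empty)), 0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t100.0\t50", bad)
  expect_error(import_blast_tabular(bad), "line 1", class = "fedprot_parse_error")
})

test_that("the match criterion is strict at 75% identity and 20-residue runs", {
  row <- function(frac, run, qlen = 100) tibble::tibble(
    query_id = "q", subject_id = "s",
    n_identities = as.integer(frac * qlen), alignment_length = qlen,
    mismatches = 0L, gap_openings = 0L, longest_perfect_run = as.integer(run),
    score = 1, bitscore = NA_real_, e_value = NA_real_,
    query_length = qlen, subject_length = qlen
  )
  expect_false(is_match(row(0.75, 25))) # boundary: strict inequality
  expect_false(is_match(row(0.80, 19))) # run one short
  expect_true(is_match(row(0.80, 25)))
  expect_true(is_match(row(0.76, 20)))
  expect_error(is_match(row(0.8, 25, qlen = 0)), class = "fedprot_domain_error")
  # imported rows without runs require re-alignment
  expect_error(
    is_match(dplyr::mutate(row(0.8, 25), longest_perfect_run = NA_integer_)),
    class = "fedprot_domain_error"
  )
})

test_that("tightening the criterion is monotone in both parameters", {
  withr::with_seed(23, {
    rows <- tibble::tibble(
      query_id = "q", subject_id = "s",
      n_identities = sample(50:100, 40, replace = TRUE),
      alignment_length = 100L, mismatches = 0L, gap_openings = 0L,
      longest_perfect_run = sample(5L:60L, 40, replace = TRUE),
      score = 1, bitscore = NA_real_, e_value = NA_real_,
      query_length = 100L, subject_length = 100L
    )
  })
  base <- sum(is_match(rows, match_criterion(0.75, 20)))
  expect_lte(sum(is_match(rows, match_criterion(0.85, 20))), base)
  expect_lte(sum(is_match(rows, match_criterion(0.75, 30))), base)
})

test_that("top hit per query takes the best non-self hit with deterministic ties", {
  mk <- function(q, s, bs, ev = 1e-5) tibble::tibble(
    query_id = q, subject_id = s, n_identities = 10L, alignment_length = 10L,
    mismatches = 0L, gap_openings = 0L, longest_perfect_run = 10L,
    score = bs, bitscore = bs, e_value = ev, query_length = 10L,
    subject_length = 10L
  )
  res <- dplyr::bind_rows(
    mk("q1", "s1", 50), mk("q1", "s2", 40),
    mk("q2", "q2", 99), # self-hit only: omitted
    mk("q3", "sB", 30), mk("q3", "sA", 30) # tie -> lexicographic subject
  )
  top <- top_hit_per_query(res)
  expect_equal(top$subject_id[top$query_id == "q1"], "s1")
  expect_false("q2" %in% top$query_id)
  expect_equal(top$subject_id[top$query_id == "q3"], "sA")
  # tie on bitscore broken by lower e-value first
  res2 <- dplyr::bind_rows(mk("q4", "sZ", 30, ev = 1e-20), mk("q4", "sA", 30, ev = 1e-5))
  expect_equal(top_hit_per_query(res2)$subject_id, "sZ")
})

test_that("collapse partitions the library into planted families plus singletons", {
  fx <- generate_library(n_families = 4, variants_per_family = 3,
    fragment_fraction = 0, seed = 31)
  lib <- merge_libraries(fx$library)
  clusters <- collapse_types(lib)
  # partition: every protein in exactly one cluster, sizes sum to library size
  expect_setequal(clusters$accession, lib$accession)
  expect_equal(nrow(clusters), nrow(lib))
  expect_equal(sum(table(clusters$cluster_id)), nrow(lib))
  # planted family structure recovered exactly
  memb <- merge(clusters, fx$truth, by = "accession")
  expect_equal(dplyr::n_distinct(clusters$cluster_id), 4)
  for (cl in unique(memb$cluster_id)) {
    expect_equal(dplyr::n_distinct(memb$family[memb$cluster_id == cl]), 1)
  }
  # representatives are members
  expect_true(all(clusters$representative %in% clusters$accession))
})

test_that("proteins with no matching edge stay singletons; chains close transitively", {
  # no edges among unrelated proteins
  withr::with_seed(37, seqs <- replicate(5, random_protein(80)))
  lib <- merge_libraries(make_library(seqs))
  cl <- collapse_types(lib)
  expect_equal(sum(cl$is_singleton), 5)

  # chain q1-q2, q2-q3 collapses to one 3-member type even without a q1-q3 edge
  mk <- function(q, s) tibble::tibble(
    query_id = q, subject_id = s, n_identities = 90L, alignment_length = 100L,
    mismatches = 0L, gap_openings = 0L, longest_perfect_run = 50L,
    score = 100, bitscore = NA_real_, e_value = NA_real_,
    query_length = 100L, subject_length = 100L
  )
  lib3 <- make_library(
    vapply(c(100, 100, 100), random_protein, character(1)),
    c("q1", "q2", "q3")
  )
  cl3 <- collapse_types(merge_libraries(lib3), top_hits = dplyr::bind_rows(
    mk("q1", "q2"), mk("q2", "q3")
  ))
  expect_equal(dplyr::n_distinct(cl3$cluster_id), 1)
  expect_equal(cl3$n_members, rep(3L, 3))
})

test_that("variant singletons survive when each family has one member", {
  fx <- generate_library(n_families = 3, variants_per_family = 1,
    fragment_fraction = 0, seed = 41)
  cl <- collapse_types(merge_libraries(fx$library))
  expect_equal(sum(cl$is_singleton), 3)
})

test_that("alignment distributions conserve counts and isolate the machine-zero bin", {
  self <- align_pair("ACDEFGHIKLMNPQRSTVWY", "ACDEFGHIKLMNPQRSTVWY")
  d <- alignment_distributions(self)
  expect_equal(d$gap_openings$bin, "0")
  expect_equal(d$mismatches$bin, "0 (none)")
  expect_equal(d$percent_identity$bin, "100")

  path <- withr::local_tempfile()
  writeLines(c(
    "q1\ts1\t90.0\t100\t10\t1\t1\t100\t1\t100\t1e-200\t200",
    "q2\ts2\t80.0\t50\t10\t0\t1\t50\t1\t50\t1e-5\t60",
    "q3\ts3\t70.0\t40\t12\t2\t1\t40\t1\t40\t0\t30"
  ), path)
  imported <- import_blast_tabular(path)
  dd <- alignment_distributions(imported)
  # e-values below 1e-180 (and exact zeros) fall in the machine-zero bin
  expect_equal(dd$e_value$n[dd$e_value$bin == "machine zero"], 2)
  # conservation: every table's frequencies sum to the alignments counted
  expect_equal(sum(dd$e_value$n), 3)
  expect_equal(sum(dd$gap_openings$n), 3)
  expect_equal(sum(dd$mismatches$n), 3)
  expect_equal(sum(dd$percent_identity$n), 3)

  withr::with_seed(43, {
    many <- tibble::tibble(
      query_id = "q", subject_id = "s",
      n_identities = sample(10:90, 50, replace = TRUE),
      alignment_length = 100L,
      mismatches = sample(0:30, 50, replace = TRUE),
      gap_openings = sample(0:5, 50, replace = TRUE),
      longest_perfect_run = 10L, score = 1, bitscore = NA_real_,
      e_value = 10^(-sample(0:220, 50, replace = TRUE)),
      query_length = 100L, subject_length = 100L
    )
  })
  dm <- alignment_distributions(many)
  for (tab in dm) expect_equal(sum(tab$n), 50)
})

test_that("fragment-direction asymmetry exists per query but not in the partition", {
  parent <- withr::with_seed(47, random_protein(200))
  fragment <- substr(parent, 41, 100) # 60 residues, exact subset
  fwd <- align_pair(fragment, parent) # fragment as query: full coverage
  rev <- align_pair(parent, fragment) # parent as query: 30% coverage
  crit <- match_criterion()
  expect_true(is_match(fwd, crit))
  expect_false(is_match(rev, crit))
  # component collapse joins them regardless of edge direction
  lib <- merge_libraries(make_library(c(parent, fragment), c("PARENT", "FRAG")))
  cl <- collapse_types(lib, top_hits = dplyr::bind_rows(fwd, rev) |>
    dplyr::mutate(
      query_id = c("FRAG", "PARENT"),
      subject_id = c("PARENT", "FRAG")
    ))
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)
  expect_equal(cl$representative, rep("PARENT", 2))
})
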