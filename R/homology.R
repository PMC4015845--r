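#' Pairwise local protein alignment
#'
#' Smith–Waterman local alignment of two protein sequences (BLOSUM62, gap
#' open 11 / extend 1 by default — the standard BLASTp scoring), returning
#' the tabular alignment statistics used by the match criterion and the
#' distribution summaries: identities, aligned columns, mismatches, gap
#' openings, and the longest perfect run (maximal stretch of identical
#' aligned columns uninterrupted by any mismatch or gap). The internal
#' aligner reports the raw alignment score; e-values and bitscores are only
#' available from imported BLAST tables and are not needed by [is_match()].
#'
#' @param query,subject Protein sequences (character scalars), or single-row
#'   protein library tibbles.
#' @param query_id,subject_id Identifiers; default to the records' accessions
#'   or `"query"`/`"subject"`.
#' @param substitution_matrix Name of the substitution matrix (default
#'   `"BLOSUM62"`).
#' @param gap_opening,gap_extension Gap penalties (defaults 11 and 1).
#' @return A one-row alignment tibble with columns `query_id`, `subject_id`,
#'   `n_identities`, `alignment_length`, `mismatches`, `gap_openings`,
#'   `longest_perfect_run`, `score`, `bitscore`, `e_value`, `query_length`,
#'   `subject_length`.
#' @examples
#' align_pair("MKVLA", "MKVLA")
#' @export
align_pair <- function(query, subject, query_id = NULL, subject_id = NULL,
                       substitution_matrix = "BLOSUM62",
                       gap_opening = 11, gap_extension = 1) {
  qs <- as_sequence(query)
  ss <- as_sequence(subject)
  query_id <- query_id %||% names(qs) %||% "query"
  subject_id <- subject_id %||% names(ss) %||% "subject"
  if (!nzchar(qs) || !nzchar(ss)) {
    abort("cannot align an empty sequence", class = "fedprot_domain_error")
  }
  mat <- get_substitution_matrix(substitution_matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qs), Biostrings::AAString(ss),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  ap <- as.character(Biostrings::alignedPattern(aln))
  as <- as.character(Biostrings::alignedSubject(aln))
  stats <- alignment_column_stats(ap, as)
  tibble(
    query_id = query_id, subject_id = subject_id,
    n_identities = stats$n_identities,
    alignment_length = stats$alignment_length,
    mismatches = stats$mismatches,
    gap_openings = stats$gap_openings,
    longest_perfect_run = stats$longest_perfect_run,
    score = Biostrings::score(aln),
    bitscore = NA_real_, e_value = NA_real_,
    query_length = nchar(qs), subject_length = nchar(ss)
  )
}

as_sequence <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1, "sequence" %in% names(x))
    return(stats::setNames(x$sequence, x$accession %||% NULL))
  }
  stopifnot(is.character(x), length(x) == 1)
  x
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

# per-column statistics from a pair of equal-length aligned strings
alignment_column_stats <- function(aligned_query, aligned_subject) {
  if (!nzchar(aligned_query)) {
    return(list(
      n_identities = 0L, alignment_length = 0L, mismatches = 0L,
      gap_openings = 0L, longest_perfect_run = 0L
    ))
  }
  q <- strsplit(aligned_query, "")[[1]]
  s <- strsplit(aligned_subject, "")[[1]]
  gap <- q == "-" | s == "-"
  ident <- !gap & q == s
  runs <- rle(ident)
  list(
    n_identities = sum(ident),
    alignment_length = length(q),
    mismatches = sum(!gap & q != s),
    gap_openings = count_gap_openings(q) + count_gap_openings(s),
    longest_perfect_run = if (any(ident)) max(runs$lengths[runs$values]) else 0L
  )
}

count_gap_openings <- function(chars) {
  r <- rle(chars == "-")
  sum(r$values)
}

#' Align every pair of library proteins
#'
#' Runs [align_pair()] over all unordered pairs of a library and emits both
#' directions of each pair (the local alignment is symmetric; only
#' `query_length` and hence the identity fraction differ), so
#' [top_hit_per_query()] sees every protein as a query.
#'
#' @param library A protein library tibble (records keyed by accession).
#' @inheritParams align_pair
#' @return An alignment tibble with one row per ordered pair.
#' @export
align_all_pairs <- function(library, substitution_matrix = "BLOSUM62",
                            gap_opening = 11, gap_extension = 1) {
  library <- validate_protein_library(library)
  n <- nrow(library)
  if (n < 2) {
    return(align_pair("M", "M")[0, ])
  }
  pairs <- utils::combn(n, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    fwd <- align_pair(
      library$sequence[i], library$sequence[j],
      query_id = library$accession[i], subject_id = library$accession[j],
      substitution_matrix = substitution_matrix,
      gap_opening = gap_opening, gap_extension = gap_extension
    )
    rev <- fwd
    rev$query_id <- fwd$subject_id
    rev$subject_id <- fwd$query_id
    rev$query_length <- fwd$subject_length
    rev$subject_length <- fwd$query_length
    bind_rows(fwd, rev)
  })
  bind_rows(rows)
}

#' Import alignments from BLAST tabular output
#'
#' Reads the 12-column tabular dialect (query, subject, percent identity,
#' alignment length, mismatches, gap openings, query start/end, subject
#' start/end, e-value, bitscore). The identity count is reconstructed as
#' `round(pident * length / 100)`. The longest perfect run cannot be
#' recovered from tabular output, so it is `NA`; applying the match
#' criterion to imported rows then requires re-alignment with [align_pair()].
#'
#' @param path Path to a BLAST tabular file.
#' @param query_lengths Optional named integer vector giving each query's
#'   full sequence length (needed by [is_match()], whose identity fraction
#'   is over the full query length).
#' @return An alignment tibble (possibly zero rows for an empty file).
#' @export
import_blast_tabular <- function(path, query_lengths = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("BLAST tabular file not found: '%s'", path), class = "fedprot_io_error")
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(align_pair("M", "M")[0, ])
  }
  fields <- stringr::str_split(lines, "\\t|\\s+")
  bad <- which(lengths(fields) != 12)
  if (length(bad) > 0) {
    abort(
      sprintf("line %d: expected 12 tab-separated columns, found %d", bad[1], lengths(fields)[bad[1]]),
      class = "fedprot_parse_error"
    )
  }
  m <- do.call(rbind, fields)
  pident <- as.numeric(m[, 3])
  len <- as.integer(m[, 4])
  qlen <- if (is.null(query_lengths)) {
    rep(NA_integer_, nrow(m))
  } else {
    as.integer(query_lengths[m[, 1]])
  }
  tibble(
    query_id = m[, 1], subject_id = m[, 2],
    n_identities = as.integer(round(pident * len / 100)),
    alignment_length = len,
    mismatches = as.integer(m[, 5]),
    gap_openings = as.integer(m[, 6]),
    longest_perfect_run = NA_integer_,
    score = as.numeric(m[, 12]),
    bitscore = as.numeric(m[, 12]),
    e_value = as.numeric(m[, 11]),
    query_length = qlen,
    subject_length = NA_integer_
  )
}

#' Homology match criterion
#'
#' The structural-identity standard used to call two proteins the same
#' protein type: identity over **more than** `min_identity_fraction` of the
#' full query length (default 0.75, strict inequality — a fraction of
#' exactly 0.75 is not a match) **and** a perfect match string of at least
#' `min_perfect_run` amino acids (default 20).
#'
#' @param min_identity_fraction Identity fraction threshold in (0, 1].
#' @param min_perfect_run Minimum perfect-run length (>= 1).
#' @return A `match_criterion` object.
#' @export
match_criterion <- function(min_identity_fraction = 0.75, min_perfect_run = 20) {
  if (!is.numeric(min_identity_fraction) || min_identity_fraction <= 0 ||
    min_identity_fraction > 1) {
    abort("min_identity_fraction must be in (0, 1]", class = "fedprot_domain_error")
  }
  if (!is.numeric(min_perfect_run) || min_perfect_run < 1) {
    abort("min_perfect_run must be >= 1", class = "fedprot_domain_error")
  }
  structure(
    list(
      min_identity_fraction = min_identity_fraction,
      min_perfect_run = as.integer(min_perfect_run)
    ),
    class = "match_criterion"
  )
}

#' Apply the homology match criterion
#'
#' `TRUE` iff `n_identities / query_length > min_identity_fraction` and
#' `longest_perfect_run >= min_perfect_run`. The denominator is the full
#' query length, not the alignment length: a fragment aligned to its parent
#' matches when the fragment is the query, which is the direction that
#' justifies absorbing fragments into their parent's protein type.
#'
#' @param alignments An alignment tibble (rows from [align_pair()] or
#'   [import_blast_tabular()] with `longest_perfect_run` available).
#' @param criterion A [match_criterion()].
#' @return Logical vector, one element per alignment row.
#' @export
is_match <- function(alignments, criterion = match_criterion()) {
  stopifnot(inherits(criterion, "match_criterion"))
  alignments <- as_tibble(alignments)
  if (nrow(alignments) == 0) {
    return(logical())
  }
  if (any(is.na(alignments$query_length)) || any(alignments$query_length == 0)) {
    abort("query_length missing or zero; the identity fraction is over the full query length",
      class = "fedprot_domain_error"
    )
  }
  if (any(is.na(alignments$longest_perfect_run))) {
    abort(
      "longest_perfect_run unavailable (imported tabular rows?); re-align with align_pair()",
      class = "fedprot_domain_error"
    )
  }
  (alignments$n_identities / alignments$query_length > criterion$min_identity_fraction) &
    (alignments$longest_perfect_run >= criterion$min_perfect_run)
}

#' Best non-self hit per query
#'
#' For each query, the non-self alignment with the highest score (bitscore
#' where available, otherwise the raw alignment score); ties broken by lower
#' e-value, then lexicographically smallest subject. Queries whose only hit
#' is themselves are omitted.
#'
#' @param alignments An alignment tibble.
#' @return One row per query.
#' @export
top_hit_per_query <- function(alignments) {
  alignments <- as_tibble(alignments)
  if (nrow(alignments) == 0) {
    return(alignments)
  }
  alignments |>
    filter(.data$query_id != .data$subject_id) |>
    mutate(.rank_score = dplyr::coalesce(.data$bitscore, .data$score)) |>
    arrange(
      .data$query_id, desc(.data$.rank_score),
      dplyr::coalesce(.data$e_value, Inf), .data$subject_id
    ) |>
    group_by(.data$query_id) |>
    slice(1) |>
    ungroup() |>
    select(-".rank_score")
}

#' Collapse a protein library into protein types
#'
#' Builds an undirected graph with one edge per top hit satisfying the match
#' criterion and takes connected components as protein types: the minimal
#' closure under which "same type" is well defined even though the per-query
#' criterion is asymmetric for fragment pairs. Proteins with no matching
#' edge are singletons ("no close homologues"). Each cluster's
#' representative is its longest member, ties broken by lexicographically
#' smallest accession.
#'
#' @param library A protein library tibble (the distinct, merged library).
#' @param top_hits Top-hit alignment tibble from [top_hit_per_query()];
#'   computed internally via [align_all_pairs()] when `NULL` (practical for
#'   fixture-scale libraries only).
#' @param criterion A [match_criterion()].
#' @return A cluster tibble (`accession`, `length`, `cluster_id`,
#'   `representative`, `n_members`, `is_singleton`); clusters partition the
#'   library.
#' @export
collapse_types <- function(library, top_hits = NULL, criterion = match_criterion()) {
  library <- validate_protein_library(library)
  if (is.null(top_hits)) {
    top_hits <- top_hit_per_query(align_all_pairs(library))
  }
  edges <- top_hits[is_match(top_hits, criterion), c("query_id", "subject_id"), drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges,
    directed = FALSE,
    vertices = tibble(name = library$accession)
  )
  comp <- igraph::components(g)
  clusters <- tibble(
    accession = names(comp$membership),
    cluster_id = as.integer(comp$membership)
  ) |>
    left_join(select(library, "accession", "length"), by = "accession") |>
    group_by(.data$cluster_id) |>
    mutate(
      n_members = n(),
      representative = .data$accession[order(-.data$length, .data$accession)][1],
      is_singleton = .data$n_members == 1L
    ) |>
    ungroup() |>
    arrange(.data$cluster_id, desc(.data$length), .data$accession) |>
    select(
      "accession", "length", "cluster_id", "representative",
      "n_members", "is_singleton"
    )
  clusters
}

#' Alignment-statistic distributions
#'
#' Summarises a set of alignments into the five standard histograms:
#' e-value (log10 bins, with values below the numeric floor of 1e-180 — and
#' exact zeros — collected in a separate `"machine zero"` bin), gap
#' openings, alignment length (log10, one-decimal bins), mismatches (log10
#' with a separate zero-mismatch bin), and percent identity (integer bins).
#' Each table's frequencies sum to the number of input alignments with that
#' statistic available.
#'
#' @param alignments An alignment tibble.
#' @return A named list of five distribution tibbles (`bin`, `n`):
#'   `e_value`, `gap_openings`, `alignment_length`, `mismatches`,
#'   `percent_identity`.
#' @export
alignment_distributions <- function(alignments) {
  alignments <- as_tibble(alignments)
  log_bin <- function(x) as.character(round(log10(x), 1))

  e <- alignments$e_value[!is.na(alignments$e_value)]
  e_tab <- tibble(
    bin = ifelse(e < 1e-180, "machine zero", log_bin(pmax(e, 1e-180)))
  ) |>
    count(.data$bin) |>
    arrange(.data$bin != "machine zero", suppressWarnings(as.numeric(.data$bin)))

  gap_tab <- alignments |>
    count(bin = .data$gap_openings) |>
    arrange(.data$bin) |>
    mutate(bin = as.character(.data$bin))

  len_tab <- alignments |>
    filter(.data$alignment_length > 0) |>
    count(bin = log_bin(.data$alignment_length)) |>
    arrange(as.numeric(.data$bin))

  mm <- alignments$mismatches
  mm_tab <- tibble(bin = ifelse(mm == 0, "0 (none)", log_bin(pmax(mm, 1)))) |>
    count(.data$bin) |>
    arrange(.data$bin != "0 (none)", suppressWarnings(as.numeric(.data$bin)))

  pid_tab <- alignments |>
    filter(.data$alignment_length > 0) |>
    count(bin = round(100 * .data$n_identities / .data$alignment_length)) |>
    arrange(.data$bin) |>
    mutate(bin = as.character(.data$bin))

  list(
    e_value = new_distribution(e_tab, "log10 expectation value"),
    gap_openings = new_distribution(gap_tab, "gap openings"),
    alignment_length = new_distribution(len_tab, "log10 alignment length"),
    mismatches = new_distribution(mm_tab, "log10 mismatches"),
    percent_identity = new_distribution(pid_tab, "percent identity")
  )
}
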