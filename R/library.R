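#' Federate protein libraries into a non-redundant set
#'
#' Merges one or more protein libraries into a single non-redundant library:
#' records with byte-identical sequences become one record whose accessions
#' are the sorted union of the inputs' accessions (semicolon-concatenated)
#' and whose descriptions are concatenated in accession order. Sequence
#' comparison is exact — isoleucine/leucine and the ambiguity codes B, Z, X,
#' U are distinct characters, so allelic variants differing by a single
#' residue remain separate records.
#'
#' @param ... Protein library tibbles (as from [read_protein_fasta()]), or a
#'   single list of them.
#' @return A federated protein library tibble; one row per distinct sequence.
#' @section Errors:
#' If the same accession is attached to two different sequences anywhere in
#' the inputs, federation stops with a conflict error listing the accession —
#' an accession must name exactly one sequence.
#' @examples
#' a <- tibble::tibble(accession = "A", sequence = "MKVLA")
#' b <- tibble::tibble(accession = "B", sequence = "MKVLA")
#' merge_libraries(a, b)
#' @export
merge_libraries <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) && !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  inputs <- lapply(inputs, validate_protein_library)
  all <- bind_rows(inputs)
  if (nrow(all) == 0) {
    return(new_protein_library(tibble(
      accession = character(), sequence = character(), length = integer(),
      source = character(), description = character()
    )))
  }

  # one row per (accession, record): used both for conflict detection and for
  # accession-ordered description concatenation
  expanded <- all |>
    mutate(.acc = split_accessions(.data$accession)) |>
    tidyr::unnest(".acc")
  conflicts <- expanded |>
    distinct(.data$.acc, .data$sequence) |>
    count(.data$.acc) |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(
      sprintf(
        "accession attached to more than one distinct sequence: %s",
        paste(conflicts$.acc, collapse = ", ")
      ),
      class = "fedprot_conflict_error"
    )
  }

  merged <- expanded |>
    arrange(.data$sequence, .data$.acc) |>
    group_by(.data$sequence) |>
    summarise(
      accession = paste(unique(.data$.acc), collapse = ";"),
      length = nchar(.data$sequence[1]),
      source = merge_labels(.data$source),
      description = merge_descriptions(.data$description),
      .groups = "drop"
    ) |>
    select("accession", "sequence", "length", "source", "description") |>
    arrange(primary_accession(.data$accession))
  new_protein_library(merged)
}

#' Remove proteins that are perfect subsets of longer sequences
#'
#' Drops every record whose sequence is a contiguous substring of another,
#' longer record's sequence, appending the absorbed record's accessions (and
#' merging its description and source tags) onto the absorbing record. When
#' several longer records contain a sequence, the longest one absorbs it
#' (ties broken by lexicographically smallest first accession), which
#' guarantees the absorber itself survives. Accessions are conserved: the
#' multiset of accessions is identical before and after.
#'
#' @param library A federated protein library (already merged, so sequences
#'   are distinct).
#' @return The reduced library tibble; no returned sequence is a substring of
#'   another.
#' @examples
#' lib <- merge_libraries(tibble::tibble(
#'   accession = c("A", "B"), sequence = c("MKVLA", "KVL")
#' ))
#' remove_subset_proteins(lib)
#' @export
remove_subset_proteins <- function(library) {
  library <- validate_protein_library(library)
  n <- nrow(library)
  if (n <= 1) {
    return(library)
  }
  if (anyDuplicated(library$sequence) > 0) {
    abort("library contains duplicate sequences; run merge_libraries() first",
      class = "fedprot_invariant_error"
    )
  }
  seqs <- library$sequence
  lens <- library$length
  # absorber[i]: row index of the longest strictly-longer record containing
  # sequence i (tie: smallest first accession), or NA if none
  absorber <- vapply(seq_len(n), function(i) {
    cand <- which(lens > lens[i])
    if (length(cand) == 0) {
      return(NA_integer_)
    }
    hit <- cand[stringi::stri_detect_fixed(seqs[cand], seqs[i])]
    if (length(hit) == 0) {
      return(NA_integer_)
    }
    hit[order(-lens[hit], primary_accession(library$accession[hit]))][1]
  }, integer(1))

  kept <- which(is.na(absorber))
  removed <- which(!is.na(absorber))
  if (length(removed) == 0) {
    return(library)
  }
  out <- library[kept, , drop = FALSE]
  # deterministic append order: longest absorbed record first, then accession
  removed <- removed[order(-lens[removed], primary_accession(library$accession[removed]))]
  for (i in removed) {
    j <- match(absorber[i], kept)
    out$accession[j] <- paste(out$accession[j], library$accession[i], sep = ";")
    out$description[j] <- merge_descriptions(c(out$description[j], library$description[i]))
    out$source[j] <- merge_labels(c(out$source[j], library$source[i]))
  }
  new_protein_library(out)
}

# sorted, duplicate-free semicolon join of source tags (NA dropped)
merge_labels <- function(x) {
  x <- unlist(stringr::str_split(x[!is.na(x) & nzchar(x)], stringr::fixed(";")))
  if (length(x) == 0) {
    return(NA_character_)
  }
  paste(sort(unique(x)), collapse = ";")
}

#' Concatenate protein descriptions
#'
#' Duplicate-free, order-stable semicolon join; empty and missing entries are
#' dropped.
#'
#' @param descriptions Character vector of descriptions.
#' @return A single semicolon-joined string (empty string if nothing to join).
#' @examples
#' merge_descriptions(c("albumin", "albumin", "serum albumin"))
#' @export
merge_descriptions <- function(descriptions) {
  d <- unlist(stringr::str_split(
    descriptions[!is.na(descriptions) & nzchar(descriptions)],
    stringr::fixed(";")
  ))
  d <- stringr::str_squish(d)
  paste(unique(d[nzchar(d)]), collapse = ";")
}
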