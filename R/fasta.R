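#' Read a protein sequence library from FASTA
#'
#' Parses a FASTA file into a protein library tibble: one row per entry, the
#' header's first whitespace-delimited token taken as the accession and the
#' remainder as the description. Sequences are uppercased and trailing stop
#' characters (`*`) are stripped. The parser never merges entries — records
#' with identical sequences are kept separate until [merge_libraries()].
#'
#' @param path Path to a FASTA file.
#' @param source Source-library tag attached to every record. Defaults to the
#'   file name without extension.
#' @return A protein library tibble with columns `accession`, `sequence`,
#'   `length`, `source`, `description`. Accessions within a record are
#'   semicolon-concatenated; a freshly read file has one accession per record.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp1 serum albumin", "MKWVTFISLLLLFSSAYS"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path, source = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: '%s'", path), class = "fedprot_io_error")
  }
  source <- source %||% sub("\\.[^.]*$", "", basename(path))
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  accession <- stringr::word(headers, 1)
  description <- stringr::str_squish(stringr::str_remove(headers, "^\\S+\\s*"))
  sequence <- unname(toupper(sub("\\*+$", "", as.character(seqs))))
  empty <- which(!nzchar(sequence))
  if (length(empty) > 0) {
    abort(
      sprintf(
        "FASTA entry with empty sequence: %s",
        paste(accession[empty], collapse = ", ")
      ),
      class = "fedprot_parse_error"
    )
  }
  new_protein_library(tibble(
    accession = accession,
    sequence = sequence,
    length = nchar(sequence),
    source = source,
    description = description
  ))
}

#' Write a protein library to FASTA
#'
#' Headers carry the (semicolon-concatenated) accessions followed by the
#' description; sequence lines wrap at `width` columns.
#'
#' @param library A protein library tibble.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(library, path, width = 60) {
  library <- validate_protein_library(library)
  header <- ifelse(
    nzchar(library$description %||% ""),
    paste(library$accession, library$description),
    library$accession
  )
  seqs <- Biostrings::AAStringSet(library$sequence)
  names(seqs) <- header
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Export a protein library as a TSV table
#'
#' @param library A protein library tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(library, path) {
  library <- validate_protein_library(library)
  readr::write_tsv(
    select(library, "accession", "length", "source", "description"),
    path
  )
  invisible(path)
}

new_protein_library <- function(x) {
  class(x) <- unique(c("protein_library", class(x)))
  x
}

#' Validate a protein library tibble
#'
#' Checks the record invariants: non-empty uppercase sequences over the
#' residue alphabet, `length` equal to the residue count, non-empty
#' duplicate-free accession lists with no empty semicolon fields.
#'
#' @param library A protein library tibble.
#' @return The validated library (invisibly classed), or an error.
#' @export
validate_protein_library <- function(library) {
  if (!is.data.frame(library)) {
    abort("a protein library must be a data frame", class = "fedprot_type_error")
  }
  library <- as_tibble(library)
  needed <- c("accession", "sequence")
  missing <- setdiff(needed, names(library))
  if (length(missing) > 0) {
    abort(
      sprintf("protein library lacks column(s): %s", paste(missing, collapse = ", ")),
      class = "fedprot_type_error"
    )
  }
  if (!"length" %in% names(library)) library$length <- nchar(library$sequence)
  if (!"source" %in% names(library)) library$source <- NA_character_
  if (!"description" %in% names(library)) library$description <- ""
  if (any(!nzchar(library$sequence))) {
    abort("protein library contains an empty sequence", class = "fedprot_invariant_error")
  }
  bad <- stringr::str_detect(library$sequence, residue_regex())
  if (any(bad)) {
    abort(
      sprintf(
        "sequence with characters outside the residue alphabet: %s",
        paste(utils::head(library$accession[bad], 5), collapse = ", ")
      ),
      class = "fedprot_invariant_error"
    )
  }
  if (any(library$length != nchar(library$sequence))) {
    abort("length column disagrees with residue count", class = "fedprot_invariant_error")
  }
  accs <- split_accessions(library$accession)
  if (any(lengths(accs) == 0) || any(vapply(accs, function(a) any(!nzchar(a)), logical(1)))) {
    abort("accession field empty or containing empty semicolon fields",
      class = "fedprot_invariant_error"
    )
  }
  if (any(vapply(accs, anyDuplicated, integer(1)) > 0)) {
    abort("duplicate accession within a record", class = "fedprot_invariant_error")
  }
  new_protein_library(library)
}

#' Split semicolon-concatenated accessions
#'
#' @param x Character vector of (possibly semicolon-concatenated) accessions.
#' @return A list of character vectors.
#' @export
split_accessions <- function(x) {
  stringr::str_split(x, stringr::fixed(";"))
}

#' First (primary) accession of each record
#'
#' @param x Character vector of semicolon-concatenated accessions.
#' @return Character vector of first accessions.
#' @export
primary_accession <- function(x) {
  stringr::word(x, 1, sep = stringr::fixed(";"))
}
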