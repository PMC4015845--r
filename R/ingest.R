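# Parser registry: each study file declares its dialect by format name in
# config rather than being auto-sniffed, so a build is reproducible from its
# config alone.
.format_registry <- new.env(parent = emptyenv())

#' Register a study file format
#'
#' A format is a reader function `function(path, col_map)` returning a tibble
#' with character columns `peptide` and `accession` and an optional numeric
#' `count`. Formats `"tsv"` and `"csv"` (delimited files with a configurable
#' column map) are pre-registered.
#'
#' @param name Format name used by [parse_study()].
#' @param reader Reader function.
#' @return `name`, invisibly.
#' @export
register_study_format <- function(name, reader) {
  stopifnot(is.character(name), length(name) == 1, is.function(reader))
  assign(name, reader, envir = .format_registry)
  invisible(name)
}

#' List registered study formats
#' @return Character vector of format names.
#' @export
study_formats <- function() sort(ls(.format_registry))

delim_reader <- function(delim) {
  function(path, col_map = NULL) {
    col_map <- col_map %||% c(peptide = "peptide", accession = "accession", count = "count")
    raw <- readr::read_delim(path,
      delim = delim, show_col_types = FALSE,
      progress = FALSE, col_types = readr::cols(.default = readr::col_character())
    )
    pick <- function(key, default = NA_character_) {
      col <- col_map[[key]]
      if (is.null(col) || !(col %in% names(raw))) rep(default, nrow(raw)) else raw[[col]]
    }
    tibble(
      peptide = pick("peptide"),
      accession = pick("accession"),
      count = suppressWarnings(as.numeric(pick("count")))
    )
  }
}

register_builtin_formats <- function() {
  register_study_format("tsv", delim_reader("\t"))
  register_study_format("csv", delim_reader(","))
}

#' Clean a reported peptide string
#'
#' Normalises the peptide dialects found in published identification lists:
#' uppercases, strips a flanking-residue token (`K.ELVISLIVESK.R` ->
#' `ELVISLIVESK`), then deletes every character outside the residue alphabet
#' (so modification annotations such as `M(ox)`, phospho tags, numbers and
#' brackets are removed). Mapping onto the library is sequence-exact, so
#' anything that is not a residue cannot be kept.
#'
#' @param x Character vector of reported peptides.
#' @return Character vector of cleaned peptide sequences (possibly empty
#'   strings for unparseable rows).
#' @examples
#' clean_peptide(c("K.ELVISLIVESK.R", "ELVIS(ph)LIVESK", "mkvla"))
#' @export
clean_peptide <- function(x) {
  # bracketed modification tags go first, before case normalisation, so that
  # "(ph)"/"[12.3]" never contribute residue letters
  x <- stringr::str_remove_all(trimws(x), "\\([^)]*\\)|\\[[^\\]]*\\]")
  x <- toupper(x)
  # flank token: single residue (or "-") + dot ... dot + single residue/"-"
  flanked <- stringr::str_match(x, "^[A-Z-]\\.(.*)\\.[A-Z-]$")[, 2]
  x <- ifelse(!is.na(flanked), flanked, x)
  stringr::str_remove_all(x, residue_regex())
}

#' Normalise a reported accession to a bare token
#'
#' Strips database prefixes from the pipe-delimited accession dialects
#' (`gi|123|ref|NP_000001.1|` -> `NP_000001.1`; `sp|P12345|ALBU_HUMAN` ->
#' `P12345`). Accessions without a recognised prefix pass through verbatim;
#' unparseable pipe-delimited strings are returned verbatim with a warning.
#'
#' @param raw Character vector of reported accessions.
#' @return Character vector of bare accession tokens.
#' @examples
#' normalize_accession(c("gi|123|ref|NP_000001.1|", "sp|P12345|ALBU_HUMAN", "P12345"))
#' @export
normalize_accession <- function(raw) {
  out <- vapply(raw, function(a) {
    if (is.na(a) || !nzchar(a)) {
      return(NA_character_)
    }
    a <- trimws(a)
    if (!grepl("|", a, fixed = TRUE)) {
      return(a)
    }
    parts <- strsplit(a, "|", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) >= 4 && parts[1] == "gi") {
      return(parts[4])
    }
    if (length(parts) >= 3 && parts[1] == "gnl") {
      return(parts[3])
    }
    if (length(parts) >= 2 && parts[1] %in% c(
      "sp", "tr", "ref", "gb", "emb", "dbj", "pir", "prf", "ipi"
    )) {
      return(parts[2])
    }
    NA_character_
  }, character(1), USE.NAMES = FALSE)
  bad <- is.na(out) & !is.na(raw) & nzchar(raw)
  if (any(bad)) {
    warn(sprintf(
      "could not normalise %d accession(s); returned verbatim: %s",
      sum(bad), paste(utils::head(unique(raw[bad]), 5), collapse = ", ")
    ))
    out[bad] <- raw[bad]
  }
  out
}

#' Parse one study's identification list into peptide observations
#'
#' Reads a per-study peptide/protein list in a registered format, cleans the
#' peptides with [clean_peptide()], normalises accessions, and returns one
#' observation row per usable input row. Rows whose cleaned peptide is empty
#' or shorter than `min_peptide_length` are rejected — counted and attached
#' as the `rejects` attribute, never silently dropped. Missing spectral
#' counts default to 1, so redundant counts equal row counts for studies that
#' publish plain peptide lists.
#'
#' @param path Path to the study file.
#' @param study_id Short unique study identifier.
#' @param format Registered format name (see [study_formats()]).
#' @param col_map Named character vector mapping the keys `peptide`,
#'   `accession`, `count` to column names in the file.
#' @param min_peptide_length Minimum cleaned-peptide length retained
#'   (default 6; shorter peptides map too promiscuously to be informative).
#' @return A tibble of observations (`peptide`, `study_id`,
#'   `reported_accession`, `spectral_count`) with attribute `rejects`, a
#'   tibble of the rejected rows and reasons.
#' @export
parse_study <- function(path, study_id, format = "tsv", col_map = NULL,
                        min_peptide_length = 6) {
  if (!exists(format, envir = .format_registry)) {
    abort(
      sprintf(
        "study format '%s' is not registered (known: %s)",
        format, paste(study_formats(), collapse = ", ")
      ),
      class = "fedprot_config_error"
    )
  }
  if (!file.exists(path)) {
    abort(sprintf("study file not found: '%s'", path), class = "fedprot_io_error")
  }
  reader <- get(format, envir = .format_registry)
  raw <- reader(path, col_map)
  if (nrow(raw) == 0) {
    abort(sprintf("study '%s': no rows parsed from '%s'", study_id, path),
      class = "fedprot_ingest_error"
    )
  }
  cleaned <- clean_peptide(raw$peptide)
  count <- ifelse(is.na(raw$count) | raw$count < 1, 1, round(raw$count))
  reason <- dplyr::case_when(
    is.na(raw$peptide) | !nzchar(trimws(raw$peptide)) ~ "empty peptide field",
    !nzchar(cleaned) ~ "no residues after cleaning",
    nchar(cleaned) < min_peptide_length ~ sprintf("peptide shorter than %d residues", min_peptide_length),
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  obs <- tibble(
    peptide = cleaned[keep],
    study_id = study_id,
    reported_accession = normalize_accession(raw$accession[keep]),
    spectral_count = as.integer(count[keep])
  )
  rejects <- tibble(
    row = which(!keep),
    peptide = raw$peptide[!keep],
    reason = reason[!keep]
  )
  if (nrow(rejects) > 0) {
    inform(sprintf(
      "study '%s': %d of %d rows rejected (%s)",
      study_id, nrow(rejects), nrow(raw),
      paste(unique(rejects$reason), collapse = "; ")
    ))
  }
  if (nrow(obs) == 0) {
    abort(sprintf("study '%s': zero parseable rows", study_id),
      class = "fedprot_ingest_error"
    )
  }
  attr(obs, "rejects") <- rejects
  obs
}
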