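#' Run the full federation build
#'
#' Executes the whole pipeline from a declarative config: read and federate
#' the source libraries, remove subset proteins, parse the study files,
#' build the evidence store, collapse the library into protein types, attach
#' annotations when provided, and assemble the consolidated build report.
#' The run is a pure function of its config (plus a seed recorded for
#' provenance), so re-running the same config reproduces the report exactly.
#'
#' @param config A named list:
#' \describe{
#'   \item{libraries}{character vector of FASTA paths, or a list of protein
#'     library tibbles.}
#'   \item{studies}{list of per-study specs: `list(path =, study_id =,
#'     format = "tsv", col_map = NULL)`; alternatively a ready observation
#'     tibble under `observations`.}
#'   \item{annotations}{optional annotation TSV path or tibble.}
#'   \item{min_peptide_length}{default 6.}
#'   \item{min_identity_fraction, min_perfect_run}{match criterion, defaults
#'     0.75 and 20.}
#'   \item{min_distinct_peptides}{high-confidence tier threshold, default 3.}
#'   \item{seed}{recorded in the report.}
#'   \item{out_dir}{optional; when set, the store, report JSON and TSV
#'     tables are written there.}
#' }
#' @return A `build_report` object (see [summarize_evidence()]); its
#'   `store`, `clusters`, `counts` and `annotated` components carry the full
#'   results.
#' @export
run_build <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$libraries)) {
    abort("config$libraries is required", class = "fedprot_config_error")
  }
  libs <- config$libraries
  if (is.character(libs)) libs <- lapply(libs, read_protein_fasta)
  if (is.data.frame(libs)) libs <- list(libs)
  merged <- merge_libraries(libs)
  reduced <- remove_subset_proteins(merged)

  if (!is.null(config$observations)) {
    observations <- as_tibble(config$observations)
  } else {
    if (is.null(config$studies) || length(config$studies) == 0) {
      abort("config must name at least one study (or supply observations)",
        class = "fedprot_ingest_error"
      )
    }
    observations <- bind_rows(lapply(config$studies, function(s) {
      parse_study(
        s$path, s$study_id,
        format = s$format %||% "tsv", col_map = s$col_map,
        min_peptide_length = config$min_peptide_length %||% 6
      )
    }))
  }

  store <- build_evidence_store(
    observations, reduced,
    min_peptide_length = config$min_peptide_length %||% 6
  )
  criterion <- match_criterion(
    min_identity_fraction = config$min_identity_fraction %||% 0.75,
    min_perfect_run = config$min_perfect_run %||% 20
  )
  clusters <- collapse_types(reduced, criterion = criterion)

  annotated <- NULL
  if (!is.null(config$annotations)) {
    ann <- config$annotations
    if (is.character(ann)) ann <- read_annotation_tsv(ann)
    annotated <- attach_annotations(reduced, ann, clusters)
  }

  report <- summarize_evidence(
    store,
    clusters = clusters,
    merged_library = merged,
    min_distinct_peptides = config$min_distinct_peptides %||% 3
  )
  report$annotated <- annotated
  report$config_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  report$seed <- config$seed %||% NA_integer_

  if (!is.null(config$out_dir)) {
    write_build_report(report, config$out_dir)
  }
  report
}

#' Summarise an evidence store into a build report
#'
#' Recomputes every corpus counter of the reduction cascade from the store
#' alone (no re-ingest): raw / distinct / subset-reduced peptide counts,
#' library and detected protein counts, the confidence-tier tallies, the
#' unique-peptide inventory, the peptide-to-protein distributions, and —
#' when a cluster table is given — the protein-type counts. Counters always
#' satisfy the cascade inequalities (raw >= distinct >= post-subset).
#'
#' @param store An `evidence_store`.
#' @param clusters Optional cluster tibble from [collapse_types()].
#' @param merged_library Optional pre-subset-removal library, for the
#'   merged-protein counter.
#' @param min_distinct_peptides High-confidence threshold (default 3).
#' @return A `build_report`: list with `counters` (named list),
#'   `distributions`, `counts`, `unique_proteins`, `clusters`, `store`.
#' @export
summarize_evidence <- function(store, clusters = NULL, merged_library = NULL,
                               min_distinct_peptides = 3) {
  stopifnot(inherits(store, "evidence_store"))
  raw <- store$observation$peptide
  dedup <- distinct_peptides(raw)
  maximal <- remove_subset_peptides(dedup)
  counts <- protein_counts(store)
  uniq <- unique_peptide_proteins(store, min_distinct_peptides)

  counters <- list(
    n_observations = nrow(store$observation),
    n_raw_peptides = length(raw),
    n_distinct_peptides = length(dedup),
    n_post_subset_peptides = length(maximal),
    n_merged_proteins = if (is.null(merged_library)) NA_integer_ else nrow(merged_library),
    n_library_proteins = nrow(store$protein),
    n_proteins_detected = nrow(counts),
    n_single_peptide = sum(counts$distinct_peptide_count == 1),
    n_double_peptide = sum(counts$distinct_peptide_count == 2),
    n_high_confidence = sum(counts$distinct_peptide_count >= min_distinct_peptides),
    n_unique_peptide_proteins = nrow(uniq),
    n_unique_high_confidence = sum(uniq$high_confidence),
    n_unmapped_peptides = nrow(store$unmapped),
    n_clusters = if (is.null(clusters)) NA_integer_ else n_distinct(clusters$cluster_id),
    n_singletons = if (is.null(clusters)) NA_integer_ else sum(clusters$is_singleton)
  )
  structure(
    list(
      counters = counters,
      distributions = list(
        distinct = peptide_protein_distribution(store, "distinct"),
        redundant = peptide_protein_distribution(store, "redundant")
      ),
      counts = counts,
      unique_proteins = uniq,
      clusters = clusters,
      store = store
    ),
    class = "build_report"
  )
}

#' @export
print.build_report <- function(x, ...) {
  cat("<build_report>\n")
  c <- x$counters
  cat(sprintf(
    "  peptides: %d raw -> %d distinct -> %d after subset removal\n",
    c$n_raw_peptides, c$n_distinct_peptides, c$n_post_subset_peptides
  ))
  cat(sprintf(
    "  proteins: %d in library, %d detected (%d with >=3 peptides)\n",
    c$n_library_proteins, c$n_proteins_detected, c$n_high_confidence
  ))
  cat(sprintf(
    "  unique-peptide proteins: %d (%d high confidence)\n",
    c$n_unique_peptide_proteins, c$n_unique_high_confidence
  ))
  if (!is.na(c$n_clusters)) {
    cat(sprintf(
      "  protein types: %d (%d with no close homologue)\n",
      c$n_clusters, c$n_singletons
    ))
  }
  invisible(x)
}

#' @describeIn summarize_evidence `glance()` method: the counters as a
#'   one-row tibble.
#' @param x A `build_report`.
#' @param ... Unused.
#' @export
glance.build_report <- function(x, ...) {
  as_tibble(x$counters)
}

#' @describeIn summarize_evidence `tidy()` method: the per-protein counter
#'   table with tier labels.
#' @export
tidy.build_report <- function(x, ...) {
  tidy.evidence_store(x$store)
}

#' Write a build report to disk
#'
#' Persists the counters as JSON and the tables (per-protein counts,
#' distributions, clusters, unique-peptide inventory, evidence store) as
#' TSVs under `dir`. Writing the same report twice is byte-identical.
#'
#' @param report A `build_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_build_report <- function(report, dir) {
  stopifnot(inherits(report, "build_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    c(
      report$counters,
      list(config_hash = report$config_hash %||% NA, seed = report$seed %||% NA)
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  readr::write_tsv(report$counts, file.path(dir, "protein_counts.tsv"))
  readr::write_tsv(report$unique_proteins, file.path(dir, "unique_proteins.tsv"))
  readr::write_tsv(
    as_tibble(report$distributions$distinct),
    file.path(dir, "distribution_distinct.tsv")
  )
  readr::write_tsv(
    as_tibble(report$distributions$redundant),
    file.path(dir, "distribution_redundant.tsv")
  )
  if (!is.null(report$clusters)) {
    readr::write_tsv(report$clusters, file.path(dir, "clusters.tsv"))
  }
  export_evidence_store(report$store, file.path(dir, "store"))
  invisible(dir)
}
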