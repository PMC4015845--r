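#' Read an annotation table
#'
#' Expects a TSV keyed by accession with columns `accession`, `description`,
#' `gene_symbol`, `go_cc`, `go_mf`, `go_bp` (missing columns tolerated). GO
#' fields hold the comma-joined label strings used by the frequency tables;
#' several annotation rows per record are separated by semicolons.
#'
#' @param path Path to the TSV.
#' @return An annotation tibble.
#' @export
read_annotation_tsv <- function(path) {
  ann <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  for (col in c("description", "gene_symbol", "go_cc", "go_mf", "go_bp")) {
    if (!col %in% names(ann)) ann[[col]] <- NA_character_
  }
  ann
}

#' Attach annotations to a federated library
#'
#' Annotations whose accession appears in a record's (semicolon-concatenated)
#' accession list attach directly. When a cluster table is supplied, records
#' with no direct annotation inherit the annotations of their cluster
#' representative (homology transfer); the `annotation_provenance` column
#' records `"direct"`, `"transferred"` or `"none"` per record. Annotation
#' accessions absent from the library are counted and reported via the
#' `unmatched` attribute.
#'
#' @param library A protein library tibble.
#' @param annotations An annotation tibble ([read_annotation_tsv()]).
#' @param clusters Optional cluster tibble from [collapse_types()].
#' @return The library with columns `gene_symbol`, `go_cc`, `go_mf`,
#'   `go_bp`, `annotation_provenance` added and descriptions merged;
#'   attribute `unmatched` holds the unmatched annotation accessions.
#' @export
attach_annotations <- function(library, annotations, clusters = NULL) {
  library <- validate_protein_library(library)
  annotations <- as_tibble(annotations)
  stopifnot("accession" %in% names(annotations))

  acc_map <- library |>
    mutate(.row = row_number(), .acc = split_accessions(.data$accession)) |>
    tidyr::unnest(".acc") |>
    select(".row", ".acc")
  hits <- annotations |>
    inner_join(acc_map, by = c(accession = ".acc"))
  unmatched <- setdiff(annotations$accession, acc_map$.acc)
  if (length(unmatched) > 0) {
    inform(sprintf(
      "%d annotation accession(s) absent from the library: %s",
      length(unmatched), paste(utils::head(unmatched, 5), collapse = ", ")
    ))
  }

  join_field <- function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (length(x) == 0) NA_character_ else paste(unique(x), collapse = ";")
  }
  direct <- hits |>
    group_by(.data$.row) |>
    summarise(
      ann_description = merge_descriptions(.data$description),
      gene_symbol = join_field(.data$gene_symbol),
      go_cc = join_field(.data$go_cc),
      go_mf = join_field(.data$go_mf),
      go_bp = join_field(.data$go_bp),
      .groups = "drop"
    )

  out <- library |>
    mutate(.row = row_number()) |>
    left_join(direct, by = ".row") |>
    mutate(
      description = ifelse(
        is.na(.data$ann_description) | !nzchar(.data$ann_description),
        .data$description,
        purrr::map2_chr(.data$description, .data$ann_description, ~ merge_descriptions(c(.x, .y)))
      ),
      annotation_provenance = ifelse(.data$.row %in% direct$.row, "direct", "none")
    ) |>
    select(-"ann_description")

  if (!is.null(clusters)) {
    rep_of <- clusters |>
      select("accession", "representative")
    rep_ann <- out |>
      filter(.data$annotation_provenance == "direct") |>
      select(
        representative = "accession", rep_gene = "gene_symbol",
        rep_cc = "go_cc", rep_mf = "go_mf", rep_bp = "go_bp"
      )
    out <- out |>
      left_join(rep_of, by = "accession") |>
      left_join(rep_ann, by = "representative") |>
      mutate(
        transfer = .data$annotation_provenance == "none" &
          (!is.na(.data$rep_gene) | !is.na(.data$rep_cc) |
            !is.na(.data$rep_mf) | !is.na(.data$rep_bp)),
        gene_symbol = ifelse(.data$transfer, .data$rep_gene, .data$gene_symbol),
        go_cc = ifelse(.data$transfer, .data$rep_cc, .data$go_cc),
        go_mf = ifelse(.data$transfer, .data$rep_mf, .data$go_mf),
        go_bp = ifelse(.data$transfer, .data$rep_bp, .data$go_bp),
        annotation_provenance = ifelse(.data$transfer, "transferred", .data$annotation_provenance)
      ) |>
      select(-"representative", -"rep_gene", -"rep_cc", -"rep_mf", -"rep_bp", -"transfer")
  }
  out <- select(out, -".row")
  attr(out, "unmatched") <- unmatched
  new_protein_library(out)
}

#' GO-term frequency (5-decimal convention)
#'
#' The frequency reported in the annotation summary tables:
#' `round(count / total, 5)` with R's round-half-even.
#'
#' @param count Term count(s).
#' @param total Table total.
#' @return Numeric frequency rounded to 5 decimals.
#' @examples
#' go_frequency(2958, 22926)
#' @export
go_frequency <- function(count, total) {
  if (any(total <= 0)) abort("total must be positive", class = "fedprot_domain_error")
  round(count / total, 5)
}

#' Annotation frequency table
#'
#' Tabulates an annotated library by GO category, treating each comma-joined
#' label string as one atomic term (no GO DAG traversal — the convention of
#' the summary tables this reproduces). A record contributes one row per
#' annotation entry (semicolon-separated entries count separately, the
#' default `total = "rows"`); `total = "proteins"` divides by the number of
#' labelled records instead.
#'
#' @param annotated An annotated library ([attach_annotations()]).
#' @param category `"cc"`, `"mf"` or `"bp"`.
#' @param total `"rows"` (annotation entries, default) or `"proteins"`.
#' @return A tibble (`term`, `count`, `frequency`) sorted by descending
#'   count, with a leading `Total` row of frequency 1. Empty category gives
#'   an empty table with total 0.
#' @export
frequency_table <- function(annotated, category = c("cc", "mf", "bp"),
                            total = c("rows", "proteins")) {
  category <- match.arg(category)
  total <- match.arg(total)
  col <- paste0("go_", category)
  stopifnot(col %in% names(annotated))
  labels <- annotated[[col]]
  labels <- labels[!is.na(labels) & nzchar(labels)]
  entries <- unlist(stringr::str_split(labels, stringr::fixed(";")))
  entries <- stringr::str_squish(entries)
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0) {
    out <- tibble(term = character(), count = integer(), frequency = numeric())
    attr(out, "total") <- 0L
    return(out)
  }
  denom <- if (total == "rows") length(entries) else length(labels)
  tab <- tibble(term = entries) |>
    count(.data$term, name = "count") |>
    arrange(desc(.data$count), .data$term) |>
    mutate(frequency = go_frequency(.data$count, denom))
  out <- bind_rows(
    tibble(term = "Total", count = as.integer(denom), frequency = 1),
    tab
  )
  attr(out, "total") <- denom
  out
}

#' Keyword category query with peptide-count filtering
#'
#' Returns the proteins whose description, gene symbol or GO labels contain
#' at least one keyword (case-insensitive substring), optionally restricted
#' to proteins supported by at least `min_distinct_peptides` distinct
#' peptides (`0` = unfiltered). Output carries gene symbols for pasting into
#' downstream network tools.
#'
#' @param annotated An annotated library.
#' @param keywords Non-empty character vector of keywords.
#' @param min_distinct_peptides Peptide filter threshold, default 0.
#' @param counts Per-protein counts ([protein_counts()]); required when
#'   `min_distinct_peptides > 0`.
#' @return A tibble (`accession`, `gene_symbol`, `distinct_peptide_count`,
#'   `matched_keyword`).
#' @export
query_category <- function(annotated, keywords, min_distinct_peptides = 0,
                           counts = NULL) {
  if (length(keywords) == 0 || all(!nzchar(keywords))) {
    abort("at least one keyword is required", class = "fedprot_domain_error")
  }
  haystack <- tolower(paste(
    annotated$description %||% "",
    annotated$gene_symbol %||% "",
    annotated$go_cc %||% "",
    annotated$go_mf %||% "",
    annotated$go_bp %||% ""
  ))
  haystack <- stringr::str_replace_all(haystack, "\\bna\\b", "")
  hit_mat <- vapply(
    tolower(keywords),
    function(k) stringi::stri_detect_fixed(haystack, k),
    logical(nrow(annotated))
  )
  hit_mat <- matrix(hit_mat, nrow = nrow(annotated))
  hit <- rowSums(hit_mat) > 0
  first_kw <- apply(hit_mat, 1, function(r) if (any(r)) keywords[which(r)[1]] else NA_character_)
  out <- tibble(
    accession = annotated$accession[hit],
    gene_symbol = (annotated$gene_symbol %||% rep(NA_character_, nrow(annotated)))[hit],
    matched_keyword = first_kw[hit]
  )
  if (min_distinct_peptides > 0) {
    if (is.null(counts)) {
      abort("counts (protein_counts()) required when min_distinct_peptides > 0",
        class = "fedprot_domain_error"
      )
    }
    out <- out |>
      left_join(select(counts, "accession", "distinct_peptide_count"), by = "accession") |>
      filter(
        !is.na(.data$distinct_peptide_count),
        .data$distinct_peptide_count >= min_distinct_peptides
      )
  } else {
    dpc <- if (is.null(counts)) {
      NA_integer_
    } else {
      counts$distinct_peptide_count[match(out$accession, counts$accession)]
    }
    out$distinct_peptide_count <- dpc
  }
  select(out, "accession", "gene_symbol", "distinct_peptide_count", "matched_keyword")
}
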