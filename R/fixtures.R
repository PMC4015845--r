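# Synthetic corpus generator: libraries with planted variant families and
# fragments, in-silico tryptic digests, and multi-study observation tables in
# mixed reporting dialects, with the planted truth carried alongside. All
# randomness flows from one seed (withr::with_seed), so regeneration is exact.

STANDARD_RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

FAMILY_ROLES <- c(
  "transcription factor", "zinc finger protein", "serum transport protein",
  "protease inhibitor", "signal transduction kinase", "DNA repair enzyme",
  "cytoskeletal protein", "cell surface receptor"
)

GO_CC_VOCAB <- c(
  "Nucleus,", "Cytoplasm,", "Membrane, integral to membrane,",
  "Extracellular region,", "Mitochondrion,"
)
GO_MF_VOCAB <- c(
  "Protein binding,", "DNA binding,", "Zinc ion binding,",
  "Receptor activity,", "Catalytic activity,"
)
GO_BP_VOCAB <- c(
  "Transport,", "Signal transduction,", "Proteolysis,",
  "Transcription, DNA-dependent,", "Metabolic process,"
)

#' Generate a synthetic protein library with planted structure
#'
#' Builds `n_families` variant families: each family derives
#' `variants_per_family` sequences from one random base sequence by point
#' substitutions at sites spaced 25 residues apart, so within-family pairs
#' keep well over 75% full-length identity and perfect runs of at least 20
#' residues, while unrelated random families sit near chance identity
#' (~5%) — the homology criterion separates them with wide margin.
#' A further `fragment_fraction` of the variant count is emitted as exact
#' contiguous substrings of parent variants (planted subset proteins). The
#' planted truth (family, variant, fragment parentage) is returned alongside
#' the library.
#'
#' @param n_families Number of unrelated families.
#' @param variants_per_family Sequences per family (>= 1).
#' @param fragment_fraction Fragments emitted as a fraction of the variant
#'   count (rounded).
#' @param length_range Integer range of base-sequence lengths; the minimum
#'   must be at least 50 so substitution spacing and the 20-residue run
#'   constraint are feasible.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A list with `library` (protein library tibble) and `truth`
#'   (tibble `accession`, `family`, `variant`, `is_fragment`,
#'   `parent_accession`).
#' @examples
#' fx <- generate_library(n_families = 2, variants_per_family = 2, seed = 7)
#' fx$truth
#' @export
generate_library <- function(n_families = 5, variants_per_family = 3,
                             fragment_fraction = 0.2,
                             length_range = c(100, 300), seed = 1) {
  if (n_families < 1 || variants_per_family < 1 || fragment_fraction < 0) {
    abort("fixture parameters must be positive", class = "fedprot_config_error")
  }
  if (length_range[1] < 50) {
    abort(
      "minimum sequence length below 50 cannot honour the 20-residue perfect-run and substitution-spacing constraints",
      class = "fedprot_config_error"
    )
  }
  withr::with_seed(seed, {
    fam_rows <- purrr::map(seq_len(n_families), function(f) {
      len <- sample(seq(length_range[1], length_range[2]), 1)
      base <- sample(STANDARD_RESIDUES, len, replace = TRUE)
      sites <- seq(13, len - 12, by = 25)
      variants <- list(base)
      if (variants_per_family > 1) {
        for (v in 2:variants_per_family) {
          repeat {
            var <- base
            for (s in sites) {
              var[s] <- sample(setdiff(STANDARD_RESIDUES, base[s]), 1)
            }
            if (!any(vapply(variants, identical, logical(1), y = var))) break
          }
          variants[[v]] <- var
        }
      }
      tibble(
        accession = sprintf("FAM%02d_V%d", f, seq_len(variants_per_family)),
        sequence = vapply(variants, paste, character(1), collapse = ""),
        family = f,
        variant = seq_len(variants_per_family),
        description = sprintf(
          "synthetic %s, family %d variant %d",
          FAMILY_ROLES[(f - 1) %% length(FAMILY_ROLES) + 1], f,
          seq_len(variants_per_family)
        )
      )
    })
    fams <- bind_rows(fam_rows)

    n_frag <- round(fragment_fraction * nrow(fams))
    frags <- NULL
    if (n_frag > 0) {
      parent_idx <- rep(seq_len(nrow(fams)), length.out = n_frag)
      frags <- purrr::map(seq_len(n_frag), function(k) {
        p <- fams[parent_idx[k], ]
        len <- nchar(p$sequence)
        # interior window covering >= 1 substitution site, strictly shorter
        start <- 20
        end <- start + max(40, floor(0.55 * len))
        tibble(
          accession = sprintf("%s_FRAG%d", p$accession, k),
          sequence = substr(p$sequence, start, min(end, len - 1)),
          family = p$family,
          variant = p$variant,
          description = paste0(p$description, " fragment"),
          parent_accession = p$accession
        )
      }) |> bind_rows()
    }

    all <- bind_rows(
      mutate(fams, is_fragment = FALSE, parent_accession = NA_character_),
      if (!is.null(frags)) mutate(frags, is_fragment = TRUE)
    )
    library <- validate_protein_library(tibble(
      accession = all$accession,
      sequence = all$sequence,
      length = nchar(all$sequence),
      source = "synthetic",
      description = all$description
    ))
    truth <- select(
      all, "accession", "family", "variant", "is_fragment", "parent_accession"
    )
    list(library = library, truth = truth)
  })
}

#' Annotation table for a synthetic library
#'
#' Deterministic annotations keyed to the planted families: each family gets
#' one GO label per category (cycling through small vocabularies), a gene
#' symbol, and the family role in the description. By default only variant 1
#' of each family is annotated, so cluster-based homology transfer has work
#' to do; `coverage = "all"` annotates every non-fragment record.
#'
#' @param fixture The list returned by [generate_library()].
#' @param coverage `"variant1"` (default) or `"all"`.
#' @return An annotation tibble suitable for [attach_annotations()].
#' @export
generate_annotations <- function(fixture, coverage = c("variant1", "all")) {
  coverage <- match.arg(coverage)
  truth <- fixture$truth |> filter(!.data$is_fragment)
  if (coverage == "variant1") truth <- filter(truth, .data$variant == 1)
  cyc <- function(vocab, f) vocab[(f - 1) %% length(vocab) + 1]
  tibble(
    accession = truth$accession,
    description = sprintf(
      "synthetic %s, family %d",
      FAMILY_ROLES[(truth$family - 1) %% length(FAMILY_ROLES) + 1], truth$family
    ),
    gene_symbol = sprintf("SYN%d", truth$family),
    go_cc = cyc(GO_CC_VOCAB, truth$family),
    go_mf = cyc(GO_MF_VOCAB, truth$family),
    go_bp = cyc(GO_BP_VOCAB, truth$family)
  )
}

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every K or R not followed by P (the
#' trypsin rule). With `missed_cleavages = m`, every concatenation of up to
#' `m + 1` consecutive fully-cleaved fragments is returned. With no missed
#' cleavages and `min_length = 1`, concatenating the peptides reconstructs
#' the input.
#'
#' @param sequence A protein sequence (character scalar).
#' @param missed_cleavages Number of missed cleavages allowed (0–2).
#' @param min_length Peptides shorter than this are dropped (default 1).
#' @return Character vector of peptides in sequence order.
#' @examples
#' tryptic_digest("AAKBBBRCCC")
#' tryptic_digest("AAKPBBB") # KP bond is not cleaved
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0, min_length = 1) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!missed_cleavages %in% 0:2) {
    abort("missed_cleavages must be 0, 1 or 2", class = "fedprot_config_error")
  }
  sequence <- toupper(sequence)
  cuts <- stringr::str_locate_all(sequence, "[KR](?!P)")[[1]][, "start"]
  bounds <- c(0, cuts[cuts < nchar(sequence)], nchar(sequence))
  frags <- substring(sequence, utils::head(bounds, -1) + 1, bounds[-1])
  k <- length(frags)
  peps <- character()
  for (span in 0:missed_cleavages) {
    if (k - span < 1) break
    starts <- seq_len(k - span)
    peps <- c(peps, vapply(
      starts,
      function(i) paste(frags[i:(i + span)], collapse = ""),
      character(1)
    ))
  }
  peps[nchar(peps) >= min_length]
}

#' Generate multi-study peptide observation tables
#'
#' Emulates a corpus of independently published identification lists: each
#' study samples the tryptic peptides of every library protein with a
#' per-peptide detection probability, draws spectral counts from a geometric
#' distribution (count = 1 + Geom(`count_prob`)), and reports accessions and
#' peptides in a per-study dialect — plain, `gi|...|ref|ACC|` with flanked
#' peptides, or `sp|ACC|SYMBOL` with lowercase peptides — to exercise
#' ingest normalisation. An optional planted high-abundance protein has its
#' spectral counts multiplied by `boost_factor`.
#'
#' @param library A protein library tibble (typically from
#'   [generate_library()]).
#' @param n_studies Number of studies.
#' @param detection_prob Per-peptide detection probability in each study
#'   (1 gives a noise-free corpus where every peptide is observed).
#' @param count_prob Success probability of the geometric spectral-count
#'   distribution.
#' @param min_peptide_length Digest peptides shorter than this are not
#'   observable (default 6).
#' @param missed_cleavages Missed cleavages in the digest (default 0).
#' @param boost_accession Optional accession of a planted high-abundance
#'   protein.
#' @param boost_factor Spectral-count multiplier for the boosted protein.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, one `<study_id>.tsv` per study
#'   is written (columns `peptide`, `accession`, `count`).
#' @return A list with `studies` (named list of raw study tibbles in their
#'   dialects), `observations` (the clean planted observation table:
#'   `peptide`, `study_id`, `reported_accession`, `spectral_count`),
#'   `files` (paths or `NULL`), and `params`.
#' @export
generate_studies <- function(library, n_studies = 3, detection_prob = 0.5,
                             count_prob = 0.5, min_peptide_length = 6,
                             missed_cleavages = 0,
                             boost_accession = NULL, boost_factor = 10,
                             seed = 1, dir = NULL) {
  library <- validate_protein_library(library)
  digests <- purrr::map2(
    library$sequence, library$accession,
    function(s, a) {
      peps <- tryptic_digest(s, missed_cleavages, min_length = min_peptide_length)
      if (length(peps) == 0) {
        return(NULL)
      }
      tibble(accession = a, peptide = unique(peps), sequence = s)
    }
  ) |> bind_rows()

  withr::with_seed(seed, {
    studies <- list()
    clean <- list()
    for (s in seq_len(n_studies)) {
      study_id <- sprintf("study%02d", s)
      det <- stats::runif(nrow(digests)) <= detection_prob
      obs <- digests[det, , drop = FALSE]
      if (nrow(obs) > 0) {
        cnt <- 1L + stats::rgeom(nrow(obs), prob = count_prob)
        if (!is.null(boost_accession)) {
          cnt <- ifelse(obs$accession == boost_accession, cnt * boost_factor, cnt)
        }
      } else {
        cnt <- integer()
      }
      dialect <- (s - 1) %% 3 + 1
      raw <- tibble(
        peptide = render_peptide(obs$peptide, obs$sequence, dialect),
        accession = render_accession(primary_accession(obs$accession), dialect),
        count = cnt
      )
      studies[[study_id]] <- raw
      clean[[study_id]] <- tibble(
        peptide = obs$peptide,
        study_id = study_id,
        reported_accession = primary_accession(obs$accession),
        spectral_count = as.integer(cnt)
      )
    }
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      files <- vapply(names(studies), function(id) {
        path <- file.path(dir, paste0(id, ".tsv"))
        readr::write_tsv(studies[[id]], path)
        path
      }, character(1))
    }
    list(
      studies = studies,
      observations = bind_rows(clean),
      files = files,
      params = list(
        n_studies = n_studies, detection_prob = detection_prob,
        count_prob = count_prob, min_peptide_length = min_peptide_length,
        missed_cleavages = missed_cleavages, seed = seed
      )
    )
  })
}

render_peptide <- function(peptide, sequence, dialect) {
  if (length(peptide) == 0) {
    return(character())
  }
  switch(dialect,
    peptide,
    purrr::map2_chr(peptide, sequence, function(p, s) {
      pos <- stringi::stri_locate_first_fixed(s, p)
      before <- if (pos[1] > 1) substr(s, pos[1] - 1, pos[1] - 1) else "-"
      after <- if (pos[2] < nchar(s)) substr(s, pos[2] + 1, pos[2] + 1) else "-"
      paste0(before, ".", p, ".", after)
    }),
    tolower(peptide)
  )
}

render_accession <- function(accession, dialect) {
  if (length(accession) == 0) {
    return(character())
  }
  switch(dialect,
    accession,
    sprintf("gi|%d|ref|%s|", seq_along(accession) + 1000L, accession),
    sprintf("sp|%s|%s_SYN", accession, accession)
  )
}

#' Planted unique-peptide truth for a synthetic library
#'
#' Brute-force ground truth for the unique-peptide inventory: enumerates the
#' observable tryptic peptides of every record of `library`, counts how many
#' sequences of `against` (the distinct, subset-reduced reference by
#' default) contain each peptide, and attributes each single-carrier peptide
#' to its carrier. Intended for checking pipeline recovery on generated
#' fixtures — it shares no code path with the evidence store.
#'
#' @param library Records whose digests define the observable peptide
#'   universe (typically the full generated library, fragments included).
#' @param against Records against which uniqueness is judged (default
#'   `library`; pass the subset-reduced library to mirror the pipeline).
#' @param min_peptide_length Observable-peptide length floor (default 6).
#' @param missed_cleavages Missed cleavages in the digest (default 0).
#' @return A tibble (`accession`, `n_unique_peptides`) over `against`
#'   records with at least one unique peptide.
#' @export
planted_unique_peptides <- function(library, against = library,
                                    min_peptide_length = 6,
                                    missed_cleavages = 0) {
  library <- validate_protein_library(library)
  against <- validate_protein_library(against)
  peptides <- unique(unlist(lapply(
    library$sequence, tryptic_digest, missed_cleavages, min_peptide_length
  )))
  if (length(peptides) == 0) {
    return(tibble(accession = character(), n_unique_peptides = integer()))
  }
  carrier_rows <- purrr::map(peptides, function(p) {
    hit <- which(stringi::stri_detect_fixed(against$sequence, p))
    if (length(hit) == 1) tibble(accession = against$accession[hit]) else NULL
  }) |> bind_rows()
  if (nrow(carrier_rows) == 0) {
    return(tibble(accession = character(), n_unique_peptides = integer()))
  }
  carrier_rows |>
    count(.data$accession, name = "n_unique_peptides") |>
    filter(.data$n_unique_peptides >= 1)
}
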