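# Independent brute-force oracles used to cross-check the implementation.

# O(n^2) containment oracle: which strings are NOT substrings of any longer
# string in the set (pure double loop, no shared code with the package).
oracle_maximal_strings <- function(strings) {
  n <- length(strings)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && nchar(strings[j]) > nchar(strings[i]) &&
        grepl(strings[i], strings[j], fixed = TRUE)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  strings[keep]
}

# brute-force peptide -> protein mapping row count
oracle_mapping_rows <- function(peptides, sequences) {
  total <- 0L
  for (p in peptides) {
    for (s in sequences) {
      if (grepl(p, s, fixed = TRUE)) total <- total + 1L
    }
  }
  total
}

# longest run of identical characters between two equal-length strings
oracle_longest_run <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  best <- 0L
  cur <- 0L
  for (k in seq_along(av)) {
    if (av[k] == bv[k] && av[k] != "-") {
      cur <- cur + 1L
      best <- max(best, cur)
    } else {
      cur <- 0L
    }
  }
  best
}

# Affine-gap Smith-Waterman score by dynamic programming (pure R; a gap of
# length L costs gap_open + L * gap_ext, matching the aligner's convention).
oracle_sw_score <- function(a, b, mat, gap_open = 11, gap_ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s, Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
    collapse = ""
  )
}

# a set of n random sequences with n_planted of them substrings of others
random_string_set <- function(n, n_planted, len_range = c(30, 60)) {
  stopifnot(n_planted < n)
  full <- replicate(n - n_planted, random_protein(sample(seq(len_range[1], len_range[2]), 1)))
  full <- unique(full)
  planted <- vapply(seq_len(n_planted), function(k) {
    parent <- full[(k - 1) %% length(full) + 1]
    L <- nchar(parent)
    w <- sample(seq(5, L - 3), 1)
    s <- sample(seq_len(L - w), 1)
    substr(parent, s + 1, s + w)
  }, character(1))
  out <- unique(c(full, planted))
  out[sample(length(out))]
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

make_library <- function(sequences, accessions = NULL) {
  accessions <- accessions %||% sprintf("P%03d", seq_along(sequences))
  tibble::tibble(accession = accessions, sequence = sequences)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
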