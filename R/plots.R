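#' Plot a distribution table
#'
#' Bar chart of a distribution tibble (`bin`, `n`). For numeric bins with a
#' wide dynamic range (the peptide-to-protein distributions), plot on log10
#' axes via `log10 = TRUE` — the stored table always holds raw counts; log
#' scaling is presentation only.
#'
#' @param object A distribution tibble (class `fedprot_distribution`).
#' @param log10 Log-scale both axes (numeric bins only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fedprot_distribution <- function(object, log10 = FALSE, ...) {
  df <- as_tibble(object)
  df$bin <- as.character(df$bin)
  what <- attr(object, "what") %||% "bin"
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$bin, levels = unique(.data$bin)), y = .data$n
  )) +
    ggplot2::geom_col(fill = "steelblue4") +
    ggplot2::labs(x = what, y = "frequency") +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot the peptide-to-protein distribution of an evidence store
#'
#' @param object An `evidence_store`.
#' @param mode `"distinct"` or `"redundant"` peptide counts.
#' @param ... Passed to the distribution autoplot.
#' @return A ggplot object.
#' @export
autoplot.evidence_store <- function(object, mode = c("distinct", "redundant"), ...) {
  mode <- match.arg(mode)
  autoplot(peptide_protein_distribution(object, mode), log10 = TRUE, ...)
}

#' Plot the five alignment-statistic distributions
#'
#' @param alignments An alignment tibble.
#' @return A named list of ggplot objects, one per statistic.
#' @export
plot_alignment_distributions <- function(alignments) {
  purrr::map(alignment_distributions(alignments), autoplot)
}
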