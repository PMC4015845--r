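Package: fedprot
Title: Federated Non-Redundant Protein Libraries and Peptide Evidence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for federating heterogeneous protein sequence libraries
    into a non-redundant reference, mapping peptide identifications from
    multiple published studies onto it, and summarising the evidence. The
    package implements the reduction cascade used for meta-analysis of blood
    proteomics data (distinct peptides, subset-peptide and subset-protein
    removal, redundant versus distinct protein counts), collapses homologous
    proteins into protein types with a full-length-identity plus
    perfect-match-run criterion, derives peptide-count confidence tiers,
    builds GO annotation frequency tables, runs keyword category queries, and
    performs LC-MS detection-limit arithmetic. A deterministic synthetic-data
    generator with planted homology and peptide ground truth makes every
    pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
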