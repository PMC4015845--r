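---
title: "Federating peptide evidence onto a non-redundant protein library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federating peptide evidence onto a non-redundant protein library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedprot)
library(dplyr)
```

## The problem and the model

Published peptide identification lists from blood (serum/plasma) LC-MS/MS
studies disagree in format, accession dialect and reference database, and
they over-count: the same protein appears under many accessions, as
fragments, splice variants and alleles, and the same peptide is reported
many times. `fedprot` treats the corpus as a relational object — peptides,
proteins and the substring relation between them — and derives everything
else from three reductions:

1. **Sequence-exact federation.** Two library records are the same protein
   iff their sequences are byte-identical; equivalent accessions are
   concatenated with semicolons so no information is lost. A record whose
   sequence is a perfect contiguous subset of a longer record is absorbed by
   it. Exactness is an assumption with consequences: isoleucine and leucine
   are distinct characters, the ambiguity codes B, Z, X, U compare
   literally, and allelic variants differing by one residue stay distinct.
   We prefer this conservative semantics because every relaxation
   (I/L-equivalence, wildcard X) silently changes peptide uniqueness, the
   quantity the confidence analysis rests on.

2. **The peptide cascade.** Raw reported peptides are deduplicated
   (`distinct`), then peptides that are contiguous substrings of longer
   peptides are dropped (`maximal`). Peptides map to proteins by exact
   substring occurrence; a peptide occurring at several offsets in one
   protein counts once — the mapping captures identification, not coverage.

3. **Homology closure.** Distinct proteins that still describe the same
   molecule (fragments, variants) are collapsed into *protein types* by the
   match criterion: identity over more than 75% of the full query length
   **and** a perfect match string of at least 20 aligned residues. Matching
   is asymmetric for fragment/parent pairs (the fragment as query matches,
   the parent as query does not — the identity denominator is the full
   query length precisely so that fragments are absorbed); taking connected
   components of the top-hit match edges makes the resulting partition
   independent of edge direction, and it is the minimal closure under which
   "protein type" is well defined.

The confidence model is deliberately simple: the distinct-peptide count per
protein. Randomised-library and randomised-spectra controls put roughly 88%
of false-positive proteins at one peptide, ~11% at two and ~1% at three or
more, so the tiers are `single` (1), `double` (2) and `high` (≥ 3, < 1%
false-positive rate). The most conservative inventory restricts further to
proteins with at least one *unique* peptide — a peptide found in exactly
one distinct protein sequence. Uniqueness is evaluated against the
subset-reduced library: against the raw library every peptide of a fragment
record is shared with its parent by construction, which would empty the
unique set without conveying any information.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_peptide_length` | 6 | residues | shorter peptides occur by chance in many sequences; their substring mappings are uninformative |
| `min_identity_fraction` | 0.75 (strict `>`) | fraction of full query length | the structural-identity standard for calling two proteins the same type |
| `min_perfect_run` | 20 | residues | a contiguous exact block this long is vanishingly unlikely between unrelated proteins |
| gap open / extend | 11 / 1 | score units (BLOSUM62) | standard BLASTp protein scoring |
| `min_distinct_peptides` | 3 | peptides | the < 1% false-positive tier |
| `instrument_limit` | 1 or 10 | fmol on column | ion-trap detection limit vs reproducible confident identification |
| `recovery` | 1.0 | fraction | assumes efficient capture/fractionation; lower it to model losses |

Spectral counts default to 1 when a study publishes plain peptide lists, so
redundant counts then equal row counts — the number of reported
spectrum-to-peptide correlations. Where per-study semantics differ
(spectral counts vs detection lists) both are representable; rows-as-
detections is the default.

## The internal aligner and imported BLAST tables

`align_pair()` is a Smith–Waterman local alignment (via Biostrings) that
reports the tabular statistics — identities, aligned columns, mismatches,
gap openings — plus the longest perfect run, computed from the aligned
columns and broken by any mismatch or gap. It runs without e-value
calibration: the match criterion needs only the identity fraction and the
run length, so e-values and bitscores are optional fields populated when
alignments are imported from BLAST tabular output (`import_blast_tabular()`).
Imported rows cannot carry the perfect run (tabular output does not encode
it), so applying the criterion to them requires re-alignment; the import
path is intended for the distribution summaries, where e-values below
1e-180 are collected in a separate "machine zero" bin rather than being
log-transformed into nonsense. Top hits are ranked by bitscore where
available and raw score otherwise, with ties broken by lower e-value and
then lexicographic subject — every tie-break is total, so the collapse is
deterministic.

`align_pair()` is cross-checked in the test suite against an independent
affine-gap dynamic-programming oracle written in plain R (sequences ≤ 30
residues), and the run statistic against a brute-force run scan.

## What the synthetic generator emulates — and what it does not

`generate_library()` plants the structures the pipeline must undo:

* **families** of `variants_per_family` sequences derived from one random
  base by point substitutions at sites spaced 25 residues apart — within a
  family, identity stays ≥ ~90% and perfect runs ≥ ~24, comfortably above
  the 0.75/20 criterion; across families random sequences sit near 5%
  identity, far below it. The margin is deliberate: criterion *boundary*
  behaviour is tested separately with hand-built alignment rows, not with
  the generator;
* **fragments** — exact interior substrings (≈ 55% of the parent length,
  spanning at least one substitution site so they are substrings of their
  parent only) emitted as additional records, default 20% of the variant
  count;
* **studies** — `generate_studies()` digests every record with the trypsin
  rule (cleave after K/R except before P), samples peptides with a
  per-study detection probability, draws spectral counts from a geometric
  distribution (count = 1 + Geom(0.5)), and renders each study in a
  different reporting dialect (plain; `gi|…|ref|ACC|` with flanked
  peptides; `sp|ACC|…` with lowercase peptides) so ingest normalisation is
  exercised end to end.

All randomness flows from a single integer seed through one generator, so
fixtures regenerate identically. Default sizes (5 families × 3 variants,
20% fragments, 3 studies, lengths 100–300) keep every planted relationship
unambiguous at a scale where the O(n²) containment and all-pairs alignment
steps run in seconds; the federation procedure itself is scale-free.

What the generator does **not** emulate: spectra, retention times,
instrument noise, false peptide-spectrum matches, shared peptides between
unrelated proteins (possible in real proteomes, vanishingly rare between
random sequences), and biased amino-acid composition. Passing the
planted-recovery tests therefore demonstrates the correctness of the
reductions, not the error rates the confidence tiers would show on real
spectra — those rest on the published control experiments the tier
thresholds encode.

## Numerical and design choices

* **Strict boundary.** An identity fraction of exactly 0.75 is *not* a
  match ("greater than 75%"); a perfect run of exactly 20 *is* ("at least
  20").
* **Frequencies** are reported as `round(count/total, 5)` with R's
  round-half-even. Published summary tables mix rounding and truncation at
  the fifth decimal, so reproduction is asserted within ±1e-5.
* **Table totals** default to annotation rows (a record contributes once
  per attached annotation entry), with `total = "proteins"` as the
  alternative; the choice is a visible argument because published totals do
  not state which convention they use.
* **Representatives** (of merged records, absorbing supersets, clusters)
  are always the longest sequence, ties broken by lexicographically
  smallest accession — deterministic output everywhere.
* **Absorption targets.** A subset protein is absorbed by its *longest*
  container: the longest container is provably itself maximal, so chains
  of containment (A ⊂ B ⊂ C) terminate at a surviving record in one pass.
* **GO labels are flat strings.** The comma-joined label sets of the
  summary tables are treated as atomic terms; no GO DAG traversal. This
  reproduces the published table semantics exactly and keeps the package
  free of ontology dependencies.
* **Degenerate inputs.** Empty libraries, empty observation sets and empty
  categories return empty, well-typed tibbles; zero-length queries,
  non-positive scenario values and counts below 1 raise classed errors
  (`fedprot_domain_error`, `fedprot_config_error`, …) rather than warnings.
* **Evidence store.** The relational image (study / observation / protein /
  mapping / unmapped tables) is held as a list of tibbles and exported as a
  directory of TSVs; re-export from the same inputs is byte-identical,
  which the suite asserts. Counters are pure functions of the store, so
  `summarize_evidence()` after `run_build()` reproduces the build's own
  report.
* **Both collapse entry points** are exposed: the redundant (merged-only)
  library and the distinct subset-reduced library can each be collapsed,
  since corpus-level type counts are meaningful on either; analyses in this
  package default to the distinct library, where uniqueness is defined.
* **Unique-peptide analysis entry points.** Whether the peptide universe
  feeding the unique-peptide inventory is taken before or after
  subset-peptide removal is left to the caller — `unique_peptide_proteins()`
  works on whatever observations the store was built from, and
  `remove_subset_peptides()` is a separate, composable step.

## Known limitations

* Exact-substring peptide mapping cannot represent peptides with residue
  ambiguity (an X in a library sequence never matches a peptide residue).
* The internal aligner is exact Smith–Waterman, not a seeded heuristic: at
  corpus scale (tens of thousands of proteins) all-pairs alignment is not
  practical, and pre-computed BLAST tabular input plus re-alignment of
  candidate pairs is the intended route.
* Connected-component collapse can chain: A–B and B–C matches merge A and C
  even if A–C would not match directly. This is the stated closure
  semantics, but on corpora with long fragment chains it can collapse
  proteins that are pairwise distinct — the same caveat noted for
  BLAST-based reduction generally.
* No parsimony/set-cover protein inference: proteins are never minimised
  against each other; the unique-peptide inventory is the conservative
  counterpoint.
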