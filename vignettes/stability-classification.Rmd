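---
title: "Classifying amino acid substitution effects on protein stability"
author: "protstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying amino acid substitution effects on protein stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protstab)
```

## The problem

An amino acid substitution changes the free energy of unfolding of a
protein by an amount ΔΔG (kcal/mol; in the convention used throughout
this package a positive value means the variant *stabilizes* the
protein). Experimental ΔΔG measurements are scarce, noisy and measured
under heterogeneous conditions, so sequence-based predictors are used to
triage variants. `protstab` implements a complete pipeline for building
and evaluating such a predictor as a three-class problem — stability
**increase**, **no effect**, **decrease** — rather than a regression,
because measurement uncertainty near zero makes the sign of small ΔΔG
values unreliable. Values within ±0.5 kcal/mol of zero are treated as
having no effect; the band is closed, so ΔΔG = ±0.5 itself is neutral.

The pipeline has five stages, each usable on its own: curation of raw
thermodynamic records, feature extraction, homology-aware partitioning,
two-step feature selection, and a two-layer random-forest cascade, plus
an evaluation module designed for heavily imbalanced class sizes.

## Curation of thermodynamic records

Public collections of stability measurements are known to mix units
(kcal/mol and kJ/mol), temperature scales (Celsius and Kelvin), sign
conventions, pseudo-wild-type backgrounds (e.g. a cysteine-free
construct carrying C54T/C97A), measurements on unfolded proteins,
per-stage values of multi-step denaturation pathways, very short
peptides, and duplicated entries. `apply_curation()` makes the cleaning
mechanical and auditable: every record is either kept, corrected (unit,
temperature-scale and declared sign-convention fixes in
`harmonize_units()`), or rejected with a machine-readable reason code.

Decisions worth stating explicitly:

* **Kelvin detection.** Temperatures above 150 are treated as Kelvin
  readings and shifted by −273.15. No folded-protein measurement in
  scope happens above 150 °C, so the heuristic cannot misfire on real
  Celsius values.
* **Sign convention.** A wrong ΔΔG sign cannot be detected mechanically
  from a single number; records may declare their convention in an
  optional `ddg_sign` column and are flipped to positive-stabilizing.
* **Stage records.** Per-stage values of a two-step denaturation pathway
  (`state_flag = "stage_partial"`) are always rejected: neither the
  middle value nor an average of stages is the folded→unfolded ΔΔG. The
  recorded total of the pathway (`stage_total`) is kept, since it is
  that quantity.
* **Conditional deletion.** Measurements at pH outside 5–9 or above
  0.2 M salt are rejected *only* when an in-window measurement of the
  same variant exists — a lone measurement at pH 4 is better than no
  measurement.
* **Short peptides.** Chains under 30 residues are not considered
  proteins with a defined fold. The threshold is a package choice; the
  underlying principle ("very short peptides") does not come with a
  number.
* **Representative selection.** Residual multiplicity is resolved by
  method preference (differential scanning calorimetry, then other
  thermal methods, then chemical denaturation), then pH closest to 7,
  then lowest salt, with record-id order as the final deterministic
  tie-break.

`make_reverse_variants()` can augment a dataset with mirrored
substitutions (wt and mutant swapped, ΔΔG negated, reference sequence
carrying the forward change); whether that helps is an empirical
question the package leaves to the user.

## The 1106-feature descriptor

`feature_registry()` fixes an ordered, named census of 1106 features in
nine families:

| family | n | content |
|---|---|---|
| condition | 2 | measurement temperature (°C) and pH, verbatim |
| conservation | 3 | information content at the site; PSSM score of wt and of mutant residue |
| coevolution | 4 | `is_coevolving`, `max_cor`, `is_coevolving_grp`, `grp_count` |
| aaindex | 617 | physicochemical index differences and pair matrix entries |
| vartype20x20 | 400 | one-hot (wt, mut) residue pair |
| vartype6x6 | 36 | one-hot (group(wt), group(mut)) over six physicochemical groups |
| neighborhood_counts | 20 | residue counts in a 23-position window, site excluded |
| neighborhood_classes | 5 | nonpolar / polar / charged / positive / negative neighbour counts |
| external_protein | 19 | precomputed per-protein descriptors, accepted as a sidecar table |

Conservation is computed from a *pre-computed* multiple sequence
alignment (the package reads aligned FASTA and Clustal); collecting
homologs (typically a BLAST search at E < 0.001) and aligning them is
deliberately upstream of this package. Information content is
`log2(20) + Σ p log2 p` in bits over gap-free counts; PSSM scores are
log-odds against a background with a pseudocount. The pseudocount
(total mass 1.0, spread by the background), the uniform 0.05 background
and log base 2 are package defaults — reasonable standard choices, made
explicit because nothing forces them.

The four co-evolution features are produced by a correlation proxy:
pairwise column association by Cramér's V on residue identities, a
threshold (default 0.8) for the binary call, and connected components of
the thresholded association graph for group membership. The original
external co-evolution tool is unmaintained; the proxy keeps the feature
names and value ranges so downstream models are drop-in comparable, but
numeric agreement with the original tool is explicitly not a goal.
Alignments with fewer than 10 homolog rows yield all-zero co-evolution
tuples flagged low-depth.

For the AAindex family, per-residue indices are encoded as
`value(mut) − value(wt)` — one scalar per index, which is what makes the
617 count attainable — and pairwise matrices contribute their (wt, mut)
entry. The packaged default table combines the real AAindex per-residue
collection distributed with seqinr (531 complete indices) with 86
deterministic **synthetic** symmetric matrices (`SYNM` accessions)
standing in for the substitution-matrix and contact-potential section,
which is not redistributable here; the census of 617 usable features is
preserved, and `parse_aaindex()` reads the standard flat-file dialect if
a user supplies a real file.

The 19 external per-protein descriptors (thermodynamic and
property-based indices computed by external structure/sequence software)
are accepted as a precomputed sidecar TSV; absent values are masked and
imputed with training-set medians at prediction time.

## Homology-aware partitioning

Proteins — not variants — are the unit of splitting, because many
features are protein-wide: two variants of one protein in different
partitions leak information. `cluster_proteins()` builds single-linkage
clusters over the graph of global-alignment identities above 30%
(identity = identical positions / alignment length, the conservative
denominator). `make_cv_plan()` then draws a blind test set only from
singleton clusters (proteins with no close homolog anywhere, the most
stringent test) and assigns whole clusters to five folds greedily,
largest first, onto the currently smallest fold.

Class balancing for the cascade follows the layer semantics: layer 1
keeps all decrease cases and assembles an equally sized "no decrease"
class from equal halves of increase and no-effect cases (the equal-halves
reading of an ambiguous published description — a documented choice);
layer 2 undersamples the larger of increase/no-effect. A half is
resampled with replacement only when it cannot fill its share, and that
event is flagged in the result.

## Two-step feature selection

Per fold, `backward_eliminate()` trains a forest, drops the feature with
the smallest impurity importance, and repeats down to 8 features,
recording the held-out error path. The five per-fold subsets are merged
without duplicates (8–40 candidates) and `forward_select()` grows the
final subset greedily: each round adds the candidate with the lowest
mean CV error, accepting only strict improvements, and stops at the
first round without one — so the accepted error sequence is strictly
decreasing by construction. Ties break by candidate order, which makes
the whole procedure deterministic under a fixed seed. Whether the
per-fold step should return the terminal 8 features or the best-scoring
intermediate subset is ambiguous in the published description; both are
implemented (`keep = "terminal"` / `"best"`), terminal being the default
because it is insensitive to error-path ties.

## The two-layer cascade

`train_two_layer()` fits two balanced binary forests of 300 trees
(package default, overridable): layer 1 decides *decrease vs not*; only
variants not called decrease reach layer 2, which decides *increase vs
no effect*. Both layers threshold the vote fraction at 0.5 — the
published description does not state the threshold, and 0.5 is the
natural choice for balanced training sets. The cascade rule is strict:
a layer-1 decrease call is terminal, which the test suite asserts as an
invariant. The model stores its feature lists, imputation medians, tree
count, seeds and a registry checksum so feature-order drift is caught at
prediction time.

## Evaluation under class imbalance

With class sizes of roughly 1:2:4 (increase : no effect : decrease), raw
accuracy rewards predicting the majority class. The metrics module
therefore provides, besides the six standard binary measures (accuracy,
PPV, NPV, sensitivity, specificity, MCC; undefined values are reported
as `NA`, never as 0):

* **CPR**, the correct prediction ratio: trace over total of the K×K
  confusion matrix.
* **GC²**, the generalized squared correlation: χ²-based association in
  [0, 1], equal to MCC² on 2×2 tables; undefined when a margin is zero
  (as happens when a tool never predicts one class).
* **Class-size normalization**: each true-class row of the confusion
  matrix is rescaled so its total equals the reference (no-effect) class
  size. Row proportions are preserved exactly; sensitivities are
  invariant; column-derived measures (PPV, specificity, NPV) change and
  are recomputed from the scaled matrix. Both single-pass normalization
  of a pooled matrix and per-fold normalization before averaging
  (`normalize_folds()`) are available; single-pass is the default, and
  the two differ slightly whenever fold compositions differ.

`confusion_from_ovr()` rebuilds a K×K matrix from published one-vs-rest
TP/FN/FP counts: the diagonal and both margins are determined exactly
(which is all that CPR, normalized CPR and every one-vs-rest measure
depend on); the off-diagonal split, which is undetermined, is filled by
iterative proportional fitting. The packaged benchmark count files under
`inst/extdata/` feed the acceptance script through exactly this route.

## Synthetic data: what it does and does not show

The fixture generators emulate the *mechanics* of the study conditions,
not protein energetics. `generate_variant_corpus()` uses the benchmark's
class proportions (1:2:4), ΔΔG range (−17.4 to 23.0 kcal/mol), pH range
(2.7–9.6) and temperature range (0–89 °C); class-conditional ΔΔG values
are truncated normals (decrease mean −2, increase mean +1.5, sd 1) with
the neutral class uniform on the ±0.5 band — range-anchored inventions,
fixed once so tests are reproducible. `generate_feature_table()` plants
a known number of mean-shifted informative columns among standard-normal
noise; `generate_toy_msa()` plants invariant columns and perfectly
correlated column pairs; `generate_corrupted_variant_file()` plants
curation issues with a ground-truth sidecar. Passing tests on these
fixtures demonstrates that the machinery (curation audit, selection
recovery, cascade consistency, evaluation arithmetic) is correct — they
say nothing about predictive performance on real proteins, which is
bounded by data quality and size, not by code.

Problem sizes used in the shipped tests were chosen to exercise the
algorithms well inside a laptop-scale budget: selection-recovery runs
use 150×50 feature tables over 20 seeds; separability checks use 600×12
tables; coevolution nulls use 200-row alignments. The published
evaluation quantities that the acceptance script reproduces (blind-test
CPR 0.552 and its normalized value 0.429, the comparison tool's
normalized CPR 0.37, the cross-validation CPR 0.520) are arithmetic
consequences of the packaged confusion counts and are exact at any
scale.

## Numerical choices and degenerate inputs

* Rounding for display follows half-away-from-zero
  (`round_half_up()`), matching how the reference tables are printed;
  all downstream arithmetic uses unrounded values. (The reference
  tables themselves round inconsistently in one place — two normalized
  CPRs of 0.36 vs 0.37 arising from nearly identical counts — which is
  why display rounding is isolated in one function.)
* PSSM computation refuses a zero pseudocount, which would produce
  −∞ log-odds for unobserved residues.
* A column whose homolog rows are all gaps gets its information content
  from the reference residue alone and is flagged degenerate.
* Empty prediction input returns an empty, correctly typed result;
  single rows are handled as 1-row matrices.
* All generators, balancers, planners and trainers take explicit seeds;
  equal seeds give identical artifacts (asserted down to byte-identical
  output files in the test suite).

## Known limitations

* The pairwise-matrix section of the default AAindex table is synthetic
  (see above); users wanting the real matrices should supply an AAindex
  flat file via `parse_aaindex()` + `aaindex_table()`.
* The co-evolution proxy is a documented approximation, not the original
  tool.
* The external 19 protein descriptors are consumed, never computed.
* O(L²) column-pair association limits co-evolution profiling to
  moderate protein lengths; for long proteins compute profiles once and
  reuse them.
* The curation rules are mechanical; they reproduce auditable decisions,
  not the literature checks a human curator performs against original
  publications.
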