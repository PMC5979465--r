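# protstab

Three-class classification of amino acid substitution effects on protein
stability, for structural bioinformaticians building or auditing
sequence-based stability predictors.

An amino acid substitution changes a protein's free energy of unfolding
by ΔΔG (kcal/mol; here positive = stabilizing). Because experimental
ΔΔG values near zero are dominated by measurement uncertainty, the
package treats prediction as a three-class problem — **increase**,
**no effect** (|ΔΔG| ≤ 0.5 kcal/mol, closed band), **decrease** — and
implements the full pipeline around it:

* **Curation** of ProTherm-style thermodynamic records: unit
  (kJ/mol → kcal/mol, ÷4.184) and temperature-scale (Kelvin → Celsius)
  harmonization, declared sign-convention flips, background variants
  (pseudo-wild-type constructs), rejection of unfolded-protein,
  partial-stage, short-peptide, sequence-mismatched, superseded
  out-of-window (pH 5–9, salt < 0.2 M) and duplicate records — every
  exclusion carrying a machine-readable reason code.
* **Features**: a fixed 1106-slot named registry — temperature and pH
  (2), MSA information content and wt/mutant PSSM scores (3),
  co-evolution proxy scores (4), AAindex encodings (617), one-hot
  substitution type over residues (400) and physicochemical groups (36),
  23-position sequence-neighbourhood composition (20 + 5), and 19
  precomputed external protein descriptors.
* **Homology-aware partitioning**: single-linkage clustering at >30%
  global-alignment identity, blind test sets drawn from singleton
  clusters only, cluster-intact 5-fold assignment, and the balanced
  binary training sets of the cascade.
* **Two-step feature selection**: per-fold random-forest backward
  elimination to 8 features, duplicate-free merge, then greedy forward
  selection with a strict-improvement stopping rule over the full CV.
* **Two-layer cascade**: a 300-tree balanced forest deciding *decrease
  vs not*, then a second forest splitting the remainder into *increase
  vs no effect*; a layer-1 decrease call is terminal.
* **Evaluation for imbalanced classes**: one-vs-rest accuracy, PPV, NPV,
  sensitivity, specificity and MCC; the correct prediction ratio
  CPR = trace(z)/N; the generalized squared correlation
  GC² = Σᵢⱼ (zᵢⱼ − eᵢⱼ)² / (eᵢⱼ · N · (K−1)), with eᵢⱼ = xᵢyⱼ/N, which
  equals MCC² for K = 2; and class-size normalization that rescales every
  true-class row of the confusion matrix to the no-effect class size.

A synthetic-fixture module generates variant corpora, alignments with
planted conservation/co-evolution, feature tables with known informative
columns, and corrupted input files with ground truth — everything the
test suite needs, built in code.

## Worked example: evaluating a blind test

The package ships the one-vs-rest confusion counts of a published
blind-test evaluation (165 variants in proteins with no close homolog in
training). `confusion_from_ovr()` rebuilds the 3×3 matrix (diagonal and
margins exact), and `full_report()` produces the raw and
class-size-normalized report:

```r
library(protstab)
m <- benchmark_confusion("blind")
full_report(m, reference_class = "no_effect")
```

```
Raw confusion matrix:
           predicted
true        increase decrease no_effect
  increase         3       14         6
  decrease        10       66        16
  no_effect        6       22        22
CPR 0.552  GC2 0.039
      class accuracy   ppv   npv   tpr   tnr   mcc
1  increase    0.782 0.158 0.863 0.130 0.887 0.019
2  decrease    0.624 0.647 0.587 0.717 0.507 0.229
3 no_effect    0.697 0.500 0.769 0.440 0.809 0.258

Normalized to reference class size:
           predicted
true        increase decrease no_effect
  increase       6.5     30.4      13.1
  decrease       5.5     35.9       8.7
  no_effect      6.0     22.0      22.0
CPR 0.429  GC2 0.032
```

Reading this: of 165 blind variants, 55.2% are labelled correctly
(CPR 0.552), but the raw number flatters the majority class — decrease
variants outnumber increase 4:1. After every true class is rescaled to
the 50-case no-effect size, the comparable figure is CPR 0.429.
Sensitivities (0.130 / 0.717 / 0.440) are scaling-invariant; PPVs are
not, which is why both forms are reported. (Off-diagonal cells are an
iterative-proportional-fitting reconstruction from the published
one-vs-rest counts; CPR, normalized CPR and all one-vs-rest measures
depend only on the exact diagonal and margins.)

Training and predicting on a synthetic separable corpus:

```r
ft <- generate_feature_table(n_rows = 600, n_features = 12,
                             n_informative = 4, effect_size = 3, seed = 113)
hold <- seq(3, 600, by = 3)
model <- train_two_layer(ft$x[-hold, ], ft$y[-hold],
                         features1 = colnames(ft$x),
                         features2 = colnames(ft$x),
                         ntree = 150, seed = 2)
pred <- predict(model, ft$x[hold, ])
cpr(confusion_matrix(ft$y[hold], pred$label, classes = STABILITY_CLASSES))
#> [1] 0.995
head(pred, 3)
#>      label score_decrease score_increase
#> 1 increase    0.000000000    1.000000000
#> 2 decrease    0.986666667    0.006666667
#> 3 increase    0.006666667    0.980000000
```

## Command line

A thin Rscript dispatcher over the same functions lives at
`inst/cli/protstab.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "protstab.R", package = "protstab"))')" \
    simulate --out-dir corpus --n-proteins 8 --seed 1
# subcommands: curate, features, select, train, predict, evaluate, simulate
```

## Package layout

```
R/                  curation, conservation, features, partitioning,
                    selection, cascade, metrics, fixtures, runners
inst/extdata/       benchmark confusion counts (TSV), synthetic AAindex
                    example file
inst/cli/           command-line dispatcher
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, assumptions, choices)
scripts/            acceptance.R
```
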