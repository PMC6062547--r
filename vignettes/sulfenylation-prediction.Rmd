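---
title: "Predicting S-sulfenylation sites: model, encodings and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting S-sulfenylation sites: model, encodings and evaluation protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfenpred)
```

## The problem

S-sulfenylation is the reversible oxidation of a cysteine free thiol (-SH)
to sulfenic acid (-SOH), typically driven by hydrogen peroxide and largely
non-enzymatic. It regulates the activity, stability and interactions of many
redox-sensitive proteins, but mapping it experimentally (chemoselective
probes plus tandem MS) is slow and expensive. `sulfenpred` addresses the
complementary *in silico* task: given only primary sequence, rank the
cysteines of a protein by how sulfenylation-like their sequence
neighbourhood looks.

The unit of prediction is a 21-residue peptide window: the candidate
cysteine plus 10 flanking residues on each side. Windows that would run past
a protein terminus are padded with the pseudo-residue X, which always forms
a contiguous run at one or both ends of a window. The classifier never sees
the protein beyond this window, so the model's central assumption is that
the local sequence context carries the signal — a reasonable assumption for
a largely non-enzymatic modification governed by the physicochemical
environment of the thiol, and the same assumption made by most peptide-based
PTM predictors.

## Feature encodings

Each window is converted to a numeric vector by five blocks, concatenated in
a fixed order. The central cysteine is constant by construction, so the
position-wise blocks drop it and encode the 20 flanking positions only.

| Block   | Content                                                | Dimension |
|---------|--------------------------------------------------------|-----------|
| BE      | one-hot over the 21-letter alphabet per flank position | 20 x 21 = 420 |
| AAindex | 14 physicochemical properties per flank position       | 20 x 14 = 280 |
| KSAAP   | ordered residue-pair counts at spacings k = 0, 1, 2    | 21 x 21 x 3 = 1,323 |
| AAC     | frequency of each canonical residue among the flanks   | 20 |
| HQI     | 8 high-quality AAindex indices per flank position      | 20 x 8 = 160 |

Total: 2,203 features. The fixed alphabet order is ACDEFGHIKLMNPQRSTVWY
followed by X; any fixed order would do, and stating one makes the encoding
bit-reproducible.

Design choices that were genuinely open:

* **KSAAP spacer range.** The block dimension 21 x 21 x 3 = 1,323 requires
  exactly three spacer values; we use k in {0, 1, 2}, starting at the
  standard CKSAAP dipeptide case k = 0. The pair counts run over the *full*
  21-residue window, central cysteine included: pairs spanning the centre
  carry motif information, and unlike the three position-wise blocks there
  is no redundancy argument for removing the constant residue from pair
  counting (a pair involving C still varies through its partner).
* **AAC denominator.** We compute F_a = R_a / R with R = 20, the flank
  length including X positions, and the central C excluded from the counts.
  This keeps the block at 20 dimensions, makes all-X flanks encode as
  all-zero (consistent with the X-is-zero convention of BE/AAindex/HQI),
  and gives the exact identity `sum(F_a) + X-fraction = 1`.
* **Property scaling.** The 14 AAindex properties and 8 HQI indices have
  wildly heterogeneous units (molecular weight ~ 100s, net charge ~ ±1).
  Because the RBF kernel is a function of Euclidean distance, unscaled
  values would let molecular weight dominate every other property, so each
  scale is min-max normalised to [0, 1] across the 20 canonical residues
  before use; X then maps to 0. `aa_property_table(scale = FALSE)` exposes
  the raw values.
* **Property provenance.** The 14 properties are named concepts
  (hydrophobicity, polarity, pK-N, ...), each of which matches several
  AAindex entries. The accessions chosen here (see
  `?aa_property_table`: ARGP820101, JANJ780101, GRAR740102, CHAM820101,
  CHOC760102, FASG760101–FASG760105, KLEP840101, HUTJ700101–HUTJ700103) are
  the classical scale for each name; values are read from the AAindex copy
  distributed with \pkg{seqinr}. The 8 HQI accessions are fixed by
  definition (BLAM930101, BIOV880101, MAXF760101, TSAJ990101, NAKH920108,
  CEDJ970104, LIFS790101, MIYS990104 — the fuzzy-clustering representatives
  of 544 AAindex scales). Numeric values in the AAindex block are therefore
  implementation-defined up to the accession choice; the dimensions and
  zero-conventions are not.
* **Non-canonical letters.** Input FASTA letters outside the 20-letter
  canonical alphabet (B, J, O, U, Z, stop/gap) are normalised to X with a
  warning, since every encoder is defined over the 21-letter alphabet.

## Class imbalance and where oversampling happens

Experimentally verified sulfenylation sites are heavily outnumbered by
unmodified cysteines (the benchmark shape this package targets is 900
positive vs 6,858 negative training sites). `oversample()` balances the
classes by replicating randomly chosen minority rows, uniformly with
replacement, until the counts match — no majority information is discarded,
which is the reason to prefer oversampling over under-sampling on a dataset
this small.

The *placement* of that step matters more than the step itself.
`cross_validate()` exposes it as the `balance` argument:

* `"paper"` (default) oversamples the whole training set once and then
  folds the balanced data. Replicates of one fragment can then appear in
  both a training and a test fold, so cross-validated sensitivity is
  systematically optimistic. This is the protocol used historically for
  this predictor, and the default reproduces it deliberately.
* `"fold-safe"` folds the original data and oversamples inside each
  training fold only; per-fold provenance bookkeeping guarantees (and the
  test suite asserts) that no replicate of a test-fold fragment is ever
  trained on.

The acceptance checks demonstrate the mechanism: on moderately separable
synthetic data, CV sensitivity under `"paper"` balancing exceeds that under
`"fold-safe"` — the same optimism that shows up as a large drop in
sensitivity when such a model meets a genuinely independent test set.

## The classifier

An RBF-kernel support-vector machine (libsvm via \pkg{e1071}), with the
operating point C = 0.1 and kernel width kw = 0.005. "Kernel width" is
interpreted as the exponent coefficient gamma in exp(-gamma ||u - v||^2) —
the usual meaning in SVM tools — with the bandwidth parameterization
(gamma = 1/(2 sigma^2)) selectable via `kw_is = "sigma"`. Features are fed
to the kernel as produced by the encoders, which are already in [0, 1]-ish
ranges; an optional `standardize` flag adds z-scoring for users who supply
their own feature matrices. libsvm's decision values are sign-ambiguous
(they follow the class it encounters first), so the fit stores an
orientation factor making `decision_scores()` always positive-class-high.
Classification uses the decision boundary (score > 0) by default; ROC
analysis uses the continuous scores, never the thresholded labels.

## Evaluation

`classification_metrics()` implements the four standard measures: ACC, SN
and SP as percentages and the Matthews correlation coefficient. When an MCC
denominator factor is zero the coefficient is undefined; it is reported as
0 with a `mcc_degenerate` flag, the usual "no correlation" convention.
Sensitivity is `NaN` when no positives exist to measure it on.

`roc_curve()` sweeps all distinct score thresholds, grouping tied scores
into a single step, anchors the curve at (0, 0) and (1, 1), and integrates
by the trapezoid rule. Under this tie convention the AUC equals the
Mann–Whitney U statistic over positive–negative pairs with ties counted
half, so a constant-score classifier scores exactly 0.5. The test suite
verifies this equivalence by brute-force pair enumeration, and checks
against \pkg{pROC} on continuous scores.

`cross_validate()` uses class-stratified folds (per-class fold sizes differ
by at most one), which avoids empty-class folds on imbalanced data; the
headline metrics are unweighted means over the fold models, with pooled
confusion counts and a pooled ROC reported secondarily because the choice
between the two aggregations is not canonical. `ablation()` re-runs CV on
feature-block subsets with identical folds and seed so that
one-feature-at-a-time rows are directly comparable to the all-features row.

## The synthetic generator

`motif_spec()` + `generate_fragments()` provide the data every stage is
tested on. Negative flanks are i.i.d. draws from a background distribution
(uniform over the 20 canonical residues by default); positive flanks are
drawn per position from `(1 - strength) * background + strength * motif`,
where the motif prefers one fixed residue per flank position. `strength`
therefore interpolates between statistically identical classes (0) and a
fully deterministic positive motif (1); `terminal_x_rate` (default 0.1)
controls how often a fragment is terminal-padded. The signal is
compositional and positional, which is exactly the kind of signal all five
encoders can represent — so recovery tests exercise every block.

What the generator does *not* emulate: the real sulfenylation motif,
sequence homology between fragments (real benchmarks must be filtered at a
sequence-identity threshold upstream), protein-level structure, or realistic
amino-acid background frequencies. Passing signal-recovery tests shows the
pipeline is statistically sound and leak-free under its own assumptions; it
says nothing about biological accuracy on real proteomes, which is
determined by the curated training data a user supplies.

`generate_benchmark_dataset()` reproduces the *shape* of the curated
benchmark (900/6,858 training, 145/268 independent, disjoint windows) at
moderate strength 0.5, so count-contract and end-to-end tests run at the
realistic scale without any download. `generate_protein_dataset()` embeds
motif windows into full synthetic proteins to exercise the FASTA/site-table
path, including X-padding near termini and unlabelled background cysteines.

## Problem sizes and numerical choices

The test-suite and acceptance sizes are chosen to be informative at desk
scale: signal recovery uses 10-fold CV on 400 fragments at strength 0.9
(expected near-ceiling performance) and 2,000 fragments at strength 0
(chance band 0.45–0.55 for AUC); monotonicity is checked at strengths
{0, 0.5, 0.9} with 400 fragments each; the sensitivity-inflation comparison
uses 150 positive / 600 negative fragments at strength 0.5 — imbalanced
enough that balancing matters, small enough to cross-validate twice. Oracle
equivalence runs on 1,000 random windows (pair counting), 100 random score
vectors (AUC vs U statistic, with ties forced by rounding) and 10,000 random
confusion tables (metric formulas).

Seeds are explicit arguments everywhere randomness exists (fold assignment,
replication draws, fragment generation); identical seeds give identical
results, and the RNG state of the calling session is restored afterwards.
Ties in classification (score exactly at the threshold) go to the negative
class.

## Limitations

* Predictions are only as good as the curated site table used for training;
  the package deliberately does not curate data or filter homology.
* The default `balance = "paper"` protocol reports optimistic CV
  sensitivity by construction; use `"fold-safe"` (or an independent test
  set via `evaluate_model()`) for honest generalisation estimates.
* The AAindex block depends on the documented accession choices; a user
  reproducing another tool's numbers must match its property scales.
* Training cost grows quadratically with fragments; datasets beyond ~10^4
  fragments need subsampling or a different solver.
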