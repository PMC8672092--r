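---
title: "Predicting phage virion proteins from fused sequence descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phage virion proteins from fused sequence descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phage virion proteins (PVPs) are the structural proteins packaged into a
bacteriophage particle. Distinguishing them from non-virion proteins by wet-lab
experiment is slow and expensive, so sequence-based classifiers are the
standard first screen. `pvpkit` implements one family of such classifiers: the
protein sequence is turned into a fixed-length numeric vector by two
complementary encoders, an importance ranking prunes the high-dimensional
k-mer block, and a linear model trained by stochastic gradient descent (SGD)
separates the two classes. The package also ships a synthetic labelled-sequence
generator so that every stage — and the pipeline end to end — is testable
without downloading any external benchmark.

```{r setup}
library(pvpkit)
```

## The two encoders

**k-tuple composition (kNC).** For a declared alphabet $A$ (DNA, RNA, or the
20 standard amino acids) and a maximum tuple length $k$, the encoder counts
every $i$-mer, $i = 1 \dots k$, as an overlapping substring. The dimension is
$\sum_{i=1}^{k} |A|^i$: 20, 420 and 8{,}420 for protein at $k = 1, 2, 3$.
Counts are normalised per block by the window count $L - i + 1$, so each
$i$-mer block sums to 1 and features are comparable across sequence lengths;
raw counts remain available (`normalize = FALSE`). Columns are ordered by
ascending $i$ and lexicographically within a block using the alphabet's
declared symbol order, so column 21 of the protein space is always `AA`.

**The 188-dimensional descriptor.** The classical "188D" protein
representation is the amino-acid composition $V_i = N_i / L$ (20 values)
plus composition/transition/distribution (CTD) features over eight
physicochemical properties, each of which partitions the 20 residues into
three groups: per property, 3 composition (group frequencies), 3 transition
(adjacent cross-group pair rates over $L - 1$ pairs) and 15 distribution
values, i.e. $(3 + 3 + 15) \times 8 = 168$, for 188 in total. The property
partitions (hydrophobicity, normalized van der Waals volume, polarity,
polarizability, charge, secondary-structure propensity, solvent
accessibility, surface tension) are the canonical CTD tables; they ship as a
plain-text file (`inst/extdata/ctd_properties.tsv`) that users can override,
and every table is validated as three disjoint groups covering exactly the
20 standard residues.

Two conventions in the D (distribution) block are underdetermined by prose
descriptions and are pinned here explicitly: with $n$ occurrences of a group
at positions $p_1 < \dots < p_n$, the anchor for quantile $q \in
\{0^+, 0.25, 0.5, 0.75, 1\}$ is $p_{\max(1,\lceil q\,n\rceil)} / L$ (ceiling
convention, 1-based positions, divided by the full length), and a group
absent from the sequence contributes five zeros. Both choices are enforced by
a brute-force oracle in the test suite. A consequence worth knowing: the
quantile anchors are exactly length-free only when the occurrence count is a
multiple of 4; the test suite asserts the homopolymer case at such lengths.

## Feature selection by boosted stumps

The 8,420-column $k=3$ space is far wider than any realistic training set,
so the pipeline ranks k-mer features with discrete AdaBoost over depth-1
decision stumps and keeps the top $n$. Each boosting round finds the single
feature/threshold split minimising the weighted misclassification, weights
it by $\log((1-\varepsilon)/\varepsilon)$, and re-weights the samples; a
feature's importance is the estimator-weighted Gini impurity decrease summed
over the rounds in which it was split on, normalised to sum to one. The
search is exhaustive and vectorised, so the procedure is fully
deterministic: ties between equally good splits go to the lower column
index, and the recorded `seed` is provenance metadata only. Boosting stops
early if no stump beats chance or a stump is perfect.

Per-$k$ selection counts are configuration with defaults chosen so the fused
dimensions land on 208, 335 and 448: $k=1$ keeps all 20 (no selection),
$k=2$ keeps 147, $k=3$ keeps 260, each fused with the 188 descriptor
columns. (Published accounts of this pipeline are internally inconsistent at
$k=2$ — a selected count of 167 cannot concatenate with 188 to the printed
fused dimension of 335 — so the fused dimension, which is printed twice and
is consistent with the $k=1$ and $k=3$ rows, is taken as authoritative.)

By default the ranker is fitted inside each cross-validation training split
only (`selection_scope = "train"`), keeping the evaluation leakage-free;
`selection_scope = "full"` fits it once on the whole matrix before
splitting, mimicking protocols that select features up front. The two can
differ noticeably on small benchmarks, which is precisely why both are
available and logged.

## The SGD linear classifier

The classifier is the linear score $h_\theta(x) = \theta_0 + \sum_i \theta_i
x_i$ fitted by per-sample least-mean-squares updates
$\theta \leftarrow \theta - \alpha\,(h_\theta(x) - y)\,x$ on 0/1 targets,
with a seeded uniform$(-0.01, 0.01)$ initialisation and a freshly shuffled
visit order each epoch; prediction thresholds the score at 0.5 (ties
positive). Because the update is a regression rule, `train_sgd()` accepts
any targets in $[0,1]$, which is also what makes closed-form recovery tests
possible. Hyperparameters that matter:

* **Learning rate $\alpha$** (constant; no decay). The LMS update is stable
  only for roughly $\alpha < 2/p$ on $p$ z-scored columns, so the pipeline
  default is automatic: $\alpha = \min(0.01,\ 1/(p+1))$ resolved at fit
  time. `train_sgd()` itself defaults to $0.01$, appropriate for the
  low-dimensional settings in which it is called directly.
* **Ridge term $\lambda$** (per-update L2 shrinkage of all weights except
  the bias; `lambda = 0` is the plain LMS rule and the `train_sgd()`
  default). The fused pipeline operates with a feature count of the same
  order as the sample count, where unregularised least squares interpolates
  the training data and generalises poorly, so the pipeline default is
  $\lambda = 0.3$ on the z-scored feature scale — mid-range of the broad
  plateau in which the planted-signal benchmarks behave equivalently. Set
  `lambda = 0` in `pvp_config()` to recover the unregularised update.
* **Epochs** (default 1000 full passes) and **seed**: fits are
  deterministic given `(x, alpha, lambda, epochs, seed)`.
* **Standardisation** is on by default — the k-mer and descriptor blocks
  live on different scales — always with training-split statistics, which
  are stored in the model and re-applied at prediction time.
* A hinge-loss variant (`loss = "hinge"`, labels recoded to $\pm 1$) exists
  for comparison; the least-mean-squares rule is the reference behaviour.

The inner loop is compiled (Rcpp); shuffle orders and initialisation come
from R's seeded RNG, so results are reproducible across machines.

## Evaluation

`confusion_counts()` and `classification_metrics()` implement Sn, Sp, ACC
and MCC from Tp/Fn/Fp/Tn with the positive class = virion protein; MCC is 0
by convention when its denominator vanishes. `kfold_cv()` runs stratified,
seeded k-fold cross-validation (stratification matters: the canonical
benchmark shape is a 99/208 imbalance); encoding is done once — it uses no
labels — while selection, standardisation and training happen per fold on
the training folds only. Pooled (micro) confusion counts are the primary
report and the per-fold macro average is reported alongside, since published
tables rarely say which was used. `holdout_eval()` draws a stratified
seeded 80/20 split (per class, the training share is
`round(fraction * n_class)`), fits on the 80% and reports metrics on the
20%.

## The synthetic generator

`generate_fixture()` draws sequence lengths uniformly from a range and
residues i.i.d. from class-specific weight tables, optionally overwriting a
short motif at a uniform position in every positive. The signal is
parameterised at the residue/motif level — not at the feature level — so
both encoders must discover it through their own arithmetic.
`benchmark_fixture()` reproduces the 99-positive/208-negative class shape of
the published virion-protein benchmark with lengths 50–300 and a moderate
compositional bias (K, R, W upweighted 2.5-fold in positives), chosen as a
learnable-but-not-trivial default for the documentation and end-to-end
tests.

What the generator deliberately does not emulate: homology structure between
sequences (real benchmarks are clustered to <40% identity; i.i.d. draws have
no such structure), domain architecture, or realistic residue
autocorrelation. Passing the planted-signal tests therefore demonstrates
that the pipeline recovers compositional and short-motif signal through the
full encode–select–fuse–classify path; it does not certify performance on
real proteomes.

## Problem sizes used by the checks

The bundled checks run at desk scale, chosen to exercise every stage at full
feature dimension while staying comfortably inside a single-CPU session: the
planted-motif benchmark uses 150 positives and 150 negatives of length
50–300 with motif `WWWHHH` and a mild W/H compositional bias at the full
$k=3$ + 188D configuration under 10-fold cross-validation; the null control
uses 20 seeded replicates of a 30/30 uniform-composition fixture at the
$k=1$ + 188D configuration (300 epochs), pooled into one binomial test
against chance at $\alpha = 0.01$; oracle-equivalence checks use dozens of
random sequences up to length 200 per encoder; and the closed-form SGD
recovery uses 50 noiseless points. The acceptance script
(`scripts/acceptance.R`) recomputes the same kinds of quantities from
scratch under a caller-supplied seed (with a shorter, five-replicate null
control).

## Known limitations

* The distribution-block quantile convention, the empty-group-zeros rule
  and the k=2 selection count are pinned choices among several defensible
  readings of the underlying method descriptions (see above).
* Constant-rate LMS-SGD without the ridge term can diverge or interpolate
  in high dimension; the automatic learning rate and default ridge exist
  precisely because of this, and both are overridable.
* Sequences shorter than $k$ (or 2, for the 188D transitions) cannot be
  encoded and are rejected by name rather than silently padded.
* The CLI's `--config` YAML accepts only flat keys mirroring
  `pvp_config()`; nested experiment grids are out of scope.
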