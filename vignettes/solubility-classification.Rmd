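---
title: "Hydrophobicity-scale ensembles for construct solubility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrophobicity-scale ensembles for construct solubility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sevc)
```

## The problem

Engineered protein constructs -- the motivating case is chimeric
virus-like particles (VLPs), hepatitis B core antigen scaffolds carrying a
foreign peptide epitope in their major immunodominant region -- frequently
fail to express solubly.  Because VLP capsid assembly is itself an
entropy-driven, hydrophobically controlled aggregation process, whether a
given insert/insertion-strategy combination yields soluble capsids or
insoluble aggregates is strongly tied to hydrophobicity.  This package
implements a sequence-only binary classifier of construct solubility built
entirely from published hydrophobicity scales.

## The model

A *hydrophobicity scale* assigns one real value to each of the 20
canonical amino acids.  Given a scale $s$ and a construct sequence, the
*feature value* is the sum of per-residue scale values over the variable
window of the sequence (the constant N- and C-terminal flanks, identical
across constructs, are trimmed; for the HBcAg application these are 73 and
71 residues, and the synthetic generator records its own flank lengths as
trim provenance).  Scales are first centred, scaled to unit variance, and
sign-oriented so that aspartic acid is non-positive -- after orientation,
larger always means more hydrophobic.

Each scale defines one *decision stump*: a one-split tree over its
feature, induced by minimizing the weighted Gini diversity index

$$G = \sum_{\text{child}} \frac{n_{\text{child}}}{n}
      \left(1 - p_0^2 - p_1^2\right)$$

over candidate thresholds at midpoints between consecutive distinct
sorted feature values.  Each child predicts its majority training class
with probability equal to the majority fraction.  The *soft ensemble vote
classifier* (sEVC) sums, over the $k$ most important stumps, each stump's
child probability into the score of its decided class; the larger score
wins.  *Feature importance* is the stump's training-set accuracy, and the
embedded feature-selection step simply sorts stumps by it, so "the best
$k$ classifiers" is a single, fully deterministic ordering.

Model quality is reported as Matthews correlation coefficient (MCC) and
accuracy; for a balanced, symmetric confusion matrix the two are linked by
$\mathrm{MCC} = 2A - 1$, which the test suite checks.  The MCC is
undefined when a denominator factor is zero; such folds are recorded as
missing and excluded from medians, with exclusion counts reported.

## Deterministic conventions

Several micro-decisions are not fixed by the method description of stock
tree fitters; this package pins them down so results are bit-reproducible:

* a feature equal to the stump threshold goes to the **right** child;
* Gini ties between candidate splits go to the **smallest** threshold
  (a numerical tolerance of $10^{-12}$ absorbs float noise between
  algebraically equal impurities);
* a 50/50 child predicts class 0, insoluble -- conservative for a
  solubility screen -- with probability 0.5;
* tied stump importances keep library order (stable sort), and reported
  ranks use min-rank so tied stumps share rank 1;
* a tied ensemble vote returns class 0;
* every repeated-randomization routine expands one master seed into
  per-fold/per-replicate child seeds (`set.seed(seed)` followed by
  `sample.int(.Machine$integer.max - 1, n)`), so single folds can be
  replayed in isolation.

Stumps are re-implemented here rather than delegated to a tree library so
that these conventions are guaranteed; the test suite cross-checks the
splits against exhaustive Gini enumeration on a thousand random datasets
and against a stock one-level CART fit.

## Sampling, validation and the learning experiment

`stratified_sample()` draws a training set while capping every insert at
$\lceil n_{\text{train}} / n_{\text{inserts}} \rceil$ occurrences and
every strategy at $\lceil n_{\text{train}} / n_{\text{strategies}}
\rceil$; once a stratum hits its cap its remaining constructs leave the
pool.  The strategy cap uses the same ceiling convention as the insert
cap; for training sizes divisible by the strategy count the two readings
coincide.

`mc_cv()` is Monte Carlo cross-validation: each fold draws
$\lfloor n/2 \rfloor$ records (training fraction configurable) without
replacement, fits and ranks the stumps *within the fold*, and predicts
the remainder for every candidate ensemble size.

`learning_experiment()` screens training size against ensemble size on a
fixed pool and a fixed, disjoint external test set.  Default sizes are 5%
to 95% of the pool in 5% steps plus the full pool as the 19th size -- for
a 384-record pool that is 19, 38, ..., 384, honouring the printed
endpoints rather than strict rounding of $0.95 \times 384$.  Training
draws are deliberately *not* stratified, replicates are repeated `reps`
times, and every cell stores its replicate MCCs so the reported median
and (unscaled) MAD are recomputable.  Strategy-level TP/TN/FP/FN counts
are accumulated over all models for `misclassification_frequency()`,
which normalizes each strategy's counts by its total occurrence; a
strategy with excess FP share is one whose solubility the model
systematically overestimates.

Two single-feature baselines are provided: a stump on the net window
charge (D, E $= -1$; K, R $= +1$; else 0, used raw) and a stump on the
lysine/arginine count ratio of the full sequence.  K/R is undefined for
arginine-free sequences and raises an error; the motivating scaffold
always contains arginine.

## The synthetic generator

The real 568-construct solubility screen is confidential, so the package
ships a generator that reproduces its *structure*: a complete
71 x 8 insert-by-strategy grid (568 constructs), constant flanks, a
roughly balanced class split, insert-dominant labels with a weak
strategy-level effect, and a tunable label-noise rate.

Design choices, made once:

* **Bimodal insert bands.**  Each insert's summed true-scale
  hydrophobicity is drawn uniformly from one of two bands of width 6
  separated by an empty margin of $2 \times 1.5$ around the decision
  threshold; sequences are built by greedy residue swaps until the sum
  matches the draw.  Half the inserts (rounded up) are assigned to the
  soluble band, giving $f_{sol} = 288/568 \approx 0.507$ by default; a
  `"median"` threshold option re-balances to exactly 0.5.  The margin
  guarantees that at zero noise the dataset is *exactly* separable by the
  true scale's feature and that a stump threshold learned on any
  reasonable training subset generalizes perfectly -- the anchor used by
  the recovery tests.  Real screens have no such margin; passing these
  tests demonstrates correct mechanics, not real-data performance.
* **Strategy effects.**  Each strategy is an insertion position plus a
  deletion (0-4 residues) in a 12-residue scaffold core; its retained
  fragment shifts the feature of every construct sharing the strategy.
  The latent score is the window feature itself (both effect weights
  default to 1), so the strategy offset is exactly the fragment's
  true-scale feature.  A purely additive offset with a weight other than
  1 would decouple the latent score from the observable feature and void
  the separability anchor, which is why non-unit weights are documented
  as experimental dials.
* **Label-level strategy effect.**  At zero noise the margin construction
  makes labels constant within an insert row, so the weak strategy
  dependence of labels is carried by noise: each label flips with
  probability `label_noise * strategy_noise_mult[s]`, and the last
  strategy defaults to a 3x multiplier (the designated "bad" strategy).
  An optional `flip_strategy` flips one stratum outright to exercise the
  misclassification analysis.
* **Residue composition.**  Insert residues start uniform over the 20
  canonical codes before target matching; flanks and core are uniform
  random but fixed across the grid.  No biophysical realism beyond the
  hydrophobicity structure is attempted -- no secondary-structure,
  codon or positional effects.

## Problem sizes used by the shipped checks

The bundled library holds ten canonical published scales (fixtures, not
the 91-scale study table), so screening "all" ensemble sizes means
$k = 1..10$.  The recovery checks run ten seeds of the full 71 x 8 grid
with a stratified 384-construct training set and 184-construct external
test set; the scaled-down learning experiment uses 5 sizes x 10 ensemble
sizes x 3 replicates.  Cross-validation examples use 10-100 folds on
48-568 constructs.  These sizes keep the whole suite interactive while
still exercising every code path at full grid width.

## Worked example

```{r example, eval = FALSE}
lib <- example_scale_library()
sim <- generate_dataset(synthetic_config(label_noise = 0.1, seed = 1))
split <- stratified_sample(sim$dataset, 384, seed = 2)

cv <- mc_cv(split$train, lib, n_folds = 100, seed = 3)
plot(cv)

fm_train <- build_feature_matrix(split$train, lib)
fit <- sevc(fm_train, split$train$records$label, k = which.max(cv$median))
pred <- predict(fit, build_feature_matrix(split$rest, lib))
mcc(confusion_matrix(split$rest$records$label, pred$class))
```

## Known limitations

* Feature values ignore residue order entirely (a windowed sum); motifs,
  sliding-window aggregation profiles and per-position scores are out of
  scope.
* Non-canonical residues (B, Z, X, U, O) have no scale values; the
  default policy is a hard error, with explicit `zero`/`skip` opt-ins,
  because silently zeroing them would bias features.
* The PCA diagnostic (`pca_variance_explained()`) treats amino acids as
  observations and scales as variables, the natural orientation when
  scales are normalized per scale; with 20 observations it yields at most
  19 non-trivial components.
* The synthetic generator's separation margin makes zero-noise recovery
  exact by construction; conclusions about noisy, margin-free real data
  must come from real data.
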