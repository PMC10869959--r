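---
title: "Hybrid feature selection with hesitant-fuzzy method scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid feature selection with hesitant-fuzzy method scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfselect)
```

## The problem and the model

Predicting the per-cycle success of IVF/ICSI treatment is a tabular
binary-classification problem with an awkward shape: a few dozen
candidate clinical predictors (hormone doses, ages, oocyte and embryo
counts, embryo quality grades, treatment history), around a thousand
cycles, and an imbalanced outcome — roughly a third of cycles end in a
clinical pregnancy. Clinicians want a *small* set of influential factors,
not a model over all of them, and single feature-selection families
disagree: filters are fast but model-blind, embedded methods depend on
one model family's inductive bias, and wrapper searches are accurate but
quadratically expensive in the number of candidates.

`hybrid_select()` chains the three families and lets a scoring system
arbitrate. The stages are: a stratified 80/20 train/test split; four
filter/embedded pre-selectors fitted on training rows (variance
threshold, ANOVA-F k-best, L1-penalised logistic regression,
random-forest impurity importance); hesitant-fuzzy scoring of each
pre-selector's six-criterion test profile; wrapper searches
(SFS/SBS/SFFS/SFBS/random) over the winning pre-selector's pool, guided
by cross-validated random-forest accuracy; and a final profile of each
wrapper's subset on the held-out rows. Pre-selection matters for the
wrapper stage twice over: it removes noise candidates that greedy search
could mistake for signal, and it shrinks the candidate pool (e.g. 38 to
19), which cuts the number of model evaluations roughly in half at each
step.

## The hesitant-fuzzy scoring system

Each pre-selector's held-out performance is summarised by six criteria on
[0, 1]: accuracy, AUC, F-score, normalized MCC, PPV and recall. With an
imbalanced outcome no single criterion is trustworthy — accuracy and
recall are inflated by the majority class, while MCC and AUC are not —
so instead of ranking methods by any one of them, the scoring system
treats the six values as a hesitant fuzzy element \(h\) and rewards
*agreement among criteria*. The deviation degree

\[\bar\sigma'(h) \;=\; \frac{1}{l_h}\sqrt{\sum_{(\gamma_i,\gamma_j)\in h}
(\gamma_i-\gamma_j)^2},\]

with the sum over all ordered pairs (each unordered pair counted twice)
and \(l_h = 6\), is the pairwise spread of the criteria; the score
function \(SF(h) = 1/\bar\sigma'(h)\) ranks methods by consistency. A
method whose accuracy is high but whose MCC and AUC lag — the signature
of majority-class exploitation — is spread out and scores low.

Two readings of the deviation-degree formula circulate (pair sum under
one radical vs. per-pair radicals); this package fixes the ordered-pair
sum under a single radical, the reading under which the published
reference scores for the four pre-selectors (42.735, 35.842, 34.482,
13.947) are reproduced from their printed six-criterion profiles to
within 0.5%. The residual is input rounding: printed profiles carry 2–3
digits. For the same reason `build_hfs()` has a *table-fidelity* switch
(`round_digits`) that rounds a profile to print precision before
scoring, reproducing scores computed downstream of a printed report;
by default unrounded values are scored.

Degenerate elements are legal: a method whose six criteria are all equal
has deviation 0 and scores +Inf with a warning — under the scoring
logic it is maximally self-consistent and ranks first. Ties between
scores break lexicographically by method id, for determinism.

### Which method feeds the wrapper stage

The wrapper stage's contract is to return exactly `target_k` features,
so its candidate pool must hold at least `target_k`. On cohorts with
strongly concentrated signal the tree-importance selector can keep fewer
(its mean-importance threshold rises with concentration); a method whose
pool cannot supply `target_k` features therefore stays in the ranking
but cannot win the hand-off. The winner is the highest-scoring method
with a sufficient pool; if none qualifies, the overall winner is used
and `target_k` is capped at its pool size, with a warning.

## Evaluation metrics and their conventions

All scalar metrics derive from confusion counts. Zero denominators
(e.g. no positive predictions) yield 0 with a warning, keeping profiles
total on degenerate splits; MCC returns 0 when any marginal is empty,
the standard convention. MCC enters HFS elements only through the affine
map \((m+1)/2\) onto [0, 1].

Two aggregation modes exist for PPV/recall/F because published reports
of this pipeline are only consistent with class-weighted values (a
profile with PPV 0.79 and recall 0.8 but F 0.77 is impossible for a
positive-class harmonic mean). The default `support_weighted` averages
the per-class precision/recall/F weighted by true class support — under
which weighted recall equals accuracy exactly, a tested identity —
while `positive_class` gives the textbook positive-class formulas.

AUC is trapezoidal integration over the ROC step curve, which equals the
Mann–Whitney probability with ties counted ½ (a tested equivalence, and
cross-checked against pROC). Whether a reported AUC used probability
scores or hard labels is often unclear in practice — a label-based ROC
has a single interior vertex and gives values near 0.5 even for accurate
classifiers — so `evaluate_model(auc_mode =)` supports both;
`"probability"` is the default.

The evaluation model everywhere is a seeded random forest (ranger, 100
trees by default, single-threaded): majority vote for labels, mean leaf
probability for scores. The forest is the field's default for this
cohort type and is the model the selected subsets are ultimately used
with.

## Wrapper searches

`cv_score()` evaluates a subset by stratified k-fold cross-validated
accuracy. Folds are a deterministic function of (outcome, fold count,
seed) — every subset a search examines is scored on identical folds, so
subset comparisons are paired. The default is `cv_folds = 10`;
the per-step statistics reported alongside published traces of this
pipeline, however, satisfy `std_err = std_dev/sqrt(3)` and
`ci_bound/std_err = t(0.975, df = 4)`, which is the arithmetic of 4
folds, so 4-fold configurations are first-class and the trace records
the fold count used. Step statistics follow exactly that arithmetic:
`std_dev` is the population SD of the fold scores, `std_err` is
`std_dev/sqrt(m - 1)` (the sample SD over `sqrt(m)`), and `ci_bound` is
`std_err` times the two-sided 95% t quantile with df equal to the fold
count.

SFS grows from the empty set, adding the candidate with the best CV
score; SBS shrinks from the full pool. All ties break toward the lowest
feature index, making every trace deterministic. The floating variants
perform counter-moves (an exclusion after each inclusion, and vice
versa) for as long as the move *strictly* improves the best score
recorded at the size it lands on; the strict-improvement bookkeeping
guarantees termination, and the returned subset is the best of size
`target_k` seen anywhere — hence floating results never score below
their plain greedy counterparts at equal size (a tested invariant, along
with agreement of every greedy step with exhaustive enumeration on small
pools). Random search draws subsets of uniform random size and keeps the
argmax; with enough iterations on a small pool it provably reaches the
global optimum, which the tests exercise by full enumeration. All
searches share a memoised scorer, so floating revisits cost nothing.

## The synthetic cohort generator

No patient-level data is distributed, so `generate_cohort()` provides
the benchmark substrate. It draws the outcome first (Bernoulli at the
configured prevalence, default 0.317) and features conditional on class,
which makes the planted standardized mean differences hold by
construction. The seven informative predictors follow clinically
plausible marginals — female age normal around 30.9 years, FSH dose
normal around 11.5 mIU/ml, and nonnegative integer counts (Poisson) for
oocytes, embryo-cell counts, embryo grade and prior failed cycles — with
default |d| between 0.4 and 0.8, the moderate range typical of these
predictors. All effects are planted negative (the successful class has
the lower mean), matching the direction consistently reported for age,
FSH dose and prior failures. Noise features are independent standard
normals, optionally equicorrelated.

What the generator does *not* emulate: correlations among informative
predictors (oocyte and embryo counts are strongly dependent in real
cycles), center effects and repeated cycles per couple, missingness
patterns, and mixed continuous/categorical noise. Passing tests
therefore demonstrate that the pipeline recovers planted independent
signal at realistic effect sizes and prevalence — not that it handles
confounded or clustered clinical data. One consequence surfaces in
testing already: discrete low-rate counts offer fewer split points than
continuous noise, so Gini importance — which favours many-valued
features — can rank weak count predictors below continuous noise,
shrinking the tree-based pool. That is faithful impurity-importance
behaviour, not a generator artifact.

## Numerical and design choices

* The deviation degree is computed as an explicit ordered-pair sum
  (`outer`), not the expanded closed form `l·Σγ² − (Σγ)²`, which
  cancels catastrophically for near-equal criteria — exactly the regime
  the scoring system cares about.
* Variances use the population (ddof = 0) form throughout (variance
  threshold, fold-score SD), matching the conventions of the tooling
  this pipeline is usually compared against. The variance threshold
  applies to *raw* features; standardized features all have variance 1,
  which would make any threshold below 1 vacuous.
* Standardization and median imputation are fitted on training rows only
  and applied to all rows; a poisoned-sentinel test asserts no test-row
  statistic leaks into them.
* The L1 selector parameterises the penalty as an inverse strength C
  with lasso weight 1/(nC), so larger C means weaker regularization; it
  sees standardized inputs inside `run_filter_stage()`.
* Seeds: every stochastic component (split, forests, folds, random
  search, generator) takes an explicit seed; `hybrid_select(seed =)`
  derives sub-seeds by small offsets unless explicit control objects are
  given.

## Problem sizes used by the test suite

The acceptance-style checks run at sizes chosen to make each property
statistically meaningful: planted-feature recovery uses the default
cohort (n = 1000, p = 38) over 20 seeds with 4-fold CV and 100-tree
forests; search-vs-enumeration oracles use 10 random tables with p = 5,
k = 3; the permuted-label null control uses n = 2000 cohorts with a 30%
test split, because the null MCC's sampling sd scales as one over the
square root of the test-set size and a 600-row test set keeps it well
inside the ±0.1 acceptance band — on a 120-row test set the same check
would measure sampling noise, not the pipeline.

## Limitations

The pipeline inherits the weaknesses of its parts: greedy searches can
miss interaction-only features unless floating steps rescue them; HFS
scoring rewards consistency, which can prefer a uniformly mediocre
method over an unevenly excellent one (that is its stated intent, but
worth knowing); and impurity importance is biased toward many-valued
features. Runtime is dominated by wrapper-stage forest fits —
approximately pool size × target_k × folds fits — so large pools with
10-fold CV are expensive; the memoised scorer and pre-selection are the
mitigations.
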