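---
title: "Variable-interaction subset selection for MLR QSAR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable-interaction subset selection for MLR QSAR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsmvi)
```

## The problem

A QSAR study starts from an activity measured on a few dozen compounds —
here the motivating case is logRBA, the log10 relative binding affinity of
candidate endocrine disruptors to the estrogen receptor — and a very wide
table of computed molecular descriptors (constitutional, topological,
WHIM, GETAWAY, 3D-MoRSE, ...; thousands of columns from a generator such
as E-Dragon). The modelling goal is a *small* multiple linear regression,

$$ y = b_0 + \sum_{j \in S} b_j x_j + \varepsilon, \qquad |S| \ll m, $$

because a compact MLR is unambiguous, interpretable and easy for others to
apply — properties that regulatory acceptability frameworks (OECD QSAR
principles) ask for explicitly. The hard part is choosing the subset $S$:
with $m$ descriptors there are $2^m - 1$ candidate subsets, and even a
fixed-size scan costs $\binom{m}{k}$ model evaluations
(`count_asr_combinations(53, 5)` = 2,869,685).

## Descriptor preselection

Raw descriptor tables carry columns that can only hurt a subset search:
numerically constant columns, near-duplicates computed under slightly
different theories, and sparse counts that are zero for almost every
compound. `preprocess_descriptors()` applies three filters, in this
order:

1. **near-constant**: sample SD < 1e-5 (strictly below — a column exactly
   at the threshold survives);
2. **inter-correlated**: scanning pairs (j, k > j) in column order, the
   *later* column of any pair with |Pearson R| ≥ 0.95 is dropped. "Either
   of them" could be deleted in principle; dropping the later column is a
   deterministic, auditable choice, and the filter report records every
   (kept, removed, |R|) triple. Because the scan is greedy, the surviving
   set depends on column order; the order is fixed, so results are
   reproducible.
3. **zero-inflated**: columns whose fraction of *exact* zeros (no epsilon
   — descriptor files encode true zeros) is ≥ 0.90.

The boundary semantics ("≥" for correlation and zeros, strict "<" for SD)
follow from reading each rule as naming the excluded set by its property.
The input table is never modified, so removed descriptors are recoverable
at any time, and re-running the pipeline on its own output removes nothing
(idempotence, covered by tests). Running (3) before (2) could change the
outcome; the enumerated order above is canonical here.

## The search

VSMVI rests on one empirical observation: a descriptor only weakly
correlated with the response can still carry decisive information *in
combination* — variable interaction. So a good $k$-subset is, almost
always, a one-variable extension of a good $(k-1)$-subset, and it suffices
to retain a sizeable pool of good subsets per size instead of enumerating
everything:

* **sizes 1..Na** (`Na` default 3): exhaustive scan in lexicographic
  order, each size filling its own fixed-capacity pool of the best `Ns`
  (default 1000) subsets ranked by the stop criterion SC;
* **sizes Na+1..min(vm, ⌊n/5⌋)**: every pool subset of the previous size
  is combined with every descriptor not in it (at most `Ns × m`
  candidates — `count_vsmvi_combinations(53, 1000)` = 53,000, versus
  2,869,685 for the exhaustive scan), deduplicated by sorted index set,
  and offered to a fresh pool. When the pool is full, a candidate enters
  only by displacing the current minimum SC (SC_min), which is then
  updated.

The size cap ⌊n/5⌋ enforces the usual five-compounds-per-descriptor rule
of thumb; `vm` (default 15) caps it absolutely.

Two gates precede the expensive scoring of a candidate:

* **r_int** (default 0.9): if any pairwise |correlation| inside the
  candidate is ≥ r_int, the candidate is skipped before any model is
  fitted. This both avoids redundant models and keeps the final
  coefficient estimates away from collinearity.
* **r_cri**: if the training r² is below a size-dependent floor, the
  cross-validation step — the dominant cost — is skipped. The floor
  starts at 0.1 for one variable and must grow with size; the schedule
  here is $r_{cri}(k) = \min(0.8,\; 0.1k)$, capped so that no size can
  gate out every candidate. A user-supplied vector or function replaces
  it via `vsmvi_config(r_cri = ...)`. Equality passes the gate (the skip
  rule is "r² smaller than the floor").

**The stop criterion.** SC is the mean q² of leave-multiple-out
Monte-Carlo cross-validation (LMOCV): `cv_N` (default 100) random
two-fold splits; on each, the model is refitted on the construction half
and scored on the validation half. An RMSEV flavour (`sc_kind =
"rmsev"`, pool keeps the smallest) is provided through the same
comparator abstraction. Crucially, *one split plan is shared by every
candidate of a run*: subset comparison is then paired, so Monte-Carlo
noise cancels out of the ranking and the search is fully deterministic
given the plan. The seed in `vsmvi_config` governs only that plan.

**Tie-breaking and pool law.** Exact SC ties go to the lexicographically
smaller index set, making results platform-independent. After any
insertion sequence the pool holds exactly the top-min(Ns, #scored)
records under this total order (tested against brute-force rankings).
Enlarging Ns can never lower the best SC found at any size.

**Exactness.** When `Ns ≥ C(m, k-1)` the parent pool holds *every*
gate-passing subset, and the extension stage is provably equivalent to
exhaustive enumeration at size k — except for the measure-zero case of a
subset all of whose sub-subsets fail the r² gate (a pure suppressor
combination), which is unreachable by construction in any
forward-building search of this family. The test suite verifies
index-exact agreement with an independently coded all-subsets scan on 20
seeded fixtures at sizes 2–4.

## Model size

The per-size best SC traces a rising, flattening curve.
`select_model_size()` picks the smallest size whose relative gain going
one size up falls below 5% (configurable); a non-positive gain stops
immediately. This prefers the parsimonious model once extra descriptors
stop paying for themselves, in line with the cross-validation rationale
above.

## Cross-validation statistics

For a split $i$ with validation set $V_i$:
$q^2_i = 1 - \sum_{V_i}(y - \hat y)^2 / \sum_{V_i}(y - \bar y_{V_i})^2$
(the reference mean is the validation set's own) and
$RMSEV_i = \sqrt{\sum_{V_i}(y-\hat y)^2 / n_v}$. `lmocv()` reports the
means and standard deviations of both across splits — the means estimate
predictive performance, the SDs robustness. Design choices worth stating:

* **split sizes**: validation gets ⌊fraction·n⌋ compounds, so for
  two-fold CV of odd n the construction half receives the extra compound,
  keeping fits well-posed (n = 53 → 27/26).
* **RMSE denominator is n**, not a residual degree of freedom, so
  training RMSE and RMSEV are on the same scale across fold sizes.
* **LOOCV** has singleton validation sets, so per-split q² is undefined;
  `loocv()` therefore pools the predicted residuals
  ($q^2 = 1 - PRESS/SS_{tot}$, $RMSEV = \sqrt{PRESS/n}$) and computes
  them by the hat-matrix closed form $e_i/(1-h_{ii})$ — no refit loop.
  `lmocv()` given an all-singletons plan detects the situation, pools the
  same way, and says so. The two routes agree to 1e-10 in tests.
* failed folds (singular construction design) are tolerated up to 10% of
  the plan and reported; beyond that the summary errors out.
* **external q²** uses the test-set mean in its denominator; a
  training-mean variant is exported separately
  (`external_q2_train_mean()`) but is not the default. Predictions for
  external compounds apply the model verbatim, with no re-centering.

## Chance correlation

`y_randomization()` permutes the response (sampling without replacement —
scrambling, not parametric resampling) `runs` times (default 1000, the
usual precision for the probability statement), refits the *fixed* subset
and records training r² and mean LMOCV q² under the same split plan as
the real model, so the comparison is like-for-like. For a real
relationship the scrambled q² values fall almost entirely below zero. The
distance-from-chance statistic is Roy's
$^c r^2_p = r\sqrt{r^2 - \bar r^2_r}$; a mean scrambled r² exceeding the
model's r² is an error, never clipped. One caveat is documented rather
than hidden: randomizing after selection tests the *model*, not the
selection procedure; `reselect = TRUE` reruns the whole search per
permutation for the stricter (and far costlier) selection-level test.

Under permutation the expected scrambled r² of a p-descriptor fit is
exactly $p/(n-1)$ — with an intercept the total SS is
permutation-invariant and the numerator averages to $p\,SS_{tot}/(n-1)$
by exchangeability — which the test suite uses as a closed-form oracle
(p = 5, n = 50: 0.102).

## Applicability domain

The leverage of a query compound against the training design (intercept
included) is $h = x(X'X)^{-1}x'$; training leverages sum to k, the number
of model parameters *including* the constant term. The control value is
$h^* = 3k/n$ (for a five-descriptor model of 53 compounds, 3·6/53 ≈
0.34): beyond it a prediction is substantial extrapolation and the
compound is an **X outlier**. Response misfits are judged by standardized
residuals — centred residuals over their population SD, so a symmetric
±c pattern maps exactly to ±1 — with the conventional 2.5-SD cut
defining **Y outliers**; external compounds are standardized by the
*training* centre and scale, because the training error scale is the
yardstick. `williams_classify()` pools training and test compounds under
one h*, labels each with its set, and emits the (h, standardized
residual) pairs that `plot()` renders as a Williams plot. The studentized
(leverage-adjusted) variant is deliberately not the default: the
2.5-"standard-deviation-unit" rule is an internal scaling, and the plain
form keeps the threshold meaning transparent.

## Synthetic fixtures

`generate_qsar_dataset()` emulates the *shape* of a descriptor-table
study: standard-normal decoy columns, a sparse linear signal with
Gaussian noise, and on request redundant columns (correlated at a chosen
ρ with planted ones), exactly constant columns and zero-inflated columns
for the preselection filters to find. Ground truth travels with the data.
`paper_shaped_fixture()` instantiates the geometry of a small
estrogen-receptor study — 53 training and 16 external compounds, 120
columns (a width chosen so test runs stay fast), five planted descriptors
whose coefficient pattern (−0.63, −0.52, −0.37, −0.58, +0.79) echoes the
standardized coefficients of a published five-descriptor logRBA model.
The default recovery fixture (n = 60, m = 40, four planted descriptors
with coefficients 1.5, −1.2, 1.0, 0.8, noise SD 0.3) gives a
signal-to-noise ratio at which an honest search should essentially always
succeed, so recovery failures indicate algorithmic defects rather than
statistical bad luck.

What the fixtures do *not* emulate: real Dragon descriptor marginals
(heavy tails, discreteness, block correlation across descriptor
families), measurement error in the activity, or class structure among
compounds. Passing recovery tests therefore demonstrates correctness of
the machinery, not expected performance on any particular chemical
dataset.

## Numerical choices

* OLS fits in the R layer go through QR (`qr()`/`lm.fit`); designs that
  are rank-deficient, or whose triangular factor has a reciprocal
  condition below 1e-10, are rejected with the offending columns named —
  descriptor tables are near-collinear by nature and silently unstable
  coefficients are worse than an error.
* The compiled search core scores candidates on the normal equations: the
  full-width Gram matrix of [1 X] is computed once, each split's
  construction Gram once per plan (validation rows subtracted), and every
  candidate solves a (p+1)-dimensional Cholesky system gathered from
  those precomputed blocks. A pivot below 1e-12 of the largest diagonal
  marks the fold singular. The R and C++ routes agree to better than
  1e-10 in the tests, and the search-reported SC is bit-identical to
  `lmocv()` on the winning subset.
* All RNG consumption is seeded and isolated (`with_seed`), so plans,
  fixtures and permutations never perturb the caller's RNG stream; the
  pipeline fans one global seed out to per-stage seeds deterministically.
* Reports serialize numbers at full precision (no rounding), making
  write/read a true identity and byte-identical reruns checkable.

## Problem sizes used in the test suite

Module tests run on 18–60 compounds and 4–40 descriptors with 15–50 CV
splits; the exhaustive-equivalence suite uses 20 fixtures at m = 10,
sizes 2–4, 30 shared splits; recovery uses 100 seeded n = 60, m = 40
runs; randomization suites use 1000 permutations. These sizes were chosen
as the smallest at which each property is sharply testable.

## Known limitations

* The interaction heuristic is exact only with an unbounded pool; with
  finite Ns it is a beam search, and a true subset whose every
  sub-subset scores badly can be missed. Raising Ns monotonically
  improves the attainable SC.
* Greedy correlation filtering keeps the earlier column of a redundant
  pair, which is an ordering convention, not an optimality claim.
* Plain MLR only, by design: no PLS, regularization or robust loss. For
  m ≫ n the preselection filters and gates are what keep the search
  honest; they do not make MLR itself suitable for dense
  high-dimensional signals.
* The model-level y-randomization does not account for selection bias;
  use `reselect = TRUE` when that question matters and the budget allows.
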