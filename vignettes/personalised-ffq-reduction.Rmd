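---
title: "Personalised reduction of a food frequency questionnaire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalised reduction of a food frequency questionnaire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A grid-style Food Frequency Questionnaire (FFQ) for the Mediterranean diet
asks about the daily consumption of 24 food items and scores 11 nutrition
goals (fruit & vegetables, carbohydrates, proteins, milk, oil, water, dried
fruit, processed meats, sweets/snacks, sweet drinks, sugar) on a
portions-per-day scale. Even 24 image buttons crowd a phone screen, so the
question is: which $n \in \{4, 6, 9, 12\}$ questions (the 2×2, 3×2, 3×3 and
4×3 grid layouts) should be shown, such that the quality scores of the goals
a user has activated can still be predicted well from the answers?

`ffqreduce` treats this as a multi-target regression problem — one linear
model predicting all activated goal scores simultaneously from the shown
questions — and compares three ways of picking the question subset:

1. **random** — a uniform draw of $n$ questions (baseline);
2. **static** — the $n$ questions with the highest cross-validated feature
   importance, treating all activated goals as equally important;
3. **personalised** — a two-step scheme in which predicted threshold
   violations become per-goal weights that re-scale the targets before the
   importance is recomputed, emphasising the goals the user is failing.

## Model and procedure

### Scores, scaling and split

The quality score of goal $g$ for a user is the unweighted sum of the
portions-per-day answers of the questions mapped to $g$. A sum (rather than
a mean or a scaled index) keeps the scores in portions per day, the unit in
which both thresholds and prediction errors are stated. The mapping,
thresholds and threshold directions are configuration shipped as an editable
JSON schema (`default_schema()`); they are sensible Mediterranean-diet
defaults, not measured reference values.

Features (answers) and targets (scores) are both min–max scaled,

$$x' = \frac{x - \min(x)}{\max(x) - \min(x)},$$

per column. Rows are split 3:1 into train and test by a seeded permutation.
Scaling parameters are fitted on the training rows only, so nothing about
the test set leaks into the transform; fitting on all rows is available via
`scaling_scope = "all"` for pipelines that scale before splitting. Test
values are transformed with the training parameters and may legitimately
fall outside $[0, 1]$; they are not clipped. A constant column has
$\max(x) = \min(x)$, where the formula divides by zero; such degenerate
columns map to 0 (and invert back to their constant), which keeps the
pipeline total — a constant feature carries no information, and a zero
column receives a zero coefficient in the minimum-norm fit below.

### Multi-target regression and importance

The prediction model is ordinary least squares per target — a deliberately
simple choice: the scores are sums of (subsets of) the features, so the
relationship really is linear, and flexible learners gain nothing here but
variance. `fit_mtr()` solves the joint system with a QR decomposition and
falls back to the minimum-norm pseudo-inverse solution for rank-deficient
designs rather than failing.

Feature importance is computed by 5-fold cross-validation on the training
set: folds are contiguous blocks of a seeded permutation; on each fold's
training part the model is fitted on **all 24** features and the importance
of question $j$ is the mean over targets of $|\beta_{tj}|$; the final
importance is the mean over folds. Absolute coefficients are comparable
across features because the features share the $[0,1]$ min–max scale. The
ranking is descending by importance with ties broken by schema question
order — a fixed, documented order that makes every run reproducible.
Importance functions are a seam in the design: the ranking object is plain
data (`question_id, importance, rank`), so an alternative scorer (e.g.
univariate correlations) can be swapped in without touching selection.

### The personalised step

Let $y_{\mathrm{pred}}$ be the vector of predicted activated-goal scores,
$y_{\mathrm{opt}}$ the thresholds mapped into the scaled target space, and
$y_{\mathrm{adj}}$ the per-goal sign: $+1$ for *at most* goals, $-1$ for
*at least* goals. The threshold distance is

$$\mathrm{dist}(y_{\mathrm{pred}}, y_{\mathrm{opt}}) =
  \max\bigl((y_{\mathrm{pred}} - y_{\mathrm{opt}}) \cdot y_{\mathrm{adj}},\ 0\bigr),$$

positive exactly when a goal is violated. Distances are scaled to $[0,1]$
by dividing by the largest distance and used as target weights. Two
numerical choices matter here:

* **Divide-by-max, not min–max.** Min–max rescaling would force the
  least-violated activated goal to weight 0, deleting it from the
  regression entirely. The intent is to *de-emphasise*, not erase, the
  goals the user is doing well on — their predictions should degrade
  gracefully, not vanish. The alternative reading is available as
  `weight_scaling = "minmax"`.
* **A weight floor** $\varepsilon = 0.05$ (configurable) bounds every
  weight away from zero for the same reason: a zero target column has
  meaningless coefficients and a meaningless error.

If no activated goal is violated, all weights fall back to 1 and the
personalised selection reduces — exactly, not approximately — to the static
one. The same happens with a single activated goal (its weight is 1 by
construction), so personalisation only matters when at least two goals are
activated; the standard experiments therefore use activated sets of size
≥ 2.

The full personalised pipeline (`personalised_selection()`) is: static
ranking → top-$n$ subset → fit → predict on the held-out rows → mean
predicted score per goal → distances → weights → re-scale the *training*
targets → recompute the ranking → reselect top-$n$. Because each target is
fitted independently, re-scaling a target by a scalar changes its
coefficients proportionally but not its predictions after unscaling — the
entire personalisation effect flows through the *selection*: violated
goals' large weighted coefficients pull their questions up the ranking.
The final model in every arm is refitted on the unweighted training targets
restricted to the selected subset, so arms differ only in which questions
they show.

Weights are computed from the mean predicted score of the evaluation rows
(*population mode*), which is what a cohort-level experiment measures. For
the app use-case — one user answering repeatedly — *user mode*
(`weight_mode = "user"`) computes weights from a single user's predicted
scores instead.

## The synthetic population

Real FFQ response data of this kind is typically not redistributable, so the
package ships a generator (`simulate_responses()`) that emulates the
features of such data that make the selection problem non-trivial:

* **Non-negative portions/day answers** — multivariate normal draws
  truncated at zero. Truncation (not resampling) is simple and monotone; it
  biases low-mean questions slightly upward, negligibly so at the default
  coefficient of variation of 0.3.
* **Within-food-group correlation** — questions in a block (carbohydrates;
  sweets; fruit/vegetables) share a common correlation $\rho$
  (0.6, 0.5, 0.5 by default). Correlated questions are partially redundant,
  which is precisely what makes "which questions to keep" an interesting
  question.
* **Heterogeneous goal attainment** — a three-profile mixture
  (`default_population()`): *prudent* (40%) satisfies every default
  threshold with slack; *sweet-tooth* (30%) over-reaches sugar,
  sweets/snacks and sweet drinks while falling short on fruit & vegetables
  and water; *low-veg* (30%) violates most at-least goals and over-reaches
  carbohydrates. Different users fail different goals, which is what gives
  the personalised arm signal to exploit.

What the generator does **not** emulate: real marginal distributions
(zero-inflation, heaping on integer portions), within-user longitudinal
correlation, and any demographic structure. Passing experiments on this
population therefore demonstrate that the machinery behaves as designed —
they are not evidence about any particular real cohort. One
`population_spec` seed drives a dedicated RNG scope; changing `n_users`
re-draws the whole matrix (no prefix property).

## Reproducibility and seed discipline

A single master seed drives each experiment cell. Sub-seeds for the
generator, the 3:1 split, the CV folds and the random-arm draw are derived
deterministically (`derive_seed()`), so the three arms always see identical
splits and folds, and the random arm's subset varies with the feature count
but not with the activated-goal set. Identical configurations reproduce
sweep results exactly.

## Experiment scale

The default sweep samples 60 activated-goal combinations stratified by size
(out of $2^{11} - 1 - 11 = 2036$ combinations with at least two of the 11
goals activated), runs 3 arms × 4 subset sizes × 10 seeds at 1000 users,
and takes on the order of a minute on a single core; `--full-sweep` in the
CLI runs all 2036 combinations. With roughly six combinations per size, the
aggregate error-versus-activated-goals curve is smooth enough to be
monotone; much smaller stratified samples (two combinations per size) leave
the per-size means dominated by which goals happen to be drawn, and the
curve can wobble by a few hundredths of a portion per day even though the
underlying trend is clear. The package's tests use 1000-user populations
and 10–20 seeds for the end-to-end properties, and smaller matrices for
unit-level checks.

## Known limitations

* Several goals depend on a single question, so their prediction is trivial
  once that question is selected and impossible to improve otherwise; the
  headroom for clever selection on this questionnaire is bounded.
* Thresholds and the question→goal mapping are editable defaults, not
  clinically validated values; conclusions about specific goals should not
  be read off the default schema.
* Population-mode weights personalise to the evaluated cohort, not to an
  individual; user mode exists but is only as good as the single user's
  prediction.
* The linear model is the right tool for sum-scores; questionnaires whose
  targets relate nonlinearly to items would need a different model behind
  the same interfaces.

## A worked run

```{r example}
library(ffqreduce)

schema <- default_schema()
responses <- simulate_responses(default_population(1000, seed = 42), schema)
prep <- prepare_experiment_data(responses, schema, seed = 1)

active <- c("sugar", "water", "fruit_vegetables")
static <- run_arm("static", 4, active, prep, seed = 1)
pers <- run_arm("personalised", 4, active, prep, seed = 1)

pers$weights   # 1 for the most violated goal, epsilon-floored otherwise
pers$subset    # the four questions the personalised arm would show
```
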