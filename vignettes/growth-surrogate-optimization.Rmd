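---
title: "Surrogate modelling and evolutionary optimization of in vitro growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate modelling and evolutionary optimization of in vitro growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cultivopt)
```

## The modelling problem

A micropropagation experiment measured five growth traits of *Cannabis
sativa* plantlets — shoot length (mm), root length (mm), node number,
shoot number, canopy surface area (mm²) — after six weeks of culture under
66 treatments: 22 light-spectrum combinations of blue, red, white and
far-red LED channels (each 0–100 μmol·m⁻²·s⁻¹) crossed with 1, 3 or 6 %
(w/v) sucrose, four plantlets per treatment (264 plantlets). The package
treats each trait as an unknown smooth response surface over the 5-D box
$[0,100]^4 \times [1,6]$ and follows a three-stage workflow:

1. **Surrogate fitting** — approximate the response surface from the
   observed treatments with one of three model families, compared by
   repeated cross-validation;
2. **Sensitivity analysis** — rank the five inputs by the variable
   sensitivity ratio (VSR) of the fitted surrogate;
3. **Optimization** — maximize the fitted surrogate over the box with four
   independent evolutionary algorithms, whose agreement is itself a
   robustness check.

Only the 66 treatment means (± SE, n = 4) are published; the individual
plantlet values are not. All default analyses therefore operate on the 66
means. Where the plantlet level matters (see *Sensitivity* below),
`pseudo_replicates()` reconstructs per-plantlet values consistent with the
recorded mean, SE and replicate count.

## Preprocessing

**Target normalization.** Growth traits are non-negative and
right-skewed, with SEs that grow with the means. Each target is Box-Cox
transformed before fitting, with λ chosen by profile maximum likelihood
on [−2, 2] (`boxcox_fit()`; checked in the tests against the profile
computed by `MASS::boxcox`). Root length contains exact zeros (treatments
in which no roots emerged), so a shift of half the smallest positive
value of the column is added first — a scale-aware constant that keeps
the transform defined without distorting the bulk of the data.

**Input scaling.** Inputs are designed factor levels, not skewed
observations, so they are not power-transformed; they are min–max scaled
to [0, 1] so that kernel distances (GRNN) and membership widths (ANFIS)
are comparable across channels with different ranges.

**Back-transform guard.** For λ < 0 the Box-Cox image is bounded above
and its inverse explodes near the boundary; an unconstrained network
prediction slightly past the boundary would back-transform to an
astronomical length. `predict()` therefore clamps transformed-scale
predictions to the training-target range padded by 10 % (and strictly
inside the image) before inverting. This is an explicit extrapolation
limit: the surrogates are trusted only slightly beyond the observed
response range. GRNN predictions are never affected (they are convex
combinations of training values); it matters only for MLP/ANFIS
predictions on extrapolated queries.

**Outlier screen.** `pca_outlier_flags()` standardizes the design,
projects onto the principal components covering ≥ 95 % of variance, and
flags score distances more than 3 SD above the mean. The rule is
deliberately permissive; on the packaged balanced design it flags
nothing, and the tests verify that a row planted at 10× scale is caught.

**Cross-validation.** `make_folds()` builds shuffled, near-equal-size
k-fold plans repeated r times (default 5 × 10 = 50 train/test pairs),
bit-reproducible from the seed. `evaluate_cv()` refits the input scaler
and target transform inside each training fold, so no information leaks
into test scores.

## The three surrogate families

**GRNN** (`fit_grnn`) is Nadaraya–Watson kernel regression: the model
stores the scaled training inputs and transformed targets and predicts
$$\hat y(x) = \frac{\sum_i y_i \exp(-D_i^2/2\sigma^2)}
                   {\sum_i \exp(-D_i^2/2\sigma^2)},
  \qquad D_i^2 = \lVert x - x_i \rVert^2 .$$
Every prediction is a convex combination of training targets, so the
fitted surface can never exceed the best observed value — a bound the
tests exploit. As σ → 0 the model interpolates; as σ → ∞ it predicts the
global mean. The study does not state its σ, so `select_sigma()` picks it
from a 20-point log-spaced grid on [0.02, 2] (scaled-input distance
units) by minimum CV RMSE, ties toward the smaller width. Numerical note:
kernel weights are computed after subtracting the row-maximum exponent,
which keeps tiny-σ predictions finite and yields the nearest-neighbour
limit exactly.

**MLP** (`fit_mlp`) is a single-hidden-layer perceptron with tanh hidden
units and a linear output, trained by Levenberg–Marquardt on
sum-of-squares loss: each step solves $(J^\top J + \mu I)\,\delta =
J^\top r$ with μ × 10 on a rejected step and ÷ 10 on an accepted one
(initial 10⁻³), stopping at `max_iter` (default 200), a gradient norm
below 10⁻⁸, or damping saturation (μ > 10¹⁰). Targets are z-standardized
internally so the damping scale is problem-independent, and weight
initialization is seeded: the same seed reproduces the same weights
bit-exactly. The hidden size is chosen by CV over a small candidate set
(default 2, 4, 8, 12, within 1–20) — an exhaustive sweep adds little at
n = 66 and the selection criterion (mean CV test R²) is what matters.

**ANFIS** (`fit_anfis`) is a first-order Takagi–Sugeno system on a grid
partition: each input carries 3–5 Gaussian membership functions
$\mu(x) = \exp[-((x-c)/a)^2]$ (this width convention, without the factor
2 in the denominator, is implemented exactly; the conventional form is
available behind `conventional_mf = TRUE`), one rule per combination of
memberships, normalized firing strengths, and a linear consequent per
rule. Hybrid learning alternates (default 10 epochs) ridge-regularized
least squares for the consequents with a numeric-gradient descent step on
the premise (c, a) parameters. Two consequences of the architecture
deserve emphasis:

- With 5 inputs and 3 MFs each there are 3⁵ = 243 rules and
  243 × 6 = 1458 consequent parameters against 66 observations: the
  printed architecture is unidentifiable at this sample size. The
  consequent solve uses the dual (kernel) form of ridge regression when
  parameters exceed observations, and `rule_cap` (default 500) refuses
  configurations that would explode further, with an error advising fewer
  membership functions. This under-determination is the likely reason the
  ANFIS family cross-validates far worse than GRNN on this dataset — a
  property the acceptance tests assert rather than hide.
- The ridge penalty defaults to 10⁻⁶, the effective regularization of the
  standard recursive-least-squares initialization with a large initial
  covariance. A heavier penalty (say 10⁻³) visibly biases even noiseless
  representable targets, which would defeat the structural test that a
  linear target is recovered to RMSE < 10⁻³.

**Performance indices.** `compute_metrics()` reports the conventional
coefficient of determination R² = 1 − SSE/SST, RMSE, and the mean bias
error MBE = mean(ŷ − y) (positive = overprediction; the sign convention
is fixed here because the source descriptions of prediction and
observation are interchangeable). A constant observed vector leaves R²
undefined: the function returns `NA` with a warning rather than failing,
because RMSE and MBE remain meaningful.

## Sensitivity analysis

The VSR of input j is VSE(j)/RMSE_full, where VSE(j) is the RMSE of the
model after input j is "removed". Removal is not further specified in the
source literature; the package default is **mean-substitution without
refitting** (replace column j by its training mean), which is
model-family agnostic; refitting without the column is available behind
`refit = TRUE`. A model that ignores input j has VSR(j) = 1 exactly, and
ranking is by descending VSR with ties broken in the fixed input order.
For near-interpolating models the resubstitution RMSE_full approaches
zero and the ratio degenerates; `rank_inputs()` therefore uses a
cross-validated RMSE denominator by default. The denominator is shared
across inputs, so this choice rescales the VSRs but cannot change the
ranking.

**Replicate-level ranking.** Fitted to the 66 treatment means, the
CV-selected GRNN is heavily smoothed and its VSRs cluster near 1: the
ranking among the four light channels is then essentially noise, and
sucrose does not reliably surface as rank 1 for every trait. The models
of interest, however, were developed on the 264 individual plantlets.
`replicate_sensitivity()` reconstructs plantlet-level datasets with
`pseudo_replicates()` (truncated-normal draws consistent with each
recorded mean, SE and n), fits a GRNN per trait at a CV-selected width,
and averages the VSRs over five independent reconstructions to suppress
the Monte-Carlo noise of any single draw. Under this replicate-level
analysis sucrose attains rank 1 for all five traits, stably across
unrelated base seeds — consistent with the mixotrophic physiology of
sealed culture vessels, where CO₂ depletion makes supplemental carbon the
binding factor.

## The four optimizers

All four algorithms share one contract: maximize a (vectorized) objective
over box bounds, seeded initial population uniform in the box, every
candidate clipped to the bounds after every move, incumbent best tracked
elitistically so the reported convergence history is non-decreasing, and
a fixed generation budget as the only stopping rule. Defaults mirror the
study configuration: population 200, 1000 generations; `test_profile()`
(population 50, 200 generations) is used in the test suite to keep runs
fast.

- **GA** — roulette-wheel selection on shifted-positive fitness,
  two-point crossover on 60 % of pairs, uniform resampling mutation at
  0.05 per gene, elitism.
- **BBO** — habitats ranked by fitness; emigration rates μ form an
  arithmetic progression over [0, 1] with step 1/(population − 1) and
  λ = 1 − μ; per-variable immigration with probability λ, donor chosen by
  roulette on μ, blended migration SIVᵢ + α(SIVⱼ − SIVᵢ) with α = 1;
  Gaussian mutation (SD 0.1 × range) at rate 0.05. The migration update
  is printed in the source description with a plus sign inside the
  parenthesis, SIVᵢ + α(SIVⱼ **+** SIVᵢ); with α = 1 that doubles values
  and leaves the box immediately, and it matches no published variant of
  the algorithm, so the minus-sign blend is implemented, with the
  as-printed form kept behind `as_printed_migration = TRUE` for
  comparison.
- **ISA** — mirror threshold α rising linearly 0.1 → 0.9 over the run;
  the fittest element random-walks with scale 0.01 (UB − LB); other
  elements reflect through a random mirror placed between themselves and
  the fittest (r₁ ≤ α) or resample uniformly in the box; greedy
  acceptance. The greedy rule is expressed through the problem's sense,
  so the minimization form of the update carries over to maximization
  with the inequality flipped.
- **SOS** — mutualism (mutual vector = pair average, benefit factors
  drawn from {1, 2}), commensalism, and parasitism (a copy of the
  organism with a random non-empty subset of dimensions resampled
  uniformly, replacing a random host only if strictly better); each phase
  greedily accepted. SOS has no operator parameters beyond the budget.

Two properties are worth noting. First, because the Box-Cox transform is
monotone, maximizing original-unit predictions and maximizing
transformed-scale predictions locate the same argmax; the package
optimizes in original units. Second, on the smooth GRNN surrogate of the
shoot-length means all four algorithms reach the same best value to
within ~10⁻⁴ relative spread at the default budgets — the agreement
property the acceptance suite asserts at the 0.1 % level — while their
best input vectors may differ along flat ridges of the fitted surface.

## The synthetic-data generator

`growth_surface()` builds ground-truth surfaces as
baseline + Σⱼ Aⱼ exp[−((xⱼ−cⱼ)/wⱼ)²] (+ optional weak pairwise product
interactions). With non-negative amplitudes the argmax is exactly the
center vector and the amplitudes are a known importance ordering, which
is what makes end-to-end recovery testable. Defaults emulate the packaged
experiment: centers in the central 60 % of each range, widths 0.4 ×
range, strictly decreasing amplitudes in a seed-shuffled input order,
baseline 30 (a typical small shoot length in mm), and replicate noise
CV = 0.4 — the median SE-implied replicate coefficient of variation of
the packaged dataset (CV = √n·SE/mean at n = 4). `simulate_growth()`
draws replicates from Normal(f(x), CV·f(x)) truncated at zero, which
reproduces the observed mean-proportional heteroscedasticity; truncation
induces a small positive bias that is negligible below CV ≈ 0.3 and is
accepted as the price of non-negativity. What the generator does **not**
emulate: trait-to-trait correlation within a plantlet, spatial/shelf
effects, the discreteness of count traits, or any mechanistic
photomorphogenesis — passing recovery tests therefore demonstrate that
the pipeline's code is correct, not that the biology is this simple.

**Recovery-test conditioning.** The experiment's own 22-spectrum design
is extremely sparse in 5-D (most points have two or more channels at
zero): fitted surrogates are accurate near the data but unconstrained in
the empty corners, and no model can localize an arbitrary interior
optimum from it — the best design point of a typical synthetic surface
reaches only ~70 % of the true maximum. The end-to-end recovery tests
therefore simulate from a 250-point Latin-hypercube design
(`lhs_design()`), with all five amplitudes substantial (150/95/80/65/50,
top clearly separated so the rank-1 recovery is identifiable) and
replicate noise CV = 0.05. Under these conditions the pipeline recovers
the planted rank-1 input and places every optimizer's argmax within a few
percent of box width of the truth; under the original sparse design it
cannot, and that negative result is itself informative about how much the
real experiment's optima should be trusted far from its design points.

## Pipeline and reporting

`run_pipeline()` executes, per trait: hyperparameter selection, CV
scoring of the configured families, selection of the family with the
highest mean CV test R² (ties by lower test RMSE — R² is the headline
index and RMSE the natural tie-breaker), refit on all data, VSR ranking
(CV RMSE denominator), and `optimize_all()` on the refitted surrogate
(the model refit on all data, not a CV fold, since a single optimum per
trait is wanted). Stage failures are recorded per trait without stopping
the others. `write_report()` writes the three result tables and the
convergence histories as CSV plus a JSON summary carrying every seed,
using write-to-temporary-then-rename so a failed write never leaves a
partial report; re-running the same configuration reproduces the files
byte-for-byte. The package's interface is its functions and this
document; no command-line wrapper is shipped.

## Problem sizes used by the tests

The shipped test-suite and acceptance script keep within a few minutes on
one core by using the reduced budgets described above: `test_profile()`
optimizer settings everywhere except the four-optimizer agreement check
(run at the full population 200 / 1000 generations), CV with 2–3 repeats
in the structural tests and the full 5 × 10 plan in the acceptance
checks, 250-point designs for recovery, and 5 pseudo-replicate draws for
the replicate-level sensitivity ensemble.

## Known limitations

- The treatment-mean dataset (n = 66) supports only coarse surrogate
  accuracy; cross-validated R² for shoot length is near zero at the
  treatment level, and the package's value on the real data lies in the
  relative family comparison, the importance ranking, and the
  optimizer-agreement structure rather than in absolute predictive skill.
- GRNN surfaces are flat far from data and pinned to the nearest training
  values in empty regions of a sparse design; optima located there should
  be read as "the best region the data can see", not as precise recipes.
- ANFIS at the printed architecture is over-parameterized for this sample
  size; its weak CV performance here is structural.
- The sensitivity ranking depends on the removal convention
  (mean-substitution vs refit); only the rank order, not VSR magnitudes,
  should be compared across implementations.
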