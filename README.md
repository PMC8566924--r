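# cultivopt

Surrogate modelling and evolutionary optimization of *in vitro* plant
growth responses to light spectrum and carbohydrate supply.

## The problem

Micropropagation outcomes depend jointly on light quality (blue, red,
white, far-red irradiance, each 0–100 μmol·m⁻²·s⁻¹), light intensity and
the sucrose concentration of the medium (1–6 % w/v) — a 5-dimensional,
non-linear design space that factorial experiments cannot cover
exhaustively. `cultivopt` implements the surrogate-assisted workflow used
to optimize *Cannabis sativa* tissue-culture conditions from a single
66-treatment experiment (22 light spectra × 3 sucrose levels, 4 replicate
plantlets each): fit a data-driven response-surface model per growth
trait, rank the inputs by importance, and maximize the fitted surface over
the design box with evolutionary algorithms.

It is intended for tissue-culture researchers and for anyone who wants a
tested, reusable R implementation of this model-then-optimize pattern.

## What is inside

**Data.** The packaged 66-treatment dataset (`growth_data()`): treatment
means ± SE of shoot length (mm), root length (mm), node number, shoot
number, and canopy surface area (mm²), with CSV read/write in wide and
long layouts, design-matrix extraction, and per-trait extremes.

**Surrogate families**, all behind one fit/predict contract
(`growth_surrogate` objects; inputs min–max scaled, targets Box-Cox
normalized, predictions returned in original units):

- `fit_grnn()` — generalized regression neural network, the
  Nadaraya–Watson kernel average
  ŷ(x) = Σᵢ yᵢ exp(−Dᵢ²/2σ²) / Σᵢ exp(−Dᵢ²/2σ²) with Dᵢ² = ‖x − xᵢ‖²;
  width σ selected by cross-validation (`select_sigma()`).
- `fit_mlp()` — single-hidden-layer perceptron, tanh hidden units, linear
  output, trained by Levenberg–Marquardt; hidden size by CV
  (`select_hidden_size()`).
- `fit_anfis()` — first-order Takagi–Sugeno neuro-fuzzy system on a grid
  partition with Gaussian memberships μ(x) = exp[−((x−c)/a)²], hybrid
  least-squares/gradient learning.

**Evaluation.** `compute_metrics()` (R², RMSE, MBE with
MBE = mean(ŷ − y)), `make_folds()` (repeated k-fold plans, default 5×10),
`evaluate_cv()` (leakage-free fold scoring), `pca_outlier_flags()`.

**Sensitivity.** `compute_vsr()` / `rank_inputs()`: the variable
sensitivity ratio VSR(j) = RMSE with input j mean-substituted ÷ full-model
RMSE; `replicate_sensitivity()` ranks inputs at the individual-plantlet
level via pseudo-replicate reconstruction.

**Optimizers.** Four bound-constrained single-objective metaheuristics
with a shared contract (`optim_problem()`, `optim_control()`,
`optimize_all()`): genetic algorithm (`optimize_ga`), biogeography-based
optimization (`optimize_bbo`), interior search (`optimize_isa`), and
symbiotic organisms search (`optimize_sos`). Defaults mirror the study
settings (population 200, 1000 generations, mutation rate 0.05, crossover
fraction 0.6, BBO α = 1, ISA mirror threshold 0.1→0.9).

**Synthetic ground truth.** `growth_surface()` builds seeded response
surfaces with analytically known argmax and importance ordering;
`simulate_growth()` draws replicate datasets with the experiment's
mean ± SE structure; `pseudo_replicates()` inverts recorded summaries into
plantlet-level draws; `lhs_design()` provides space-filling designs.

**Pipeline.** `run_pipeline()` chains everything per trait — family
comparison by CV test R², refit of the winner, VSR ranking, four-optimizer
maximization — and `write_report()`/`load_report()` persist the result
tables.

## Worked example

Fit the shoot-length surrogate and find the culture conditions that
maximize it:

```r
library(cultivopt)

d <- growth_data()
trait_extremes(d)[, 1:3]
#>          trait      max    min
#> 1 shoot_length   154.68  22.95
#> 2  root_length   477.10   0.00
#> 3  node_number    11.50   5.75
#> 4 shoot_number     3.00   1.00
#> 5  canopy_area 13061.97 493.01

tm    <- trait_matrix(d, "shoot_length")
plan  <- make_folds(66, k = 5, repeats = 10, seed = 101)
sigma <- as.numeric(select_sigma(tm$X, tm$y, plan, bounds = input_bounds()))
model <- fit_grnn(tm$X, tm$y, sigma = sigma, bounds = input_bounds(),
                  trait = "shoot_length")
model
#> Growth surrogate (grnn), 66 training points, 5 inputs, trait: shoot_length
#>   target Box-Cox: lambda = -0.2282  shift = 0
#>   sigma = 0.2877

optimize_sos(surrogate_problem(model), test_profile(seed = 42))
#> SOS maximization: best f = 86.7943
#>   at x = (0, 0, 41.822, 100, 3.3198)
#>   200 generations, 40050 objective evaluations, seed 42
```

Reading the output: the fitted kernel surface predicts the longest shoots
(86.8 mm on the smoothed surface — necessarily below the best single
observed treatment mean of 154.68 mm, since a GRNN prediction is a convex
combination of training values) at no blue, no red,
~42 μmol·m⁻²·s⁻¹ white, 100 μmol·m⁻²·s⁻¹ far-red and 3.3 % sucrose — a
low-PAR, far-red-rich, ~3 % sucrose recipe, the classic shade-avoidance
elongation signature. All four optimizers converge to best values within
a fraction of a percent of each other on this surface
(`optimize_all()` reports the spread).

## Documentation

The methods vignette (`vignettes/growth-surrogate-optimization.Rmd`)
describes the models, their assumptions, the tunable parameters, the
synthetic-data generator, and the numerical and design choices in detail.
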