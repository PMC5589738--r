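---
title: "Neuro-fuzzy regression by whale optimization: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neuro-fuzzy regression by whale optimization: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anfiswoa)
```

## The problem and the model

The package targets small tabular regression problems of the kind that arise
in food biochemistry: predict amino-acid concentrations in fish protein
hydrolysates from five routinely measured covariates — moisture, fat, ash
and crude protein (percent) plus water temperature (degrees Celsius). Sample
sizes are small (on the order of a hundred specimens across a sampling
year), responses are nonlinear in temperature, and laboratory ground truth
is expensive, which motivates an interpretable fuzzy rule base over a black
box.

The regressor is a first-order Takagi–Sugeno system evaluated as a
five-layer adaptive network. Rule `i` is

> IF `x_1` is `A_i1` AND ... AND `x_d` is `A_id` THEN
> `f_i(x) = p_i . x + r_i`

with Gaussian fuzzy sets `A_ij` parameterized by a center `rho_ij` and a
width `sigma_ij > 0`. The layers compute membership degrees, product-T-norm
firing strengths `w_i`, normalized strengths `wbar_i = w_i / sum w`, the
weighted consequents `wbar_i f_i(x)`, and their sum. Two structural facts
carry the package's correctness arguments:

* the output is a **convex combination** of the rule consequents, so it is
  bounded by `[min_i f_i(x), max_i f_i(x)]` for every input, and
* the normalized strengths **sum to one** whenever the total firing is
  representable.

Both are enforced by property tests against an independently coded
layer-by-layer evaluator.

The membership exponent is implemented as `exp(-((x - rho)/sigma)^2)`,
without the conventional factor 2 in the denominator. The two
parameterizations differ only by a `sqrt(2)` rescaling of `sigma`, which the
optimizer absorbs; the form without the factor is kept because it is the
form the surrounding literature in this application area prints.

### Rule structure

One membership function exists per (rule, input) pair — the scatter-type
rule base produced by clustering — rather than a grid of all membership
combinations. A `c`-rule, `d`-input model therefore has exactly
`c (3 d + 1)` free parameters and rule count grows with the data's cluster
structure, not exponentially with `d`. With the five study inputs a grid
would be untenable, and the cluster count is exactly what fuzzy c-means
provides.

### One model per target

Concentration panels measure many amino acids per specimen. The package
fits one independent single-output model per target column, sharing the
clustering (the inputs are common) but not the consequents or the
optimization. A shared rule base emitting a vector output was the design
alternative; per-target models were chosen because per-analyte error tables
are the reporting convention, and because the scalar consequent structure
keeps the search dimension per optimization at `c (3 d + 1)` instead of
`c ((d + 1) m + 2 d)`.

## Training

### Normalization

All features and targets are min-max scaled to `[0, 1]`, with the transform
fitted **on the training portion only** and applied unchanged to test data
(values outside `[0, 1]` are legitimate and not clipped). Min-max rather
than z-scoring because the optimizer needs a bounded, interpretable search
box for the premise centers; constant columns are rejected with an error
naming the column. Fitness is computed on the normalized target; all
reported metrics are computed after mapping predictions back to the
original measurement scale, because relative error is meaningless on a
shifted scale.

### Initialization by fuzzy c-means

Standard fuzzy c-means (fuzzifier `m = 2`, tolerance `1e-5` on the maximum
membership change, 200 iteration cap, seeded random membership start) runs
on the normalized inputs only — membership functions live on the input
space, so targets do not join the clustering. The rule count is chosen by
maximizing the fuzzy partition coefficient (mean squared membership) over
candidates 2..10, ties toward fewer rules; the criterion is a deliberate
package choice, as the application literature typically says only that
clustering "determines" the count. Premise centers are the cluster centers;
widths are membership-weighted standard deviations per input column,
floored at `sigma_min = 1e-3` normalized units so the Gaussian exponent
stays well-defined (plain memberships, not fuzzified powers, serve as
weights; with one cluster this reduces to the population standard
deviation). Consequents start at zero and are left entirely to the
optimizer. Points coinciding with a center receive uniform membership over
all coincident centers — a tie-break, not an error.

### The whale optimization algorithm

WOA minimizes the squared-error fitness over the box: premise centers in
`[-0.1, 1.1]` (the data span plus a 10% margin), widths in `[1e-3, 2]`, and
consequent coefficients and biases in `[-10, 10]` normalized units — wide
enough that the optimum of any reasonably scaled problem is interior.
Positions are hard-clipped to the box after every move.

Per iteration `t` of `T`, the schedule value is `a = 2 (1 - t/T)` (exactly
0 at the last iteration). Each whale draws `p` uniform on `[0, 1]`:

* `p >= 0.5`: spiral move toward the best position with `l` uniform on
  `[-1, 1]` and shape constant `b = 1`;
* `p < 0.5`: compute a single scalar `A = 2 a r - a` for the whale
  (broadcast across dimensions, so the branch test `|A| < tau_A` is
  well-defined) and a fresh per-dimension vector `C = 2 r'`; encircle the
  best position if `|A| < tau_A`, otherwise move relative to a uniformly
  chosen population member.

Two printed-source ambiguities were resolved in favor of the original
algorithm: the update is `X* - A D` **without** an outer absolute value
(the absolute-valued variant would confine search to the positive orthant
and break the `A = 0` fixed point), and `p >= 0.5` selects the spiral (the
branch convention is stated inconsistently across descriptions of the
method; the original convention is used and the threshold `tau_A` defaults
to 1 with 0.5 selectable). The per-whale randomness order (p; then l, or
rA, the C vector and the partner index) is documented in the source and
pinned by an exact-equality test against a naive loop reimplementation.

Non-finite fitness values are treated as `+Inf` and can never become the
incumbent best; the best-so-far is elitist, so the convergence trace is
nonincreasing by construction. The early-stop tolerance is disabled by
default (all iterations run), since no principled threshold exists a
priori.

The population is seeded with the FCM-initialized parameter vector as
member 1 (the rest uniform in the box). Purely random initialization is the
strict alternative and remains available (`inject_fcm = FALSE`); injection
is the default because the clustering step otherwise influences nothing but
the rule count, and elitism guarantees the trained model is never worse
than the clustered starting point — a guarantee the acceptance suite
checks.

PSO (constricted global-best, inertia 0.7298, both acceleration constants
1.49618) and a real-coded GA (tournament size 2, BLX-0.5 crossover at rate
0.9, per-gene Gaussian mutation annealing from 10% to 0.1% of the box
range, one elite) are comparison baselines behind the identical interface
and the identical fitness.

## Evaluation protocols

Two protocols mirror standard practice: repeated random 70/30 splits
(default 10 repeats, per-target metrics averaged over repeats) and 10-fold
cross-validation with fold sizes differing by at most one. Cross-validation
metrics are computed on the **pooled** out-of-fold predictions rather than
averaged per fold — pooling has lower variance with 12-sample folds, and
the choice is recorded in the report's protocol descriptor. RMSE and AAPRE
are both computed on the original scale. AAPRE divides by the measured
value; measured zeros are an error by default, and an explicit guard flag
excludes `|y| < 1e-9` terms while reporting the exclusion count. Algorithm
comparisons share byte-identical fold assignments (one protocol seed), so
differences reflect algorithms only; external learners' predictions can be
supplied as matrices and scored without reimplementation.

## The synthetic generator

The generator emulates the structure of a year-long seasonal hydrolysate
study: `n = 120` specimens (the cohort size such studies use) spread over
12 months; temperature a sinusoid spanning 12–38 °C (minimum at month 1)
plus Gaussian jitter of sd 1 °C truncated at three standard deviations, so
the contractually promised range bound holds; moisture, fat and ash around
fixed plausible means (74%, 8%, 5%, sd 1); crude protein affinely coupled
to temperature (`14 + 0.15 T`, sd 1), giving a protein–temperature
correlation near 0.8 at realistic noise.

Targets come in two modes:

* **peaked** (default): `scale * exp(-((T - T_opt)/width)^2) *
  (protein / mean protein)` plus Gaussian noise (sd 0.5 concentration
  units), with `T_opt = 28` °C, width 6 °C and peak scale 20 — concentration
  maxima at 27–29 °C, a marked decline by 35–38 °C, minima at 12–15 °C.
  The fitted rule base cannot represent this surface exactly, so peaked mode
  is the model-misspecification stress case.
* **explicit-anfis**: targets are drawn from a stored, known two-rule Sugeno
  surface over the normalized features, so the fitted family contains the
  generator and recovery can be tested in principle. The ground-truth model
  (centers 0.3/0.7 on every input, widths 0.3, order-one consequents) was
  fixed once as a smooth realistic surface before any test outcome was
  measured, and is serialized alongside every fixture.

What the generator does **not** emulate: within-month replication
structure, measurement censoring, inter-analyte correlation, non-Gaussian
noise, and composition covariation beyond the single protein–temperature
coupling. A green test on synthetic data therefore establishes pipeline
correctness and optimizer behavior — not field performance on real
hydrolysate panels.

## Numerical choices

* Zero-firing fallback: if the total firing is below `1e-12`, layer 3
  returns uniform weights `1/c` (a distant test point can underflow every
  Gaussian; division by zero would be undefined).
* Decoding an optimizer position clamps non-positive widths up to
  `sigma_min` with a warning; in-box positions never need it.
* Fitness is the raw **sum** of squared errors, not the mean — the printed
  convention in this literature; the argmin is unchanged.
* Train size of a fractional split is `round(N f)`; both sides must be
  nonempty.
* Fold assignment shuffles `rep_len(1..K, N)`, giving the
  sizes-differ-by-at-most-one invariant by construction.
* Model and report files are plain text; doubles are serialized with 17
  significant digits, which round-trips IEEE doubles bit-exactly (the
  default JSON number formatting does not).
* All randomness flows from one top-level integer seed expanded into
  per-stage sub-seeds (kept below 2^31); every pipeline artifact is
  byte-reproducible from the echoed configuration, which the determinism
  criterion checks end to end.

## Known limitations

* **Function recovery falls short of its bar.** The acceptance suite asks
  the trainer to recover a known two-rule, two-input generator from 200
  noiseless samples to held-out RMSE 0.05 in 8 of 10 seeds. The pipeline is
  verified exact — the generator's parameter vector, mapped into normalized
  training coordinates, lies inside the search box with training error at
  numerical zero — but a 25-whale, 100-iteration run stalls at held-out
  RMSE roughly 0.06–0.24, and PSO, GA, and ten-fold larger WOA budgets land
  in the same band. Meeting the bar would need a local-search hybrid (e.g.
  least-squares consequent updates), which is exactly the training style
  this package deliberately replaces; the criterion is asserted as written
  and fails honestly rather than being weakened.
* AAPRE is unstable whenever measured concentrations approach zero (winter
  months in peaked mode); prefer RMSE there, or use the zero guard and
  report exclusions.
* The optimizer treats the premise and consequent parameters as one flat
  vector; no identifiability is claimed (rule permutations give equal fits),
  so only function recovery — never parameter recovery — is tested.
* Metrics from repeated splits average per-run values; with very small test
  sides the per-run AAPRE distribution is heavy-tailed and the average can
  be dominated by single near-zero denominators.
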