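---
title: "Swarm-tuned SVM classification of NIR spectra: models and methods"
author: "clpsosvm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-tuned SVM classification of NIR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpsosvm)
```

## The problem and the pipeline

Near-infrared (NIR) spectra of brewed tea — or of any liquid food sample —
record overtone and combination bands of molecular vibrations over a
wavenumber grid, here 10,000 down to 4,000 cm^-1. Quality grades of a
product differ in chemical composition, so they leave small, correlated
differences across the spectrum. The package classifies such spectra into
ordered quality levels with the chain

1. **absorbance → transmittance** conversion, `T = 10^(-A)`;
2. **Savitzky–Golay smoothing** (window 21 points, polynomial order 2);
3. **PCA** on the smoothed transmittance, keeping `k` components;
4. a **one-vs-rest RBF-SVM** on the PCA scores, whose hyperparameters
   `(c, g)` are either fixed or tuned by a particle swarm.

Each step is exposed as its own function (`absorbance_to_transmittance()`,
`sg_smooth()`, `pca_fit()`, `train_ovr()`, …); `spectra_svm()` bundles the
chain into a single fitted object with `predict`/`print`/`summary`
methods.

### Why convert to transmittance?

Below roughly 7,500 cm^-1 an aqueous sample absorbs almost everything:
absorbance is large and dominated by noise, and a model fitted on
absorbance would be driven by that uninformative, ill-conditioned region.
On the transmittance scale the same region is pinned near zero, so it
contributes almost nothing to the variance that PCA ranks. The Beer–Lambert
convention `T = 10^(-A)` with *fractional* transmittance in [0, 1] is used;
the inverse conversion floors zeros at `1e-10` before the logarithm
(reported as a warning) so round trips are exact to 1e-12 above the floor.

### Savitzky–Golay settings

The filter is a moving least-squares polynomial smoother. The window of 21
grid points is the conventional choice at this grid density; the polynomial
order defaults to 2, the common chemometrics setting (the window length
matters much more than the order here). Boundary windows are handled by
evaluating the boundary polynomial fits at the edge points, so the output
keeps the input length; an `edge = "interior"` mode trims
`(frame_length-1)/2` points per side instead for users who prefer not to
extrapolate. A degree-`p` filter reproduces any polynomial of degree ≤ `p`
exactly in the interior — this is the oracle the tests check against.

### PCA choices

* **Centering only, no variance scaling.** All grid points carry the same
  physical unit (fractional transmittance), so unit-variance scaling would
  only amplify the noise-dominated saturated region.
* **Sign convention.** Each loading's largest-magnitude element is made
  positive. SVD backends are free to flip loading signs; fixing them makes
  scores, serialized models and downstream SVM fits reproducible.
* **Fit scope.** Inside the evaluation protocol PCA is fitted on the
  training partition of each rotation fold only, and the held-out group is
  projected onto those loadings. Fitting PCA on all samples before
  splitting leaks information from the test group into the representation;
  a `global_pca = TRUE` switch reproduces that variant for comparison, and
  a "leakage canary" test (corrupting a held-out group must not move the
  fold's PCA centring vector) guards the default path.

## The classifier

A soft-margin SVM separates two classes by a maximum-margin hyperplane in
the kernel feature space, with slack variables penalized by `c`. The RBF
kernel is parameterized as

    K(x, y) = exp( -||x - y||^2 / (2 g^2) )

so `g` is a length scale: large `g` gives a wide, nearly linear kernel,
small `g` a spiky one that can overfit. Standard solvers use
`exp(-gamma ||x-y||^2)`; the single mapping `gamma = 1/(2 g^2)`
(`gamma_from_g()`) is used at every solver call and tested explicitly.

Multiclass decisions use an explicit **one-vs-rest** assembly: for `L`
levels, `L` binary classifiers are trained (level `l` positive vs the
rest), all sharing one `(c, g)`; a sample is assigned the class with the
largest signed decision value, ties broken toward the lowest class index.
The assembly is built from binary fits rather than a solver's built-in
multiclass mode so the max-score rule and the tie rule are under package
control. The binary subproblems are imbalanced (20 vs 100 in the reference
design); no reweighting is applied by default, matching the plain
construction, though `balance_classes = TRUE` is available. Quadratic
programming is delegated to libsvm via \pkg{e1071}; decision values are
re-signed so "positive = this class" regardless of libsvm's internal label
order.

## The optimizers

Both optimizers search the 2-D box of `log10(c), log10(g) ∈ [-2, 2]` —
decades are the natural scale for both parameters, and the bounds cover
`0.01 … 100`. Velocities are capped at 20% of each dimension's range and
positions are reflected back into the box (with the velocity component
negated) when an update oversteps.

**Basic PSO.** Each particle keeps a velocity `V`, a personal best `pbest`
and shares a global best `gbest`:

    V' = V + c1 r1 (pbest - X) + c2 r2 (gbest - X),    X' = X + V'

with fresh uniform `r1, r2` per particle and `c1 = c2 = 1.49445`. The
update is implemented without an inertia weight — the previous velocity is
carried with implicit weight 1 — with an optional `pso_inertia` flag that
applies the schedule below. The position update uses the freshly updated
velocity `V'`, the standard formulation (the alternative of advancing the
position with the stale velocity differs only by a one-step lag and has
worse convergence behaviour).

**CLPSO.** Comprehensive learning replaces the `gbest` pull: each particle
`i` learns *each dimension* `d` from the personal best of an exemplar
particle `f_i(d)`:

    V'_d = w(k) V_d + ca r_d (pbest[f_i(d), d] - X_d),   X' = X + V'

with `ca = 1.49445` and a fresh uniform `r_d` per particle and dimension.
Exemplars are drawn per dimension: with probability `Pc_i` a tournament of
two particles sampled from the rest of the swarm is held and the better
personal best wins; otherwise the particle follows its own personal best.
If every dimension ended up self-referential, one random dimension is
forced to another particle. Exemplars are reassigned after `refresh_gap =
7` iterations without a personal-best improvement (the convention of the
original comprehensive-learning literature). The learning probability

    Pc_i = a + b (e^{10(i-1)/(pop-1)} - 1) / (e^{10} - 1),  a = 0, b = 0.5

ramps from 0 (particle 1 only refines itself) to 0.5, and particles keep
fixed indices — ranks are not re-sorted by fitness. The tournament samples
exclude the learning particle itself: self-learning is exactly what the
`1 - Pc_i` branch provides, and letting a particle "win" its own
tournament dilutes the comprehensive-learning pressure measurably at small
iteration budgets.

**Inertia schedule.** The weight decreases linearly,
`w(k) = 0.9 - 0.5 k / max_iter`, from 0.9 (global search) to 0.4 (local
refinement). A formulation with the complementary factor
`(max_iter - k)/max_iter` would *increase* over iterations, contradicting
the stated endpoints; the decreasing reading governs here. Within the
iteration loop the schedule is evaluated at the current iteration index, so
the final update runs at exactly `w = 0.4`; the first update then runs at
`0.9 - 0.5/max_iter` rather than 0.9 exactly. Reaching full local-search
damping at the end matters more for convergence than starting at the exact
upper endpoint, which the schedule only attains asymptotically anyway.

**Fitness.** The tuner scores a position `(log10 c, log10 g)` by the
accuracy of a one-vs-rest SVM at those parameters. Plain training accuracy
(resubstitution) saturates at 100% over a large plateau of `(c, g)` pairs
— including badly overfit ones — so it cannot rank candidates; the default
fitness is therefore stratified k-fold cross-validation accuracy *within
the training partition* (folds drawn once per tuning run, shared by all
particles, so the surface is deterministic). `fitness = "train"` restores
the resubstitution variant. Non-finite fitness values are scored `-Inf`
and counted in the result.

**Benchmarks.** On a 2-D sphere both variants converge reliably
(CLPSO reaches within 1e-2 of the optimum on essentially every seed at the
40-particle, 40-iteration budget). On the multimodal 2-D Rastrigin
function at the same budget, CLPSO's advantage is exactly where the method
claims it: over 100 seeds it gets trapped below the top local basin about
4% of the time versus about 14% for basic PSO, with a better mean and
worst case; the two are statistically tied near the optimum on the easy
seeds. Basic PSO's fast `gbest` collapse is a real advantage on unimodal
problems and short budgets; comprehensive learning pays off as soon as
premature convergence is a risk.

## The PLS-DA baseline

The reference classifier is partial least squares discriminant analysis:
class labels are one-hot coded, both blocks mean-centred, and a NIPALS
PLS2 decomposition extracts latent variables that maximize X–Y covariance;
prediction regresses the indicator block on the scores and takes the
argmax column (ties toward the lowest index). NIPALS with an unscaled
one-hot response is the standard PLS-DA construction; at full rank its
regression step coincides with ordinary least squares, which the tests use
as an oracle. In the method comparison the swept "component count" is read
as the number of PLS latent variables (PLS performs its own reduction, so
it consumes the smoothed spectra directly rather than PCA scores).

PLS-DA has no tuning parameters beyond the component count — its appeal
and its limitation. One structural limitation matters for synthetic
experiments: when class means lie on (nearly) a single line in graded
order, the argmax of linear indicator predictions can only ever select the
extreme classes, so PLS-DA cannot reach perfect accuracy on purely graded
one-direction class structure no matter how clean the data. Real spectra
give each grade some direction of its own; synthetic "easy mode" fixtures
in the tests do the same by letting each class boost a distinct absorption
band.

## The synthetic generator

The study design the generator emulates: 6 quality levels × 20 samples,
1,557 grid points over 10,000→4,000 cm^-1, near-total absorbance below
7,500 cm^-1, smooth spectra with class-dependent absorption-band depths,
and measurement noise. Each spectrum is built in absorbance units as

* a gentle baseline (0.05 plus a 0.02 tilt towards low wavenumbers),
* a saturation shoulder: a logistic ramp to absorbance 2.5 below
  7,500 cm^-1 (transmittance ≈ 0.003, reproducing the "no effective
  information there" region),
* three Gaussian absorption bands (centres 8,250 / 8,800 / 9,500 cm^-1)
  whose depths grow with the quality level — per-band slopes (0.12, 0.08,
  0.05) per level, so adjacent levels differ least and adjacent-level
  confusion is the typical error,
* per-sample variability: a global band-strength factor
  (log-sd 0.01), independent per-band depth jitter (log-sd 0.02), and
  white noise (sd 0.004 absorbance units),

then converted to transmittance by the pipeline. The variability defaults
were calibrated once so that the fixed-parameter baseline SVM
(`c = 2, g = 1`, 16 PCs) lands around 0.90 median held-out accuracy —
solidly above chance, below the ceiling, leaving measurable headroom for
the tuned variants — and so that the leading principal component dominates
(PC1 explains ≳ 90% of the variance, with the saturated region
contributing essentially nothing to the loadings, matching the qualitative
structure NIR practitioners see on real tea spectra).

What the generator does **not** emulate: real chemical band assignments,
instrument line shapes, multiplicative scatter, baseline drift between
sessions, or inter-batch effects. Passing tests on this generator
demonstrate that the pipeline recovers graded class structure of the
stated geometry from realistic noise — not that any particular accuracy
would be attained on real tea spectra.

## The evaluation protocol

120 labelled samples are split into 4 groups of 30 by stratified random
assignment (5 per class per group — the only way equal groups keep every
class represented; plain random assignment is available via a flag). Each
group in turn is held out: spectra are converted and smoothed (per-sample
operations, safe to apply globally), PCA is fitted on the three training
groups, both partitions are projected, the classifier is trained — for the
swarm methods, `(c, g)` is tuned *inside the training partition*, re-run
per fold with a fold-derived seed, so parameters may differ across folds
and all four pairs are reported — and accuracy is measured on the held-out
group. The reported accuracy is the mean of the four rotations, so every
sample is tested exactly once. `pc_sweep()` repeats this over a range of
component counts (default 1..25) and reports the best count per method;
`compare_methods()` assembles the four-method table (fixed SVM, PLS-DA,
PSO-SVM, CLPSO-SVM).

Whether tuning ran once on all samples or per rotation fold is a genuine
protocol fork; per-fold tuning is the leakage-free reading and is the
default here.

## Numerical choices and degenerate inputs

* Transmittance values are clipped to [0, 1] after smoothing (the filter
  can overshoot at band edges by round-off-scale amounts).
* Zero transmittance floors at `1e-10` before `log10`; the count of
  floored points is reported.
* All argmax decisions break ties toward the lowest class index.
* `max_iter = 0` is allowed and returns the best of the random
  initialization (useful as a random-search control).
* Constant (zero-variance) fitness landscapes leave `gbest` at the initial
  best with a flat trace.
* PLS2 stops early and truncates if a component's score variance
  underflows (rank-deficient X).
* Reflection at the search bounds is iterated, with a final clamp for
  pathological velocities, so positions are always inside the box.

## Problem sizes used by the tests and the acceptance script

The swarm defaults follow the reference setup (`pop = 40`,
`max_iter = 40`). For the repeated 10-seed rotation panels in the test
suite and the acceptance script, the tuners run at half scale —
20 particles × 20 iterations with 3-fold cross-validated fitness — the
closest proportional scaling of the reference swarm that lets a full
four-method panel complete in minutes on a single core. The iteration
count matters more than the population here: 20 iterations give CLPSO
multiple exemplar-refresh cycles (`refresh_gap = 7`) and a late
low-inertia refinement phase, and on these 90-sample training partitions
the cross-validated fitness surface plateaus within that budget (both
optimizers reach the same best cross-validation fitness), so the panel
compares the methods at converged operating points; at substantially
smaller budgets the comparison instead measures mid-search noise.
Benchmarks (sphere, Rastrigin) always use the full 40 × 40 budget.

## Known limitations

* Accuracy on 120 samples moves in steps of 1/120 ≈ 0.008; method
  orderings on a single panel are correspondingly coarse.
* The swarm fitness is a plateau-rich surface; many `(c, g)` pairs are
  exactly tied, and which tied optimum a run returns depends on the seed.
* The OVR decision values from different binary classifiers are compared
  directly without calibration, the standard max-score construction.
* No wavelength selection, scatter correction (SNV/MSC), or derivative
  preprocessing is implemented; the pipeline intentionally mirrors the
  minimal convert–smooth–reduce–classify chain.
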