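# clpsosvm

Multi-class classification of near-infrared (NIR) spectra with RBF-kernel
support vector machines tuned by particle swarm optimization — including
the comprehensive-learning variant (CLPSO) that resists premature
convergence — plus the full chemometrics pipeline around the classifier
and a rotation-fold evaluation protocol.

The package is aimed at chemometricians classifying graded product quality
(the motivating case is brewed tea scanned at 10,000→4,000 cm⁻¹) and at
anyone who wants a compact, fully tested reference implementation of
CLPSO-tuned SVM classification.

## The method

Raw absorbance spectra are converted to fractional transmittance
(`T = 10^(−A)`, which pins the saturated low-wavenumber region near zero),
smoothed with a Savitzky–Golay filter (window 21, order 2), and reduced by
mean-centred PCA to `k` score dimensions. A one-vs-rest assembly of `L`
soft-margin SVMs classifies the scores with the RBF kernel

```
K(x, y) = exp( −‖x − y‖² / (2 g²) )
```

assigning each sample the class with the largest decision value. The
penalty `c` and kernel width `g` are tuned over `log₁₀ c, log₁₀ g ∈
[−2, 2]` by a swarm of particles scoring cross-validated accuracy:

* **PSO** — `V′ = V + c₁r₁(pbest − X) + c₂r₂(gbest − X)`, `X′ = X + V′`;
* **CLPSO** — `V′_d = ω(k)V_d + c_a r_d (pbest[f_i(d), d] − X_d)`, where
  each dimension `d` of particle `i` follows the personal best of an
  exemplar `f_i(d)` chosen by tournament with probability
  `Pc_i = a + b(e^{10(i−1)/(pop−1)} − 1)/(e^{10} − 1)`, and the inertia
  weight `ω(k)` falls linearly from 0.9 to 0.4.

A NIPALS PLS-DA classifier serves as the untunable baseline, and a
synthetic generator produces tea-like six-level spectra (graded Gaussian
absorption bands, saturation below 7,500 cm⁻¹, measurement noise) so the
whole pipeline is testable without proprietary data.

The evaluation protocol splits 120 samples into four stratified groups of
30, holds each group out in turn (PCA and tuning see only the training
partition), averages the four test accuracies, sweeps the component count,
and compares the four methods (fixed SVM, PLS-DA, PSO-SVM, CLPSO-SVM) in
one table.

## Worked example

```r
library(clpsosvm)

set <- generate_tea_spectra(synth_config(seed = 42))
set
#> <spectra_set> 120 spectra x 1557 points, mode = absorbance
#>   grid: 10000 -> 4000 cm^-1
#>   labels: 1 (n=20), 2 (n=20), 3 (n=20), 4 (n=20), 5 (n=20), 6 (n=20)

train_idx <- c(1:15, 21:35, 41:55, 61:75, 81:95, 101:115)
fit <- spectra_svm(set[train_idx], pc = 16, tune = "clpso",
                   swarm = swarm_control(pop = 12, max_iter = 8, seed = 1),
                   cv_folds = 3)
summary(fit)
#> Pipeline: transmittance -> Savitzky-Golay (frame 21, order 2) -> PCA(16) -> one-vs-rest RBF-SVM
#> <spectra_svm> 6-class RBF-SVM on 16 principal components
#>   tuning: CLPSO; c = 92.75866, g = 0.9602279
#>   training accuracy: 100.00%
#>   PCA explained variance (%): 98.5, 0.7, 0.6, 0.0, 0.0, ...
#>   swarm: clpso, fitness = cv, best fitness = 0.9888889
#>   support vectors per class: 3, 6, 9, 7, 12, 5

hold <- set[setdiff(1:120, train_idx)]
accuracy(predict(fit, hold), hold$label)
#> [1] 1
```

The summary reads: the swarm settled on `(c, g) ≈ (92.8, 0.96)`, the
first principal component carries 98.5% of the transmittance variance
(the saturated region contributes none), the tuned model fits its training
partition perfectly with a 0.989 cross-validated fitness, and all 30
held-out spectra — five per quality level — are classified correctly.

For the full protocol:

```r
plan <- make_rotation_folds(set$label, G = 4, stratified = TRUE, seed = 7)
cmp  <- compare_methods(set, pc_range = 10:20, plan,
                        eval_control(seed = 7))
cmp            # four-row table: method, best PC count, train/test accuracy
```

A thin command-line front end over the same functions ships in
`inst/cli/clpso-svm.R` (`simulate`, `evaluate`, `compare`).

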