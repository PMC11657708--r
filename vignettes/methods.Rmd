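---
title: "Texture-based ultrasound plane classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based ultrasound plane classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Routine maternal–fetal ultrasound screening produces many images per session,
from which a handful of canonical *standard planes* (fetal brain, abdomen,
femur, thorax, maternal cervix, plus an "other" catch-all) must be
identified before biometric measurements can be taken. `fetalplanes`
implements a classical texture-analysis route to automating that triage:
gray-level co-occurrence matrix (GLCM) features, metaheuristic wrapper
feature selection, and a radial basis function network classifier trained by
a convex dual program rather than gradient descent. Because the real
screening collections cannot ship with a package, a seeded synthetic texture
generator stands in for them throughout the tests.

## Preprocessing

Images are 8-bit grayscale matrices. The chain runs in a fixed order —
resize, crop, histogram equalization, median despeckling, min–max
normalization — and each stage can be disabled independently (disabling the
despeckle stage reproduces the noise-removal ablation).

* **Resize** uses exact area averaging (overlap-weighted box filter), so a
  constant image is invariant and mean intensity is preserved; with aspect
  preservation the image is centred on a zero canvas. The default target is
  224×224, a common imaging default; the synthetic pipeline keeps its native
  64×64.
* **Crop** coordinates are 0-based and half-open, `[x, x+w) × [y, y+h)`.
  Burned-in annotation detection is out of scope; crop bounds are
  user-supplied or whole-frame.
* **Equalization** is the standard 256-bin CDF map `v -> round(255 cdf(v))`,
  a monotone transform. It must precede normalization (it requires integer
  intensities).
* **Despeckling** is a median filter (default 3×3) with edge replication.
  The filter type is a package choice: the median is the usual rank-order
  answer to multiplicative speckle, removes isolated impulses exactly, and
  can never leave the input range.
* **Normalization** maps `(p - min)/(max - min)`; a constant image maps to
  all zeros by declared convention.

Class rebalancing (`balance_classes()`) forces every class to an exact
target count by random undersampling without replacement and random
duplication — no synthetic interpolation — reproducing, at the published
inventory `(3092, 711, 1040, 1718, 1626, 4213)`, the balanced 1050-per-class
design.

## GLCM texture features

For each of the five angles {0°, 30°, 45°, 90°, 135°} the normalized image
is quantized to `N_g = 8` gray levels and a symmetric co-occurrence matrix
is accumulated at displacement `round(d(-sin θ, cos θ))` with `d = 5`
(Haralick convention: 0° is the rightward neighbor, angles counter-
clockwise). Nine descriptors are computed per matrix — contrast,
dissimilarity, homogeneity, energy, angular second moment, correlation,
entropy, marginal mean and marginal variance — giving the 45-feature
vector.

Descriptor conventions worth calling out:

* The angular second moment is implemented as the **fourth**-power sum
  `Σ p(i,j)^4`, exactly as the source formulation prints it, even though the
  classical definition is the second-power sum (which is what the energy
  feature already reports). The deviation is deliberate and documented.
* Entropy uses `log10` ("lg"), with `0·log 0 := 0`; the base is
  configurable.
* The source lists ten formulas but reports 45 features over five angles,
  forcing nine per angle. Marginal standard deviation is the one dropped
  here: under an enforced-symmetric GLCM it is a deterministic monotone
  transform of the variance and carries no independent information.
* Under a symmetric matrix the row and column marginals coincide, which
  resolves the ambiguity between the `i`- and `j`-marginal moment
  definitions.
* `N_g = 8` keeps distance-5 co-occurrence matrices well populated on 64×64
  synthetic images; 16/32/256 are available through `texture_config()`.

Correctness is anchored by an independent double-loop oracle: on random
symmetric matrices up to 16×16 the vectorized implementation must agree to
1e-12.

## Wrapper feature selection

Candidate feature subsets are binary masks over the 45 columns, scored by

```
fitness = w_acc * accuracy(mask) + w_feat * (45 - |mask|) / 45
```

with defaults `w_acc = 0.9`, `w_feat = 0.1`; `accuracy(mask)` is the holdout
accuracy of a 1-nearest-neighbor classifier on a stratified 70/30 split
fixed once per run. The evaluator works in the **raw** masked feature space:
standardizing columns first would shrink exactly the class-informative
columns (their standard deviation includes the between-class spread) and
hand the distance over to the noise columns. The published 45→25 reduction
is treated as an emergent outcome, not a constraint; `target_k` additionally
tracks the best mask of an exact size for users who want a fixed budget.

Three optimizers share one driver (`swarm_optimize()`), all maximizing over
continuous positions that a stochastic sigmoid transfer binarizes
(`bit_j = 1` iff `sigmoid(x_j) > u_j`, with an always-at-least-one-bit
repair):

* **PSO** — inertia `w` decaying linearly 0.9→0.4, accelerations
  `c1 = c2 = 2`, fresh per-dimension uniforms, velocities clamped to ±6 (the
  sigmoid's saturation range).
* **GWO** — control scalar `a` decaying 2→0; per wolf and dimension
  `A = 2ar - a`, `C = 2r`; distances `D = |C x_leader - x|` to the three
  best-so-far leaders; new position the mean of the three guide points.
* **PSOGWO hybrid** — the grey-wolf guide points replace the personal/global
  attractors inside a three-term particle velocity, damped as a whole by the
  inertia weight: `v <- w (v + c1 r1 (x1-x) + c2 r2 (x2-x) + c3 r3 (x3-x))`,
  `c3 = 0.5`. The whole-update damping follows the published hybrid scheme;
  the undamped three-term variant was measured to stall around 1e-2 on the
  5-D sphere benchmark, while this form reaches ~1e-9. The global best is
  additionally reconciled with the leaders every iteration.

The best-so-far bookkeeping makes the fitness history non-decreasing by
construction for all three algorithms, and every returned mask selects at
least one feature.

## The fast RBF network

**Hidden layer.** Fuzzy C-means (fuzzifier `m = 2`, seeded random
row-stochastic initialization, alternating updates until the objective
change falls below 1e-6) clusters the standardized training features. The
RBF centers are then recomputed as plain membership-weighted means and each
width as the membership-weighted mean squared distance to its center,
floored at 1e-8 so degenerate clusters keep a valid Gaussian. Hidden
activations are `exp(-||x - c_i||^2 / δ_i)`, in (0, 1].

**Dual training.** Instead of gradient descent on the output weights, each
one-vs-rest machine solves the ε-insensitive-loss, structural-risk dual: for
targets `y ∈ {-1, +1}^n`, maximize

```
[αᵀ α*ᵀ] (2/λ)(y, -y)  -  [αᵀ α*ᵀ] K̃ [α; α*]
subject to  Σα + Σα* = 1,  α, α* ≥ 0
```

where `K̃` is the 2n×2n block matrix `[[K + (μn/λ)I, -K], [-K, K + (μn/λ)I]]`
and `K` the Gaussian kernel evaluated on the hidden activations — a double
nonlinearity retained exactly as the derivation states. The single
normalization constraint over the concatenated multipliers (rather than a
per-sample box) is likewise implemented as printed. Slacks are recovered as
`ξ = α μ n`, and ε is never solved for explicitly: the dual internalizes it;
an `eps_effective` diagnostic (the largest residual among inactive training
points) is reported per class.

The solver is an accelerated projected gradient (FISTA with objective-based
restart) over the probability simplex. `K̃` is positive definite (PSD kernel
blocks plus a positive diagonal shift), so convergence is geometric; the
step is `1/L` with `L` twice the largest eigenvalue, and iteration stops at
a Karush–Kuhn–Tucker complementarity residual below 1e-8 (scaled by the
linear term). On random small instances the objective must match
`quadprog`'s active-set solution to 1e-6.

**Prediction.** The decision value is
`λ Σ (α_i - α*_i) K(x̃_i, x̃_test)` — the plain Gaussian kernel, since the
block matrix `K̃` is a training-only object — and the multiclass label is
the argmax over the six one-vs-rest machines, ties broken toward the lowest
class index.

**Defaults** (the source reports none): `M = 20` hidden units, `λ = 1`,
`μ = 0.1`, `γ = 1/M`. All are exposed. Features are standardized inside the
model (stored center/scale) purely for kernel conditioning.

## Evaluation metrics

Per class in one-vs-rest view: accuracy, specificity, sensitivity,
precision, F1, Matthews correlation, false rejection rate
`FRR = FN/(TP+FN) = 1 - sensitivity` and false acceptance rate
`FAR = FP/(TN+FP) = 1 - specificity`; any 0/0 ratio is 0. The macro row is
the unweighted mean over classes. The source's metric table transposes the
F1 and MCC formulas (its "F1" cell prints the textbook MCC and its "MCC"
cell prints sensitivity); the standard definitions are implemented, with
this deviation noted. Note that one-vs-rest *accuracy* averaged over
balanced classes is systematically higher than plain multiclass accuracy —
a random guesser scores about 0.72 macro accuracy on six balanced classes —
so macro accuracy figures should be read with that baseline in mind.

## The synthetic data generators

**Textured images.** Each class is an anisotropic Gaussian random field:
white noise smoothed with an oriented Gaussian kernel (long axis = the
correlation length, short axis a third of it), standardized, scaled around
mid-gray by a contrast factor, then multiplied by `(1 + s)` with `s`
zero-mean Gaussian speckle — the standard multiplicative ultrasound noise
model, which is what makes the despeckle ablation meaningful. The six
default classes vary correlation length (2–12 px), orientation (0°–150°)
and contrast (40–65), giving each "plane" a distinct GLCM signature; the
shared speckle variance defaults to 0.3. What the generator does **not**
emulate: anatomy, attenuation, shadowing, probe geometry, operator
variation, or inter-vendor differences. Passing tests on these textures
demonstrate that the pipeline machinery separates classes that differ in
spatial correlation structure; they say nothing about clinical performance.

**Planted feature tables.** Informative columns are Normal(class mean, 1)
and noise columns Normal(0, 1). Each informative column `j` carries a
shifted saturating ramp of class means,
`effect_size * min(max(k - j + 2, 0), 3)` for class `k`, so the five
planted columns are complementary: each is the dominant separator of a
different stretch of adjacent classes. This structure matters. If all
informative columns shared one identical ramp they would be mutually
redundant, and the wrapper fitness — which explicitly rewards sparsity —
would be *maximized* by masks that drop planted columns; full recovery
would be anti-optimal by construction. With the windowed design, recovery
of the planted set and high all-features accuracy are simultaneously the
fitness optimum.

**Scale choices.** The test suite and the acceptance script run the
end-to-end benchmark at 30 images/class (64×64), selection at 20 agents ×
50 iterations, and planted-recovery at 300 rows — sizes at which every
stage's behavior is already stable across seeds while the whole suite stays
interactive. The published class inventory is exercised at full scale for
balancing and at 1/10 scale for imbalanced image generation.

## Numerical conventions

* Constant-image normalization → all zeros; correlation of a degenerate
  marginal → 0; all 0/0 metric ratios → 0.
* RBF widths floored at 1e-8; FCM samples coinciding with a center get full
  membership there.
* Prediction ties → lowest class index; binarization repair → highest
  sigmoid bit forced on.
* Every random draw flows through seeds derived deterministically from one
  global seed (kept below 2^31), and package functions restore the caller's
  RNG state; reruns are bit-identical, including serialized artifacts
  (JSON numbers are written with 17 significant digits for exact
  round-trips).

## Limitations

* GLCM features are whole-image; the patch-tiling mode hinted at by the
  source's hyperparameter table is undefined there and not implemented.
* The conventional gradient-descent RBFNN, CNN/ANN baselines, ROC analysis
  and probability calibration are out of scope.
* The hybrid optimizer's exact interleaving of its two parents is
  underdetermined in the source; the fused velocity rule implemented here
  is the closest published reading, and is documented as an interpretation.
* Real-data performance claims cannot be verified without the external
  image collection; all quantitative statements in this package are about
  the synthetic study conditions above.
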