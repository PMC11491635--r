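---
title: "Controlled in silico trials of morphological bias: models and methods"
author: "synthbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlled in silico trials of morphological bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Medical-imaging classifiers often show subgroup performance disparities, and
in real data it is rarely possible to know which image features cause them.
`synthbias` builds a fully controlled substitute world: synthetic 3D
neuroimages in which a *disease* effect (the prediction target) and a *bias*
effect (a spurious subgroup marker) are known, localized morphological
deformations. Because the generator is explicit, one can create paired
counterfactual datasets — the same simulated subjects with no bias effect,
with a bias effect adjacent to the disease region ("near"), or in the
opposite hemisphere ("far") — train identical CNNs on each, and attribute
any change in subgroup disparity purely to the bias manipulation.

## Deformation model

Anatomy is represented by stationary velocity fields $v$ in the
Log-Euclidean framework: the deformation applied to the template is the
group exponential $\phi = \exp(v)$, computed by scaling and squaring
(`exponentiate()`: scale by $2^{-n}$, then compose the displacement with
itself $n$ times with trilinear interpolation; $n = 6$ by default).
Morphological variability is a PCA generative model over such fields
(`fitEffectModel()`): mean field $\bar v$, orthonormal components $\phi_k$
and scales $\lambda_k^{1/2}$, from an SVD of the mean-centered flattened
fields. A sampled effect is $v = \bar v + \sum_k c_k \phi_k$ with
$c_k \sim N(0, \lambda_k)$; its *magnitude* is the Mahalanobis norm
$\big(\sum_k c_k^2/\lambda_k\big)^{1/2}$, a scale-free scalar used for
stratification.

Three models play different roles:

* the **subject** model (global morphology) is fitted on unrestricted fields;
* the **disease** model is fitted on fields pre-masked to the disease region
  (`restrictToRegion()`, Gaussian-smoothed mask renormalized to max 1,
  exact zero below 1e-8);
* the **bias** model is fitted on unrestricted fields and its samples are
  masked *at application time* to the near or far region. This is forced by
  the counterfactual contract: the same coefficients must generate the
  effect in two different regions, so the restriction cannot be baked into
  the model.

Effects combine by **velocity addition before a single exponentiation**
(Log-Euclidean sum). This is order-independent and uses one interpolation
pass; composing three separate warps would introduce order dependence and
double interpolation.

## The phantom

No external atlas is required: `makePhantomTemplate()` builds a head-like
template (nested ellipsoidal tissue levels on a constant zero background)
with labeled regions satisfying the spatial contract — disease region in the
left hemisphere, near-bias region face-adjacent to it, far-bias region
mirrored and sharing no axial slice. Role regions get strong intensity
contrast (0.95 for disease, 0.10 for bias targets against 0.45 cortex) so
that deforming them is visible to an image classifier. Region volumes
default to 2–3% of head volume, comparable to insula/putamen fractions of
brain volume.

`makePhantomFieldBank()` generates the training fields for the PCA models:
Gaussian-smoothed white noise per component, tapered linearly to zero at the
head surface (a hard cut would make the velocity discontinuous and the
exponential lose inverse consistency at the boundary), normalized to a
stated maximum displacement. Fifty fields is the default bank size.

What the phantom does **not** emulate: anatomical detail, MR physics,
intensity artifacts, partial-volume effects, multi-site variation. A green
test here establishes that the *pipeline logic* behaves as designed, not
that any real scanner population behaves this way.

## Dataset composition

The full-scale composition is 1000 disease / 1002 non-disease subjects with
70% of the disease class and 30% of the non-disease class in the bias group
(counts rounded half away from zero), a 50/25/25 train/val/test split, and
one volume per subject per scenario. Non-bias-group subjects are generated
once and reused, so their volumes are bit-identical across scenarios; a
bias-group subject keeps the same bias coefficients across near/far, only
the region mask changes.

Magnitude stratification removes a subtle confound: if subject or disease
effect magnitudes differed between the class-by-group cells, that
distribution shift would itself be a learnable signal. `stratifyMagnitudes()`
ranks the sampled magnitudes and deals them to cells in an evenly
interleaved (Bresenham) order proportional to cell sizes, so every cell
receives a near-identical distribution; the acceptance contract is a maximum
pairwise two-sample KS statistic below the 10%-level critical value.

Splits are assigned at subject level within strata keyed by (class, group,
subject-magnitude bin, disease-magnitude bin), with largest-remainder
rounding; strata smaller than 3 fall back to the (class, group) stratum with
a warning.

## Classifier

The reference architecture is a 3D CNN of five convolutional blocks
(filters 32, 64, 128, 256, 512; 3×3×3 kernels, batch normalization, sigmoid
activation, 2×2×2 max pooling), global average pooling, 20% dropout and a
single sigmoid output; batch size 4, Adam at 1e-4 (the optimizer is our
choice; only the learning rate is inherited), early stopping on validation
loss with patience 15 and restoration of the earliest best epoch. Because no
deep-learning runtime exists in the target environment, the engine is
implemented in the package itself (Rcpp/RcppArmadillo, double precision,
single-threaded); all randomness — initialization, shuffling, dropout —
flows from R's RNG, so a run is a bit-reproducible pure function of
(seed, data, config).

Grids that cannot survive one 2×2×2 pooling per block get the block count
reduced with a warning. The dense head initializes to zero by default (an
untrained model scores exactly 0.5); the desk preset uses a small random
head because a zero head delays encoder learning by several epochs at small
scale.

## Desk scale

The full-scale world (173×211×155, 2002 subjects, 5 seeds) is far beyond a
single-CPU budget with a hand-rolled engine, so the package ships a desk
preset (`deskTrialConfig()`) that was calibrated **once** and then frozen:

* grid 16³, 260 subjects (130/130), 3 seeds, filters (4, 8, 16);
* ReLU block activation: at this depth and budget the printed sigmoid
  blocks do not escape their plateau within any affordable epoch count
  (the config switch keeps sigmoid available, and it remains the
  full-scale default);
* subject amplitude 1.5 voxels (max displacement), disease amplitude 2.4
  restricted to the disease region, bias bank amplitude 10 with the masked
  field rescaled so its prior RMS inside each bias region is 4.5 voxels.
  The rescaling (`biasLocalRms`) equalizes effective effect strength across
  regions, because a globally normalized bank is systematically weaker near
  the head boundary where the far region sits — the analogue of fitting
  per-region models of comparable variance;
* hard bias masking (`boundarySigma = 0`): at 16³ a smoothed mask support
  would overlap the adjacent disease region and corrupt the disease signal
  rather than act as a shortcut;
* Adam at 2e-3, batch 8, patience 8, max 30 epochs.

These choices put the classifier in the intended regime: the disease task
learnable but imperfect, the bias effect easily
detectable, so that the 70/30 group composition makes the bias deformation a
worthwhile shortcut. Desk-scale deformations are deliberately
supra-physiological for the grid (a 4–5 voxel displacement at 16³); the
full-scale configuration keeps physiological scales.

## Bias mitigation

**Reweighing** assigns each training sample the Calders weight
$w(c,g) = N(c)N(g)/(N\,N(c,g))$ from training-split counts, making class and
group exactly independent in the weighted distribution. Validation loss is
left unweighted (early stopping tracks plain predictive loss).

**Adversarial unlearning** follows the encoder/two-heads scheme: (1) the
naive model; (2) a 2-class bias head trained to convergence on the frozen
encoder's pooled features; (3) an adversarial phase in which disease
cross-entropy is minimized while a confusion loss — cross-entropy between
the bias head's softmax and the uniform distribution — is maximized against
the encoder. The schedule within phase 3 is a free choice; ours is: per epoch, one disease pass over the training data,
then up to `innerRounds` rounds of (refit the bias head on current features
with the probe's own protocol; one confusion pass against that head),
stopping early when the refit head is within 3 points of chance. Refitting
the adversary to near-optimality each round matters: a lagging adversary
lets the encoder *fool the current head* without removing group
information. The phase stops when disease validation accuracy has stopped
improving and bias validation accuracy has stopped decreasing for
`patience` epochs. Verification is a post-hoc probe: a freshly initialized
head trained on the frozen unlearned encoder; success means probe accuracy
at chance. At desk scale the 16-dimensional representation entangles
disease and bias, so driving the probe to chance costs substantial disease
accuracy — an exaggerated version of the performance degradation that
unlearning is known to cause when applied to unbiased data.

**Group models** pretrain one model for 5 epochs on the full training split,
then fine-tune one copy per bias group; each test sample is scored by its
own group's model. Under the 70/30 composition the two group models see
opposite class imbalances, which by itself induces a strong disparity — the
induced-disparity mechanism is visible even in the No-Bias scenario.

## Evaluation and statistics

Subgroup metrics are stored as exact confusion counts; accuracy/TPR/FPR are
derived on access (percent). Disparities are ΔTPR and ΔFPR
(bias − non-bias, percentage points); *relative* disparities subtract the
matched-seed No-Bias value of the same strategy. Pairwise comparisons use a
Shapiro–Wilk gate (α = 0.05) on the paired differences to choose between a
paired t-test and the Wilcoxon matched-pairs signed-rank test, two-tailed at
the Bonferroni-corrected α = 0.005; all-zero differences give exact p = 1,
constant nonzero differences go to the rank test. A two-way
repeated-measures ANOVA (scenario × strategy, seed as the repeated unit,
via `stats::aov` with an `Error(seed/…)` term) is reported as an omnibus
gate. Note that at n = 5 seeds the Wilcoxon branch can never reach
p < 0.005, which caps the pipeline's power whenever normality is rejected.

## Explainability

SmoothGrad saliency is the mean over `nNoise` draws (default 25) of the
absolute input gradient of the positive-class *pre-threshold score*,
evaluated at the volume plus Gaussian noise with SD equal to
`noiseFraction` (default 0.10) of the intensity range. Subgroup maps average
the first `nSubjects` (default 10) correctly classified test subjects of a
(class, group) cell, ordered by subject id (averaging is
per (class, group) cell). The weighted saliency score of region $r$ is the
size-normalized enrichment
$\mathrm{WSS}_r = \frac{\sum_{x\in r} s(x) / \sum_{x\in L} s(x)}{|r|/|L|}$
over labeled voxels $L$: uniform saliency gives every region 1, and the
voxel-weighted mean of scores is always 1. The scoring function is an
argument, so other variants can be slotted in.

A desk-scale caveat: with three pooling stages at 16³, saliency is coarse,
and the near-bias region — face-adjacent to the disease region by
construction — receives bleed-over from disease saliency in every scenario.
The far region, spatially separated, gives the cleaner localization signal.

## Numerical choices and degenerate inputs

* Exponentiation: 6 squarings, trilinear interpolation, border-clamped
  sampling; inverse consistency is ≤ 0.05 voxels for smooth fields of
  ~1 voxel amplitude at 32³ (the voxel-relative scale of a few-mm
  full-resolution deformation). Larger amplitudes degrade gracefully.
* Warping: background fill is the most frequent corner value of the input.
* Masking: weights below 1e-8 are set to exactly zero (compact support).
* PCA: at most n−1 components; orthonormality enforced to 1e-6 by the
  class validity.
* Prediction threshold 0.5 is inclusive (0.5 → positive).
* Empty masks, empty composition cells, seed mismatches and shape
  mismatches raise immediate errors naming the offending object.

## Known limitations

* The engine is CPU-bound; full-scale replication of the reference
  experiment is out of reach here by design.
* Phantom anatomy is schematic; effect sizes needed at 16³ are
  supra-physiological, and per-seed disparity estimates at ~65 test
  subjects are noisy (SDs of tens of percentage points are normal).
* Unlearning at desk scale trades most shortcut-driven accuracy for group
  invariance; it demonstrates the mechanism, not a deployable recipe.
* Only morphological (deformation) effects are modeled; intensity
  artifacts, prevalence shift and multiple simultaneous biases are out of
  scope.
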