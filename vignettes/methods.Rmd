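---
title: "Methods: ensemble-decoder skull stripping of multiparametric MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble-decoder skull stripping of multiparametric MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Problem

Skull stripping (brain extraction) removes non-brain tissue — scalp, skull,
CSF shells, eyes — from head MRI so that downstream analyses see only brain.
`enstrip` treats it as a voxelwise binary segmentation problem over
co-registered multiparametric MRI (mpMRI): up to four channels, always in the
fixed order **FLAIR, T1, T1ce, T2**, identified by the single-character codes
`f`, `1`, `c`, `2`. Any of the 15 nonempty channel subsets can be used; a
combination is written as the concatenation of its codes in that canonical
order (the full set is `"f1c2"`).

# Synthetic phantoms

Validating a skull-stripping pipeline requires volumes with *exact* ground
truth. The package generates synthetic head phantoms
([`generate_case()`], [`generate_cohort()`]) built from nested ellipsoids:
brain, a CSF rim (default 1 mm), a skull shell (1.5 mm) and a scalp shell
(1.5 mm), embedded in background with at least a two-voxel margin — a hard
invariant that is checked and refused, never silently clipped.

Three clinical conditions are modelled: `healthy`, `pre_op` (a bright
spherical tumor inside the brain, included in the brain mask) and `post_op`
(a resection cavity at background intensity, *excluded* from the mask). The
ground-truth mask is brain plus tumor.

The per-tissue, per-modality intensity table
([`default_contrast_table()`]) is deliberately adversarial for single-channel
models:

* scalp is nearly isointense with brain on FLAIR, T1 and T1ce, and only
  separates on T2;
* the CSF rim is nearly isointense with brain on T2, and only separates on
  the other channels.

No single modality therefore suffices to isolate the brain, which is what
makes the modality-combination study (below) informative: models with more
channels have strictly more discriminative information available.

Gaussian noise is added per modality with standard deviation expressed as a
fraction of the full contrast range (default 0.05); an optional low-order
polynomial bias field can be applied multiplicatively. Cohort generation
jitters the template geometry per case (semiaxes ±10 %, lesion radius
±20 %), apportions conditions by largest remainders, and derives one
deterministic seed per case from the master seed, so a cohort is a pure
function of `(n, spec, condition_mix, seed)`.

Phantoms are idealised: real heads are not ellipsoids, real noise is Rician
and spatially correlated, and real skull/scalp interfaces are far more
complex. The phantoms are designed to exercise every code path with exact
ground truth, not to certify clinical performance.

# Preprocessing

`preprocess_case()` runs, per channel:

1. **Reorientation** to the RAS-dominant axis ordering
   (`reorient_to_atlas()`), a pure permutation/flip that preserves every
   voxel's world coordinates exactly; oblique acquisitions trigger a warning.
2. **Resampling** onto an atlas grid (`resample_to_atlas_grid()`), default
   240×240×155 voxels at 1 mm isotropic, trilinear for images and
   nearest-neighbour for masks, with a centre-aligned target affine.
3. **Intensity normalization** (`normalize_intensity()`): z-scoring over the
   *nonzero* voxels only (zero is background/padding and stays exactly
   zero).
4. **Stacking** (`stack_modalities()`) into a `modality_stack` in the fixed
   canonical channel order.

`reduce_noise()` and `correct_bias_field()` exist as explicit no-op hooks:
they document where denoising/bias correction would plug in and error on any
requested method, rather than pretending to an implementation.
Skull-stripped images are produced by voxelwise multiplication of each
channel with the binary mask (`apply_mask()`).

# Model

The network (`network_spec()`, `build_ennet()`) is a 3D encoder–decoder
with an *ensemble* of two decoders. Feature maps are kept as V×C matrices
(V voxels in column-major order, C channels).

**Encoder.** Level $l$ (of depth $D$) has width $w_l = w_1 2^{l-1}$. Each
level applies a conv unit (3×3×3 convolution → GroupNorm → leaky ReLU) and a
residual block

$$\mathrm{Res}(x) = \phi\big(\mathrm{GN}_2(K_2 * \phi(\mathrm{GN}_1(K_1 * x))) + x\big),$$

with $\phi$ the leaky ReLU (slope 0.01), followed by 2×2×2 max pooling
between levels.

**Main decoder.** From the bottom up, each level trilinearly upsamples by 2,
applies a conv unit halving the width, *adds* the encoder feature of that
level (additive skip), then a residual block.

**Auxiliary decoder.** In parallel, a 2×2×2 stride-2 transposed convolution
maps the same lower-level input to the upper level's width.

**Ensemble.** The two branches are summed elementwise at every level:
$x_l = m_l + a_l$. This is the model's defining feature; `use_aux = FALSE`
switches the auxiliary branch off for ablations. The head is a 1×1×1
convolution to one channel with a sigmoid, giving a per-voxel brain
probability, binarised at a threshold (default 0.5) by `binarize()`.

All forward *and backward* passes are hand-written: convolutions are 27
offset-blocked GEMMs in C++ (calling R's BLAS), with exact adjoints for
upsampling, pooling and the transposed convolution, and the standard
GroupNorm backward recursion. Gradients are verified against central finite
differences in the test suite.

# Training

The objective is the soft Dice loss

$$L(p, y) = 1 - \frac{2\sum_v p_v y_v}{\sum_v p_v^2 + \sum_v y_v^2 + \epsilon},
\qquad \epsilon = 10^{-5},$$

whose numerator uses the product $p\cdot y$ (the overlap); with binary
$p = y \ne 0$ the loss approaches 0 and for disjoint supports it equals 1.

Optimisation uses Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8), batch size 1, with
a polynomial learning-rate decay per epoch $i$ of $N$:

$$r_i = r_0\,(1 - i/N)^{0.9}, \qquad r_0 = 10^{-3},$$

so training starts exactly at `1e-3`, decreases strictly and ends at 0.

On-the-fly augmentation per case and epoch: random crop (to the configured
crop shape), rotation about a random axis by U(0°, 10°) (trilinear for
images, nearest for the mask), a per-channel intensity shift in ±0.1 (images
only), and independent per-axis flips with probability 0.5. Every
augmentation draw is seeded per (epoch, case), so a run is bit-for-bit
reproducible from its configuration seed.

Validation runs every 5 epochs (soft-Dice loss and thresholded hard Dice on
full volumes); the weights with the best validation Dice are kept as the
fit's model. `tidy()`, `glance()` and `autoplot()` expose the history as
tibbles and training curves.

# Metrics

With brain as the positive class and TP/FP/FN/TN voxel counts:

* Dice $= 2\,\mathrm{TP} / (2\,\mathrm{TP} + \mathrm{FP} + \mathrm{FN})$
  (the overlap form; equivalently $2|P\cap G| / (|P| + |G|)$),
* precision, recall, FPR, FNR with fixed degenerate conventions
  (two empty masks count as perfect agreement; `fnr = 1 - recall` always).

**HD95** is the symmetric 95th-percentile Hausdorff distance in millimetres
between the 6-connectivity boundary voxels of the two masks (grid edges
count as outside), computed with an exact anisotropic Euclidean distance
transform (Felzenszwalb's lower-envelope algorithm) and the type-7 sample
quantile. It equals the brute-force pairwise definition to within
floating-point error; the test suite checks this on random masks, along
with a voxel-loop oracle for the confusion counts.

# Modality-combination study

`run_combination_study()` trains one model per requested combination —
identical seed, config and architecture apart from the input channel count —
and tabulates cohort mean ± sd of all six metrics per combination. Because
of the contrast-table design above, the full four-channel model should match
or beat every single-channel model; the acceptance suite checks exactly
that with a reduced epoch budget (10 epochs per combination).

# Numerical and size choices

These are the package's own defaults, chosen so the full protocol runs on a
single CPU in minutes:

* acceptance-scale phantoms: 48³ voxels at 1 mm, brain semiaxes
  (13, 15, 12) mm (head plus shells fits the margin invariant with jitter);
* network: depth 3, base width 8, GroupNorm with 8 groups;
* training: 40 epochs, crop 16³ (divisible by the pooling factor
  $2^{D-1} = 4$), full augmentation, validation every 5 epochs. The
  modality-combination study uses the same budget: shorter budgets compare
  convergence speed rather than information content (multi-channel models
  converge more slowly per epoch but end higher);
* cohorts: 24 training, 6 validation, 10 test cases, mixed 50 % healthy /
  30 % pre-op / 20 % post-op.

GroupNorm (not BatchNorm) is used because batch size is 1; its statistics
are per-volume, so inference on full 48³ volumes after training on 24³
crops is well-behaved. All computation is double precision; determinism
holds bit-for-bit for a fixed seed and BLAS.
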