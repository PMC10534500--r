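---
title: "Predicting tablet dissolution from chemical images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tablet dissolution from chemical images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Sustained-release tablets built on a hydroxypropyl methylcellulose (HPMC)
matrix release their drug over many hours; the release rate is governed
mainly by two manufacturing properties of the HPMC: its w/w concentration
and its particle size. Both leave a visible signature in a chemical image of
the tablet face — a hyperspectral cube in which every pixel carries a Raman
or near-infrared (NIR) spectrum. `dissmap` implements the full inference
chain from such a cube to a predicted 37-point in vitro dissolution profile:

1. **Preprocessing** of every spectrum (modality-specific recipes),
2. **CLS unmixing** against the pure-component spectra, giving an HPMC
   concentration map,
3. two scalar image features: the **mean HPMC concentration** and a
   **CNN-regressed HPMC particle size**,
4. a **single-hidden-layer feedforward network** trained with Bayesian
   regularization that maps the two features to the dissolution profile,
5. **profile metrics**: the f2 similarity factor with the 85% truncation
   rule, RMSE, and R².

Because no measured spectra or dissolution curves are distributed with the
study this package follows, a synthetic-data module generates the whole
world — the formulation design, the tablet microstructure, the spectra and
the release curves — so every stage is testable end to end.

## The synthetic world

**Formulation design.** 36 compositions: drug 8%, MCC 20%, magnesium
stearate 2%, lactose as balance, with HPMC at seven levels from 10 to
30 w/w% crossed with four sieve fractions (<45, 45–63, 63–100, 100–150 µm)
for calibration, plus 8 validation compositions at intermediate levels.
Five tablets per composition were pressed in the original design; four went
to dissolution testing, so the generator's default is 4 replicates per
composition — 112 calibration and 32 validation records. Replicates receive
multiplicative Gaussian jitter (σ = 1% relative) on the HPMC fraction,
renormalized, to emulate tablet-to-tablet variation.

**Tablet faces.** A particle map places HPMC as non-overlapping disks with
diameters drawn uniformly from the sieve interval (the "<45" fraction uses
(0, 45) µm, midpoint 22.5 µm) until the realized area fraction is within
±0.02 of the target; area fraction stands proxy for w/w% (equal densities —
the same equivalence CLS itself assumes). Remaining area is the homogeneous
mixture of the other four components. Disks are rasterized by 4×4
subsampling per pixel. Two instrument geometries are emulated: 31×31 pixels
at 40 µm (Raman) and 48×48 at 25 µm (NIR), both covering ~1200×1200 µm².

**Spectra.** Pure components are sums of Gaussian peaks on a band index
axis: Raman-like spectra have 4–7 narrow, well-separated peaks; NIR-like
spectra 3–5 peaks roughly six times broader, so they overlap strongly. The
crux of the real unmixing problem — HPMC and MCC being nearly
indistinguishable, especially in NIR — is imposed explicitly: the MCC
spectrum is blended toward (or away from) HPMC until their Pearson
correlation hits a target, 0.6 for Raman and 0.92 for NIR by default.
All pure spectra are scaled to equal total area (an equal-spectral-response
assumption); this is what licenses the abundance → w/w% factor of 100 in
the CLS step. Pixel spectra are fraction-weighted sums of the pure spectra
plus an additive baseline plus i.i.d. Gaussian noise (default σ = 0.02
against peak intensities of order 1). The Raman baseline is a smooth
4th-order polynomial scaled by the **local MCC fraction** and an amplitude
of 2 — MCC-driven fluorescence that dominates the raw signal; NIR gets a
gentle global slope (amplitude 0.2) instead.

**Dissolution.** The ground-truth release model is Weibull,
F(t) = 100·(1 − exp(−(t/τ)^0.9)), with
τ = 300 min · (c/0.20)^1.2 · (45/d_mid)^0.5 for HPMC fraction c and sieve
midpoint d_mid (µm). τ increases with HPMC level and decreases with
particle size, so release is slower for more and finer HPMC — the two
monotonicities the pipeline must recover — and the curves span the 16-hour
window without all saturating. Measured-style profiles add Gaussian noise
(default σ = 1%), are clipped to [0, 100] and made non-decreasing. The
sampling grid is fixed: 2, 5, 10, 15, 30, 45, 60 min, then every 30 min to
960 min — 37 points, matching the ANN output width.

What a green test does *not* establish: the generator has no detector
physics, no 3-D tablet structure (surface maps only), no response-factor
asymmetry between components, and its release model is a two-parameter
Weibull — real formulations are harsher on every count. The tests establish
that the *pipeline machinery* recovers a stated world faithfully, not that
it would reach any particular accuracy on real spectra.

## Preprocessing

- **Savitzky–Golay** (window 15, 2nd-order polynomial): smoothing for
  Raman, first derivative for NIR. The derivative is taken per band index —
  no division by physical band spacing — because CLS is invariant to that
  scale when the library is treated identically. Edges use a
  shrink-window polynomial fit on the available points rather than padding,
  so no intensity is fabricated at the spectrum ends; the filter reproduces
  polynomials of the fit order exactly.
- **Whittaker baseline, asymmetric least squares** (λ = 10,000, p = 0.001):
  iteratively reweighted penalized regression with a second-difference
  penalty, weights p above / 1−p below the current baseline, at most 50
  iterations. Convergence is declared when the weight pattern settles *or*
  the baseline stops moving (tolerance 1e-6 relative); the second clause
  matters because near-tie pixels can oscillate their weights forever
  without moving the baseline. The solver is a banded (pentadiagonal)
  LDLᵀ factorization in C++, O(bands) per iteration.
- **Normalization**: total-area (Σ|x| = 1). The recipe's "normalization" is
  not further specified anywhere authoritative; area normalization is the
  common Raman chemometrics choice and keeps CLS linear up to a per-pixel
  scale. It is configurable (`vector`, `none`).

Raman recipe: smooth → subtract baseline → normalize. NIR recipe:
first derivative only. Pure libraries go through the same functions as
cubes, which is what makes CLS consistent.

## CLS unmixing

The unmixing operator is the pseudo-inverse of the preprocessed library,
`(S Sᵀ)⁻¹ S`; its condition number is reported because HPMC–MCC similarity
is exactly what inflates it. Abundances are unconstrained least squares
with negatives clamped to zero — no closure constraint — matching the
observation that CLS systematically under/over-estimates components; the
systematic bias is corrected only for reporting, by adding the difference
of means (`mean_shift_correction`), never on the path into the ANN, which
can absorb a constant bias itself. On noiseless, baseline-free synthetic
cubes the NIR recipe recovers the generator's fraction maps to 1e-6; the
Raman recipe (nonlinear baseline stage, per-pixel rescaling) recovers them
up to pixel-wise proportionality with slope ≈ 1.

## The particle-size CNN

Architecture per block: same-padded 3×3 convolution → ReLU → dropout (0.2)
→ batch normalization → average pooling; two blocks of 16 filters, then a
32-unit ReLU layer and one linear output. The regression target is the
upper sieve pore size (45/63/100/150 µm) — "the smallest pores the HPMC
passed through" — z-scored internally; predictions are de-standardized and
clipped to [22.5, 200] µm.

Two design choices deserve record:

- **Pooling is 4×4, not 2×2.** With 2×2 pooling the dense head holds ~25k
  parameters against 96 training maps and overfits badly (held-out MAE
  10–18 µm depending on seed). 4×4 pooling collapses 31 → 7 → 1 spatially,
  leaving ~3k parameters whose convolutional part computes local texture
  statistics and whose head sees their global average — structurally the
  right inductive bias for "how large are the blobs", and it brings
  held-out MAE to 4.6–6.9 µm across seeds and both geometries. A
  handcrafted-feature GAM oracle reaches ~2 µm, confirming the information
  is in the maps and the bottleneck was architectural.
- **Best-validation checkpointing.** Validation loss is computed every 5
  epochs (the stated schedule); the weights of the best validation epoch
  are restored at the end. With 96 training maps this measurably reduces
  seed-to-seed variance.

Training: Adam, initial learning rate 0.001 dropped by 0.9 every 10 epochs
(`lr(e) = 0.001·0.9^⌊(e−1)/10⌋`), at most 100 epochs, batch 16 (batch size
is not externally specified). The implementation is plain R — im2col
convolutions as matrix products, exact backpropagation verified against
numerical gradients — with feature maps kept in a flat pixel×channel matrix
layout for speed. One model per modality; no weight sharing, no
augmentation.

## The dissolution ANN and Bayesian regularization

A 2 → h → 37 network, h ∈ 1..10, tangent-sigmoid hidden units, linear
outputs, one output neuron per time point. Inputs and outputs are z-scored
on training statistics (tanh saturation). Training minimizes
F = β·E_D + α·E_W (E_D half the summed squared residuals, E_W half the
squared weight norm) by Levenberg–Marquardt with MacKay evidence updates
after every accepted step: γ = P − 2α·tr(H⁻¹), α = γ/(2E_W),
β = (N − γ)/(2E_D) — the classical "trainbr" recipe. Stopping: 1000-epoch
cap (the pipeline's desk-scale config uses 100 — LM converges in tens of
epochs on two-input data), objective-gradient ∞-norm below 1e-7, or LM
damping exhausted (µ > 1e10). The Gauss–Newton matrix JᵀJ is assembled
blockwise in closed form from the network structure rather than through the
explicit (N·37)×P Jacobian; the two paths agree to machine precision and
the structured one is what makes 100-model ensembles cheap. Setting
`regularization = "none"` fixes α = 0, reducing the objective to the plain
MSE path (verified against a hand-stepped LM oracle in the tests).

Model selection trains `runs` networks per hidden width from different
random initializations and keeps the one with the highest **mean validation
f2** (arithmetic mean over validation tablets, truncation rule applied).
The full-scale setting is 100 restarts × widths 1–10; the package default
is `runs = 10`, which exercises identical selection behavior at desk scale.
Per-run seeds derive deterministically from a master seed.

## Metrics

f2 = 50·log₁₀(100·[1 + (1/n)Σw(R−T)²]^(−1/2)). The −1/2 exponent is the
regulatory-standard form; a printed +0.5 variant would make f2 *increase*
with disagreement, contradicting its own use as a similarity score, and is
treated as a typo. Truncation keeps reference points up to and including
the first one above 85% release and is keyed to the *reference* (measured)
profile, per regulatory practice; fewer than 3 survivors is an error.
Weights default to 1. RMSE and R² are computed on the full 37-point grid
(no truncation), R² with the measured profile's variance in the denominator
(the standard form). f2 = 100 at identity; f2 = 50 corresponds exactly to a
mean squared difference of 99.

## Numerical choices and degenerate inputs

- Seeds: every randomized stage draws `derive_seed(master, counter)` from a
  fixed integer-hash splitter; all results, including report JSON files,
  are byte-identical under a repeated (config, master seed) pair.
- Rank-deficient CLS libraries (numerical rank < K) abort rather than
  silently regularize; near-collinearity is only warned about (condition
  number > 1e6).
- All-zero spectra cannot be normalized (degenerate-input error); a flat
  noiseless Raman spectrum therefore errors in the recipe's last stage,
  by design.
- Particle placement is rejection sampling capped at 10,000 attempts with a
  diagnostic error; disks that would overshoot the target fraction by more
  than half the tolerance are redrawn.
- ANN ensemble members that fail score −∞ and are logged, never silently
  dropped; ties in model selection resolve to the first maximum.
- Win counts between modalities split ties 0.5/0.5.

## Scale reductions relative to the full study

Desk-scale defaults keep the complete pipeline under ~6 minutes on one CPU:
ANN ensemble `runs = 10` (not 100) and a 100-epoch LM cap; the
ground-truth-input recovery benchmark in the acceptance suite uses 3
restarts over widths 1–5. All reductions change compute, not structure:
the selection logic, seed derivation and evaluation are identical at any
scale, and `runs = 100` reproduces the full-scale protocol.

## Known limitations

- The CNN sees concentration maps, not raw cubes; unmixing errors propagate
  into the size feature (by design, matching the two-stage protocol).
- The spatial model is 2-D disks; real HPMC particles are irregular and the
  imaged plane cuts them at random heights.
- The evidence framework assumes the Gauss–Newton Hessian approximation;
  with very small h the γ estimate can pin to its bounds.
- `read_dataset` restores particle maps without their placed-particle
  lists (fractions are the ground truth that matters downstream).
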