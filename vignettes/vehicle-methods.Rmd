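---
title: "Enhancing Hi-C contact maps with a variationally encoded adversarial model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enhancing Hi-C contact maps with a variationally encoded adversarial model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vehicle)
```

## The problem

A Hi-C experiment measures pairwise contact frequencies between genomic
loci; binned at a resolution (here 10 kb), one chromosome becomes a square,
symmetric contact matrix. Downstream structures — topologically associating
domains (TADs), loops, stripes — are only callable when coverage is deep
enough for the chosen bin size; shallow experiments give sparse, noisy maps.
`vehicle` implements a resolution-enhancement model: a convolutional
generator, conditioned on a low-coverage map, is trained adversarially to
output a map that looks and *behaves* like the matched high-coverage map.

## The model

Training is two-phase. First a variational autoencoder (VAE) is fit to
high-coverage windows; then its frozen encoder becomes a feature extractor
inside the composite objective of a conditional GAN.

**Windows.** Chromosome maps are balanced (Knight-Ruiz), scaled to
`[0, 1]`, and cut into diagonal windows of 269 x 269 bins (2.69 Mb at
10 kb) moved with a stride of 50 bins, so consecutive windows overlap by
219 bins and every contact within 2 Mb of the diagonal falls in at least one
window. The window size is chosen so a whole typical TAD fits inside one
sample; the generator's valid convolutions shrink each side by 12 bins, so
targets are the center 257 x 257 crop. Trailing partial windows at
chromosome ends are dropped. Scaling to `[0, 1]` is a percentile clip
(default 99.9th, computed chromosome-wide) followed by division, so rare
extreme counts saturate at 1 instead of crushing the rest of the dynamic
range. Chromosomes are split non-sequentially (train
1,3,5,6,7,9,11,12,13,15,17,18,19,21; validation 2,8,10,22; test 4,14,16,20)
so each set mixes large and small chromosomes.

**VAE.** The encoder applies 7 strided convolutions (kernel 3, stride 2,
pad 1; filter counts 32, 64, 128, 256, 256, 512, 512), each followed by
leaky ReLU and batch normalization, then two affine heads give the
posterior mean and log-variance of a 128-dimensional latent code. The
decoder mirrors this with transposed convolutions (512, 512, 256, 256, 128,
64, 32), a 1 x 1 output projection and a sigmoid, reproducing the input
side exactly. With this stride arithmetic a side `s` maps to `(s + 1) / 2`,
so the input side must be of the form `2^L * m + 1`; 257 is the smallest
such side spanning more than 2 Mb, which is what fixes the window geometry.
Strides and kernel sizes per layer are this package's choice — only the
filter counts and the layer count are fixed by the published architecture —
selected so every intermediate dimension is a whole number and the
decode(encode(x)) round trip preserves shape. The training loss is the
per-sample sum of squared reconstruction errors (the tractable surrogate
for the decoder log-likelihood) plus the closed-form KL divergence of the
posterior from the unit Gaussian prior,
`KL = -0.5 * sum(1 + logvar - mu^2 - exp(logvar))`, with the KL weight
annealed linearly from zero so early training is free to fit
reconstructions before the prior is enforced.

**Generator and discriminator.** The generator is a residual network: a
valid 3 x 3 convolution, 15 residual blocks of 64 filters (two padded
convolutions with batch normalization each, additive skip), a valid
convolution whose output is summed with the cropped head features, four
more valid convolutions, and a sigmoid output so enhanced maps live in
`[0, 1]` (values below zero would break the probabilistic VAE input
contract). The six valid convolutions shrink each side by 12 in total. The
discriminator is fully convolutional (strided 3 x 3 convolutions with 32,
64, 128 filters, ReLU, batch normalization) with global average pooling and
a sigmoid score.

**Composite objective.** The generator minimizes

`L_tot = 0.0025 * L_adv + 1 * L_mse + 0.01 * L_vae + 1 * L_ins`

with the four terms:

* `L_adv = sum(-log D(G(x_low)))` — the non-saturating adversarial loss
  (inside the training gradient it enters as a batch mean so the operating
  point does not depend on batch size);
* `L_mse` — bin-wise squared error divided by the number of bins. The
  published formula is labeled mean *squared* error but printed with an
  absolute value; the squared form is the default and the absolute reading
  is available as a configuration option (`mse_form = "absolute"`);
* `L_vae` — mean absolute difference between the latent posterior means of
  the enhanced and target windows under the frozen encoder (the posterior
  mean, not a sample, so the loss is deterministic);
* `L_ins` — mean absolute difference between the *delta insulation
  vectors* of enhanced and target, computed by a differentiable
  re-expression of the insulation TAD pipeline (below).

The discriminator minimizes the standard binary cross-entropy against real
high-coverage crops and enhanced outputs, with one discriminator update per
generator update. All logarithms are guarded by small epsilons.

## The insulation pipeline

The insulation score of bin `i` is the total signal in a `w x w` square
(default `w = 20` bins = 200 kb) sliding along the diagonal; this package
places the square over bins `[i - w/2, i + w/2)`, so the vector has length
`N - w`. Scores are normalized as `log2(raw / mean(raw))`, which cancels
any global rescaling of the map. The delta vector contrasts the mean
insulation over the `d = 10` bins (100 kb) downstream of `i` against the
mean over the `d` bins ending at `i` (the trailing window includes `i`
itself); with that convention the composed length is exactly
`N - w - (2d - 1)` — the published bookkeeping formula, which is why a
40-bin axis yields a single delta value and why meaningful insulation
features need the large 269-bin windows.

Boundaries are insulation valleys: positions where delta crosses zero from
negative to positive. The interpolated crossing is assigned to the nearer
bin (a crossing exactly at zero counts as the non-negative side). Boundary
strength is the amplitude of the delta swing through the crossing — the
nearest local maximum to the right minus the nearest local minimum to the
left, with series ends counting as extrema — and boundaries with strength
at most 0.1 are discarded. Under the original upstream-minus-downstream
sign convention of the Crane insulation method these same extrema are the
"left local max" and "right local min"; with the downstream-minus-upstream
sign used here (chosen so valleys give negative-to-positive crossings) the
left/right roles of the extrema swap, while the amplitude — and hence every
called boundary — is identical. Sweeping which flanking extrema to use is
the one genuinely ambiguous reading of the procedure; the amplitude
interpretation is the only one that assigns strong boundaries a large
strength under both sign conventions.

For the training loss the pipeline (block sums, log2, mean differences) is
expressed end-to-end in smooth primitives with an additive guard
`eps = 1e-8` inside the logarithm, so the gradient with respect to every
matrix entry exists even when a window sum is zero; the package's tests
verify the differentiable operator agrees with the plain pipeline to 1e-5
and that its hand-derived gradient matches central finite differences.

## Balancing

Knight-Ruiz balancing is implemented as a symmetric fixed-point iteration
`d <- d / sqrt(rowsum / mean(rowsum))` on the unmasked submatrix, with the
contract that all unmasked row sums of `D A D` agree to a relative
tolerance (default 1e-6). Zero-marginal bins (unmappable regions) are
masked before balancing and restored as zero rows and columns. The test
suite checks the result entrywise against an independent alternating
row/column Sinkhorn scaling.

## The synthetic generator

Real Hi-C from GEO is far beyond desk scale, so the package ships a
generative fixture with exactly the features the losses see: expected
contacts follow a power-law distance decay `(1 + |i - j|)^-alpha`
(`alpha = 1`, the canonical intra-chromosomal exponent), multiplied inside
planted TAD intervals by an enrichment factor, plus additive Gaussian
corner-loop bumps and decaying stripe terms; counts are Poisson draws,
symmetrized, and low-coverage data is emulated by binomial thinning of each
upper-triangle count (`Binomial(c, keep)`, mirrored). Thinning with
`keep = 1/16` reproduces the order-of-magnitude coverage gap between the
deep combined map and a single sequencing run.

What the generator does *not* emulate: A/B compartment plaid structure,
trans contacts, restriction-fragment-level digestion bias, and —
importantly — the *independent* systematic biases of a genuinely separate
low-coverage experiment. Binomial thinning is coupled to the deep map and
unbiased, so quantities that average many bins (the insulation vector sums
400 cells per window) are almost untouched by it; the downsampled baseline
is therefore much harder to beat on insulation similarity here than a real
low-coverage experiment would be, and a passing improvement on that metric
at desk scale is a correspondingly strong result. Conversely, passing tests
on this fixture demonstrate the machinery optimizes and generalizes in the
intended directions, not that the published effect sizes transfer to any
particular real dataset.

## Desk-scale study conditions

The package's end-to-end harness (used by the test suite) runs the full
two-phase pipeline at reduced geometry: synthetic chromosomes of 300 bins,
windows of 69 bins (enhanced crop 57 = 2^3 * 7 + 1, so a 3-layer VAE with
filter counts 8, 16, 16 has exact shape round-trip), stride 15 (the 269/50
window-to-stride ratio, scaled), a 16-dimensional latent space, a generator
with 2 residual blocks of 16 filters, Adam with a constant step size of
1e-3, 20 VAE epochs and 40 GAN epochs on three training chromosomes with
one held out (longer schedules kept lowering the training loss but began
to overfit the small window set, so the epoch budget doubles as the
regularizer). These sizes are the smallest at which every component is
exercised meaningfully: the 57-bin crop still yields an 18-element delta
vector for the insulation loss, and three chromosomes provide enough
windows (about 48) that held-out improvement is not a fluke of
memorization.

## Numerical choices

* All randomness is seeded explicitly: weight initialization, batch
  shuffling, the reparameterized latent draw, Poisson/binomial simulation.
  Training twice with the same seed reproduces the loss trajectory and the
  final weights exactly.
* Optimizer is Adam (beta1 0.9, beta2 0.999) throughout; learning rates and
  epoch counts are configuration fields since the publication does not state
  them. An optional step decay halves the rates every `lr_decay_every`
  epochs.
* Batch normalization uses batch statistics during training and running
  statistics at inference; backpropagating *through* a frozen network (the
  encoder inside `L_vae`, the discriminator inside `L_adv`) treats the
  normalization as the affine map its running statistics define.
* The log-variance head is soft-clamped to `[-8, 8]` during VAE training;
  outside that range the clamp's gradient is zero.
* SSIM uses a Gaussian-weighted 11 x 11 window with sigma 3 and stabilizers
  `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L = 1` for unit-scaled maps
  (the standard constants; the publication states only the window size and
  sigma), evaluated over fully covered window placements.
* The signal-to-noise ratio of identical maps is reported as `Inf` rather
  than raising an error.
* Reassembling enhanced windows into a chromosome places each 257-bin
  output at diagonal offset `start + 6` and averages overlapping
  predictions entrywise; bin pairs never covered by any window are `NA`
  with coverage 0, never fabricated.

## Limitations

* The networks run on a single CPU; the default 15-block, 64-filter
  generator is practical for inference (a 269-bin window enhances in
  seconds to minutes depending on BLAS), but full-size training at the
  published window geometry is out of reach without accelerators — which is
  exactly what the desk-scale harness is for.
* `.cool` access shells out to the `python`/`h5py` on `PATH`; the two
  native formats (dense text, dense binary) have no external dependency.
* The window counts printed for the hg19 dataset assembly (3309 training /
  1051 validation / 798 test) are not reproducible from chromosome lengths
  alone: counting every stride-50 placement on full hg19 autosome lengths
  gives about 9% more windows, the excess matching placements that overlap
  assembly gaps (centromeres, acrocentric short arms). The original
  pipeline evidently dropped windows from empty regions of the real
  matrices; `expected_window_counts()` implements the documented
  drop-partial rule and therefore reports the larger numbers.
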