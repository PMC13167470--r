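---
title: "Splitting superimposed fluorescence channels: model, objective and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting superimposed fluorescence channels: model, objective and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Multiplexed fluorescence imaging acquires one channel per labeled
structure, which costs photon budget and acquisition time. An alternative
is to image several structures *at once* into a single channel and split
the superimposed image computationally, using the distinct structural
appearance of each label rather than spectral separation. `vsplit`
implements this semantic unmixing as a supervised-plus-unsupervised
learning problem: a network maps one noisy superimposed image to `k`
denoised structure channels, and, because the network is variational, it
can sample alternative plausible splits and report where its prediction is
uncertain.

## Model

The network is a hierarchical variational encoder-decoder (ladder-VAE
family), except that it is not an autoencoder: the decoder's target is the
set of unmixed channels, not the input. Components:

* **Bottom-up encoder.** A convolutional stem at full resolution, then one
  block per hierarchy level. Spatial resolution halves per level through
  average pooling.
* **Lateral context (LC).** Each prediction is made for a primary patch
  (default 64 x 64); context patch `l` covers a `2^l`-times larger window
  centered on the same spot, block-averaged down to the primary pixel
  dimensions. At a context-bearing level the pooled primary features are
  zero-padded to the primary patch size — placing them in the *center* of
  the context window's downscaled coordinate frame, which is where the
  primary patch physically sits — and concatenated with the output of a
  pooling-free input branch that digests the matching context patch.
  Merged maps therefore keep the primary patch's pixel dimensions at every
  context level.
* **Top-down stochastic decoder.** The top level draws a latent from a
  posterior inferred from the deepest features against a standard-normal
  prior; every lower level has a conditional prior predicted from the
  top-down state and a posterior inferred from that state plus the
  bottom-up features. Moving one level down, the state is re-aligned into
  the finer level's coordinate frame: a plain 2x upsampling where the
  grids double, and a center-crop of the inner half followed by 2x
  upsampling where both grids have primary size (the context-level case
  — the inner half of a context frame *is* the next finer frame).
  Upsampling is bilinear, implemented as nearest-neighbor duplication
  followed by a fixed separable [1,2,1]/4 smoothing (whose symmetric
  stencil makes the gradient pass the same operator). A final
  full-resolution block and a 3x3 head emit per-channel means and
  log-variances.
* **Variants.** `lean_lc` uses single convolutions per block; `deep_lc`
  adds a third input-branch convolution and extra merge/top-down/output
  convolutions. Two hierarchy levels, 16 base filters and one context
  level make up the desk-scale preset used throughout the tests;
  full-scale presets follow the reference protocol (`L = 2`, i.e.
  `multiscale_lowres_count = 3`).
* **3D.** Convolutions are applied per z-slice with shared weights
  (z folded into the batch axis); the volumetric treatment specific to
  this method is in the KL term (below). A learned receptive field along
  z is a known limitation of this implementation.

There is no deep-learning framework in this package's dependency
footprint; the network runs on a small built-in reverse-mode autodiff
engine (`R/autodiff.R`) whose convolutions are compiled C++ loops over
BLAS matrix products. Every operator is finite-difference gradient-checked
in the test suite.

## Objective

The loss is a weighted average of two branches sharing one set of KL
terms:

```
loss = w * loss_denoise + (1 - w) * loss_direct
```

with `w = 0.9` by default. `loss_direct` is the Gaussian negative
log-likelihood of the (noisy) targets under the predicted means, with
learned per-pixel variance by default. `loss_denoise` scores the noisy
targets under a *pixel noise model* `p(obs | clean)` evaluated at the
predicted clean signal; because the noise model absorbs the noise
statistics, the maximizing prediction is the clean signal and the network
denoises without ever seeing clean data. Setting `w` to 1 or 0 recovers
the pure noise-model or pure direct objective.

**Center-cropped KL.** With LC inputs the latent tensors keep the primary
patch's spatial size, so summing the pixel-wise KL would scale with the
(context-inflated) number of summands and overweight the KL against the
likelihood. The pixel-wise KL at level `i` is therefore center-cropped to
the shape it would have without LC inputs before summation — which is also
exactly the region corresponding to the primary patch in the level's
coordinate frame.

**z-averaged KL (3D).** For volumetric data the pixel-wise KL is averaged
along z before the cropped summation, making the scalar invariant to the
number of input planes; otherwise adding z-context would be penalized.

**KL weight `alpha`** is not stated numerically by the reference
protocol; the default here is `1 / n_pixels` of the cropped latent shape
per level (a per-pixel-normalized KL), with a config override. In the
training graph the likelihood terms are also normalized per pixel — a
monotone rescaling that does not change minimizers but keeps the two
scales comparable across patch sizes.

**KL warm-up.** At desk scale the KL initially dominates and collapses
the posterior onto the prior before the likelihood can make the latents
informative (the classic ladder-VAE failure). `train_config()` therefore
anneals the KL weight linearly over `kl_warmup_epochs` (default 3).
Latent log-variance biases are initialized at -2 for the same reason.
Free-nats floors are available (`kl_free_nats`) but default to 0 to match
the printed objective.

## Noise models

Three families: a plain Gaussian; an analytic Poisson-Gaussian
(`variance = a * signal + b^2`), which is the generator-matched default in
the pipelines; and a Gaussian mixture over residuals fitted from
co-registered (reference, noisy) calibration pairs by EM, optionally with
signal-binned, polynomial-smoothed component scales (`degree > 0`). EM is
used rather than generic gradient ascent because, for this 1D mixture
family, it is the standard and far more stable maximizer of the identical
likelihood. Signals outside the fitted `signal_range` are clamped, and the
training gradient is taken at the clamped point (straight-through) so that
the denoising branch keeps pulling out-of-range predictions back rather
than going silent — with a hard zero gradient outside the range, half of
all pixels receive no denoising gradient at initialization.

## Training protocol

Defaults mirror the reference protocol: Adamax, learning rate 0.001,
batch 32, up to 400 epochs, reduce-on-plateau on the validation loss with
patience 150 (factor 0.5, floor 1e-6, both unstated upstream and set to
conventional values). One "epoch" is `steps_per_epoch` freshly sampled
batches — patch sampling has no natural dataset pass, so the epoch length
is configuration (default 20 batches). The desk-scale preset shrinks
epochs/batches and raises the learning rate to 0.003 so that training
completes in minutes on one CPU; the tests document this explicitly.

## Inference and uncertainty

For a trained model, `S` posterior samples (reference protocol: 50) are
drawn per input; their pixel-wise mean approximates the MMSE prediction
and their pixel-wise (unbiased) standard deviation estimates the
pixel-wise RMSE. Full frames use *inner tiling*: overlapping 64 x 64
tiles whose central 32 x 32 regions partition the frame exactly once
(edge tiles shift inward), samples averaged per tile before stitching.
Calibration is assessed by binning pixels into predicted-uncertainty
quantiles and comparing per-bin RMV (root mean predicted variance)
against per-bin RMSE (root mean squared error against a reference): a
calibrated model shows slope about 1 and high rank correlation, and
`fit_calibration_scale()` provides an optional multiplicative correction
(default: not applied).

## Synthetic phantoms: what they emulate, what they do not

The generator renders four structural archetypes — random-walk filaments,
soft anisotropic blobs, Gaussian puncta and annular rings — spanning the
morphology classes of typical fluorescence targets (cytoskeleton, nuclei,
vesicles/kinetochores, envelopes). Training pairs are assembled in the
four canonical modes: co-located channel sums (I), sums of independently
located crops (II), sums of manually isolated pure-structure crops (IIb;
lateral context must be disabled because such crops are small), and a
separately "acquired" superimposed frame carrying its own noise
realization (III). Noise is Poisson-Gaussian with controllable photon
scale and read noise, applied once per frame like a real acquisition.
The scaled-copy task reproduces the structural-similarity stress test:
two independently located crops of the *same* structure image, the second
scaled by `s >= 1` (`s = 1` being the provably ambiguous case).

Stated-world defaults for the desk-scale tests, chosen once: 192 x 192
training frames; filaments at density 5e-4; spots at density 2e-3 with
doubled size (sigma 2-4 px) and peak amplitudes 120-180 versus 80-120 for
filaments (so each structure carries comparable loss mass — with
equal-amplitude 1-2 px spots, the sparse-spot channel trains far more
slowly than desk scale permits); read noise sigma = 35 with photon scale 5
(low enough SNR that denoising visibly pays off). What a green test
establishes is that the *mechanism* unmixes, denoises and calibrates on
structurally distinct phantoms at toy scale; it does not establish
performance on real micrographs, on highly skewed mixtures, or at
publication scale.

Phantoms are flat 2D worlds: no point-spread function, no spectral
bleedthrough, no axial structure (3D stacks replicate a plane), no
intensity nonuniformity.

## Numerical choices

* Center crops and pads drop/add the extra pixel on the trailing side for
  odd margins; fixed and documented in `kl_loss_cropped()`.
* Latent and output log-variances are clamped to [-8, 8].
* Posterior sample s.d. uses the unbiased (n-1) estimator.
* LC downscaling is area (block) averaging; boundary handling for context
  windows is reflection by default (zero padding available) — a dark
  border would leak into context statistics.
* All randomness flows from explicit seeds; a global seed fans out to
  per-module seeds via a fixed hash (`derive_seed`).

## Known limitations

* Desk-scale capacity: the tiny preset trades accuracy for minutes-scale
  CPU training; expect MMSE correlations around 0.8-0.9 on the bundled
  phantoms, not publication-grade PSNR. Two consequences are visible in
  the test suite and deliberately left as failing assertions rather than
  weakened: (1) on the bars-vs-spots task the MMSE of the thin-filament
  channel does not beat the noisy acquisition's PSNR — the 50-sample
  average hedges over sub-resolution stroke positions, systematically
  under-predicting filament intensity (the compact-spot channel, which is
  resolvable at the half-resolution latent grid, beats its noisy
  acquisition comfortably); this is the perception-distortion trade-off at
  toy capacity. (2) In the scaled-copy task at factor 2, the bright copy
  is recovered well but the dim copy converges too slowly for the desk
  budget — the delayed-inflection behavior expected when channels are
  structurally identical.
* No genuine 3D receptive field (per-slice convolutions; z enters only
  through the KL average).
* The microscopy-adapted multi-scale SSIM here fixes its own parameters
  (Gaussian windows of s.d. 1.5 px, 3 dyadic scales, equal weights,
  1st-percentile background subtraction, affine normalization); it
  satisfies the same invariances as the published microscopy variant but
  is not guaranteed numerically identical to it. The same caveat applies
  to the affine-fit PSNR.
* Thin, high-frequency structures (1-2 px filament profiles) remain the
  hardest content for the half-resolution latent hierarchy; bilinear
  upsampling and the full-resolution output block compensate only
  partially at desk-scale capacity.
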