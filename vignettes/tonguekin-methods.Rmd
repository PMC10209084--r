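---
title: "Tongue kinematics, shape and decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tongue kinematics, shape and decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonguekin)
```

The tongue is a muscular hydrostat: a jointless, volume-conserving organ
whose movement cannot be summarised by joint angles. `tonguekin`
implements an analysis pipeline for marker-based 3D tongue kinematics
during feeding and for decoding those kinematics from cortical spiking:
standard kinematic variables, a Procrustes shape space, a causal LSTM
sequence decoder evaluated by fraction of variance accounted for (FVAF),
and population-level statistics. Because marker-based feeding recordings
with simultaneous cortical data are not publicly distributable, the
package ships a synthetic-data generator that emulates their statistical
structure, so every stage is testable end to end.

## Kinematic variables

The marker constellation has seven tongue markers (tip, anterior
superficial left/right, anterior deep, middle superficial left/right,
posterior deep) tracked at 200 Hz in the cranial frame, with X
anteroposterior (positive anterior), Y superoinferior and Z mediolateral.
Marker coordinates and rigid-body transforms are low-pass filtered with a
zero-lag Butterworth filter (30 Hz cutoff, 2nd order applied
forward-backward, so 4th-order effective) before any variable is
computed. The filter subtracts the series mean before filtering — DC
passes exactly — and damps edge transients with an odd (point-reflected)
extension.

The seven standard tongue variables, plus jaw pitch:

* **Sagittal flexion** (degrees): the planar angle at the middle
  superficial vertex between the posterior deep marker and the tip. With
  left and right middle superficial markers, the vertex is their
  midpoint. Coincident markers make the angle undefined; those frames
  are flagged `NA` with the frame index in a warning.
* **Protrusion** (mm): mean anteroposterior (X) position of the three
  anterior-most markers.
* **Roll** (degrees): a pseudo-rigid-body estimate. The rest
  constellation of the anterior six markers (all but the posterior deep)
  is fitted to each frame by a rigid rotation + translation (Kabsch,
  determinant forced positive so reflections never appear). The rotation
  is decomposed as intrinsic X-Y-Z Tait-Bryan angles and the X
  (anteroposterior) component is the roll. The intrinsic X-Y-Z order was
  chosen so that a pure rotation about the anteroposterior axis is
  recovered exactly. The decomposition is performed in the reference's
  anatomical frame (the `axes` argument), which keeps roll invariant
  when the whole scene — markers and reference — is rigidly moved.
* **Regional lengths and widths** (mm): straight-line distances between
  marker pairs — anterior length (tip to anterior deep), middle length
  (anterior deep to posterior deep), anterior width and middle width
  (the left/right superficial pairs).
* **Jaw pitch** (degrees): the mandible-relative-to-cranium transform is
  computed per frame (mandible transform pre-multiplied by the inverse
  cranium transform) and its rotation about the inter-condylar axis —
  the primary axis of a temporomandibular joint coordinate system — is
  extracted as the angle of a condyle-orthogonal direction's image in
  the plane orthogonal to the axis. This projection is exact for pure
  rotations about the axis and additive under their composition.

## Procrustes shape space

Tongue *shape* is separated from position and orientation by
superimposition: every frame's 7 x 3 configuration is centered, scaled
to unit centroid size, and rotated onto an iteratively refined consensus
(Generalized Procrustes Analysis). The superimposition is *constrained*:
the fitted rotation always has determinant +1, so reflections are never
introduced. Scale removal defaults on (`allow_scale = TRUE`) and is
exposed as a flag, because rigid-only superimposition is also a
defensible reading; with scaling off, centroid size differences remain
part of "shape".

GPA iterates to a consensus tolerance of 1e-10 (RMS change) with a cap
of 100 iterations; non-convergence warns and returns. The consensus is
then rotated onto its principal axes with a deterministic sign
convention, which makes the whole alignment — and everything downstream
— invariant to an arbitrary rigid motion applied to the raw data.

PCA of the aligned, flattened coordinates (7 markers x 3 = 21
dimensions, column-mean-centered) yields the shape components; the
scores of the first 7 are the "complex deformation" variables. Component
signs are fixed deterministically (largest-magnitude loading positive)
so decoded-score comparisons are stable across fits. Two numerical
caveats are documented rather than hidden: (1) projecting the mean
configuration returns scores that are zero only to second order in the
shape dispersion, because the mean of unit-size shapes has centroid size
slightly below one; (2) centroid size is normalised per frame
(standard GPA); a single global normalisation is a defensible
alternative and would change scores only through per-frame size
variation.

Reconstruction inverts the projection (`mean + basis %*% scores`),
reported in consensus coordinates; multiplying by the mean centroid size
of the raw frames expresses errors in mm.

## The synthetic feeding session

The generator's defaults describe one recorded session: 28 trials of
6-10 s at 200 Hz. Kinematics are driven by smooth latent modes sharing a
jittered ~1.5 Hz chew phase — sagittal bending, axial roll (an exact
rigid rotation about an anteroposterior axis, so the roll variable has a
known ground truth), anteroposterior protrusion, regional length/width
scaling — plus one or two swallow-like raised-cosine transients per
trial that elevate the posterior markers, and a mandible pitching in
phase with the chew cycle about the inter-condylar axis. An onset/offset
envelope brings every trial to rest at its edges. Gape-cycle labels
(stage 1 transport, chew, swallow, stage 2 transport) mark every frame.
The rest constellation uses fixed, arbitrary coordinates with order-10 mm
inter-marker spacing; real inter-marker geometry is animal-specific and
deliberately not matched.

Spiking populations follow a lag-tuned encoding model: for neuron $i$
with unit-norm weights $w$ over the z-scored kinematic variables
$z(t)$,

$$\lambda_i(t) = \mathrm{softplus}\left(b + g \sum_v w_v\, z_v(t - L_i)\right),$$

with $b$ set so a flat input gives the 10 spikes/s base rate, gain
$g$ = `tuning_snr`, and per-neuron lags $L_i$ drawn from -120 to -20 ms
for the M1-like population (negative = neural activity leads movement).
The SC-like population receives a positive +50 ms lag offset and a
weaker gain (x 0.35), so motor/sensory region contrasts are testable by
construction. Spikes are inhomogeneous Poisson at the 5 ms frame
resolution. The softplus keeps rates positive and differentiable; with
`tuning_snr = 0` neurons are exactly homogeneous Poisson. A single
master seed fans out into per-trial and per-neuron substreams, so any
subset of the session is reproducible on its own.

The default `tuning_snr` of 1.5 gives moderately informative populations
(a causally smoothed linear readout of 100 neurons reaches roughly
R² 0.3); `tuning_snr = 4` is used as the package's *strong-encoding*
condition in the decoding demonstrations, where the kinematics are
recoverable with high accuracy. What passing tests on this generator
show is that the pipeline's machinery — variables, shape space, decoder,
statistics — recovers known ground truth from realistic spike trains; it
does not show that real cortical populations encode these variables, nor
does the generator reproduce real data's non-Poisson firing,
behavioural irregularity, electrode noise, or marker-tracking error.

## Causal decoding

Each variable is decoded independently (one network per variable) from
binned spikes: 5 ms bins, tied exactly 1:1 to the 200 Hz kinematic
frames — no resampling path exists. The decoder is a single-layer LSTM
with a linear readout, implemented in the package (RcppArmadillo) with
batched backpropagation through time and Adam. Correctness of the
gradients is established against finite differences in the test suite.
Inference unrolls strictly stepwise, so the prediction at bin $t$
depends only on bins $\le t$; this causality contract is asserted by
truncation tests on every trained model in the acceptance suite.

Inputs are z-scored per neuron and the target z-scored, both with
training-set statistics; predictions are de-normalised. Training
details, all exposed in `decoder_hyperparams()`:

* `hidden = 200` units by default, the scale typical of sequence
  decoders in motor neuroscience. The demonstration analyses in this package use 48 units with 25
  epochs at learning rate 0.01 — accuracy on the synthetic session is
  insensitive over this range, consistent with the general observation
  that decoder hyperparameters matter little within a broad envelope,
  and the smaller network keeps a full multi-variable cross-validation
  at desk scale.
* Training sequences are split into chunks of `chunk_len = 400` bins
  (2 s), which multiplies the number of optimizer updates per epoch; the
  hidden state resets per chunk during training only.
* A mid-trial validation segment (`val_frac = 0.15` of each training
  trial) drives epoch selection: the returned weights are those of the
  epoch with the lowest validation MSE. This early stopping is what
  makes the sequence-shuffle null behave correctly — on uninformative
  inputs the selected model stays near its constant-output
  initialisation instead of memorising training sequences, so shuffled
  FVAF sits near zero rather than strongly negative. The segment is
  taken mid-trial because trials start and end at rest, and a resting
  validation tail would select for predicting quiescence. A decoupled
  weight decay (0.02) adds mild regularisation.
* Adam with global gradient-norm clipping at 5; weight initialisation
  and batch order come from a dedicated deterministic RNG, so training
  is bit-reproducible given the seed.

Cross-validation follows the rotating scheme: trials are randomly
assigned to 7 folds; one fold is reserved for hyperparameter selection
and never serves as a test set; each remaining fold is tested once,
training on all other trials (28 trials: 4 test / 24 train). Note the
reserved fold's trials do appear inside the 24-trial training sets; only
its role as a test set is excluded. The per-fold score is the FVAF,

$$\mathrm{FVAF} = 1 - \frac{\sum_t (y_t - \hat y_t)^2}{\sum_t (y_t - \bar y)^2},$$

computed on the concatenated test trials of the fold (per-trial scoring
is an option); it can be negative. Analyses that train many decoders
(the single-neuron screen) use a reduced scheme in which 3 of the
rotating folds are randomly selected as test folds.

## Population analyses

* **Region comparison**: equal-size ensembles (default n = 55) from each
  region decode identical targets; per-variable mean FVAFs are compared
  with a paired two-sided Wilcoxon signed-rank test, exact for <= 20
  pairs. All-zero differences are degenerate and reported as p = 1 with
  a warning.
* **Ensemble-size sweep**: random without-replacement sub-populations at
  each size (default grid 1-100, 10 draws per size, chosen to bound the
  number of trained decoders while covering the curve's rise and
  plateau). Kinematic variables are averaged unweighted; shape variables
  are weighted by their fraction of shape variance explained. Draws are
  kept in canonical pool order so a full-population draw reduces exactly
  to the standard cross-validation.
* **Single-neuron screen**: neurons passing a mean-rate filter
  (> 3 spikes/s) are screened with single-neuron decoders under the
  3-fold reduced scheme; per-variable accuracies are pooled and the
  positive-FVAF values retained — the right tail of the performance
  distribution. Whether the screened subsample is drawn at random among
  rate-passing neurons or taken as the top performers is a config
  choice (`selection`), since either reading of a "high-performing
  subsample" is defensible.
* **Sequence shuffle**: a derangement of the neural-kinematic pairing
  across feeding sequences (no sequence keeps its own pairing; length
  mismatches truncate to the shorter member). Marginal spike statistics
  are preserved while the correspondence is destroyed.
* **Permutation test**: per shuffle iteration (10 by default), a
  two-sample permutation test of observed vs shuffled accuracies with
  the *mean of the fourth quartile* (values at or above the 75th
  percentile, linear interpolation) as statistic, 10,000 label
  permutations, p = (1 + #{null >= observed}) / (n + 1), and the
  maximum p over iterations reported — the conservative choice. Several
  constructions could pair the unshuffled and shuffled values; the
  two-sample scheme implemented here is the one that makes the
  quartile-mean statistic well defined, and the suite verifies its
  calibration (uniform p under a simulated null) and its agreement with
  exhaustive enumeration on small cases.
* **Tongue-jaw correlation control**: mastication correlates the tongue
  with the jaw, so high decoding accuracy could in principle be
  inherited from jaw coupling. Sliding windows (defaults 1 s window,
  0.25 s step — values chosen to resolve individual chew cycles) yield
  per-window Pearson correlation with jaw pitch and windowed FVAF; the
  summary is the accuracy distribution within the least-correlated
  quartile of windows. Windows with constant series are skipped and
  counted.

## Degenerate inputs and numerical choices

Collinear marker configurations make the Procrustes fits rank-deficient
and are rejected with the frame named. Deformation amplitudes large
enough to drive markers within 1 mm of each other are rejected at
generation time. Constant truth series make FVAF undefined (`NA` with a
warning). Spike times outside a trial span are an error listing the
offenders. CSV round trips are lossless to well below 1e-9 mm (12
significant digits).

## Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(tuning_snr = 4, seed = 7)
ds  <- make_dataset(cfg)
ds  <- add_shape_scores(ds, k = 7)

cv <- cross_validate(ds, "roll",
                     hyperparams = decoder_hyperparams(hidden = 48,
                                                       epochs = 25,
                                                       lr = 0.01),
                     seed = 1, n_eval_folds = 2)
cv
```

The problem sizes used by the test suite and the acceptance script — a
48-unit decoder, 25 epochs, 2 evaluation folds on the 28-trial session —
are the package's demonstration scale; all analyses accept the full
6-fold scheme and larger networks through the same interfaces.

## Known limitations

The generator has no biomechanical tongue model (no muscle activations,
no volume conservation) and no X-ray imaging artefacts; its latent modes
are low-dimensional by construction, which flatters the shape PCA's
concentration of variance relative to real tongues. The decoder is a
single-layer network without hyperparameter search. Shape spaces are
per-dataset: components are not registered across subjects or sessions.
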