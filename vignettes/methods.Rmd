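---
title: "Domain-generalized motor-imagery EEG decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-generalized motor-imagery EEG decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A motor-imagery brain-computer interface decodes which movement a person is
imagining from their EEG. Imagined movement attenuates band power of the
sensorimotor rhythms — event-related desynchronization (ERD) — in the theta
(4–7 Hz), alpha/mu (7–13 Hz) and beta (13–32 Hz) bands over motor cortex,
with hand imagery lateralized to the contralateral hemisphere. A classifier
trained on one person rarely transfers to another: electrode placement, skull
geometry and idiosyncratic rhythms shift the joint distribution of signals
and labels between subjects. Domain generalization (DG) asks for a model
trained only on *source* subjects that works on an unseen *target* subject,
with no target data at training time — the "plug-and-play" BCI setting.
`eegdg` implements such a framework as a tested R library with a command-line
interface, exercised end-to-end on synthetic multi-subject EEG.

## The model

Two convolutional networks share a trunk of temporal convolution (F1 filters
of width C1 ≈ fs/4), a depthwise spatial convolution collapsing the electrode
axis, and two densely connected units (three time-convolutions each with
growth rate F2, every layer receiving the concatenation of all earlier
outputs, so layer *l* sees k0 + F2·(l−1) channels), interleaved with ELU,
batch normalization, dropout and width-5 average pooling; a 1×1 convolution
(F3 filters), flattening and a softmax layer whose weight rows are clipped to
L2 norm 0.25 after every optimizer step complete the classifier.

* The **teacher** consumes the trial after a zero-phase Butterworth filter
  bank (theta, alpha, beta, and the 4–32 Hz overall band) has decomposed it
  into Nb stacked band-limited copies; a linear pointwise (1×1) convolution
  fuses the bands with adaptive weights before the trunk. Its flattened
  post-ELU 1×1-convolution output is the *spectral feature* vector.
* The **student** consumes the raw trial (no filter bank) and doubles the
  1×1-convolution width to 2·F3. The flattened features split into halves:
  z1, the *internally invariant* half, is distilled toward the (frozen)
  teacher's spectral features by a mean-squared-error loss; z2, the
  *mutually invariant* half, is aligned across sub-source domains by
  correlation alignment (CORAL): with unbiased feature covariances C_i per
  subdomain, the loss is 2/(N(N−1)) Σ_{i≠j} ‖C_i − C_j‖²_F over ordered
  pairs. A divergence regularizer L_div = −mean_i ‖z1_i − z2_i‖² pushes the
  halves apart so they carry complementary information.

The student objective is
L = L_cls + λ1·L_mse + λ2·L_align + λ3·L_div,
with non-negative weights λ (defaults 1; see "Stability" below).

## Training protocol

Evaluation is leave-one-subject-out (LOSO): each subject in turn is the
unseen target; the remaining subjects form the source domain, randomly
grouped into k subdomains of near-equal size (default: one per subject).
Mini-batches are stratified so every subdomain contributes at least two
samples — the minimum for its covariance to exist — which is why
`batch_size >= 2k` is enforced.

Stage one trains teacher then student on a stratified 80/20 split (five-fold
cross-validation by default, each fold an 80/20 split; the fold with the
highest student validation accuracy is kept, and its validation loss
recorded), with Adam at learning rate 0.001, early stopping on validation
loss, and a 1000-epoch cap. Stage two resumes that model on *all* source
trials (so no data is wasted), at learning rate 0.001 dropping to 1e-4 after
epoch 150, stopping as soon as the loss monitored on the former validation
subset falls below the recorded stage-one loss, or after 400 epochs.

Interpretation choices that the protocol description leaves open, and how
this package resolves them:

* Early stopping and the stage-two comparison both monitor the student's
  *classification* cross-entropy, not the full DG objective: the recorded
  stage-one loss and the stage-two monitored loss must live on a common
  scale for "fell below the previously recorded loss" to be meaningful, and
  the auxiliary terms depend on batch composition.
* Stage two continues both networks by default (`stage2_scope = "both"`);
  `"student"` freezes the teacher permanently.
* The distillation target is the teacher's post-ELU 1×1-convolution output,
  detached — no gradient reaches the teacher; teacher parameters are
  bit-identical before and after student training (hash-checked in tests).
* A `stage1_mode = "single"` switch replaces the five-fold stage one with a
  single stratified 80/20 split for cheap experiments.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` produces epoched multi-subject trials with exactly the
statistical structure the method exploits:

* class-conditional band-power effects on motor-channel groups — class 0:
  right-hemisphere alpha ERD (left-hand imagery); class 1: left-hemisphere
  alpha ERD; class 2: bilateral beta ERD; class 3: theta enhancement — with
  attenuation factor (1 − `erd_depth`);
* 1/f (pink) plus white background noise, matching the gross EEG spectrum
  well enough to exercise band-pass filters;
* subject-level domain shift: per-subject spatial mixing
  M_s = I + `subject_shift_scale`·G (G Gaussian, rows renormalized) and a
  log-normal per-subject gain, drawn from independent per-subject
  substreams of one master seed, so adding subjects never perturbs earlier
  ones.

It does **not** emulate volume-conduction forward models, ocular/muscular
artifacts, non-stationarity within a session, or realistic electrode
covariance structure. Passing tests on this generator therefore show that
the pipeline recovers the class- and subject-structure it is designed for —
not that it reaches any particular accuracy on real recordings.

## Numerical choices

* **Filtering** is order-3 Butterworth applied forward–backward (zero
  phase), so band-limited features are not lag-shifted relative to the raw
  trial the student sees; the description of the filter bank does not fix
  phase handling, and zero-phase is the natural choice when teacher and
  student inputs must stay time-aligned. Each epoch is reflection-padded by
  three filter lengths (21 samples at order 3) before filtering: one filter
  length proved too short for the 4 Hz transient to decay.
* The "overall band" is implemented as a 4–32 Hz band-pass, not the raw
  signal, consistent with the motor-imagery-relevant range; configurable.
* C1 defaults to fs/4 rounded up to the nearest odd integer so "same"
  padding is symmetric (250 Hz → 63). Kernels must be odd for this reason.
* Pooling is non-overlapping width-5 averaging with floor division
  (T → T%/%5 → T%/%25), and the depthwise depth multiplier D defaults to 1.
* Unstated architecture sizes default to F1 = 24, D = 1, F2 = 12, F3 = 32,
  C2 = C3 = 15, dropout 0.5 — sized near common compact EEG decoders
  (EEGNet/FBCNet practice) and fully configurable.
* Softmax is computed in log-space; cross-entropy clips probabilities at
  1e-12 so a confident wrong prediction stays finite.
* Batch-norm uses momentum 0.1 and epsilon 1e-5 (framework defaults);
  gradients of every layer are verified against finite differences in the
  test suite.
* The CORAL sum is implemented literally over ordered pairs with
  coefficient 2/(N(N−1)), so N = 2 yields 2‖C1 − C2‖²_F; reported loss
  values are reproducible against the formula as written.

## Stability of the divergence term

L_div is unbounded below, and maximizing ‖z1 − z2‖² has no interior
optimum: under Adam (whose per-parameter step size does not shrink with
gradient magnitude) any λ3 large enough relative to the classification
gradient produces runaway feature magnitudes. No clamping is applied — the
term is implemented as defined — and stability is delegated to keeping λ3
small and to early stopping, which returns the best-validation checkpoint
from before any runaway. The per-epoch log records all four components so
the onset of divergence growth is visible. In short-budget experiments on
this package's synthetic data, runaway begins around λ3 ≈ 3e-3; the bundled
end-to-end experiment uses λ = (0.01, 0.001, 1e-4), sized so that each
auxiliary gradient stays well below the classification gradient within a
25-epoch budget, with λ3 smallest because its objective is unbounded.

## Problem sizes of the bundled experiments

The package's own end-to-end experiment (mirrored by
`scripts/acceptance.R` and the acceptance tests) uses 4 subjects × 4
classes × 20 trials/class, 22 channels, 500 timepoints at 250 Hz, ERD depth
0.8, subject shift 0.5; a reduced network (F1 = 3, F2 = 2, F3 = 3, C1 = 25,
C2 = C3 = 7, dropout 0.25) and reduced budgets (single-split stage one,
≤ 25 stage-one epochs, ≤ 4 stage-two epochs, batch 16, stage-two scope
"student"). The acceptance tests repeat the experiment over 3 seeds;
`scripts/acceptance.R` runs the single seed it is given. These sizes keep a full LOSO × ablation comparison
tractable on one CPU core while leaving the 4-class task clearly above
chance (25%). With the full-size defaults the same code scales to
BCIC-IV-2a-shaped data (9 subjects × 288 trials, 22 × 1000 @ 250 Hz),
converted by the user into the NPZ container (`save_dataset()` /
`load_dataset()` document the schema: arrays `X`, `y`, `subject`, scalar
`fs`).

## Known limitations

* No GPU path; the hand-written CPU kernels are practical at the desk scale
  above, not at multi-hour real-data scale.
* The divergence regularizer requires manual weighting (see above); no
  automatic hyperparameter search is provided.
* Raw recording formats (GDF/EDF/MAT) are out of scope; users convert to
  the NPZ container themselves.
* The synthetic generator's realism limits are listed above; conclusions
  about real EEG require real data.
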