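---
title: "Methods: classifying individual gait patterns and explaining the predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying individual gait patterns and explaining the predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Human gait is individual: the time courses of ground reaction forces (GRF)
and joint angles during a stride carry enough subject-specific structure
that a classifier can identify who is walking.  `gaitlrp` implements the
full analysis around that observation:

1. classify subjects from time-normalized gait curves with a family of
   linear and neural network models,
2. decompose every prediction into per-input relevance values with
   Layer-Wise Relevance Propagation (LRP), so one can see *which* variables
   at *which* time of the stride identify an individual,
3. quantify model robustness under random input perturbations (AOPC), and
4. quantify the reliability of the explanations across trials and
   cross-validation splits (a coefficient of variation).

Because the package must be testable without any recorded data, a
synthetic gait generator with controllable between- and within-subject
variability is a first-class component.

## The models and the explanation rule

Every classifier is an explicit layer sequence: affine maps, convolutions
over the channel-by-time grid, elementwise ReLU, and a terminal softmax.
The family is

* **Linear (SGD)** - a single affine layer trained by SGD on the softmax
  cross-entropy;
* **Linear (SVM)** - one-vs-rest linear soft-margin SVMs (`e1071`,
  `C = 0.1`), re-assembled into a single affine layer `(w_c, b_c)` so that
  prediction and explanation use exactly the same code path;
* **MLP (L, H)** - `L` affine layers in total (`L - 1` hidden ReLU layers
  of width `H` in 64...1024), consuming the row-concatenated
  channel-by-time vector (6 x 101 = 606 inputs for GRF);
* **CNN presets** `cnn_a` (one full-channel C x 3 convolution, 32 maps)
  and `cnn_c3` (three convolutional layers, time stride 2 after the
  first).  These presets are documented approximations - the point is the
  layer structure LRP needs, not an exact published architecture.

LRP starts from the pre-softmax score of the explained class,
`f_c(x) = R_j`, sets all other output relevances to zero, and propagates
backwards.  An affine or convolutional layer redistributes each output
neuron's relevance in proportion to the forward contributions
`z_ij = x_i w_ij`:

```
R_{i<-j} = z_ij / (z_j + eps * sign(z_j)) * R_j,    R_i = sum_j R_{i<-j}
```

with the bias acting as an always-on neuron that retains `R_b = b_j`
fractions.  Elementwise nonlinearities pass relevance through unchanged;
flatten layers only remap indices.  Summing input and bias relevances
recovers `f_c(x)` (conservation); the package verifies this to 1e-6
relative for deep models and exactly (zero stabilizer) for linear ones.

Numerical choices:

* the stabilizer is `eps * sign(z_j)` with `eps = 1e-9` by default and
  `sign(0) = +1`; `eps = 0` is allowed and then a vanishing denominator
  with nonzero incoming relevance raises an explicit error rather than
  producing silent `Inf`s;
* bias relevance is reported per layer and never redistributed to the
  inputs - conservation statements always include it;
* the explained class defaults to the sample's true label, the practice
  used throughout the analyses here; it can be overridden.
* convolutional LRP is implemented on the im2col patch decomposition and
  is checked against an independently constructed unrolled sparse affine
  form of the same layer (equality to 1e-9 on random instances).

## Preprocessing

The chain from raw trial to model input follows standard practice in
instrumented gait analysis:

1. zero-phase second-order Butterworth low-pass filtering, 12 Hz for
   kinematic and 50 Hz for kinetic channels.  The forward-backward pass is
   implemented with odd-reflection padding of several filter time
   constants plus steady-state initial conditions, so constants pass
   through exactly and edge transients die inside the padding (the
   edge-handling of a bidirectional filter is otherwise underdetermined);
2. stride segmentation on the filtered vertical GRF with a 10 N contact
   threshold; the stride runs from right-foot heel strike to left-foot toe
   off.  Contact intervals are 1-based and half-open;
3. normalization of forces to body weight (`g` = 9.81 m/s^2);
4. linear interpolation of each channel onto 101 points (0-100% stride);
5. z-transformation with the population (divide-by-N) standard deviation -
   per trial for kinematic channels, pooled over the fitting split for
   kinetic channels;
6. min-max scaling to [-1, 1], fitted **per input component** (channel x
   time) on the training split of the current cross-validation round.
   Held-out values may leave [-1, 1] and are not clipped; constant
   components map to 0 and are flagged.

Steps 5-6 are the only split-dependent stages; the trial-level part is
computed once and cached (`preprocess_trials()`), and `run_experiment()`
refits the normalization on each round's training folds so no test
information leaks into the normalization state.

## Training and cross-validation

`make_folds()` assigns each subject's trials to `k = 10` folds as evenly
as possible (with 20 trials, exactly 2 per fold), and each round uses 8
folds for training, one for validation and one for testing, so every trial
is tested exactly once.  With 57 subjects this gives the familiar 912
training samples per split and an upper bound of
`30000 * 5 / 912 = 164` passes over the training set.

SGD uses mini-batches of 5 samples drawn with replacement, learning rate
5e-3 lowered to 1e-3 and 5e-4 after every 10^4 iterations (stage length
configurable).  Early stopping is per learning-rate stage: validation
accuracy is evaluated every 250 iterations and a stage ends once 8
consecutive evaluations fail to improve its best by 0.1 percentage points;
the returned model carries the weights of the best validation evaluation
seen.  The loss is the softmax cross-entropy.  The dense step is a fused
compiled kernel (`src/sgd_dense.cpp`) that updates the weights in place
and flushes denormal floats - vanishing gradients late in training
otherwise make iterations orders of magnitude slower; updates below
1e-14 x learning rate are skipped as they are far beneath the weights'
representation noise.

Weights initialize from a mean-zero normal with standard deviation
`m^(-1/2)` (`m` = inputs per output neuron), biases at zero.

## The synthetic generator

Each subject owns per-channel template waveforms built from a shared
population base: compact-support cosine-squared bumps for the forces (an
M-shaped vertical GRF peaking near 1.1 body weights, a braking/propulsion
fore-aft force of about 0.2 BW, a small medial-lateral oscillation
mirrored between feet) and order-6 Fourier series for the sagittal joint
angles.  The right stance occupies about 0-68% of the stride and the left
stance 32-100%, so force channels are exactly zero - and therefore below
any contact threshold - outside their stance windows.

Two dimensionless multipliers control the statistical structure:

* `inter_subject_sd` scales the spread of subject-specific coefficient
  offsets (bump amplitudes, centers, widths, Fourier coefficients, stance
  timing and body weight).  At the default 1, amplitude differences
  between subjects are on the order of 10-15% - the magnitude of
  between-subject differences reported for gait curves;
* `intra_subject_sd` scales trial-level variability: a ~8% amplitude
  factor, a smooth ~3% time warp and band-limited additive noise of ~4%
  of the channel's peak.  Stride duration is drawn per trial (mean 1.1 s,
  sd 0.05 s) as a separate variability source.

The within-subject level is calibrated so that a linear SGD classifier
identifies 20-30 subjects from GRF in the mid-90% range while a linear SVM
sits near 100% - the operating point instrumented-gait identification
reports.  This calibration matters beyond accuracy: robustness contrasts
between models only exist when the linear model sits below ceiling; with
much cleaner data every model's margins are so wide that 50 random
perturbation steps change nothing and AOPC degenerates to zero for all
models alike.  Reproducibility
is strict: every subject and trial derives its own random stream from the
root seed by stable hashing, so datasets are byte-identical for identical
configurations and independent of generation order.

The generator does **not** emulate several features of real data: no
marker-level kinematics or joint-angle estimation, no force-plate targeting
artefacts, no fatigue or session effects, no left-right asymmetries beyond
the mirrored medial-lateral force, and trial noise is stationary and
band-limited rather than movement-dependent.  Passing tests therefore
demonstrate the correctness and the qualitative behaviour of the pipeline,
not clinical validity on recorded gait.

### The planted signature

For explanation-localization experiments the generator can plant a
class-discriminative signature: one designated subject receives a pattern
of three narrow bumps inside a stated channel/time window (amplitude in
body weights, coefficients a fixed sign pattern plus small jitter).  With
`inter_subject_sd = 0` every other source of between-subject difference is
switched off - including body weight, which would otherwise leak subject
identity through the body-weight normalization at the contact edges - so
the signature subject's class identity is localized in the window by
construction.  The localization experiment then asks whether the majority
of that subject's positive relevance mass falls inside the window (+-5%
stride); with natural between-subject variability switched on instead, the
planted window competes with genuine gait differences everywhere and no
such concentration should be expected.

## Robustness and reliability

The perturbation protocol draws, per test sample and repetition, one
uniformly random order of its input components; at each of 50 steps the
next component of every sample is perturbed simultaneously (perturbations
accumulate) and test accuracy is re-evaluated.  The area over the
perturbation curve, `AOPC = mean(a_0 - a_k)` over steps 0..L, summarizes
sensitivity: higher AOPC = less robust.  Noise types: additive gaussian
(sigma in 0.5/1/2), salt replacement at the scaled-input extremes (-1/+1),
pepper (0), and multiplicative Poisson(1) shot noise - the replacement
values are configurable because their exact definitions are a convention.
AOPC is averaged over repetitions within a fold and aggregated as mean
(population sd) over repetition-by-fold runs.

Explanation reliability collects, per subject, the relevance maps of all
their test trials (each trial explained once, by its fold's model) and
computes per input component the population standard deviation over
trials; the coefficient of variation is the mean of these standard
deviations normalized by the root mean square of the mean relevance
signal.  This form is scale-invariant and grows when attributions flip
sign between trials.  The verbal definition it implements admits several
formalizations (per-component versus whole-signal normalizers); this one
is fixed, documented, and isolated in `relevance_cv()` so alternatives can
be swapped.

## Study sizes used by the tests and the acceptance script

All empirical checks run on generated data at sizes chosen once:

* subject classification: 20 subjects x 20 trials, GRF channels, ten
  folds - both the linear SVM and MLP (3, 256) must reach >= 95% mean test
  accuracy;
* robustness and reliability: 30 subjects x 20 trials at the default
  calibration.  Class crowding and sub-ceiling linear accuracy are what
  make the linear model noise-sensitive; in this regime the ordering
  AOPC(Linear SGD) > AOPC(MLP 3x1024) and its monotone growth in sigma
  emerge clearly, as does the reliability ordering
  CV(Linear SGD) > CV(MLP 3x1024);
* these experiments use the stated learning-rate schedule with stages of
  2500 iterations (7500 total): on the synthetic data validation accuracy
  converges within the first few hundred iterations, and the shortened
  stages change none of the compared quantities materially;
* localization: 5 subjects x 20 trials at a quarter of the default
  within-subject noise (clean parameter-recovery conditions), signature on
  `grf_r_vert` at 60-70% stride, amplitude 0.4 BW, explained with the
  linear SVM over all of the signature subject's trials, five seeds.

## Known limitations

* The CNN presets stand in for unavailable architecture details; they are
  labeled approximations and configurable.
* Convolutional models train through a per-sample R path and are slow to
  train (LRP and prediction are fast); the compiled kernel covers the
  dense family only.
* The AOPC and CV magnitudes on synthetic data are smaller than those
  reported for recorded gait - synthetic classes are more separable than
  real ones - so only orderings and trends, not magnitudes, are
  meaningful.  At 30 subjects the sigma = 1 AOPC gap between the linear
  model and the large MLP is moreover of the same order as its
  model-instance-to-instance variability: the robustness ordering is
  checked at the package's fixed study seeds, and an acceptance run at a
  different seed can report a pair in either order while the sigma = 2
  contrast and the reliability ordering remain stable.
* `relevance_cv()` is undefined (NaN, with a warning) when the mean
  relevance signal is identically zero.
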