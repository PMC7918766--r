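---
title: "Assessing pain-related reactions from multimodal physiological signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing pain-related reactions from multimodal physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painreact)
```

## The problem

Manual fascial therapy is effective but painful, and the pain arrives
unpredictably: the therapist continuously adjusts pressure, plane, and
location, so stimulus timing cannot be scripted the way it can in
heat-pain protocols. A therapist benefits from an objective, continuous
estimate of the patient's pain-related reaction (PRR) — too much force
risks tissue damage, too little limits the therapeutic effect — while
verbal 0–10 self-reports are sparse, delayed, and subjective.

`painreact` implements a frame-based PRR classifier over five
synchronized channels: electrodermal activity (EDA), corrugator
electromyography (EMG), respiration (RSP), blood volume pulse (BVP), and
hand grip force (GRIP). Each 4 s frame (50% overlap) is assigned one of
three classes — *no pain*, *moderate pain*, *severe pain* — derived from
the patient's own thresholded self-reports, which keeps the target
subject-relative rather than pretending the 0–10 scale is comparable
across patients.

## Processing model

### Preprocessing

Channels are resampled with anti-aliasing FIR low-pass filters to fixed
rates (EMG 256, BVP 64, EDA 8, RSP 8, GRIP 75 Hz). The resampler is a
polyphase rational design: the rate ratio is reduced to $p/q$, the
signal is upsampled by $p$, filtered with a Kaiser-windowed linear-phase
low-pass at the lower of the two Nyquist frequencies ($\beta = 8$,
10 zero-crossings per phase), and decimated by $q$. Each polyphase
branch is normalized to unit DC gain, so constant signals are preserved
exactly; edges are reflected.

EDA is then smoothed with a Gaussian-weighted moving average (1 s
window, $\sigma = \mathrm{window}/5$; the width is a package choice — a
1 s window suppresses sensor noise while leaving skin-conductance
responses, whose rise times are ~0.7 s at minimum, intact).

### EDA decomposition

Skin conductance is modeled as tonic + phasic + noise. A sudden pain
stimulus produces a sudomotor burst whose conductance signature is the
Bateman impulse response
$h(t) = e^{-t/\tau_1} - e^{-t/\tau_0}$ (defaults $\tau_0 = 0.7$ s rise,
$\tau_1 = 2.0$ s recovery — conventional SCR values). We solve the
convex program

$$\min_{p \ge 0,\;\ell}\;
\tfrac12\lVert y - Mp - B\ell\rVert^2
+ \alpha \lVert p \rVert_1
+ \tfrac{\lambda_t}{2}\lVert \ell_s \rVert^2$$

where $M$ applies the Bateman convolution, realized as a second-order
ARMA filter obtained by bilinear (Laplace-domain) discretization of the
kernel's transfer function at 8 Hz; $B$ is a coarse cubic B-spline basis
(10 s knots) plus an unpenalized offset and linear drift; $p$ is the
nonnegative sparse driver. Defaults $\alpha = 8\times10^{-4}$,
$\lambda_t = 10^{-2}$. The solver is a monotone FISTA with a power-iteration
Lipschitz estimate — matrix-free (the filter and its adjoint are $O(n)$),
fully deterministic, and the residual definition makes the
reconstruction identity `tonic + phasic + noise = input` exact by
construction. Recovery tests plant noiseless SCR trains and require
phasic correlation $r > 0.95$ with driver impulses localized within
±2 samples; at the defaults the implementation recovers planted events
exactly. Only the phasic component is passed downstream — it carries the
stimulus-locked information, while the tonic drift reflects slow arousal
and the residual absorbs noise.

### Wavelet scattering features

A deep scattering transform computes, per layer,

$$U_1 x = |x \ast \psi_{\lambda_1}|, \qquad
S_1 x = U_1 x \ast \phi,$$
$$U_{n+1} x = |U_n x \ast \psi_{\lambda_{n+1}}|, \qquad
S_{n+1} x = U_{n+1} x \ast \phi,$$

with Morlet wavelets (frequency-domain Gaussians with an admissibility
correction giving exactly zero mean) and a Gaussian low-pass $\phi$
whose 4 s invariance scale matches the frame width. High-frequency
channels (EMG, BVP) use three layers with 8, 4, and 1 voices per
octave; low-frequency channels (phasic EDA, RSP) use two layers with 8
and 1. Scattering is preferred over plain spectrograms here because it
is invariant to small time shifts (pain onsets are not aligned to
frames) and stable to the time-warping typical of respiration.

Implementation choices:

* **Path truncation.** Only frequency-decreasing paths
  ($\xi_{n+1} < \xi_n$) are kept — the envelope $|x \ast \psi_{\lambda}|$
  has no content above $\xi_n$, so other paths are numerically empty.
* **Normalization.** Each layer is Littlewood–Paley normalized so
  $|\hat\phi(\omega)|^2 + \sum_j |\hat\psi_j(\omega)|^2 \le 1$ with the
  bound attained; this makes the whole transform nonexpansive
  ($\lVert Sx - Sy\rVert \le \lVert x - y\rVert$), which the test suite
  asserts on random signal pairs together with exact $|a|$-homogeneity
  and inter-layer energy decay.
* **Lowest octave.** Banks extend from just below Nyquist down to a
  per-channel floor: 1 Hz for EMG (corrugator activity has no slower
  content), 0.5 Hz for BVP (pulse rate stays above 30 bpm), and the
  $\phi$ cutoff (~0.19 Hz) for EDA/RSP. Content below the floor is
  captured by $\phi$ itself.
* **Boundaries.** One 4 s window of reflection padding per side,
  cropped after filtering.
* **Alignment.** Layers differ in effective time resolution, so all
  scattergrams and scalograms are brought to the common frame grid by
  Fourier-domain interpolation (`align_frames()`), which preserves DC
  exactly and per-path mean-square energy for smooth rows. Because a
  full-rate layer-3 scalogram of a 256 Hz session is prohibitively
  large, `scattering_transform(u_frames =)` can emit `U` rows already
  resampled to the frame grid; this is exactly what the aligned features
  consume, and short-signal unit tests exercise the full-resolution
  path.

Each of the aligned $S_n$ and $U_n$ matrices contributes one feature per
frame — the energy $\sum_{\text{paths}} M[\text{path}, f]^2$ — giving
6 features per three-layer modality and 4 per two-layer one,
20 scattering features in total.

### Remaining features

Spectral entropy (Shannon entropy in bits of the Hann-periodogram
distribution per frame) is computed for EMG and RSP; time-domain
statistics (max, median, sample sd, peak-to-peak amplitude) for phasic
EDA and RSP; and first-derivative statistics (max, mean, sd of the
first difference scaled by the rate) for phasic EDA. The full default
vector has 33 features; the STFT comparison variant replaces the 20
scattering energies with 4 Hann-windowed spectrogram frame energies
(17 features). The signal-to-statistic allocation is configurable: the
statistics list is fixed, but which channels receive them follows the
count arithmetic above, and GRIP consequently contributes no default
features. Features are z-scored per subject (zero-variance columns
become zeros), which removes inter-subject scale differences and is what
makes a subject-dependent protocol meaningful.

### Labeling

Verbal reports lag the reaction, so every report time is shifted 2 s
backward (floored at 0), extended forward by zero-order hold, and each
frame is tagged with the maximum held rating inside it. A double
threshold then yields the class: below $t_{low}$ → no pain, at or above
$t_{high}$ → severe, in between → moderate. Defaults
$t_{low} = 4, t_{high} = 7$ are placeholders — pain resistance is
subject-dependent and the thresholds are free experiment parameters, not
properties of the rating scale. Boundary conventions (strict `<` at the
lower threshold, `>=` at the upper) are fixed and tested.

### Classification and validation

Two classifiers are provided. AdaBoost boosts depth-limited
classification trees (grown with `rpart` at `cp = 0`, then pruned to at
most 20 split nodes, the stated tree size); binary tasks use the
classical M1 update and three-class tasks the SAMME multiclass
exponential-loss extension, with 100 learners and unit learning rate by
default. The Gaussian-kernel SVM (via `e1071`) is binary-only — its
multiclass performance does not justify reporting — with box constraint
1 and the median-pairwise-distance kernel-scale heuristic.

Four experiments (three binary pairings plus the three-class task) run
under two validation schemes, both class-balanced by random
undersampling to the minority count: pooled 10-fold CV with
class-stratified folds, and one-patient-out CV in which each subject's
frames are held out in turn (the training set never contains the test
subject — asserted structurally on every fold). The whole procedure
repeats over `runs` freshly balanced draws (default 10), and metrics
(accuracy, sensitivity, precision, specificity, F1; one-vs-rest per
class in the multiclass task) are aggregated as mean ± sd over all
fold×run evaluations, with the between-run sd reported separately since
the split of variance between folds and runs is of interest. Undefined
ratios (zero denominators) are reported as 0 and flagged.

## The synthetic cohort

The clinical dataset this method targets is not publicly available, so
the package ships a generator whose defaults encode the study protocol:
a 30 s no-pain baseline followed by 2–3.5 min of therapy (sessions drawn
uniformly in 150–210 s), pain episodes arriving at 2 per minute
(Poisson), each resetting a latent 0–10 pain level that decays with a
90 s time constant (fascial pressure is sustained, so slow decay — not
return-to-zero — is the realistic choice), and subject-specific
log-uniform reactivity gains in 0.5–2 emulating inter-patient
variability. Episodes jointly modulate all channels: Bateman SCRs in EDA
(amplitude proportional to intensity), amplitude-modulated EMG bursts,
respiratory rate/amplitude shifts, heart-rate increase with pulse
amplitude attenuation in BVP, and smooth grip squeezes for intense
episodes. Reports sample the episode intensity, rounded to integers and
delayed by 2 s ± 0.5 s jitter — the delay the backward label shift
compensates. Native device rates (e.g. EMG 512 Hz) are deliberately
different from the target rates so resampling is always exercised.

What the simulator does *not* model: motion and electrode artifacts,
emotional (non-nociceptive) electrodermal responses, respiration-gated
heart-rate variability, or any facial/video modality. Passing tests on
this cohort therefore demonstrate that the pipeline recovers a known
multichannel encoding of latent pain — not clinical performance.

Parameter-recovery checks use an "easy" regime fixed a priori: gains
1.5–2.5, noise levels one fifth of the defaults, 2.5 episodes/min,
120 s decay. On 6 such subjects the multiclass AdaBoost 10-fold macro-F1
is required to reach 0.8 (observed ≈ 0.90), with the well-detached
no-pain class outperforming the overlapping moderate class, and
label-permuted per-class F1 must fall to chance (1/3 ± 0.1, checked on a
12-subject STFT-feature cohort so the balanced set exceeds 500 frames).

## Numerical choices and degenerate cases

* Frames are half-open `[start, start + 4)`, 0-based sample indexing;
  frame count `floor((D - 4)/2) + 1` for duration `D`, shared by all
  modalities.
* Sample (n−1) standard deviations throughout.
* All-zero spectral frames have entropy 0; zero-variance feature
  columns z-score to zeros; a rating exactly at a threshold goes to the
  higher class.
* FISTA stops at a relative step change of 1e-10 or 3000 iterations;
  the reconstruction identity holds regardless of convergence because
  the noise component is the residual.
* Simulation, balancing, fold assignment, and boosting derive
  deterministic child seeds from the master seed; identical
  configurations reproduce byte-identical outputs.

## Problem sizes used in the shipped checks

Unit tests run the transform on short (6–12 s) signals at 32–256 Hz
where full-resolution scalograms are cheap; cohort-level checks use
6 subjects with the full 33-feature scattering pipeline and 12 subjects
with STFT features, with 1–3 CV repetitions. These sizes are the
package's test-design choice; the defaults users get (`runs = 10`,
34 subjects in `sim_config()`) match the study conditions.

## Worked example

```{r example, eval = FALSE}
library(painreact)

cohort <- simulate_cohort(sim_config(n_subjects = 6, seed = 1))
ds <- build_dataset(lapply(cohort, `[[`, "recording"),
                    feature_mode = "scattering")

res <- run_cv(ds$features, ds$labels, ds$subjects,
              task = "multiclass", scheme = "kfold10",
              classifier = classifier_spec("adaboost"), runs = 10, seed = 1)
res
macro_f1(res)
```

## Known limitations

* The latent-pain generative model is a convenience, not physiology;
  absolute metric values on simulated cohorts say nothing about clinical
  data.
* The SVM is binary-only by design; multiclass SVM is out of scope.
* The decomposition hyperparameters ($\alpha$, $\lambda_t$, knot
  spacing) are package defaults guarded by recovery tests, not values
  fitted to clinical recordings.
* Online (streaming) operation is not supported; the pipeline is
  strictly offline.
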