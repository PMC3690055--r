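---
title: "Detecting head-movement artifacts in EEG with camera-assisted feature fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting head-movement artifacts in EEG with camera-assisted feature fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Consumer EEG headsets are attractive for brain–computer interfacing because
they are cheap and fast to don, but they are mechanically fragile: rotating
the head (yaw) shifts the electrodes against the scalp and floods the
recording with broadband artifact that no amount of averaging removes.
`movart` implements a detection-and-excision strategy: rather than trying to
repair contaminated EEG, it decides — at the cadence of a head-mounted
frontal camera, about every 33 ms — whether the signal is currently
movement-contaminated (Class 2) or clean (Class 1), and cuts the Class-2
sections out. The classifier fuses two independent views of the same event:
the spectral signature the movement leaves in the EEG itself, and the global
image motion it induces in the frontal camera.

## Features

**EEG, per 128-sample epoch (1 s at 128 S/s).** Each epoch is first
DC-centred and min–max scaled onto $[-1, 1]$, so every feature describes
spectral/temporal *shape*, not amplitude. The window slides one sample at a
time (127-sample overlap); a per-epoch cadence is available through the
`step` argument. Twelve frequency features are the mean discrete-Fourier
magnitudes over the inclusive integer-Hz bands
3–15, 4–6, 5–7, 6–8, 7–9, 8–10, 9–11, 10–12, 15–30, 20–30, 51–64 and
59–61 Hz (at 128 samples/128 S/s each DFT bin is exactly 1 Hz wide).
Thirteen time-domain features complete the block: kurtosis, skewness, RMS
amplitude, zero crossings, minimum, maximum, variance and zero crossings of
the first and second derivatives, and the Hjorth activity, mobility and
complexity parameters.

Numerical conventions, centralised so that one switch changes them
everywhere: all moments are population (divide-by-$n$) moments; kurtosis is
the raw standardized fourth moment ($\approx 3$ for a Gaussian); the RMS
amplitude feature is the *peak* absolute value divided by $\sqrt 2$ (the
textbook peak-referred definition; the conventional root mean square is
computed alongside and exposed as an attribute); zero crossings count strict
sign changes — a product of adjacent samples below zero — so exact zeros
neither count nor interrupt a crossing, which makes the count tie-free and
deterministic; derivatives are first differences. Degenerate (constant)
epochs cannot be normalized; they are flagged invalid and carried through
the pipeline rather than dropped, so epoch counts are conserved, and the
classifier treats them conservatively (rejected, never silently trusted).

**Video, per consecutive frame pair.** Four features: (1) mean absolute
pixel difference; (2) the same difference applied to Sobel
gradient-magnitude maps (two 3×3 masks, L2-combined, replicate borders);
(3) the mean magnitude and (4) the count of Lucas–Kanade motion vectors.
Corners are detected with the Shi–Tomasi minimum-eigenvalue criterion and
tracked coarse-to-fine over an image pyramid by iteratively minimising the
windowed squared brightness residual. Points with a near-singular gradient
matrix, and points whose window leaves the frame, are dropped — never
fabricated — so a uniform scene simply yields no vectors. Differences are
*means* over pixels rather than sums, making them resolution-independent.

Tracker defaults are sized for the package's 160×120 working resolution:
up to 100 corners of quality ≥ 1% of the strongest response, ≥ 5 px apart,
a 15×15 tracking window, 3 pyramid levels, convergence at 0.01 px.
Corners are restricted to the region whose tracking window stays inside the
image at every pyramid level; windows that track out of frame at the finest
level drop the point. All of this is configurable through `video_params()`;
the defaults balance motion-statistic stability against the cost of
tracking ~1,400 frame pairs per 47 s trial on one CPU.

## Fusion and classification

Feature vectors are formed at camera cadence: each frame-pair instant is
paired with the EEG epoch completing nearest in time (an epoch of samples
$1..128$ completes at $t_0 + 1$ s; frames earlier than the first complete
epoch are dropped with a logged count). Features are z-scored with
training-fold statistics — mandatory when mixed-unit features meet an RBF
kernel.

**Dimension reduction** is Fisher-criterion LDA: with prior-weighted
within-class scatter $M_W = \sum_j q_j M_j$ and between-class scatter
$M_B = \sum_j q_j (m_j - m)(m_j - m)^\top$, directions $u$ maximise
$|u^\top M_B u| / |u^\top M_W u|$, solved as the eigenproblem of
$M_W^{-1} M_B$ (Moore–Penrose pseudo-inverse with a warning when $M_W$ is
singular). Priors are empirical class frequencies. With two classes $M_B$
has rank one, so only the leading eigendirection is theoretically
discriminative; the implementation nevertheless retains *all* directions in
descending-eigenvalue order and selects the dimension count $k$ empirically
— smallest average error of a nearest-class-mean classifier on a seed-fixed
70/30 inner split of the training fold, ties toward smaller $k$. This
mirrors the way such pipelines are tuned in practice while being explicit
that $k > 1$ directions are numerically, not theoretically, motivated.

**Classification** is a soft-margin SVM on the projected features,
$f(x) = \mathrm{sgn}\big(\sum_{x_k \in S} a_k y_k K(x_k, x) + b\big)$ with
Class 1 on the $-1$ side and Class 2 on $+1$. The kernel family and
parameters are selected on the inner split from a grid covering the four
libsvm kernels: linear; polynomial ($d \in \{2,3\}$, $r = c = 1$); RBF
($r \in \{0.125, 0.5, 2, 8, 32\}$); sigmoid ($r \in \{0.01, 0.1\}$,
$c = 0$); each crossed with cost $C \in \{1, 10\}$ (the cost parameter is
rarely reported in this literature; the grid brackets libsvm's default
region). Fitting is delegated to libsvm via `e1071`; the *decision values*
used everywhere downstream are recomputed by the package's own kernel-sum
expansion over the stored support set, which is what makes serialized
models self-contained and is cross-checked against libsvm in the tests.

The final decision is not the SVM's sign but a tuned cutoff on the raw
decision value: the threshold minimising the average of the two per-class
error rates on the held-out inner part, ties toward the threshold nearest
zero. Classification is Class 2 only when the value *strictly* exceeds the
threshold — at an exact tie the epoch is kept, so EEG is discarded only on
strict evidence.

**Error accounting.** Type 1 error is the percentage of still epochs
rejected; Type 2 the percentage of movement epochs kept; the average error
is their mean, the quantity minimised by every selection step. Evaluation
is two-fold cross-validation *by trial* — first trials train, second trials
test, then swapped — so no trial's samples ever straddle folds; ROC curves
sweep the decision value with ties advanced jointly, making the trapezoidal
area equal to the Mann–Whitney pairwise estimator.

Because libsvm training is super-linear in sample count and consecutive
vectors 33 ms apart are highly redundant, the cross-validation trains the
kernel grid on every 16th synchronized vector of the training fold and the
final model on every 8th, while always *testing* on every vector. Both
strides are `pipeline_config()` knobs; halving them changes the benchmark
errors by well under the seed-to-seed spread.

## The synthetic session generator

No public recordings exist for this task, so the generator is a first-class
module: it emulates the class-conditional structure the detection problem
exhibits, with trial-level labels (whole trials are still or moving — mixed
trials are out of scope).

*EEG*: a sum of sinusoids at 4, 6, 8, 10, 12, 18, 22, 26, 55 and 60 Hz with
random phases over a $1/f$ noise floor (sd 0.35) plus white noise
(sd 0.12). Still trials are low-frequency dominant (amplitudes 0.5–1.0
below 12 Hz, 0.06–0.12 above 15 Hz); movement trials scale the ≤ 12 Hz
components by 0.5 and the > 15 Hz components by 4, reproducing the
characteristic low-to-high spectral shift of electrode-motion and muscle
artifact, including energy in the 51–64 Hz muscle/line band. Each subject
carries a fixed log-normal gain (sd 0.25) on the low and high component
groups — inter-person spectral variability that keeps the EEG-only
classifier honest. Because epochs are min–max normalized, a plain amplitude
gain would be invisible; the tilt is therefore spectral, not scalar.

*Video*: frames are crops of a per-trial smoothed-noise texture (rich in
trackable corners). Still trials see only sub-pixel stabilization jitter
(sd 0.01 px, which keeps the still-class mean pixel difference under 2% of
the movement-class mean). Movement trials add a sinusoidal horizontal pan —
the camera surrogate of natural yaw — with 4 px/frame peak speed at
0.25 Hz. The pan's turning points matter: around them the inter-frame
displacement passes through zero, so a movement trial contains frames that
*look* still. Those frames are exactly where the image modality alone
fails, where the EEG spectral signature still carries the trial's class,
and hence where fusion earns its keep — the qualitative mechanism behind
the modality ordering the benchmark asserts.

What the generator does **not** model: realistic EEG microstates, eye
blinks, electrode pops, photorealistic scenes, rolling shutter, vertical or
rotational head motion. Passing tests therefore demonstrate that the
pipeline recovers the designed class structure under realistic noise and
inter-subject variability — not performance on human recordings.

A default session is 10 subjects × 2 classes × 2 trials of 47 s (mid-range
of a typical 45–50 s protocol): EEG at 128 S/s, video at 30 fps, 160×120 px
(a deliberate reduction from typical 640×480 capture; full size is a config
away). One session is ~55,000 synchronized labeled vectors. The end-to-end
benchmark extracts features for ten such sessions (seeds 0–9) and runs the
four method variants — fused image+frequency with LDA+SVM, the same
features LDA-only, and each single modality — in about a quarter hour on
one CPU; the unit-test fixtures use 1–2 subjects and 3–8 s trials.

## Numerical and design choices worth knowing

- *Band aggregation*: the mean (not sum) of bin magnitudes, so wide and
  narrow bands are comparable; no window taper is applied before the DFT.
- *Epoch cadence*: 1-sample steps are the primary reading; the feature
  tables accept explicit epoch end-indices, which the session pipeline uses
  to compute only frame-aligned epochs.
- *Synchronization convention*: an epoch "ends" the instant its last sample
  arrives ($t_0 + \text{end index}/\text{rate}$); nearest-epoch ties go to
  the earlier epoch.
- *LDA-only ablation*: classifies by nearest class mean in the projected
  space, with the same empirical choice of $k$.
- *Section bookkeeping*: each frame label governs the half-open interval to
  the next frame; consecutive equal labels merge; sections are clipped to
  the stream span. Half-open intervals make adjacent-section merging
  unambiguous.
- *Serialization*: models round-trip through a versioned JSON container
  holding scaler, projection, support set, kernel spec and threshold;
  loading re-validates the feature-name order and predicts through the
  package's own kernel expansion, so no fitted C object is required.

## Limitations

The detector is windowed at 1 s epochs and 33 ms label cadence: artifacts
shorter than a frame period are invisible, and epoch-level spectral
features lag rapid movement onsets by up to a second. Only horizontal yaw
is modelled by the generator; nodding and rolling produce different image
motion (vertical flow, rotation about the optical axis) that the same four
features plausibly but unverifiably capture. Eye-blink artifacts are a
non-goal. Reported error rates are synthetic-benchmark quantities; they
validate the machinery, not clinical performance.
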