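---
title: "Decoding grasp intent from dynamic surface EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding grasp intent from dynamic surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a person reaches for an object, the muscles of the hand and forearm
begin to configure the grasp well before contact. `emgrasp` implements a
complete framework for exploiting this: from 12-channel surface EMG
recorded during natural reach--grasp--return--rest trials, it decodes
*which* of 13 grasp gestures is coming, and quantifies *how early* the
decision becomes available. The practical target is robotic hand
pre-shaping: a prosthesis or supernumerary hand can start forming the
posture during the reach if the decoder commits early enough.

A session follows a fixed protocol: 13 grasp gestures, each performed on
4 different objects (52 objects), 6 trials per object, each trial 4 s long
and traversing reaching, grasping, returning and resting at the subject's
own pace. EMG is sampled at 1562.5 Hz from 12 muscles spanning hand
(FDI, APB, FDM), forearm (EI, EDC, FDS, BRD, ECR, ECU, FCU) and upper arm
(BIC, TRI).

## Synthetic sessions

No public recordings accompany this protocol, so the package ships a
generator (`generate_session()`) whose defaults *are* the protocol above,
with full ground truth. Each channel of a trial is modelled as a
zero-mean Gaussian carrier, band-limited to 20--450 Hz, multiplied by a
piecewise-constant per-phase activation envelope and topped with a white
noise floor (sd 0.02). This realizes, per phase, the stationary Gaussian
signal model under which the segmentation stage is derived.

Design choices where the protocol is silent, fixed once:

* **Gesture patterns.** Each gesture's grasp-phase activation is drawn
  once per session, per channel, uniformly on [0.1, 1]. Patterns overlap,
  so gestures are separable but not trivially orthogonal.
* **Pre-shaping blend.** Reaching-phase activation is a convex blend
  between the resting baseline (0.05) and the grasp pattern, default
  weight 0.6 toward grasp: the reach carries partial gesture information,
  which is the phenomenon the whole framework targets. Returning uses
  blend 0.35 (residual posture during retraction).
* **Timelines.** The three phase boundaries are drawn uniformly over all
  placements that keep every phase at least 300 ms long, emulating
  unconstrained movement pace; boundaries are smoothed with 50-ms
  raised-cosine ramps (instantaneous switches are implausible and would
  make segmentation artificially easy).
* **Trial-to-trial variability.** Per-trial, per-channel log-normal
  amplitude jitter (sd 0.05).
* **MVC.** One 3-s isometric recording per muscle whose target-channel
  amplitude is 1.25 x its largest task activation, so task envelopes
  normalize below 1.

What the generator does *not* emulate: motor-unit firing statistics,
electrode shift, powerline interference, cross-talk between channels
(inter-channel correlation is zero by default), fatigue, and the
kinematic variability of real reaches. Passing tests therefore show the
pipeline recovers the structure this model encodes — they do not certify
performance on human recordings.

## Preprocessing

`emg_bandpass()` applies a 4th-order Butterworth band-pass (40--500 Hz)
per channel, forward-backward so the output is phase-neutral;
`emg_envelope()` rectifies and low-passes (2nd-order Butterworth, 6 Hz,
also zero-phase) to a linear envelope; `mvc_profile()` /
`mvc_normalize()` divide each channel by the maximum of its MVC envelope,
putting hand and upper-arm muscles — whose absolute amplitudes differ by
an order of magnitude — on a common 0--1 scale.

Two choices deserve a note. The envelope method (rectify + low-pass) is
standard linear-envelope practice; the cutoff is configurable. Zero-phase
filtering looks ahead, which a strictly causal deployment could not do;
the windowed evaluation tolerates this, and the first/last 100 ms are
flagged (`meta$edge_ms`) because forward-backward filtering leaves edge
transients. At other sampling rates a cutoff at or above Nyquist is
clipped to 0.99 x Nyquist with a warning.

## Phase segmentation (greedy Gaussian segmentation)

Each trial is split into its four phases *unsupervised*, by modelling the
multichannel series as piecewise Gaussian: a segmentation with
breakpoints $b_1 < b_2 < b_3$ maximizes

$$\sum_{k} -\tfrac{n_k}{2}\,
  \log\det\!\Big(\widehat\Sigma_k + \lambda\,\tfrac{\mathrm{tr}\,\widehat\Sigma_k}{d}\,I\Big),$$

where $\widehat\Sigma_k$ is the empirical covariance of segment $k$ about
its own mean, $d$ the channel count, and $\lambda = 10^{-3}$ a unitless
trace-scaled regularizer (absolute floor $10^{-12}$, so constant segments
stay finite). Segmentation runs on the MVC-normalized envelope resampled
to 100 Hz — envelopes are band-limited to 6 Hz, so plain subsampling is
alias-free — with per-segment estimated means: the zero-mean Gaussian
assumption holds for raw EMG, while envelopes carry their activation
level in the mean, and estimating it per segment reconciles the two.

`ggs_fit()` is greedy: breakpoints are inserted one at a time at the
split maximizing the total score, and after each insertion all
breakpoints are cyclically re-optimized within their neighbours' spans
until none moves. When single-breakpoint moves stall, adjacent breakpoint
*pairs* are jointly re-optimized by an exact two-split search of their
outer span (coarse-to-fine for long spans); this escapes a class of local
optima that no single-breakpoint move can leave, and keeps the objective
monotone. `exhaustive_fit()` — exact dynamic programming over all
feasible partitions — serves as the test oracle: on multivariate
(2--3-channel) block instances the greedy fit matches the exact optimum
essentially always.

Numerical choices: minimum segment length 100 ms, floored at $d+2$ rows
so $\widehat\Sigma_k$ has full rank; ties in split position go to the
earliest index (determinism); breakpoints map back to original-rate
samples by the resampling index. A **known limitation**: on *univariate*
series with short blocks, insertion-based greedy (with any local
adjustment) can land in a joint local optimum a few percent below the DP
optimum in roughly 1--2% of draws — an intrinsic property of top-down
greedy segmentation; the EMG use case is 12-channel, where we have not
observed it.

With $K = 3$ the segments are labelled reaching, grasping, returning,
resting in temporal order; ordering is imposed by this fixed assignment
(the protocol's phase order), not by a transition prior.
`annotate_gesture()` labels motional samples with the trial's gesture and
resting samples 0.

## Windows and features

Envelopes are sliced into 320-ms windows, stepped every 40 ms. Because
40 ms is 62.5 samples, start indices are computed in milliseconds and
floored per window — the mean step stays exactly 62.5 samples with no
cumulative drift; a 4-s trial yields 93 windows. A window straddling a
boundary takes the phase of its centre sample (the least biased single
assignment). Per channel and window, three time-domain features are
computed on the normalized envelope: RMS $\sqrt{\overline{x^2}}$, MAV
$\overline{|x|}$, and population variance $\overline{(x-\bar x)^2}$,
concatenated as $[\mathrm{RMS}_{1..C},\mathrm{MAV}_{1..C},
\mathrm{VAR}_{1..C}] \in \mathbb{R}^{36}$ — a fixed ordering that is part
of the classifier contract. The identity
$\mathrm{RMS}^2 = \mathrm{VAR} + \text{mean}^2$ ties the three together
and is enforced in tests at $10^{-9}$ relative tolerance.

## Classifier and training strategies

`train_gesture_model()` fits 50 extremely randomized trees (`ranger`,
`splitrule = "extratrees"`, no bootstrap, full sample per tree) over the
14 classes (0 = rest, 1..13 = gestures). Remaining hyper-parameters stay
at the implementation defaults; a fixed seed and single-threaded
prediction make every run reproducible. Probability vectors are expanded
to all 14 classes, with classes absent from training at exactly 0, and
argmax ties resolved toward the lowest class index.

Validation uses a per-object 3-fold plan (`build_split()`): each
object's 6 trials are partitioned into 3 disjoint pairs; fold $f$ trains
on 4 trials (66.7%) and validates on pair $f$, so every trial is
validated exactly once. (The alternative reading — three independent 4/2
draws — is not implemented; the disjoint rotation gives complete
coverage with the same 4/2 shares.)

Three phase-selection strategies control which windows train the model:
S1 reaching + resting, S2 grasping + resting, S3 reaching + grasping +
resting. Returning windows are never trained on (the posture is
dissolving and carries no forward-looking intent), though the model is
still evaluated there.

## Grasp-onset-aligned evaluation

Since subjects move at their own pace, validation trials are aligned at
the start of the grasping phase ($t = 0$, the segmentation's first
breakpoint), snapped to the 40-ms window grid, and the last 700 ms of
resting-phase predictions from the session's preceding trial are
prepended at negative times (the prepended region is flagged, and counts
toward rest accuracy). At each grid time, curves are averaged over
whichever trials have a window there, with support counts recorded:

* `p_grasp(t)` — mean probability of the trial's own gesture;
* `p_rest(t)` — mean probability of class 0;
* `p_top(t)` — mean probability of the *top competitor*, the strongest
  class outside {0, gesture}, computed per trial and time point before
  averaging (the competitor's identity may change along the way);
* accuracy curves — among trials in a motional (resp. resting) phase at
  $t$, the fraction predicting the gesture (resp. rest).

Two scalar summaries characterize a strategy. The **intersection time**
$t_i$ is the earliest grid time where `p_grasp` reaches `p_rest` and
stays there for 3 consecutive grid points (persistence suppresses
single-window noise), refined below the grid by linear interpolation;
negative values mean the decoder commits before grasp onset, and earlier
is better for pre-shaping. The **probability margin** $d_p$ is
`p_grasp - p_top` at the grasp-probability peak (earliest peak on ties):
how confidently the true gesture beats its strongest distractor. Grid
points supported by fewer than 20% of trials are masked from both
searches — curve tails where few long trials survive are unreliable.
`confusion_summary()` tabulates predictions over a pre-shaping window
$[t_a, 0]$ with the trial gesture as ground truth, row-normalized, with
the mean diagonal as the headline pre-shaping accuracy.

On the default synthetic suite the qualitative pattern expected from the
physiology reproduces: S2 (grasp-trained) crosses later than S1
(reach-trained), because early-reach envelopes are scaled-down grasp
patterns that a grasp-trained model initially reads as rest, while S3
attains the largest margin by seeing both regimes. Accuracy during
returning is low for all strategies — that phase is never trained on —
and that is expected, not a defect. The printed real-data values of the
source protocol depend on human recordings and are not reproduction
targets here; the *ordering* of the strategies is.

By default accuracy/alignment use the GGS segmentation (as deployment
would); `run_pipeline(segmentation = "truth")` switches to generator
ground truth, separating segmentation error from classification error.

## Problem sizes

The shipped tests run the full pipeline on reduced sessions (13 gestures
x 1 object x 6 or 3 trials) and the segmentation-recovery suite on 104
default trials; the acceptance script runs the complete default session
(52 objects, 312 trials) end to end. These sizes were chosen so a single
CPU completes each suite comfortably; all counts other than session size
stay at protocol defaults.

## Limitations

* Synthetic EMG only; no claim transfers to human data without
  recordings (see the generator's non-goals above).
* Zero-phase filtering and whole-trial segmentation are offline
  conveniences; a causal deployment would add latency at both stages.
* The 14-class probability calibration of extra-trees is not studied;
  $t_i$ and $d_p$ compare probabilities within one model, never across
  models.
* Univariate greedy segmentation can be suboptimal (above); use
  `exhaustive_fit()` for small univariate problems.
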