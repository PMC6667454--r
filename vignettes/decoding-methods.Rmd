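---
title: "Decoding question-and-answer speech from high-gamma activity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding question-and-answer speech from high-gamma activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decoding problem

During a question-and-answer task, a participant alternately *hears* a
question and *speaks* an answer while cortical field potentials are recorded
from an electrode grid covering auditory (superior temporal) and sensorimotor
(ventral sensorimotor) speech areas. `qadecoder` implements the full chain
that turns those recordings into utterance predictions:

1. **Feature extraction** — high-gamma (70–150 Hz) analytic amplitude,
   averaged over an eight-band filter bank, z-scored in a sliding window and
   clipped; the result is a frames × electrodes matrix at ~95.37 Hz.
2. **Speech event detection** — a PCA-LDA classifier labels every frame
   *perception*, *production* or *silence* from a spatiotemporal window of
   the relevant electrodes; smoothing, thresholding and debouncing turn the
   frame probabilities into discrete events with onsets and offsets.
3. **Utterance classification** — each candidate utterance is a left-to-right
   hidden Markov model over its phone sequence with boundary silences;
   frame-wise phone likelihoods come from a second PCA-LDA model, and Viterbi
   decoding yields per-utterance log likelihoods, which are smoothed and
   normalized onto the probability simplex.
4. **Context integration** — decoded question likelihoods are mixed with the
   task's context priors (which answers validly follow which questions) to
   produce answer priors; answer likelihoods are combined with those priors
   into posteriors, and the argmax answers with and without context are
   reported.
5. **Evaluation** — utterance error rate / accuracy rate, classification
   accuracy with bootstrap intervals, cross entropy in bits, the weighted
   detection score, electrode discriminative power, decision finalization
   times, phone confusions and place-of-articulation mutual information,
   plus native Holm–Bonferroni, exact McNemar, permutation and bootstrap
   tests.

The package's own synthetic-session generator stands in for clinical
recordings so that every stage is exercisable and testable end to end.

## Models and their assumptions

**Detector.** Frame classes are modeled discriminatively as
`p(h_t | y_t)` with `h_t ∈ {perception, production, silence}` and `y_t` the
concatenated z-scores of the selected electrodes over the closed frame window
`[t + ν_shift, t + ν_shift + ν_duration]`. Electrodes enter the model when
Welch's ANOVA across the three classes rejects at the configured p-value.
PCA keeps the minimum number of components explaining the configured variance
fraction; LDA uses a shared covariance with Ledoit–Wolf shrinkage and flat
class priors. The detection stage assumes events are non-overlapping within a
modality, which matches the task's alternating structure.

**Classifier.** Each utterance HMM has states `[sp, phone_1, …, phone_K, sp]`;
every non-final state self-transitions with probability `p_self` or advances
with `1 − p_self`, and the final state is absorbing. Variable dwell makes the
likelihoods robust to natural variation in phone durations, and the boundary
silence states absorb small detection timing errors. Emission terms are the
phone model's class log posteriors under flat priors, used as likelihood
surrogates — a discriminative stand-in that is exact up to per-frame
constants, which cancel across utterances during normalization. The Viterbi
recursion weights emissions by `w_e` relative to transitions and is
initialized with path log probability 0 at the initial silence and −∞
elsewhere.

**Context.** The context prior `p(u_a | u_q)` is flat over the answers in the
question's QA set and zero outside it. Answer priors are the log-sum-exp
mixture of prior columns weighted by the decoded question likelihoods,
renormalized for reporting (the dropped constants cancel in the posterior
normalization either way — tested by perturbation). Posteriors weight the
log prior by the scaling factor `m`. Priors persist across trials within a
block, update only when question likelihoods arrive, and reset between
blocks; an answer event arriving before any question yields likelihoods but
no with-context prediction.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `anova_p_threshold`, `p_threshold` | 1e-3 | p-value | electrode inclusion (ANOVA for detection, Welch t-test vs. silence per modality for classification) |
| `nu_shift`, `nu_duration` | −9/9 (detector), −4/8 (classifier) | frames | spatiotemporal window; trailing-biased for causal operation |
| `pca_variance_fraction` | 0.8 | fraction | minimum components explaining this much variance |
| `smooth_len` | 10 | frames | trailing probability average (per modality) |
| `prob_threshold` | 0.4 | probability | binarization of smoothed event probabilities |
| `time_threshold` | 8 | frames | debounce duration for onsets and offsets |
| `onset_shift`, `offset_shift` | −20 / +20 | frames | widen detected windows to include boundary silence (~0.2 s at 95.37 Hz) |
| `p_self` | 0.9 | probability | expected dwell 1/(1 − p_self) = 10 frames ≈ 105 ms per phone |
| `w_e` | 1 | — | emission weight in the Viterbi recursion |
| `omega` | 1 | — | likelihood smoothing; 0 = uniform, 1 = plain log-softmax |
| `m` | 1 | — | context prior scaling in the posterior |
| `pad_s` | 0.3 | s | silence padding around true event windows before decoding |

All of these are exposed through `detector_config()` /
`classifier_config()` and are searchable with
`optimize_hyperparameters()` (best-of-epochs sampling from prior
distributions; `optimize_loo()` wraps the leave-one-block-out scheme in
which each block's configuration is chosen on the other blocks). The
defaults above were fixed once from exploratory runs on synthetic sessions
and are not re-tuned by any test.

## The synthetic-data generator

`generate_block()` emulates the statistical structure the decoder relies on,
not cortical biophysics:

- Each non-silence phone has a fixed random spatial pattern (unit L2 norm)
  confined to an "auditory" electrode subset for perception and a disjoint
  "motor" subset for production, scaled by `template_gain` (default 2
  z-units) and shaped in time by a smooth positive within-phone profile.
- Block structure follows the task: question training presents each of the 9
  questions 10 times in random order; answer training has each of the 24
  answers produced 10 times; testing blocks hold 26 question-answer trials
  with 2–3 s inter-event silences, the answer drawn uniformly from the
  question's valid set (an option reweights questions by their number of
  valid answers).
- Noise is i.i.d. Gaussian per frame and electrode (`noise_sd`, default 1
  z-unit, giving a realistic order-one background), optionally AR(1)
  temporally correlated; features are clipped to [−3.5, 3.5] like the real
  feature chain.
- Phone durations are uniform on `phone_duration_range` (default
  0.06–0.20 s), a plausible speech range; real stimulus-specific timing is
  not modeled.

What passing tests therefore show: the chain recovers exactly the structure
it assumes (spatially coded phones, HMM-compatible timing) at favorable SNR.
What they do not show: robustness to real ECoG nuisance structure —
electrode correlations, epileptiform artifacts, non-stationary baselines,
coarticulation, or phone patterns that overlap across modalities.

## Numerical choices

- Log-domain throughout; log-sum-exp with max subtraction; a log floor of
  −1e10 replaces −∞ wherever hard zeros must survive (zero context priors,
  rounded-to-zero LDA posteriors), so impossible options stay impossible
  deterministically.
- Argmax ties break to the lowest utterance index (stable and documented).
- Sliding z-score uses running single-pass window updates; frames before one
  full 30 s window use expanding statistics, and zero-variance windows map
  to z = 0 rather than NaN.
- PCA is computed from the eigendecomposition of the feature covariance
  (equivalent to SVD up to sign, faster for many frames); LDA covariance uses
  the Ledoit–Wolf closed-form shrinkage toward a scaled identity on
  class-mean-centered residuals, plus a 1e-10 ridge against exact
  singularity.
- Band-pass filters are equiripple (Parks–McClellan) designs with passband
  edges at the geometric half-spacing around each center and nominal 15%
  transition bands; because the exchange algorithm can fail to converge (or
  converge to a useless solution) on particular grids, the design retries
  over a deterministic ladder of grid densities and marginally narrower
  transitions and validates the response before accepting. The Hilbert stage
  is a windowed ideal (type III) FIR transformer whose real branch is the
  input delayed by half the order (40 samples at order 80).
- An event still open at the end of a stream is closed at the final frame;
  events whose shifted offset does not exceed their onset are dropped.
- Detection smoothing is a trailing (causal) average, chosen so replayed and
  batch decoding are bit-identical; the streaming detector is the same state
  machine run frame by frame.
- Discriminative power is back-projected through the absolute PCA weights as
  a normalized weighted mean, keeping every per-electrode value inside
  [0, max component value]; per-electrode scores take the maximum over that
  electrode's time lags.

## Design decisions on open points

- Phone sequences for the 33 utterances ship as a fixed ARPAbet-style
  fixture so tests are reproducible without a forced aligner; `y` and `n`
  are quoted in the YAML because bare YAML scalars would parse them as
  booleans.
- Emission scaling at the first frame: the stated initialization (zero at
  the initial silence, −∞ elsewhere) is taken literally, so the first
  frame contributes only its scaled emission.
- Hyperparameter search uses best-of-epochs random sampling from the
  declared priors; the selection contract (evaluate on a held-out
  validation block set, keep the best epoch) is what downstream analyses
  rely on, not the specific proposal mechanism.
- The nine place-of-articulation categories ship as a standard ARPAbet
  mapping fixture (vowels as one category).
- Bootstrap and permutation resample counts default to 10^4 in interactive
  use (10^3 or fewer in tests); classification-accuracy and cross-entropy
  intervals support raising this to 10^6.

## Problem sizes used by the test suite

Integration tests run a reduced study: 32 electrodes (12 auditory, 12
motor), 0.06–0.12 s phones, 0.8–1.2 s training silences and the standard 2–3
s testing silences, `noise_sd` 0.05 (high SNR), with training strides of 2–3
frames when fitting the PCA-LDA models. Block structure is never reduced:
10 repetitions per training stimulus and 26 testing trials. The generator's
defaults keep the full-scale values (128 electrodes, noise_sd 1).

## Known limitations

- The generator's phone code is purely spatial and stationary; it cannot
  probe temporal-dynamics modeling or articulatory structure, so phone
  confusions on synthetic data are uninformative about articulatory
  clustering (the mutual-information machinery is exercised with its own
  constructed confusions instead).
- LDA posteriors are likelihood surrogates; absolute cross-entropy values
  are comparable across models but are not calibrated generative
  likelihoods.
- Numerical equivalence with any particular hardware filter chain is not
  claimed; the design parameters (band centers, orders, delays, rates) are
  reproduced, the ripple behavior of specific historical filters is not.
- Real-time operation is emulated by causal replay; scheduling, latency and
  acquisition-hardware concerns are out of scope.
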