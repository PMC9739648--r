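---
title: "Methods: cooperative activity recognition with transmission suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cooperative activity recognition with transmission suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panhar)
library(dplyr)
```

## The problem and the network model

`panhar` implements human activity recognition (HAR) over a small personal
area network (PAN) of body-worn inertial nodes: a main node (a smartphone,
typically at the waist) plus up to three supporting nodes at other mounts
(chest, leg, arm). Eight activity classes are recognised — walking, jogging,
squats, jump, lying, arms_swing, sitting, standing — from 3-axis
accelerometer plus 3-axis gyroscope windows.

Every node runs its own classifier $M_i$ on its local window $X_i(t)$ and
obtains a class $d_{i,t}$ with a weight $w(d_{i,t})$, the softmax
probability of the winning class. Two mechanisms then couple the nodes:

1. **Gated reporting.** A supporting node transmits its $(d_{i,t},
   w(d_{i,t}))$ pair only when $d_{i,t}$ lies in its *transmit set*
   $D_i^s \subseteq D$: $s_{i,t} = 1 \iff d_{i,t} \in D_i^s$
   (`should_transmit()`). Everything else is suppressed, saving the radio
   energy that dominates a small node's budget.
2. **Weighted vote.** The main node sums, per class, the weights of its own
   result and of every report that arrived, and decides for the class with
   the largest sum (`vote()`). With no reports at all the main node's own
   result stands, so the network degrades gracefully to single-node
   recognition under outages.

The main node collects reports during one decision window while classifying
its own data, so the decision for step $t$ is computed at the start of step
$t+1$. `decide_stream()` and `simulate_pan()` implement this one-window
latency; `latency = FALSE` emits in place for offline evaluation (the
labels are identical, only the emission step moves).

**Tie rule.** Summed scores can tie. The decision is the tied class with
the lowest canonical index; this is deterministic and documented, and the
canonical order itself (`activity_levels()`) is fixed package-wide, since
transmit-set vectors, weight vectors and confusion matrices all index
classes by it.

**Top-1 reporting.** A support transmits only its winning class and weight
— not the full probability vector — so only the top-1 pair enters the vote.
The main node's own full vector is locally available; `vote()` can use it
via `full_vector_nodes`, but the default treats the main node like any
other voter.

## Minimizing the transmit sets

`optimize_transmit_sets()` starts from full sets ($D_i^s = D$ for every
support), computes the ensemble's accuracy on the *training* stream, and
then scans supports and activities in order, tentatively removing one
(node, activity) obligation at a time. A removal is kept when the accuracy
drop from the current baseline is at most $\varepsilon$ (default 0.001 — a
value below one misclassified window in typical training streams, so a
single outlier cannot drive a removal); after a kept removal the new
accuracy becomes the baseline and the scan restarts from the beginning.
The loop ends when a full scan keeps nothing.

Design choices where the procedure was genuinely open:

* **Only supporting nodes are optimized.** The main node always classifies
  and votes locally; its "transmit set" has no meaning because it pays no
  radio cost for its own result.
* **Accuracy during optimization is evaluated on aligned (latency-free)
  decisions** — a recorded training set has no streaming semantics.
* **Full restart after every kept removal** (configurable via
  `restart_on_removal = FALSE` to continue in place). Restarting is the
  conservative reading of a re-baselined scan; both variants terminate
  because the total flag count strictly decreases.
* **Chained tolerance.** Re-baselining means the final accuracy is only
  guaranteed to be within $\varepsilon \times (\text{kept removals})$ of
  the starting accuracy; the `transmit_opt` trace records every trial so
  this bound is checkable (`tidy()` on the result).

`brute_force_minimum_sets()` is an intentionally small exhaustive search
(at most 2 supports, 4 observed classes) used as an independent oracle in
the tests: the greedy result must satisfy the oracle's accuracy constraint
and can never be smaller than the exhaustive minimum.

**The suppression metric.** For reporting, `expected_suppression()`
computes the share of avoided transmissions under two idealisations:
every activity occupies the same amount of time, and local recognition is
correct. Then a support with $m$ flagged classes transmits $m/8$ of the
time, so suppression is $100(1 - \sum_i m_i / (8k))$ percent for $k$
supports, rounded half-up to a whole percent (62.5 → 63; plain `round()`
would round half to even). The simulator reproduces this number exactly in
its oracle mode on a balanced stream, which is how the packaged reference
table is validated; with real (imperfect) classifiers the simulated
suppression differs, and both numbers are reported by `run_protocol()`.

## Per-node classifiers

Two backends share one contract (`fit_node_model()`, `predict()`,
`evaluate_model()`); swapping backends changes accuracy, never result
shapes or determinism guarantees.

* **`rnn`** — the reference architecture: LSTM(60) → Dropout(0.5) →
  Dense(60, ReLU) → softmax over 8 classes, categorical cross-entropy,
  Adam, batch size 64, at most 40 epochs (training accuracy plateaus by
  then and later epochs risk overconfident weights, which matter here
  because the softmax outputs *are* the vote weights). Dropout is applied
  at training only. The implementation is a compact native R LSTM with
  exact backpropagation through time; its gradients are verified against
  central finite differences in the test suite. Inputs are standardized
  per channel with training-set statistics.
* **`light`** — per-channel summary features (mean, standard deviation,
  energy, dominant non-DC frequency; 6 channels × 4 features) feeding a
  multinomial logistic model (`nnet::multinom`). It is deterministic given
  a seed and trains in seconds, which keeps the full pipeline, the
  optimizer and the sweeps testable interactively; it is the default
  everywhere except where the recurrent model is explicitly requested.

Both backends consume the same windows: 6 channels, gravity removed from
the accelerometer. A flag to append the gravity estimates as extra
channels exists in the preprocessing (`split_gravity(keep_gravity =
TRUE)`) for experiments, but the packaged defaults feed 6 channels.

## Preprocessing

The pipeline order is fixed: **trim → decimate → gravity split → window**
(`prepare_windows()`), and a regression test pins it, because decimating
first lets the gravity filter run at the target rate with a rate-matched
constant.

* **Trim** (default 2% per end) discards the preparation and stop phases
  of a recording session.
* **Decimation** to $F \in \{5, 10, 20\}$ Hz uses block averaging over the
  integer stride — the raw 100 Hz rate is an integer multiple of every
  target rate, block means preserve constants exactly, and the averaging
  acts as a simple anti-alias filter.
* **Gravity separation** uses the incremental low-pass
  $g_t = \alpha g_{t-1} + (1-\alpha) a_t$, $g_0 = a_0$, body $= a_t - g_t$.
  The default $\alpha = 0.9$ at 20 Hz (time constant ≈ 0.5 s) is rescaled
  as $0.9^{20/F}$ at other rates so the cutoff is rate-invariant.
* **Windows** of $WS \in \{64, 128, 196\}$ samples with 50% overlap by
  default (the common convention for 128-sample HAR windows); the stride
  is `max(1, round(WS * (1 - overlap)))` and a trailing partial window is
  dropped.
* **Splitting is by session, stratified by activity** (default 80/20).
  Overlapping windows from one session share samples; a window-level split
  would leak those samples across the boundary and inflate accuracy, so
  whole sessions land on one side.

## The synthetic corpus

The generator (`generate_session()`, `generate_corpus()`) emulates the
acquisition protocol of the study design this package targets: 2-minute
sessions per activity and mount, raw 10 ms sampling, first and last 2%
discarded, four mounts recorded simultaneously. Since no real recordings
ship with the package, the signal family is deliberately simple: per
(activity, mount), 1–2 sinusoidal harmonics of a shared base cadence with
per-channel amplitudes, plus a constant 9.81 m/s² gravity vector in a
mount- and posture-specific orientation, plus white Gaussian noise.
Session-level frequency (±2%) and per-channel amplitude (±7%) jitter play
the role of between-subject variation and make session-level train/test
splits non-trivial.

Default cadences: walking 1.8 Hz, jogging 2.8 Hz, squats 0.7 Hz, jump
1.2 Hz, arms swing 1.0 Hz; postures 0 Hz. Three intents are baked into the
amplitude tables, and the test suite asserts all three on the packaged
seed-42 corpus:

* **The waist struggles with the exercise pair.** Squats put their waist
  energy into the second harmonic (1.4 Hz) with channel-wise amplitudes
  identical to jump's 1.2 Hz fundamental, so at the waist the pair is
  separated only by which spectral bin wins under noise — a per-window
  cue that leaves irreducible confusion. At the leg the two differ
  grossly (landing spikes vs. deep slow flexion), so the pair separates.
* **Each mount has a blind spot.** The three postures differ only in
  tremor noise level once gravity is filtered out, and per-mount noise
  overrides give the chest a hard lying-vs-sitting pair and the leg and
  arm a hard sitting-vs-standing pair. No single node is perfect, and the
  ensemble has something to gain at every main-node choice.
* **Very low rates lose information.** Jogging's 2.8 Hz cadence exceeds
  the 2.5 Hz Nyquist limit of a 5 Hz sampling rate, so the 5 Hz end of
  the rate sweep is measurably harder than 20 Hz.

What the generator does **not** emulate: biomechanics (no joint model, no
soft-tissue artifacts, no orientation drift), sensor imperfections (bias,
scale, saturation), magnetometer/GPS/pressure channels, or any
non-stationarity within a session. Green tests on this corpus therefore
validate the *method's mechanics* — windowing arithmetic, vote algebra,
gating, the optimizer's contract — not field performance on real humans;
absolute accuracies here are optimistic.

**Scale presets.** `session_plan("desk")` (8 activities × 5 sessions ×
48 s, four mounts ≈ 4,300 windows) is sized so the whole pipeline — 28
configuration sweeps included — runs in well under a minute; it is the
packaged seed-42 fixture used throughout the tests.
`session_plan("experiment")` emulates the scale of the reference
acquisition campaign: 7 two-minute sessions per activity plus one
supplementary 99 s walking session, chosen so that the standard pipeline
(2% trim, 20 Hz, 64-sample windows, 50% overlap) yields exactly 16,136
windows across the four mounts — the corpus size the method's verification
experiments are reported at.

## Numerical and degenerate-input choices

* Half-up integer rounding for reported suppression percentages.
* First-maximum tie-breaks everywhere an argmax occurs (vote, prediction,
  dominant-frequency bin), making every path deterministic.
* A series shorter than one window yields zero windows with a warning;
  `trim_session` errors only on an impossible fraction (≥ 0.5), since
  `floor` arithmetic with a valid fraction always leaves at least one
  sample.
* Decimation to a non-divisor rate errors and names the nearest valid
  rate rather than silently interpolating.
* All randomness flows from integer seeds through one derivation helper;
  per-(activity, session) seeds keep simultaneously-worn positions
  phase-aligned while their measurement noise stays independent, and
  regenerating any subset of the corpus is reproducible in isolation.
* The light backend is bit-deterministic per seed. The recurrent backend
  is deterministic per seed on one platform, but cross-platform exactness
  is not promised (BLAS differences); tests involving it assert ranges
  and contracts, not exact values.

## Known limitations

* The greedy minimization is not optimal (the tests assert it is no
  *smaller* than the exhaustive minimum, not equal), and with large
  $\varepsilon$ its chained tolerance can drift below the single-step
  bound an exhaustive search would enforce.
* Suppression percentages are a proxy for energy; there is no radio,
  battery or latency model beyond the one-step decision delay, and no
  multi-hop topology — one hop to the main node, reports either arrive
  within the step or the node is failed.
* `expected_suppression()`'s balanced-activity assumption is exactly
  that; when sedentary classes dominate real days and sets flag mostly
  dynamic classes, realised suppression is higher than the balanced
  figure.
* The eight-class set and four mounts are fixed in the packaged fixtures;
  the types are size-generic but no other configuration ships.
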