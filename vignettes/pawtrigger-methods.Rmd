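---
title: "Selective paw-movement triggering: model, simulation, and validation analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective paw-movement triggering: model, simulation, and validation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pawtrigger)
```

## The problem

Closed-loop behavioral reinforcement in head-fixed mice requires detecting a
specific movement — here, a vertical reach of the left forepaw that is *not*
accompanied by a comparable right-forepaw movement — within tens of
milliseconds of its occurrence, and coupling it to feedback (a red LED flash,
and on training trials a water reward). In the rig this package models, the
detector is a markerless pose estimator that reports the tips of all eight
forepaw digits (four per paw) per video frame, and the decision is made on
*pairs* of consecutively received frames.

`pawtrigger` re-implements that decision pipeline and its entire validation
analysis as testable, hardware-free software. A synthetic session generator
stands in for the camera, the animal, and the neural network, so every stage
— streaming, trigger logic, feedback timing, LED-based ground truth, and
multi-day behavioral statistics — can be verified against a known script.

## The trigger model

Each frame carries 8 keypoints with confidences. Per paw, the four digit-tip
positions are averaged into a single paw position; for a frame pair the
decision statistic is the absolute change in mean vertical position,
$\mathrm{d}y = |\bar y_{\text{second}} - \bar y_{\text{first}}|$ (pixel
units, image convention: origin top-left, y downward). A pair triggers
feedback iff all gates pass, in this order:

1. $\mathrm{d}y_{\text{left}} \ge$ `min_left` (default 5 px; inclusive),
2. $\mathrm{d}y_{\text{left}} \le$ `max_left` (default 100 px; inclusive —
   a guard against tracking jumping across the screen),
3. $\mathrm{d}y_{\text{right}} \le$ `max_right` (default 10 px; a
   displacement of exactly 10 px does **not** veto — "does not exceed" is
   read as an inclusive bound, and the stricter "<10 px" phrasing used for
   the reinforcement study is available by lowering `max_right`),
4. aggregated keypoint confidence $>$ `confidence_min` (default 0.20),
5. more than `refractory` ms (default 300) have elapsed since the previous
   trigger. The refractory gate is evaluated last but suppresses
   unconditionally; a suppressed passing pair does not reset the clock, and
   exactly 300 ms elapsed still suppresses (strict inequality re-arms).

Two aggregation choices are deliberately configurable because the underlying
operational definition is ambiguous: the confidence gate uses the **mean**
over the 8 keypoints of the pair's **second** frame by default
(`confidence_aggregate = "min"` and `confidence_frames = "both"` are the
conservative alternatives). Displacements are always computed from all four
digits, regardless of per-digit confidence.

Feedback is a 200 ms red-LED pulse; training trials add a simultaneous
150 ms water pulse, and a green cue LED is held on for the whole trial.
Baseline trials keep the red LED but never deliver water, and the green cue
stays off. Because the refractory period (300 ms) exceeds the LED pulse
(200 ms), feedback pulses can never overlap; the mock device asserts this
anyway.

## Streaming semantics

Frames are consumed in non-overlapping batches of two: received frames form
pairs (1st, 2nd), (3rd, 4th), ... Movement between the last frame of one
pair and the first of the next is *not* evaluated — this mirrors the batch
design of the original acquisition loop, and the brute-force offline oracle
(`offline_oracle()`) uses the same pairing so online/offline equivalence is
exact, not approximate. Dropped frames arrive as explicit placeholder
records: they are counted in the drop ledger and skipped when forming pairs,
so a pair formed across a drop is flagged `non_adjacent` rather than
discarded. Conservation (`emitted = processed + dropped`) holds exactly for
every session.

Each trial begins with a buffer period (default 10 s) during which the
analysis runs but nothing is persisted and no feedback is delivered,
followed by a short wait (default 100 ms) before persistence begins; the
recording window (default 120 s) follows. In the real rig the buffer lets
thread churn and the frame rate stabilize; here it is honored so that event
logs and latency statistics are computed over the same window a real session
would produce.

The original system ran four logical tasks per pair — acquisition,
evaluation, persistence, dispatch — on separate threads so that saving
labeled frames could never delay feedback. In this single-threaded replay
implementation that contract is modeled explicitly: persistence cost is
injectable (`persistence_delay_ms`) and is accounted in the persistence log
only; tests assert that dispatch time stamps are unaffected (within 5 ms) by
a 200 ms injected persistence delay.

## The synthetic session generator

`motion_script()` declares a session; `generate_pose_trace()` realizes it
deterministically from its seed (same seed, bit-identical output). What it
emulates, and the defaults chosen:

* **Reaches** are half-cosine vertical excursions (rise and return over
  `rise` seconds each, default 0.1 s; amplitude default 20 px). Smooth ramps
  rather than steps were chosen deliberately: per-pair displacement then
  depends on the frame rate, so the generator exercises the sampling-rate
  reasoning a step function would hide. At 50 Hz a 20 px/0.1 s reach peaks
  near 6.3 px per pair (above the 5 px criterion); at 100 Hz the same reach
  peaks near 3.1 px and does not trigger — a physically meaningful
  interaction, not a bug. Reach amplitude and rate are free parameters: the
  source study does not report reach amplitude distributions.
* **Grooming** moves both paws with correlated oscillations (default 15 px,
  4 Hz, right paw at 0.9 of the left excursion). Grooming-like co-movement
  *can* produce triggers in the slow phases of the oscillation — consistent
  with the observation that real grooming sent triggers — and it stresses
  the contralateral veto in the randomized equivalence sweeps.
* **Acquisition imperfections.** Inter-frame timestamp jitter defaults to
  4.16 ms SD, the observed between-frame variability of the modeled rig;
  per-frame drops default to probability 0.67 at a 200 Hz nominal input
  rate, reproducing the ~66 Hz realized throughput of the reinforcement
  study. Timestamps are forced monotone after jittering (a monotonic
  acquisition clock).
* **Rendering.** `render_frames()` draws 8 high-contrast square markers at
  the keypoint positions on a constant background, plus a bright disc inside
  a fixed, documented LED region of interest (top-right corner, 24 px
  square by default, scaled down on very small frames) during flash frames.
  Optional per-pixel Gaussian noise models sensor noise; ROI-level noise is
  its 576-pixel average, which is how noise enters a real LED trace.

What the generator does **not** emulate: photorealistic paws, occlusion,
lighting drift, estimator mislocalization under domain shift. Passing tests
therefore demonstrate that the *decision and analysis pipeline* is correct
given keypoints of stated quality — they say nothing about the accuracy of
any particular pose network on real video.

The oracle pose backend (`estimate_pose()`) recovers the rendered markers by
thresholding and single-linkage connected grouping, assigning labels
geometrically (four leftmost centroids are the left paw). It is exact to
well under 1 px on clean frames and within 1 px under 1 px Gaussian blur,
which is what makes full-loop round-trip tests possible without a network.

## Latency quantification, two ways

*Time-stamp latency* is `dispatch_time - frame_time` per event, measured
entirely from the software's clocks. In replay there is no real computation
to time, so the pose+decision cost is a configurable constant
(`processing_delay_ms`, default 30 ms — representative of the modeled rig's
reported delays, but explicitly hardware-dependent and not a claim) and the
device leg defaults to 0.31 ms in the mock.

*Ground-truth latency* is measured from the video itself: the mean intensity
of the LED ROI is thresholded at `baseline mean + 3 SD`; the onset is the
first crossing frame (frame-level resolution, no interpolation), re-arming
only after the intensity returns below threshold. The first 800 frames are
never searched, because drop bursts early in a trial corrupt that window.
Baseline statistics are computed from post-skip frames, excluding guard
windows around logged triggers when an event log is available — otherwise
the flashes themselves inflate the baseline SD and can push the threshold
above the flash amplitude. A zero-variance baseline is floored at an epsilon
SD (1e-6 intensity units) with a warning. Note one inherent property of the
3 SD rule: under unbounded (e.g. Gaussian) frame noise its false-positive
rate is nonzero, so spurious onsets over long traces are a property of the
method, not of this implementation.

`compare_latency_methods()` runs a standard paired t test on per-trial mean
latencies from the two routes; all-zero differences are reported as a
zero-variance case. `nyquist_limit()` reports half the processed frame rate
(the fastest movement frequency representable without aliasing), and
`px_to_mm()` applies a user-supplied scene calibration — the calibration is
a required input because a pixel threshold only acquires physical meaning
through the measured scene scale (at 44 mm across 256 px, the 5 px criterion
is 0.859 mm).

## Behavioral statistics

The multi-day analysis consumes trial records and reuses the engine's
pairing and $|\mathrm{d}y|$ conventions everywhere, so trigger counts,
post-trigger contralateral counts, and per-digit counts are computed on
identical primitives:

* `count_triggers()` / `mean_trigger_counts()`: per-trial counts keyed by
  mouse, day, mode.
* `count_post_trigger_contralateral()`: right-paw movements above threshold
  on the pair immediately following each trigger (the selectivity check);
  strictly greater than 10 px, matching the limit's role as a veto.
* `count_digit_movements()`: per-digit thresholded counts, `>= 5` px for
  left digits and `> 10` px for right digits, as in the reinforcement rules.
* `paired_t_bonferroni()`: paired t tests on per-mouse cell means with an
  explicitly declared Bonferroni family (`p_adj = min(1, p × family size)`).
  Pairing is by mouse — with seven animals, pairing by trial would be
  unjustifiable. Zero-variance cells are flagged, not significant.
* `anova_digits()`: one-way ANOVA across digits within each (day, mode)
  stratum, via `stats::aov`.
* `bootstrap_mean_difference()`: the estimation-statistics view. Mice are
  resampled with replacement; the statistic is the mean paired difference;
  the default interval is BCa (bias-corrected and accelerated, with the
  jackknife acceleration), matching the estimation-statistics package family
  this analysis style comes from, with percentile as a fallback. The seed is
  mandatory and is carried into every report. Degenerate input (all
  differences equal) yields a point interval.

A declarative QC filter (`qc_trials()`) implements the exclusion rules
applied before any summary: trials with mean time-stamp latency above 500 ms
(malfunctioning runs), optionally trials with zero above-criterion events,
and mice not run on all required days. QC is applied before summaries.

### A note on bootstrap calibration at small n

The package's calibration tests verify 95% CI coverage under a true-zero
effect across 500 simulated experiments of 40 pairs each, a regime where the
nonparametric bootstrap's nominal level applies, and effect detection at the
study scale of n = 7 mice. At n = 7 the percentile and BCa bootstrap of a
mean are known to undercover (the resampling distribution is too narrow by
roughly $\sqrt{(n-1)/n}$ and the tails are thin); this is an inherent
small-sample property of the method, shared by the original analysis style,
and users should read 95% intervals over seven animals as approximate.

## Numerical and design choices

* Pixel coordinates are 1-based with origin top-left (R convention);
  DLC-dialect CSV export writes 0-based frame indices for compatibility.
* "After the 800th frame" means onsets are allowed from frame 801.
* Boundary semantics: left gate inclusive on both ends; right gate inclusive
  (10 px passes); confidence strictly greater; refractory strictly greater.
* Dropped frames never appear in pairs; exhaustion mid-pair discards the
  unpaired frame silently (logged as `unpaired` in the ledger).
* Tie-break in event/onset matching: each event takes the nearest
  *following* onset within a 1 s window, each onset used at most once;
  negative latencies are flagged as alignment errors, never silently kept.
* All randomness flows from explicit seeds (`withr::with_seed`); no function
  mutates the global RNG state.
* Problem sizes in the test-suite and acceptance script (10–20 s sessions at
  40–120 Hz, 64 px renders, 2000 bootstrap resamples, 500 calibration
  replicates, a 7-mouse × 5-day × 6-trial experiment) were chosen as the
  smallest sizes at which every property being tested is well-resolved;
  the package itself runs full 130 s, 256 px, 200 Hz sessions with the same
  code paths.

## Known limitations

* The replay clock is simulated; absolute latency values produced here
  characterize the configuration, not any hardware.
* The pose oracle assumes non-overlapping, high-contrast markers; it is a
  test instrument, not a tracker for real video. An external estimator can
  be plugged in as a backend (frame record in, 8 keypoints out).
* The criterion is a fixed left/right vertical-displacement predicate plus
  configurable thresholds; a general multi-body-part predicate language is
  intentionally out of scope.
* Bootstrap CIs at n = 7 are approximate (see above).
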