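---
title: "Methods: quantifying proboscis extension and the gustatory signals that drive it"
author: "perflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying proboscis extension and the gustatory signals that drive it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perflex)
```

# Overview

When a starved fly encounters an appetitive stimulus it extends its
proboscis — the proboscis extension reflex (PER), the standard readout of
feeding initiation in *Drosophila*. `perflex` quantifies this behavior from
markerless pose tracking, together with the peripheral signals thought to
drive it: calcium responses of sweet- (Gr5a) and bitter-sensing (Gr66a)
gustatory receptor neurons (GRNs), and spike counts from labellar taste
sensilla. The package is organized as five analysis stages plus a
synthetic-data layer that can emulate every input modality with known
ground truth, so each detector can be validated end to end without any
experimental recording.

# Behavioral quantification

## Proboscis angles

Six head landmarks are tracked per video frame at 20 Hz: the proximal and
distal ends of the antenna, the rostrum apex, the rostrum–haustellum
joint, the haustellum–labellum joint, and the labellum tip. From these,
`computeAngles()` derives three unsigned angles in degrees:

* **rostrum angle (R)** — between the antenna line (proximal→distal) and
  the rostrum segment (apex→rostrum–haustellum joint);
* **haustellum angle (H)** — the interior angle at the rostrum–haustellum
  joint;
* **labellum angle (L)** — the interior angle at the haustellum–labellum
  joint.

Coordinates are image-convention pixels (origin top-left, y increasing
downward); because all three angles are unsigned interior angles obtained
from `acos` of normalized dot products, the y-flip has no effect on their
values. Angles always lie in [0, 180] and are reported in degrees
everywhere; radians never appear in an interface. Extension corresponds
to *larger* H (a folded proboscis has H near 60°, a fully extended one
above 100°).

The choice of the rostrum line's endpoints (apex to rostrum–haustellum
joint) is a modeling decision — the two endpoints of "the line along the
rostrum" admit alternatives — and is therefore isolated in one function
and exercised by a generate-then-invert test: `landmarksFromAngles()`
renders landmarks realizing any target angle triple, and
`computeAngles()` recovers the triple to better than 1e-6 degrees across
(1°, 179°)³.

## Tracking-likelihood filtering

Pose estimators attach a per-frame likelihood to each landmark. Frames
where any landmark's likelihood falls below `likelihood_min` (default
0.9) have that landmark's coordinates linearly interpolated from the
neighboring confident frames before angles are computed. Setting
`likelihood_min = 0` disables filtering. No other smoothing is applied —
kinematics beyond interpolation are deliberately untouched so that event
boundaries are not biased.

## Baseline and event detection

The slow posture drift of each angle is estimated by
`rollingBaseline()`: the 25th percentile of a centered 5 s rolling window
(101 frames at 20 Hz), clipped at the sequence edges. A *centered* window
was chosen over a trailing one because a trailing window lags the signal
and would systematically bias onset latencies; the percentile (rather
than a mean) makes the baseline insensitive to extension episodes that
occupy less than ~75% of the window.

Two detectors operate on the angle series:

* `detectPER()` — full PER: maximal runs of frames with **H > 100°**, the
  angle corresponding to full extension. Runs separated by at most
  `merge_gap = 2` frames (100 ms) are merged and events shorter than
  `min_duration = 2` frames are dropped; both filters exist solely to
  suppress single-frame tracker jitter, are configurable, and are set to
  0 in the oracle tests so that events tile exactly the super-threshold
  frame set.
* `detectExtensions()` — PER *and* partial extensions, segmented from the
  baseline-subtracted rostrum angle by hysteresis thresholding with a
  lower threshold of 5° and an upper threshold of 15°: an event is seeded
  wherever the signal exceeds 15° and grows outward through the
  contiguous region above 5°. Events are labelled `PER` or `partial` by
  whether H exceeds 100° inside them.

Event intervals are half-open `[onset, offset)` in 1-based frames; an
event covers frames `onset … offset-1`, and its time span is
`[(onset-1)/fps, (offset-1)/fps)` seconds.

## Trial and fly metrics

For each trial, `trialMetrics()` scores PER against a window of 4 s
starting 1 s after the valve opens. The 1 s offset absorbs the odor's
travel time to the fly (measured at ~1.1 s in the frontal-delivery
configuration; `odorArrivalDelay()` exposes the constant) and the window
covers the period in which most odor-evoked extensions occur. Reported
per trial: integrated PER duration (total event overlap with the window,
bounded by 4 s), per-second durations (the same overlap split into 1 s
bins), a response flag (any PER onset within 5 s of odor onset; a 2 s
preset suits brief-touch assays), and latency. Because the scoring window
already embeds the 1 s offset, the `odor_delay_s` argument defaults to 0
— applying the 1.1 s preset *and* the offset would double-count the
delay.

`flyMetrics()` averages across the three presentations of each stimulus:
PER probability (% of trials with a response), mean integrated duration,
mean latency. A trial is flagged *spontaneous* when a PER onset occurs in
the trial period but outside the response window — an operational reading
of "repetitive, spontaneous PER", which the assay treats as an abnormal
state. Flies with spontaneous PER in more than 9 of the 27 trials are
flagged `excluded`; the flag is informational and nothing is silently
dropped. Whether the count should run over all 27 trials or only control
trials is not determinable from the assay description; all trials are
used.

# Trajectory comparison

Extension episodes differ in duration, so their (rostrum, haustellum)
angle trajectories are compared with dynamic time warping
(`dtwDistance()`): minimal cumulative Euclidean cost over monotone
alignments with unit steps (match/insert/delete), constrained to a
slope-adjusted Sakoe–Chiba band of half-width 0.25 s (5 frames at
20 Hz). Design choices, each of which the oracles share:

* symmetric unit step pattern without step weights — the common default;
* band membership for cell (i, j) of an n×m grid is
  `|i·m − j·n| ≤ w·max(n, m)`, which reduces to `|i − j| ≤ w` for equal
  lengths and, unlike the one-sided form `|i·(m/n) − j| ≤ w`, is
  invariant to swapping the arguments, making the distance symmetric by
  construction;
* no z-normalization (both dimensions are angles in degrees and share a
  scale); exposed as an option;
* raw cumulative cost, not divided by path length; `normalize = TRUE` is
  available for robustness studies.

`kMedoids()` clusters the resulting distance matrix PAM-style: assign
each trajectory to its nearest medoid, then move each medoid to the
member minimizing the within-cluster distance sum, iterating to
stability. Restarts (default 10) are initialized by distance-weighted
farthest-point seeding; everything is deterministic given the seed, ties
break toward the smaller index, and the cost trace is non-increasing by
construction (both alternating steps are monotone). `elbowK()` picks the
number of clusters as the interior k whose (k, cost) point lies furthest
from the chord joining the first and last candidates — perpendicular
chord distance, invariant to uniform cost scaling, ties toward smaller k
(so an exactly linear cost curve yields k = 2).

# Calcium imaging

Movies are volumetric: 5 optical planes scanned every 500 ms. Frame
numbering is 1-based and matches acquisition frames: stimulation begins
at frame 11 of a trial, the baseline is the five preceding frames (6–10),
and peak quantification uses frames 12–16.

`registerStack()` corrects rigid motion by exhaustive search over integer
3-D shifts (default ±10 px in x/y, ±2 planes in depth), maximizing the
Pearson correlation with a reference volume over the overlapping region;
candidates with less than 50% overlap are skipped, and ties break toward
the smallest shift magnitude, then lexicographically. Only integer shifts
are searched — no subpixel interpolation — which keeps the recovery of
synthetic shifts exactly testable. The default reference is the mean
volume of the first trial (the reference choice is open; any volume can
be supplied), and registration is per-volume with the per-trial
alternative left to the caller via explicit references. Vacated voxels
become `NA` and are excluded from downstream ROI means.

`roiTrace()` averages pixel intensity over a rectangular ROI across its
plane span (planes are averaged, not max-projected — the conservative
choice when axial blur spreads signal across planes). Typical rectangles
are 80×60 µm for Gr5a axons and 60×40 µm for Gr66a; micrometer sizes
require the movie's `pixel_size`. `dff()` computes
ΔF/F(t) = (F(t) − F₀)/F₀ with F₀ the 5-frame pre-stimulus mean, and
errors on non-positive baselines; ΔF/F is invariant to detector gain.
`peakResponse()` averages ΔF/F over the fixed frames 12–16 per trial and
arithmetically over each stimulus' trials. An alternative mode centers
the 5-frame window on the per-trial argmax for sensitivity checks; the
fixed window is the default because the acquisition protocol names
explicit frames.

# Sensillum electrophysiology

Tip recordings (10 kHz) are bandpass filtered at 100–1000 Hz by
`bandpassFilter()` — a Butterworth response applied forward and backward
(`signal::filtfilt`), i.e. zero-phase with a 4th-order magnitude
response, so filtering cannot displace spike times. The filter family is
a choice; only the band is dictated by the recording convention.

`detectSpikes()` counts spikes without sorting them (sensilla house
several GRNs whose spikes differ in amplitude; all are counted): an
excursion beyond `k_mad = 4` robust SDs (1.4826 × MAD) in either polarity
is a spike, timed at its extremum, with events closer than 1 ms collapsed
to the larger extremum. The MAD scaling makes detection invariant to
amplifier gain. All parameters are configurable. `countWindow()` counts
spikes in the half-open window [200, 700) ms after stimulus contact —
nothing before 200 ms is ever counted, which keeps the contact artifact
out of the measurement; a spike at exactly 700 ms falls outside.

# Statistics

## Scheirer–Ray–Hare test

`scheirerRayHare()` is the rank-based analogue of crossed two-way ANOVA.
All N observations are ranked jointly with midranks for ties; sums of
squares for the main effects and interaction are computed on the ranks
and each effect's statistic is H = SS_effect / MS_total with
MS_total = SS_total/(N−1), referred to a chi-square upper tail with
(a−1), (b−1) and (a−1)(b−1) degrees of freedom. Because MS_total is the
variance of the *actual midranks*, it already carries the tie reduction
D = 1 − Σ(t³−t)/(N³−N); H is therefore the classical tie-corrected
statistic, and with one factor at a single level the other factor's H
equals `kruskal.test`'s tie-corrected statistic exactly (verified to
1e-9). D is reported alongside the table. Sums of squares are type II, so
main-effect tests in unbalanced designs do not depend on factor order;
in balanced designs they coincide with sequential sums (verified in the
tests). Designs with empty cells are rejected with the offending cell
named. No multiplicity correction is applied within a test — per-test
p-values are reported, with `bonferroni()` available but off by default.

## The GRN → PER linear model

`fitPerModel()` regresses per-odor PER magnitude on the trial-averaged
peak ΔF/F of Gr5a and Gr66a GRNs by ordinary least squares with an
intercept (disableable). A positive weight marks enhancement and a
negative weight suppression of PER; model quality is
R² = 1 − SS_res/SS_tot. Constant outcomes and collinear predictors are
errors. The PER magnitude is taken to be the per-odor mean integrated
PER duration, the natural graded readout of the behavioral pipeline.

# Synthetic data

The generators are pure functions of (scenario, seed): seeds are explicit
end to end, generators save and restore the caller's RNG state, and the
returned ground truth is sufficient to score every downstream detector.

* `generateLandmarks()` — forward kinematics of a fixed head model
  (~50 px segments) renders the six landmarks from programmed angle
  trajectories. The default protocol mirrors the assay: 9 stimuli (six
  odors plus mineral-oil, water and air) × 3 blocks, 2 s stimulation,
  15 s inter-trial interval, 20 Hz. Planted PER events raise H to a
  rectangular excursion (peak ~130°, truncated normal) with short
  sub-threshold shoulders so that the super-threshold frame set equals
  the planted interval exactly in the noiseless case; partial extensions
  peak below 100°. Tracking noise defaults to 1 px SD — about 2° of
  angle noise at the model's segment lengths, far from the 40°+ margins
  of the thresholds, so default scenarios are solvable by design — with
  a 1% likelihood-dropout rate whose frames get 25 px corruption and low
  likelihood, exercising the interpolation path.
* `generateMovie()` — a Gaussian blob (compact support, zero background)
  scales multiplicatively with 1 + a·k(t), where the indicator kernel
  k(t) = (1 − e^(−t/0.2 s))·e^(−t/1.5 s), peak-normalized, is a slow
  indicator regime appropriate to the fluorophore; because every blob
  pixel scales by the same factor, the ROI-mean ΔF/F equals a·k(t)
  exactly without noise, giving a closed form for the pipeline peak
  (a × mean kernel over frames 12–16) that the tests check to 1e-9.
  Rigid shifts follow an explicit or random schedule within the
  registration search range; Gaussian noise is added last (the blob SNR
  is F₀/noise SD).
* `generateTrace()` — spike times from Poisson thinning with a 3 ms
  absolute refractory period, convolved with a biphasic ~1.7 ms template
  (a damped one-cycle 600 Hz wavelet, so its energy lies inside the
  recording band and filtering preserves the extremum time), at two
  amplitudes mimicking multiple GRNs; a damped 30 Hz contact artifact
  occupies the first 100 ms, and Gaussian noise is added. With a dead
  time τ the expected window count is λ/(1 + λτ) × 0.5 s — at λ = 40 Hz
  about 17.9 rather than the ideal-Poisson 20, which the Monte-Carlo
  tests use.
* `generateModelDataset()` / `generateFactorialDataset()` — per-odor
  gamma-distributed positive predictors scaled so the planted weights
  (5e-4 and −2.3e-5) act on responses of order 10³ and produce PER
  magnitudes of order 1 s, plus crossed factorial layouts with planted
  shifts in residual-SD units for size and power studies of the rank
  test.

What the generators do **not** emulate: systematic tracking failures that
persist for many frames (occlusion), nonrigid or subpixel tissue motion,
photobleaching and indicator saturation, bursting or amplitude-graded
spike trains, and correlated (non-white) noise in any modality. Passing
tests therefore demonstrate correctness of the computations under the
stated acquisition model, not robustness to every failure mode of real
recordings.

# Numerical choices and degenerate inputs

* Percentiles use linear interpolation between order statistics (R's
  default type-7 definition); the test oracle re-implements the same
  formula from a sort.
* Angle computation clamps cosines to [−1, 1] before `acos` and raises a
  degenerate-geometry error naming the first frame with a zero-length
  segment.
* DTW ties between step predecessors resolve by the `min` over
  predecessors (value-identical, path-irrelevant for the distance); an
  infeasible band raises an error suggesting a larger window.
* K-medoids assignment and medoid updates break ties toward the smaller
  index; a degenerate all-zero distance matrix seeds deterministically.
* Registration ties break toward the smallest shift magnitude, then
  lexicographically; frames where every candidate falls below the overlap
  floor are errors rather than silent zeros.
* `dff()` refuses non-positive baselines; `detectSpikes()` refuses flat
  traces (MAD 0); `scheirerRayHare()` returns H = 0, p = 1 when all
  values are identical (SS_total = 0).

# Problem sizes used by the test suite

The validation suite runs at sizes chosen to exercise each property
meaningfully: 1000 random angle triples for the inversion oracle; 100
one-minute traces with the baseline checked at every frame; ~200 planted
PER events in noiseless and 1 px-noise sessions; 240 DTW oracle pairs
(40 exhaustively enumerated, 200 against the shortest-path formulation);
100 seeded clustering runs over 10 planted two-group sets; 50-volume
registration at exact and SNR-10 noise levels; 500 spike traces at SNR 8;
15,000 null replicates for the rank test's type-I error (standard error
~0.0016 against the [0.04, 0.06] acceptance band) and 500 replicates for
linear-model weight recovery. The full suite completes in a few minutes
on one CPU.

# Known limitations

* Integer-only registration cannot represent subpixel motion; residual
  jitter below 1 px passes through to ROI traces.
* The spike detector is threshold-based and unsorted by design; it will
  merge near-coincident spikes from different GRNs within the refractory
  window and undercount during very high-rate bursts.
* The SRH chi-square reference is mildly conservative at small cell
  sizes (measured type-I error ~0.044–0.050 at 3×9 with n = 5 per cell).
* The elbow rule needs at least three candidate k; with fewer it returns
  the largest candidate with a warning.
* The hysteresis detector reports no event for excursions that stay
  between the two thresholds — by construction, not by accident.
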