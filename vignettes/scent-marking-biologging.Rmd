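---
title: "Detecting canid scent marking from biologging data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting canid scent marking from biologging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scentmark)
```

## The signal model

A tri-axial accelerometer measures the sum of gravitational and dynamic
acceleration along three orthogonal axes. Mounted on the pelvis, the device
reads approximately `(0, 0, -1)` g when the animal stands level (axis
convention: x = surge, y = sway, z = heave). Canid scent-marking postures
are held, quasi-static body tilts, so they appear as sustained displacements
of the gravity vector:

| posture | signature | axis |
|---|---|---|
| left leg raised | y ≈ −1 g | sway |
| right leg raised | y ≈ +1 g | sway |
| squat (urination) | x ≈ −1 g | surge |
| squat (defaecation) | x ≈ −1 g + offset | surge |

Because the signatures are separated by 1–2 g while sensor noise is of order
0.1 g, single raw samples carry enough information to classify posture — no
windowed summary features are computed, by design. This is the central
assumption of the method: **posture detection rides on the static component
of the signal**, and any behaviour that holds a similar tilt for seconds
(digging with the rear lowered, say) is a potential confusion the validation
step must quantify.

## The classifier

`knn_predict()` implements KNN natively. For each query sample the Euclidean
distances in g to all training records are computed; the k nearest vote, and
the majority wins. Design points the contract leaves open, decided here:

* **Distance ties at the k-th neighbour** are resolved toward the
  lowest-index training record. Any rule is defensible; this one is
  deterministic and matches the behaviour of a stable sort.
* **Vote deadlocks** can occur with three or more classes even for odd k
  (e.g. votes 2/2/1 at k = 5). The tied class whose nearest representative
  is closest wins, consistent with the principle that nearer points carry
  more relevant information.
* **Distance weighting** (optional) weights votes by 1/d; a query exactly
  coinciding with a training record (d = 0) takes that record's class
  outright rather than producing an infinite weight.

Training uses 50 raw records per scent class and 500 "other" records,
sampled uniformly without replacement — deliberately few, emulating a short
observation window before release. k is tuned by stratified 5-fold
cross-validation over odd k in 1–21, ties broken toward the smallest k.
Testing pools all held-out scent records with 3000 random "other" records:
"other" is typically 50–100 times more frequent than marking, and an uncapped
test set would let a degenerate always-"other" classifier score far too well.

## Metrics

Accuracy is the fraction of correct predictions. Per class, one-vs-rest
counts give precision TP/(TP+FP), recall TP/(TP+FN) and F1 (harmonic mean).
Zero-denominator cases are reported as 0 with a warning and the class still
enters the prevalence-weighted aggregates — silently dropping a class that
was never predicted would overstate performance. AUC is computed per class
(one-vs-rest) from the fraction of the k votes for that class, via the
Mann–Whitney rank statistic with midranks for ties; the multiclass scheme is
not fixed by the method's description, so prevalence weighting is used for
consistency with the other metrics. Prevalence-weighted recall equals
accuracy algebraically (Σ (n_c/N)(TP_c/n_c) = ΣTP_c/N); the test suite
asserts this identity on every report as a self-check of the counting.

## Smoothing, events, georeferencing

Per-sample predictions are reduced to 1 s bins by modal filtering, matching
the GPS cadence and suppressing single-sample flicker. Within-bin ties are
resolved in favour of scent classes over "other" (the rare classes are the
object of study; a 25/25 bin is far more likely a real posture bordered by
locomotion than the converse), then by the longest consecutive run, then
lexicographically. A partial trailing bin is kept if at least half full.

Runs of equal scent class become events; runs shorter than
`min_duration_s = 2` s are discarded because the postures are held for a few
seconds, so 1 s detections are classifier noise. The event timestamp is the
run start — the posture's onset best marks where the deposit lands — and the
event location is the GPS fix nearest that start, within a 10 s tolerance
(default; two fix intervals). Events without a qualifying fix stay in the
record flagged unlocated rather than being dropped.

Accelerometer and GPS clocks are assumed synchronised; a constant
`clock_offset_s` correction is exposed in the pipeline configuration
(default 0) because field synchronisation procedures vary.

## Spatial indices

* **MCP.** The percentage MCP peels the ⌈(1−p/100)·n⌉ points farthest from
  the arithmetic centroid then takes the convex hull — the convention of the
  classical home-range estimators. Peeling ties (equal distance) remove the
  later index first; fewer than three surviving points, or collinear ones,
  are an explicit error rather than a degenerate polygon.
* **Overlap** is area(all ∩ scent)/area(all), computed by Sutherland–Hodgman
  clipping (both polygons are convex, so the intersection is too). The local
  planar frame is an equirectangular projection about the track centroid:
  at pasture scale its distortion is millimetres, and it keeps the package
  dependency-free; the projection is recorded in output metadata.
* **Revisits** pair each mark with the *most recent* earlier mark within
  10 m (the buffer reflects typical GPS accuracy), making "time between
  visits" single-valued; an all-pairs mode exists behind a flag.
* **Forays** are maximal runs of fixes strictly outside the territory
  polygon, the boundary counting as inside. Duration runs from the first
  outside fix to the last before re-entry, so a single-fix excursion has
  duration 0 and is classed "under" the 10 min split; a foray of exactly the
  split duration is classed "over". The reported excursion-frequency and
  percent-extra-territorial columns are not reconstructible from their
  companion quantities under any definition we tested, so this package
  declares its own: percent = 100 × total foray minutes / deployment span
  minutes, frequency = foray count / deployment span minutes, both recorded
  in output metadata.

## The simulator: what it emulates, and what it does not

`simulate_scenario()` generates the world the method assumes: 50 Hz
tri-axial traces where scent postures are instantaneous orientation switches
held 2–5 s with Gaussian sensor noise, "other" behaviour is the standing
orientation plus a 0.25 g, 2 Hz heave sinusoid (a locomotion stand-in) and
noise, and a GPS walk (discrete Ornstein–Uhlenbeck attracted to the
territory centre, ~1 m/s) confined to a 300 m territory except during foray
windows, when the attractor is displaced outside. Key defaults and why:

* `noise_sd_g = 0.1` — keeps the posture signatures ~10σ from the baseline,
  the regime the conspicuous-signature argument describes.
* `marks_per_hour = 6` per scent class and `duration_s = 3600` — mirrors
  validation sessions that required at least five marks within 50 minutes,
  and makes the 50-records-per-class training design satisfiable with high
  probability under the Poisson event model.
* `posture_hold_s = 2–5` — "held for a few seconds".
* `gps_interval_s = 5`, `gps_jitter_sd_m = 5` — deployment cadence and a
  mid-range GNSS error.
* `foray_mean_duration_s = 600` — exponential durations straddling the
  10 min reporting split.
* `squat_defaecate_offset_g = 0.08` — the two female squats are similar but
  discernible; the offset makes their separability tunable.
* `mount_roll_deg` — a per-individual device mounting angle, used to emulate
  surrogate-training transfer between morphologically different animals.

Event times are a homogeneous Poisson process per class thinned to
non-overlap; foray onsets are per-minute Bernoulli trials. To keep foray
recovery well-posed, the walk is clamped inside 0.95 r outside foray windows
and outside 1.05 r within them — ground truth and detection then agree
exactly at zero GPS jitter, which is what the recovery tests assert.

The simulator deliberately does **not** model: biomechanical gait (the
sinusoid is a stand-in for unspecified "other" dynamics), posture
transitions (switches are instantaneous), terrain or habitat-dependent GPS
error, or behavioural autocorrelation beyond the walk itself. A green test
on synthetic data therefore establishes that the pipeline's machinery is
correct under the stated assumptions — not that field accuracy will match:
real "other" behaviour can visit scent-like orientations (lying on one side,
for instance), which is exactly why per-class validation against observation
remains part of the method.

## Numerical choices and degenerate inputs

Label intervals are half-open [start, end), so abutting intervals never
overlap; overlapping ones are an error listing the offending pairs, as are
non-monotone timestamps and non-finite samples — readers reject rather than
repair. Gap detection flags sample intervals longer than twice the nominal
period. All randomness flows from explicit integer seeds and the RNG state
is restored after every simulation call; the pipeline manifest records the
seed, parameters and an MD5 per artefact, and identical configuration yields
byte-identical outputs (timestamps are deliberately excluded from the
manifest).

## Limitations

Raw single-sample KNN is memoryless: it cannot use hold duration directly,
and relies on the modal filter and the event-duration floor to impose
temporal coherence. The MCP is a deliberately simple home-range estimator —
convex, outlier-sensitive, with no utilisation density; kernel or
autocorrelation-aware estimators are out of scope. Revisit detection is
within-individual only. Reference per-deployment accuracies from the
original field data are not reproducible here (the data are unreleased);
the test suite instead pins the machinery with property-based checks and
oracle comparisons, plus exact recovery on the simulator's stated world.
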