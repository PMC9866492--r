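---
title: "Estimating detailed sedentary postures from a tri-monitor configuration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating detailed sedentary postures from a tri-monitor configuration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A static triaxial accelerometer measures the gravity vector in its own local
frame. If two monitors are strapped to adjacent body segments, the angle
between their measured gravity vectors equals the angle between the segments'
long axes, provided both rotations are about axes with a horizontal
component. `triposture` exploits this with three monitors — torso, thigh,
shin — mounted anteriorly and mutually parallel:

* **hip flexion** = angle(torso acceleration, thigh acceleration),
* **knee flexion** = angle(thigh acceleration, shin acceleration),

each computed per sample as `acos` of the normalized dot product with the
argument clamped to [-1, 1]. Because the monitors are parallel in upright
standing, both angles are approximately 0 in the anatomical reference
position and no axis permutation or calibration step is required. An optional
correction (`run_config(calibrate = TRUE)`) subtracts the median angle
observed during upright events, which absorbs small strap misalignment; it is
off by default because the core method does not require it.

The key assumption is that the monitors are quasi-static during the analyzed
time. The pipeline therefore only evaluates angles **inside thigh-classified
sedentary bouts**, where movement accelerations are small, and isolates the
gravity component with a low-pass filter first. The method is blind to
rotations about the body's long axis: cross-legged sitting or side-lying
tilts gravity toward the medio-lateral axis and biases the planar angle
estimate. No correction is attempted; such postures simply land where their
gravity geometry puts them.

## Signal conditioning

Each axis is filtered with a first-order digital Butterworth low-pass,
cutoff 0.18 Hz, applied forward and then backward so the net phase shift is
zero (`lowpass()`). The two-pass amplitude response is the square of the
single-pass response; in closed form

$$|H_2(f)| = \frac{1}{1 + \left(\tan(\pi f/f_s) \,/\, \tan(\pi f_c/f_s)\right)^2},$$

which at 5 Hz (a quarter of the 20 Hz sampling rate) is 8.0e-4 — note the
bilinear frequency warping matters there; the analog form
$1/(1+(f/f_c)^2)$ is accurate only well below Nyquist. Both forms are
verified by a frequency-sweep test.

Edge handling is not part of the filter's definition, so it is a package
choice: odd (point-symmetric) reflection padding of 25 filter time constants
(`filter_spec(pad_factor = 25)`, about 22 s at the defaults) at each end.
That choice makes the residual start/end transient on a constant signal
smaller than 1e-10 relative — effectively exact unit DC gain — at negligible
cost on multi-day records. Three time constants is the minimum the
implementation accepts; traces shorter than the padding are rejected rather
than filtered badly. Filtering is applied once to the whole trace *before*
bout extraction, so bout-edge samples are not polluted by per-bout filter
restarts; the cost is that a few seconds around each posture transition blend
adjacent orientations (visible as small dwell leakage between angle bins, not
between postures, since generated postures sit far from the thresholds).

## Bouts, thresholds and tallies

Sedentary bouts come from the thigh events file (the device labels thigh
inclination within 20° of horizontal as sedentary); the package does not
re-detect them. Bouts are intersected with the diary's waking windows
(half-open intervals `[wake, sleep)`; a sleep time at or before the wake time
is read as sleep onset after midnight). A bout partially in sleep is clipped
and flagged; a bout is *prolonged* iff its clipped waking duration strictly
exceeds 3600 s.

Classification thresholds are heuristic and exposed as parameters
(`run_config()`): hip < 30° → lying, hip ≥ 30° → sitting, knee ≥ 45° →
bent-legged, knee < 45° → straight-legged. The conventional statement of the
rule uses strict inequalities on both sides, leaving equality undefined; the
package fixes
the boundary deterministically (hip = 30 → sitting, knee = 45 → bent-legged)
and uses lower-closed 15° bins, so a sample at exactly 45° lands in [45, 60).
These conventions are measure-zero for real signals but make outputs
reproducible to the bit.

Dwell is tallied **per sample**: each non-degenerate sample inside a bout
contributes one sample period (0.05 s) to the bin containing its angle and to
its posture class, under the bout's length class and calendar day. Per-event
tallying was the alternative reading of the procedure; per-sample tallying is
the only one that lets a single event span several bins, which the bin-table
output format requires, and it is what the package implements (flagged in the
output metadata via this vignette). Samples whose vector magnitude drops
below 0.2 g (movement transients, impacts) have no reliable direction; they
are flagged, excluded from all tallies and reported as a per-day QC fraction
rather than silently dropped.

Daily summaries convert seconds to min/day over diary days; days without a
prolonged bout contribute 0 min to prolonged means. No minimum wear-time
filter is applied by default (the target protocol is 24 h/day wear); rounding
to 0.1 min happens only at presentation, so total = prolonged +
non-prolonged holds exactly in all stored tables.

Group comparisons use Shapiro–Wilk per variable, then paired two-sided
Wilcoxon signed-rank tests for the three posture contrasts and for prolonged
vs non-prolonged within each posture, judged at the Bonferroni-adjusted alpha
`0.05/3`. The unrounded 0.05/3 is the operative threshold; the rounded 0.017
is printed alongside. Zero differences are dropped (standard signed-rank
treatment); an all-zero contrast is reported as undefined rather than given a
fabricated p-value. Exact p-values are used for ≤ 25 informative pairs
without ties, otherwise the normal approximation with continuity correction.

## The synthetic generator, and what it does not show

`make_scenario()` builds a seeded schedule of posture segments tiling whole
days: a diary-consistent sleep block each night, and within each 16 h waking
window (wake 07:00, sleep 23:00) sedentary bouts separated by upright breaks
of at least 60 s. Defaults emulate free-living behaviour in healthy young
adults: 7 days; 439/113/69 min/day of bent-legged, straight-legged and lying
sedentary time (621 min/day total); one third of sedentary time in prolonged
bouts; 8.8 min mean non-prolonged bout length; sensor noise 0.05 g. A state
whose prolonged share cannot fill a single > 1 h bout (straight-legged and
lying at the defaults) gets only non-prolonged bouts, so realized prolonged
time concentrates in bent-legged sitting; `ground_truth()` always reflects
the realized schedule, not the requested mix. Per-bout angles are drawn
uniformly at least 10° clear of every classification threshold, so that
recovery failures indicate pipeline defects rather than threshold
coin-flips.

`render_traces()` uses a planar (sagittal) orientation model: torso angle
from vertical = (90° − thigh incline) − hip, shin = (90° − thigh incline) −
knee, each monitor reading the unit gravity vector for its angle plus
isotropic Gaussian noise, quantized through the device count map (8-bit ±2 g
or 10-bit ±4 g) so written files round-trip bit-exactly. Quantization alone
can tilt a unit vector by up to `asin(sqrt(2)/126)` ≈ 0.64°, which bounds the
per-sample angle accuracy achievable on rendered 8-bit data; dwell-level
recovery is unaffected because of the 10° threshold margins.

What passing these tests does **not** show about real recordings: the
generator has no movement bursts, posture transitions are instantaneous, no
long-axis rotation occurs, strap orientation is perfect, and the events file
is exactly consistent with the thigh incline. Agreement with motion capture,
drift, and wear compliance are outside what synthetic data can establish.

## Numerical and design choices

* Internal clock: seconds since the recording's first midnight (all monitors
  start simultaneously at midnight); all intervals half-open, which makes
  abutting events and bins non-overlapping by construction.
* Count maps: g = (count − 127)/63 for the 8-bit device, (count − 512)/128
  for the 10-bit device — symmetric linear maps with the midpoint at exactly
  0 g, configurable per dialect file along with column names and activity
  codes (vendor exports vary; code 0 = sedentary by default).
* Degenerate-vector floor 0.2 g: far below any plausible filtered gravity
  magnitude, far above numerical noise.
* Alignment never resamples or reorders; traces are truncated to the
  shortest common length and a start mismatch beyond one sample period is an
  error, since the protocol synchronizes all monitors.
* Missing diary days are an error by default (`strict_diary = FALSE` demotes
  them to a warning and excludes the day), because silently analyzing
  sleep-contaminated time would bias lying estimates upward.

## Problem sizes used in the tests

Unit tests run on single synthetic days or shorter constructed fixtures; the
end-to-end recovery checks use 7-day scenarios at 20 Hz (12.1 M samples per
monitor), once noiseless and once at 0.05 g noise; the cohort statistics are
exercised with 200 replicates of 20-participant cohorts. Recovery tolerances:
0.5 min/day noiseless, 5% relative at 0.05 g noise, against analytic ground
truth.

## Known limitations

Long-axis rotations (cross-legged, side-lying) bias angles; sedentary
detection is inherited from the thigh device and any exercise performed in a
seated/lying posture is misclassified by it; the energy-expenditure component
of the sedentary definition is unobservable from accelerometry; and absolute
accuracy on real bodies (soft-tissue artifact, strap migration) must be
established against motion capture, not against this package's simulator.
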