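---
title: "Posture monitoring from a necklace-worn accelerometer: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Posture monitoring from a necklace-worn accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturekit)
```

## The sensing model

A necklace worn at the back of the neck carries a triaxial accelerometer.
When the wearer is stationary, the sensor reads the gravity vector
projected onto its axes, in units of G. `posturekit` fixes the mounting
convention as: x along the spine (an upright wearer reads about 1 G), y
lateral (left-positive), z anteroposterior. With pitch $p$
(forward-positive) and roll $r$ (left-positive),

$$a_x = \cos p \cos r, \qquad a_y = \sin r, \qquad a_z = -\sin p \cos r,$$

so leaning forward lowers $a_x$, tilting left raises $a_y$, and tilting
right lowers it. This convention is an assumption: a physical device only
pins it down through the observed signal directions (spine axis near 1 G
upright, lateral reading rising on a leftward tilt), which is exactly how
it is fixed here. The projection conserves $a_x^2+a_y^2+a_z^2 = 1$, a
property the test suite checks across random orientations.

Posture is operationalized through two clinical screening criteria: a
kyphotic (forward-slouched) posture shows as a head–neck line that is not
perpendicular to the ground in side view, and a lateral tilt as a
shoulder line that is not parallel to the ground in frontal view. The
accelerometer detects the same two tilts as movements of $A_x$ and $A_y$
away from wearer-specific baselines.

## Filtering

Raw readings are smoothed by a trailing moving average: output sample $k$
is the mean of the current and previous `window − 1` readings per axis.

* `window = 10` samples at `sample_rate = 10` Hz averages one second of
  signal. That window suppresses step-synchronous walking oscillation
  (about 2 Hz in the simulator, so the window spans two full periods and
  nearly cancels it) while following genuine postural changes, which play
  out over seconds.
* Warm-up: before `window` samples exist, the mean of all samples so far
  is used and `window_fill` records how many contributed. This keeps
  output aligned one-to-one with input from the first reading onward; the
  alternative (emitting nothing for the first second) would complicate
  every downstream time alignment for no accuracy gain.

The filter is linear and shift-equivariant past the warm-up region, and
its output is bounded by the extrema of the contributing raw window —
all verified against a brute-force per-index oracle.

## Calibration

**Primary mechanism.** `auto_calibrate()` consumes a keypoint stream
(head, neck, both shoulders, 2-D world coordinates with the vertical axis
increasing upward) time-aligned with the filtered trace. Phase one scans
for the side-profile condition — head–neck segment within `tol_deg` of
vertical — and, once it has held for `hold_frames` consecutive frames,
samples `S_x` from the filtered $A_x$ at that instant. Phase two then does
the same for the frontal condition (shoulder line within `tol_deg` of
horizontal), sampling `S_y` from $A_y$. Choices made here:

* `tol_deg = 2°`: strict enough that the captured posture is near-ideal,
  loose enough that a real, slightly swaying subject ever satisfies it.
  Verticality is measured as `atan2(|Δu|, |Δv|)`, so the check is
  symmetric in the two points and independent of segment length.
* `hold_frames = 5` (half a second at 10 Hz): a debounce so a transient
  frame passing through vertical mid-movement cannot calibrate the
  device. The test suite includes exactly that scenario (a 0.3 s upright
  transient inside a slouched recording) and requires calibration *not*
  to fire.
* The standard is the filtered value at the qualifying instant, not an
  average over the hold window: the hold certifies stability, the filter
  already averages the past second.
* Streams ending before both phases complete yield a *status*
  (`"S_x not calibrated"` / `"S_y not calibrated"`), not an exception —
  an incomplete recording is an expected outcome a caller retries, while
  `run_session()` does refuse to assess uncalibrated.
* Degenerate geometry (coincident keypoints) is an error; a head at or
  below neck height only warns, since unusual but legitimate frames
  should not abort a session.

**Threshold derivation.** The trigger offsets are the minimum tilt change
`|standard − measured|` over clinician-labeled measurements of three
users (forward: 0.01159 G; lateral, pooling left and right: 0.02834 G).
Using the minimum makes the monitor deliberately strict — the least
pronounced tilt any assessed user needed to reach poor posture already
triggers. The release offsets 0.00854 G and 0.02441 G are kept verbatim
as package defaults rather than recomputed from the trigger minima (the
underlying subtractions, 0.003 G and 0.004 G, were themselves described
as approximate, and the verbatim values are the ones the threshold
formulas actually use). The packaged measurement table ships as plain
CSV; `derive_offsets()` recomputes changes from the raw standard/measured
columns rather than trusting any pre-tabulated difference.

**Secondary mechanism (sliders).** Four integer sliders in `[1, 300]`
with central value 150 rescale `S_x` (`a`), the forward offsets (`b`),
`S_y` (`c`), and the lateral offsets (`d`) by `position/150`. Read
literally, re-sending a slider value would compound the scaling on each
application. `posturekit` instead defines sliders relative to the stored
calibration-time base values, so the mapping from slider position to
device state is a pure function: applying `a = 200` twice equals applying
it once, and the four sliders act independently. This is the only
semantics under which a phone UI slider (whose position persists between
updates) behaves predictably, so the compounding reading was rejected
rather than offered as an option.

## Assessment: hysteresis comparators

Each direction gets a two-threshold comparator with trigger `Href` and
release `Lref`. Output 1 means poor posture on that direction. The
forward band sits below `S_x` (`Href_x < Lref_x < S_x`), the left band
above `S_y`, the right band below it. Because the forward and right
comparators have their trigger *below* their release, polarity is derived
from the sign of `href − lref` rather than hard-coded: `href > lref`
trips on high inputs, `href < lref` on low ones. Inputs inside the open
band never change the output (the no-chatter property), and crossing the
trigger always trips regardless of history — both verified against an
independent brute-force replay on random walks.

Further engine choices:

* Comparators initialize to `out = 0`: calibration immediately precedes
  assessment, so the session starts from certified-correct posture.
* If both lateral comparators ever report 1 (possible only with
  pathological, overlapping bands), the flag on the same side of `S_y` as
  the input wins; at exact equality both are dropped. A physical tilt
  cannot be left and right at once.
* No backward comparator exists: a reading above `S_x` is treated as
  acceptable. Backward hyperextension is rare in seated device use and
  the threshold data contain no backward measurements to calibrate one.
* Messages are fixed strings (`"Too Forward!!"`, `"Too Right!!"`,
  `"Too Forward & Left!!"`, ...); composites always name forward first.

## Reminder scheduling

A reminder event fires when the flag set becomes non-empty or changes,
and repeats while poor posture persists at most once per throttle
interval `T0 / warning_time` seconds, with `T0 = 10` s. The
`warning_time` setting (a positive integer; higher means more frequent)
has no defined unit on the device it models, so the reciprocal mapping
with a configurable base period is this package's definition. Reminders
repeat rather than firing once per transition — a monitor whose purpose
is to nag should keep nagging — and are delivered only while the phone is
connected; they are not buffered across a disconnect, because a reminder
about a posture the wearer may since have fixed is stale the moment it is
late.

## The simulator

`simulate_trace()` turns a scripted maneuver — segments holding or
linearly ramping pitch and roll — into a trace: gravity projection at
each sample, plus

* Gaussian noise, `noise_sigma = 0.005` G per axis by default, matching
  the small jitter of a stationary wearer;
* optionally a sinusoid of amplitude 0.05 G at 2 Hz on the spine axis,
  reproducing the walking interference that motivates the filter (the
  filtered fluctuation must come out strictly smaller than the raw one,
  and the suite checks it does);
* constant `mounting_pitch` / `mounting_roll` offsets applied to the
  *sensor only*, modelling how the necklace sits on an individual. This
  is what makes wearer standards individual (e.g. upright $A_x$ of
  0.95–1.0 G, upright $A_y$ of ±0.2 G) while their keypoint geometry
  remains exactly correct — the mechanism by which the same device must
  be recalibrated per wearer.

`simulate_keypoints()` emits the matching keypoint stream: the head–neck
segment tilted from vertical by the body pitch, the shoulder line from
horizontal by the body roll, both encoded in every frame (the camera is
assumed to capture whichever profile calibration currently needs).
Linear interpolation during transitions is the simplest trajectory
consistent with a monotone lean; ground-truth flags use an angle
criterion (default 5° on either axis) on the *body* angles, never the
mounting offsets.

What the simulator does **not** emulate: biomechanically realistic spine
kinematics, sensor bias or temperature drift, keypoint-detector dropout,
or the asymmetric noise of a real camera skeleton tracker. Passing
tests therefore demonstrate the correctness of the decision pipeline
under its stated signal model, not field performance of a physical
device.

## Session orchestration

`run_session()` executes the phases in order: auto-calibration (or a
supplied threshold set), untimed setting signals (manual fine
adjustment), then the assessment loop, applying timed signals as their
timestamps pass, recording every state change, setting application, and
reminder in an append-only, time-ordered log, and stopping at the
configured operating time (default 8 hours; tests always override it
with the trace length). Threshold changes mid-session rebuild the
comparators but preserve their current outputs, so an adjustment does
not spuriously clear or raise flags by itself. The device-phone-computer
exchange is modeled as timed in-process signal scripts over a
line-delimited JSON protocol (`encode_signal()` / `decode_signal()`);
no socket transport is included, as nothing in a hardware-free package
would sit on the other end.

## Problem sizes and determinism

Every stochastic test fixes its seed. The suite's standard sizes, chosen
to exercise asymptotic behavior while keeping a full run in seconds:
random-walk comparator replays of $10^4$ steps; filter oracle
equivalence on 200–500-sample traces over several seeds and windows;
parameter recovery over 50 simulated wearers (noise 0.01 G) requiring
median absolute error below 0.01 G on both standards; and 20-seed
end-to-end sessions (26 s each at 10 Hz) that must raise at least one
forward reminder and clear it after straightening.

## Known limitations

* A single necklace cannot distinguish spine curvature from whole-body
  lean; the geometry checks at calibration time are the only posture
  ground truth.
* Backward tilt is never flagged (see above).
* The lateral standard is calibrated in a frontal pose while the forward
  standard comes from a side pose moments earlier; a wearer who shifts
  between phases bakes that shift into the standards.
* Thresholds derive from three assessed users of normal skeletal
  proportions; atypical skeletal structures need their own labeled
  measurements (`read_measurements()` + `derive_offsets()` accept any
  such table).
* The 2 Hz walking model is a single sinusoid; real gait has harmonics
  the 10-sample window cancels less cleanly.
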