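---
title: "Dual-view home-cage tracking: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-view home-cage tracking: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagetrack)
```

## The measurement problem

A mouse lives in a transparent home cage fitted with a shelter ("house") and
a top-mounted running wheel, watched by two orthogonal infrared cameras: a
*front* camera seeing the cage-width and height axes, and a *side* camera
seeing cage-depth and height. An object detector reports, per video frame
and per view, bounding boxes for three objects (mouse, house, wheel) as
midpoint-plus-extent tuples `(x, y, w, h)` with a confidence score.
`cagetrack` turns these two detection streams into the behavioral
quantities used in circadian and locomotor-activity studies:

* **house / wheel / outside time** — seconds the animal spent in each
  region,
* **outside activity** — distance traveled while in neither house nor
  wheel,
* **running speed** — wheel revolutions per second of wheel occupancy, and
* per-phase aggregates of all of these over circadian windows such as the
  food-anticipatory activity (FAA) window preceding a scheduled feeding.

## Core model

### Containment (region occupancy)

The animal counts as inside a region when its detected *midpoint* lies
strictly inside the region's bounding box — in **both** views:

$$q \;=\; q_{\text{front}} \wedge q_{\text{side}}, \qquad
q_v : \; |R_{x,v} - H_{x,v}| < \tfrac{1}{2} H_{w,v} \;\wedge\;
        |R_{y,v} - H_{y,v}| < \tfrac{1}{2} H_{h,v}.$$

Design choices baked into this predicate:

* *Midpoint, not box overlap.* The mouse's box extent varies with posture
  and detector noise; the midpoint is the stable summary, and the tests
  assert classification is invariant to the mouse's `w`/`h`.
* *Strict inequalities.* A midpoint exactly on a box edge is outside. With
  continuous coordinates this is a measure-zero tie-break; fixing it makes
  the predicate deterministic.
* *Conjunction of views.* A single 2D projection cannot separate a mouse
  in front of the wheel from one inside it; requiring containment in both
  views is what makes the 3D statement honest.
* *Precedence.* The wheel hangs above the cage floor, so its 2D projection
  can overlap the house's in one view. When both conjunctions hold, the
  wheel wins by default (`region_precedence = "wheel"`), because a point
  inside the wheel volume is the physically higher-specificity statement;
  the precedence is configurable.

Region times follow by counting: each frame contributes `1/FPS` seconds to
its region, i.e. `t_region = n_region / FPS`. Frames whose mouse position
is unknown (see gap filling) are booked to a separate `unknown` bucket so
that `t_house + t_wheel + t_outside + t_unknown` always equals
`n_frames / FPS` — the conservation invariant the test suite checks
exactly, per phase and per session.

### Two-view fusion

Detected midpoints fuse into a 3D cage position by axis assignment:

$$P = (F_x,\; S_x,\; \tfrac{1}{2}(F_y + S_y)),$$

with `F`/`S` the front/side midpoints. The height coordinate averages the
two independent vertical estimates. The fused frame inherits the image
convention: origin top-left, z increasing *downward*. `fuse_views()` is a
bijection from `(F_x, S_x, F_y + S_y)`, which the simulator exploits: its
projection step is the exact inverse, and the round trip is bit-exact at
zero corruption.

### Distance and speed

Per-frame displacement defaults to the Euclidean step
`sqrt(dx^2 + dy^2 + dz^2)`; summed over consecutive frame pairs that are
*both* classified outside, this gives the outside activity. A
`paper_literal` mode that returns the plain sum of squared per-axis
displacements (no square root) is retained for bit-exact compatibility
with systems that print the displacement in that squared form; it is not
additive along a path in the Euclidean sense and is off by default.

Steps across an interruption (a wheel/house/unknown frame between two
outside frames) are *not* counted — distance accrues only within unbroken
outside runs, and likewise never across a phase boundary in per-phase
reports.

Running speed combines the wheel counter with occupancy:
`v_wheel = R / t_wheel` in revolutions per second, where `R` sums the
hourly counter records booked into the phase. With a wheel diameter (11.5
cm here) the rim speed `v * pi * d` in m/s is reported alongside. The
`rev/s` figure is the formula-literal value; the m/s conversion is a
convenience and assumes rim-speed equivalence. Degenerate cases are pinned
down: `t_wheel = 0, R = 0` gives 0; `t_wheel = 0, R > 0` is flagged
undefined rather than silently infinite.

### Calibration

Fused coordinates are pixels. Reported distances convert to meters through
a per-axis linear scale (mm/px), constructed either directly or from the
known cage dimensions (268 × 215 × 141 mm for the Eurostandard Type II
cages targeted here) and the cage's pixel extent in each view
(`calibration_from_extent()`). No lens-distortion model and no true stereo
triangulation are attempted: with near-orthogonal close-mounted cameras
and decimeter-scale geometry, per-axis linear scaling is the appropriate
first-order model, and region classification never needs calibration at
all. The default is the identity (pixel units), and the z sign is left in
image convention.

## Stream handling

**Best-per-frame selection.** Detectors emit multiple candidate boxes;
per `(view, label, frame)` the highest-confidence record wins, ties broken
by larger area then lower x (deterministic total order). Before selection,
records under `min_confidence` (default 0.5) are discarded — a spurious
low-confidence box must never beat an honest miss, because a wild
one-frame position both misbooks occupancy and injects a large fake
travel step. The simulator's false-box channel exists precisely to
exercise this failure mode.

**Frame pairing.** The two cameras free-run; frames pair greedily to the
nearest timestamp in the other stream (each frame used at most once,
implemented in a small C++ kernel for million-frame sessions), and pairs
farther apart than `sync_tolerance_s` are dropped and counted. The default
tolerance is 0.3 s, the latency the recording setup is specified to
tolerate. Unmatched frames are reported, never silently discarded.

**Gap filling.** When the mouse goes undetected (shadowing, odd postures),
`hold_last` repeats the last known midpoint into the gap — the behavior of
the original evaluation procedure this package models — and `linear`
interpolation is available as an alternative. Gaps longer than
`max_gap_frames` (default `2 * fps`, i.e. two seconds) are *not* filled:
a mouse lost for minutes must surface as `unknown` time, not as fabricated
occupancy of wherever it was last seen. Leading gaps back-fill from the
first known position under the same cap; house and wheel boxes, being
static objects, forward-fill without a cap.

## The cage simulator

No public dataset exists for this recording geometry, so the package ships
its own generator; every pipeline stage is validated against it.

* **Dwell model.** A continuous-time Markov chain over
  {house, wheel, outside} with exponential sojourns (means 300 / 120 /
  60 s) and uniform jump destinations. This is the simplest process with
  the occupancy-and-transition structure the pipeline must measure; it is
  not claimed to be biologically faithful.
* **Circadian modulation.** An hour-of-day multiplier on the rate of
  leaving the current region: 1.8 in the dark phase (6 P.M.–6 A.M.), 1.4
  in the pre-feeding ramp (9 A.M.–1 P.M.), 0.6 otherwise — enough to
  produce FAA-like activity structure in demo figures and non-trivial
  hourly variance for the correlation analysis.
* **Geometry.** Three disjoint 3D dwell zones inside the cage volume. The
  side-view projections of house and wheel overlap deliberately, so the
  precedence rule is exercised; no zone lies inside another's boxes in
  both views, so ground-truth regions stay unambiguous. Walks are confined
  to zones shrunk by an 8 mm wall margin while emitted region boxes are
  the full zones — a real shelter's bounding box includes walls the
  animal's centroid cannot reach.
* **Motion.** Within a sojourn, a reflected Gaussian random walk (per-axis
  SD 6 mm/frame at 15 FPS ≈ 0.35 m/s RMS, an unhurried ambling pace);
  region changes relocate the animal to the nearest point of the new zone.
* **Observation model.** Projection divides by the camera scale (default
  0.5 mm/px); corruption drops each mouse record with `miss_prob`, jitters
  surviving midpoints (`jitter_sd_px`), shifts side timestamps by a
  constant latency, and injects uniform false boxes with confidence in
  \[0.05, 0.3\]. Hourly wheel revolutions are
  `rate × wheel-seconds + N(0, sd)`, floored and rounded — the hourly
  summing convention of commercial wheel counters.
* **Reproducibility.** All randomness flows from one seed through named
  substreams (trajectory, per-view corruption, revolutions, rendering), so
  changing corruption settings never perturbs the trajectory.

What the generator does **not** emulate: detector bias correlated with
posture or location, non-constant camera latency, occlusion by enrichment
objects, multi-animal housing, or realistic wheel kinematics. Passing the
recovery tests therefore demonstrates the *evaluation pipeline* is
correct and robust to the modeled corruption — it says nothing about any
particular neural network's detection quality on real video.

The renderer and blob detector close the loop at the image level: frames
are drawn as a dark background, dim intensity-banded rectangles for the
static regions, and a bright ellipse for the mouse; detection is
threshold → connected components (EBImage's labeling) → minimum-area
filter → largest component, with confidence = mean component intensity /
255. Static regions are read from a mouse-free reference frame by
intensity band. This is deliberately the simplest detector that exercises
the image path; it stands in for, and does not imitate, a CNN detector.

## Circadian phase windows

Two presets mirror the windows used with a 12/12 light/dark cycle (lights
on 6 A.M., feeding 1 P.M.):

| preset | windows |
|---|---|
| `periods` | FAA 9 A.M.–1 P.M., PA 2–6 P.M., NA 6 P.M.–6 A.M., PRA 6–9 A.M.; feeding hour 1–2 P.M. **excluded** |
| `phases` | Light1 3–6 P.M., Dark 6 P.M.–6 A.M., Light2 6 A.M.–1 P.M.; 1–3 P.M. unassigned |

Windows are half-open `[start, end)` local clock intervals and may span
midnight; overlapping non-excluded windows are a configuration error. The
feeding-hour exclusion applies only where a schedule declares it (the
`periods` preset), matching the analysis convention of excluding the
feeding disturbance. Hourly revolution records are booked into the phase
containing the hour's *start* clock time, the natural convention for
hourly-summed counters.

## Numerical choices and problem sizes

* Conservation is exact by construction (integer frame counts divided by
  FPS once); the tests assert it to 1e-12.
* The greedy pairing is O(n) over sorted streams; ties in the
  nearest-neighbor scan resolve forward, and a 22 h, 15 FPS session
  (~1.2 M frames per view) evaluates in well under a minute.
* Validation sizes used by the test suite and acceptance script: 10 000
  positions for the fusion round trip; twenty seeded 2 h sessions (five in
  the quicker acceptance script) at 5 %
  misses, 2 px jitter and 0.2 s latency for parameter recovery (region
  times recover to within 2 %, outside activity within 5 %); a 100 h
  session sampled at 5 FPS for the wheel-time/revolutions correlation
  (hourly aggregation makes the correlation insensitive to the sampling
  rate); a 10 min rendered session for the image-level round trip. These
  are the package's validation conditions, chosen to exercise every
  corruption channel at realistic strengths.
* The jitter robustness margin comes from geometry, not filtering: at 0.5
  mm/px, 2 px jitter is 1 mm against an 8 mm wall margin, so boundary
  flips are vanishingly rare. Sessions whose animals genuinely hug region
  boundaries would classify noisily; a hysteresis band would be the next
  refinement.

## Known limitations

* Single animal only; no identity tracking.
* The m/s running-speed figure assumes rim-speed conversion; revolutions
  per second is the primitive quantity.
* Calibration is per-axis linear; no undistortion.
* `hold_last` deliberately freezes the animal during dropouts: within the
  `max_gap` cap this slightly biases occupancy toward the pre-gap region,
  which is the documented, conservative behavior of the modeled system.
* The simulator's dwell and motion models are statistical conveniences;
  parameter-recovery results quantify pipeline fidelity under *modeled*
  corruption only.

## A worked example

```{r example, eval = FALSE}
sc <- sim_scenario(seed = 7, duration_s = 2 * 3600, miss_prob = 0.05,
                   jitter_sd_px = 2, latency_offset_s = 0.2)
truth <- simulate_session(sc)
views <- project_views(truth)
res <- evaluate_session(corrupt_stream(views$front, sc),
                        corrupt_stream(views$side, sc),
                        revolutions = truth$hourly[c("hour_start_clock", "revolutions")],
                        config = eval_config(fps = 15, session_start_clock = 15,
                                             calibration = calibration(0.5, 0.5, 0.5)))
res$report
recovery_report(truth, res)
```
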