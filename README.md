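# cagetrack

Dual-view home-cage rodent tracking metrics in R.

Long-term locomotor and circadian phenotyping — for instance in the
starvation-induced hyperactivity (SIH) model of anorexia nervosa, where
food-restricted mice with wheel access develop pronounced food-anticipatory
activity (FAA) — needs to know *where* an animal is in its home cage around
the clock: in the shelter, in the running wheel, or moving in the open.
`cagetrack` evaluates per-frame bounding-box detection streams from two
orthogonal infrared cameras (front and side views) and computes exactly
those quantities, without requiring the animal to leave its cage.

## What it computes

For each paired video frame the mouse midpoint `R = (x, y)` is tested
against a region box `H` in both views with the strict containment
predicate

    q = q_front ∧ q_side,   q_v : |R_x − H_x| < H_w/2  ∧  |R_y − H_y| < H_h/2,

applied to the wheel and the house (wheel precedence when projections
overlap). Midpoints fuse to a 3D position `P = (F_x, S_x, (F_y + S_y)/2)`
from the front (`F`) and side (`S`) views. From the per-frame
classifications it accumulates

* region times `t_region = n_region / FPS` (house / wheel / outside /
  unknown — conservation to `n_frames / FPS` is exact),
* **outside activity**: Euclidean travel distance over consecutive
  outside-classified frames (meters via a mm/px calibration),
* **running speed** `v = R / t_wheel` (rev/s; also `v·π·d` m/s for a wheel
  of diameter `d`), from hourly wheel-counter revolutions `R`,
* all of the above aggregated over circadian phase windows — presets for
  FAA (9 A.M.–1 P.M.) / postprandial / night / preprandial with the feeding
  hour excluded, and Light1 / Dark / Light2.

Detection imperfections are handled explicitly: a confidence floor, best
box per frame, greedy nearest-timestamp pairing of the two free-running
cameras (default tolerance 0.3 s), last-known-position gap filling capped
at two seconds, and `unknown` booking for longer dropouts.

Because no public dataset exists for this geometry, the package ships a
seeded cage **simulator** (Markov dwell model over the three regions,
circadian rate modulation, reflected random-walk motion, dual-view
projection, configurable miss/jitter/latency/false-box corruption, wheel
counter model) and a threshold-plus-connected-components **blob detector**
plus frame renderer, so the entire pipeline is testable end-to-end against
ground truth.

## Worked example

Simulate two hours of a session (detections missing 5 % of frames, 2 px
jitter, 0.2 s camera latency), evaluate it, and compare with ground truth:

```r
library(cagetrack)

sc <- sim_scenario(seed = 7, duration_s = 2 * 3600, miss_prob = 0.05,
                   jitter_sd_px = 2, latency_offset_s = 0.2)
truth <- simulate_session(sc)
views <- project_views(truth)
res <- evaluate_session(corrupt_stream(views$front, sc),
                        corrupt_stream(views$side, sc),
                        revolutions = truth$hourly[c("hour_start_clock", "revolutions")],
                        config = eval_config(fps = 15, session_start_clock = 15,
                                             calibration = calibration(0.5, 0.5, 0.5)))
res$report[res$report$n_frames > 0, ]
#>   phase n_frames t_house_s t_wheel_s t_outside_s outside_activity revolutions speed_rev_s
#> 2    PA   108000      4652      1643       904.7            106.4        1694       1.031
#> 7 total   108000      4652      1643       904.7            106.4        1694       1.031
```

The session started at 3 P.M., so all frames fall into the postprandial
window: the animal spent 4652 s in the house, 1643 s in the wheel and
905 s in the open, traveling 106 m outside at 1.03 wheel revolutions per
second of wheel time. Against the simulator's ground truth:

```r
recovery_report(truth, res)
#>             metric truth recovered abs_err  rel_err
#> 1          t_house  4652      4652   0.000 0.00e+00
#> 2          t_wheel  1643      1643   0.133 8.12e-05
#> 3        t_outside   905       905   0.133 1.47e-04
#> 4 outside_activity   105       106   1.745 1.67e-02
```

Region times are recovered to a fraction of a second despite ~10 800
filled detection gaps (`res$gaps`), and the travel distance to under 2 %
(localization jitter slightly inflates path length).

A thin command-line front end over the same functions lives at
`inst/scripts/cagetrack.R` (`evaluate`, `simulate`, `detect`, `validate`;
exit codes 0 / 1 input error / 2 config error).

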