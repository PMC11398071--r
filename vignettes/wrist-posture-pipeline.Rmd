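---
title: "From raw inertial streams to wrist-posture risk: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw inertial streams to wrist-posture risk: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinewrist)
```

## The measurement problem

Manual vine pruning exposes workers to repetitive, forceful wrist motion, a
known risk factor for musculoskeletal disorders. Checklist methods (RULA,
OCRA, REBA) score such exposure from wrist-angle observations that are
usually read off photographs or video. `vinewrist` implements the software
half of a low-cost wearable alternative: three inertial sensors - each a
tri-axial accelerometer (m/s²) plus gyroscope (deg/s) sampled at a nominal
50 Hz - strapped to the hand segment (S2), the wrist rotation axis (S1) and
the forearm segment (S3), all aligned along the Y axis at rest. From these
streams the package estimates the wrist joint angles (hand relative to
forearm), finds the cutting events on the acceleration trace, and classifies
the per-cut postures into three ergonomic risk bands.

## Stream model and synchronization

Samples arrive as receiver-timestamped lines
(`sensor_id,t,ax,ay,az,gx,gy,gz`). Timestamps are authoritative: they are
never re-derived from the sample index, because the receiver polls the three
sensors round-robin and its clock is the only common one.
`round_robin_sync()` lays an exact arithmetic grid with step `1/rate` over
the overlap of the three streams and assigns each frame the nearest sample of
each sensor. The default skew tolerance is half a frame period: a round-robin
cycle at 50 Hz cannot displace a sensor's reading by more than one polling
cycle, so anything worse indicates dropped packets and the frame is discarded
(and counted). The grid is computed as `t0 + k/rate`, not by accumulation, so
output timestamps are bit-stable and the operation is invariant to the order
in which streams are supplied.

## Orientation estimation

Orientation is carried as fixed-axis X-then-Y-then-Z Euler angles in degrees
(all trigonometry internal to the package is in radians). The gyroscope
channels are integrated per axis with the trapezoidal rule,

$$\theta(t) = \theta(t-1) + \int_{t-1}^{t} \omega\,dt ,$$

which is exact for constant rates and second-order accurate otherwise
(halving the step quarters the error; this is asserted by the test suite).
We deliberately integrate the gyro channels directly as Euler-angle rates
rather than through a body-rate Jacobian: the synthetic generator emits gyro
signals that *are* Euler-angle rates, so generator and estimator form a
consistent pair, and for the moderate, largely single-axis wrist postures of
interest the distinction is well below the sensor noise floor. This is a
documented small-angle-family convention, not an oversight.

Pure integration drifts with any gyro bias, so roll and pitch are corrected
by the accelerometer. For a quasi-static sensor the measured specific force
is the world gravity vector rotated into the sensor frame,
$a = R(\theta)^{\mathsf T}(0,0,g)$. `accel_tilt()` inverts this for roll and
pitch; a sample whose magnitude deviates from $g$ by more than 30% is
treated as dynamic and yields no estimate. Two details matter:

* **Yaw coupling.** Under the X-then-Y-then-Z convention the gravity
  direction in the sensor frame depends on yaw as well. The fusion loop
  therefore de-rotates the measured acceleration by the current
  gyro-integrated yaw before inverting for roll/pitch. Without this, a
  posture combining (say) 45° flexion with 45° yaw would bias the tilt
  estimate by tens of degrees.
* **Yaw itself is unobservable** - there is no magnetometer - so yaw is
  gyro-integrated only and re-zeroed at every session start. Wrist *relative*
  yaw is still meaningful because both segments share the same convention.

Two fusion estimators are provided behind one interface
(`filter_config()`): a complementary filter,
$\theta \leftarrow \alpha(\theta_{prev} + \omega\,\Delta t) +
(1-\alpha)\,\theta_{tilt}$, with default $\alpha = 0.98$ (a ~1 s
accelerometer time constant at 50 Hz), and a Kalman variant implemented as
decoupled 1-D angle-plus-bias filters per axis (defaults
`q_angle = 0.001`, `q_bias = 0.003`, `r_measure = 0.03`). With $\alpha = 1$
the complementary filter reduces exactly to gyro integration given the same
initial orientation. Unless told otherwise, both filters initialize
roll/pitch from the first quasi-static tilt sample, which is the sensible
start for a trial that begins at rest. Under a constant gyro bias $b$ the
complementary roll error settles at $\alpha b \Delta t/(1-\alpha)$ (about 1°
for 1 deg/s at the defaults) instead of growing linearly - the property that
makes fused angles usable over multi-minute recordings.

Gravity removal follows the same rotation model:
`remove_gravity()` computes
$a_{real} = a_{meas} - R(\theta)^{\mathsf T}(0,0,g)$, so the subtracted
vector always has magnitude $g$ regardless of the orientation estimate.
Velocity and position are trapezoidal integrals of $a_{real}$
(`integrate_motion()`); without corrections their noise-driven variance grows
cubically in time, so optional zero-velocity updates reset velocity during
rest windows (gyro magnitude < 2 deg/s and acceleration within 0.3 m/s² of
gravity for at least 0.2 s). Risk analysis uses angles only; positions are
computed because the sensor placement makes them available, not because any
reported quantity depends on them.

## Kinematics and wrist angles

Rigid motion is expressed with 4×4 homogeneous transforms. Elementary
translations and rotations compose as
`rototranslate = T · Rx(θx) · Ry(θy) · Rz(θz)` in exactly that order; every
constructed transform is validated on construction (bottom row exactly
(0,0,0,1), rotation block orthonormal with determinant +1 at 1e-9). The
test suite checks `rototranslate()` against a brute-force product of the
four elementary matrices assembled independently, to 1e-12 over 1000 random
inputs.

The arm is modelled with two segments hinged at the wrist axis A: hand
segment AB (default 0.18 m) and forearm segment AC (default 0.26 m), sensors
at the segment midpoints. Segment lengths are per-operator configuration
(`[arm]` section) since anthropometric adaptability is a design goal of the
hardware. `forward_kinematics()` poses the hand segment in the forearm frame
and returns the end-effector point N and the S2 position; segment length is
preserved for every angle input (asserted over 1000 random poses).

The wrist joint angle series is the per-frame Euler decomposition of
$R_{forearm}^{\mathsf T} R_{hand}$ between the fused S2 and S3 orientations
(`wrist_angles()`). Near the $\theta_y = \pm 90°$ singularity the
decomposition returns the coupled roll branch with a `gimbal` flag rather
than failing; wrist pitch beyond 89° is anatomically implausible, so the flag
is diagnostic rather than operational. Swapping hand and forearm transposes
the recovered rotation, which the suite verifies.

## Cut detection and risk classification

During a cut the hand sensor's acceleration magnitude departs from gravity.
`detect_cut_windows()` thresholds $|\lVert a\rVert - g|$ (default excess
2 m/s²), merges super-threshold runs closer than 0.5 s, and - when the
protocol prescribes a cut count - returns the strongest k bursts in time
order, warning when fewer exist. This replaces the graphical inspection step
of the original field procedure with a reproducible rule.

The representative posture of a window is, per axis, the signed angle of
maximal absolute value inside it: risk methods score the worst posture
reached, and the sign is kept for reporting while classification uses the
magnitude. Bands follow the three-level scheme used for the published
frequency table: low $[0, 20]$, medium $(20, 45]$, high $(45, \infty)$
degrees. The boundary convention - 45.00° is still medium, 45.11° is high -
is the only one under which classifying the published per-cut angle table
reproduces every verifiable cell of the published frequency table.
Percentages are *truncated* to integers, not rounded, for the same reason
(9/84 prints as 10%, where rounding would give 11%). Two published cells are
not jointly reproducible under any single rounding rule (the X-axis
medium/low split and some Y/Z medium cells); the package reproduces the
verified cells and documents the discrepancy rather than forcing agreement.
The same reproduction logic pins down the reference-trial summary: sample
standard deviations use the n−1 denominator (verified against the
outlier-sensitive 45°/Y cell, 45.47 ± 1.37), pooled cells aggregate raw
values across axes, and reporting rounds half-even to two decimals at the
output boundary only. One pooled mean (60°, all axes) computes to 60.0761
and therefore prints as 60.08 where the published table shows 60.07 - a
one-ulp slip in the source table, since no rounding rule reproduces both it
and the 45°/Y mean.

## The synthetic generator: what it emulates and what it does not

Hardware-free testing needs inputs with known truth. `trajectory_spec()`
moves the wrist between keyframes along a smoothstep ($3u^2 - 2u^3$)
profile, so trajectories are C¹ and the angular rate is known analytically -
which is what lets round-trip tests distinguish estimator error from
generator error. `synthesize_imu()` inverts the estimation model exactly:
gyro = segment Euler rate + bias + Gaussian noise; accelerometer = gravity
(plus any burst) rotated into the sensor frame + Gaussian noise. Sessions
are bit-reproducible for a fixed seed (default noise: accelerometer
σ = 0.05 m/s², gyro σ = 0.5 deg/s, seed 20240902).

Two protocol presets mirror the validation study. The reference-angle trial
ramps (1 s) to a 15°/45°/60° target on one axis, holds 2 s, returns, rests
1 s, three repetitions - the laboratory reliability protocol. The pruning
scenario runs 3 sequences of 7 cuts per operator; each cut ramps (0.5 s) to
a peak posture, holds 0.4 s with a world-vertical raised-cosine acceleration
burst (8 m/s², 0.3 s) centred in the hold, and returns. Default peak
postures sample the published per-operator cut-angle table so the classifier
path is exercised end-to-end on realistic magnitudes. Bursts are vertical so
that the acceleration-magnitude excess equals the burst profile exactly,
which keeps the analytic detection window (`cut_window_truth()`)
well-defined and independent of the detector implementation. S1 co-moves
with the forearm and receives half the burst, S3 a tenth - the hardware
protocol never uses S1/S3 for cut detection, so only their quasi-static
behaviour matters.

What the generator does **not** model - and hence what passing round-trip
tests do *not* establish about field data: centripetal/tangential
accelerations of the rotating segments, skin-motion and strap-slip
artifacts, sensor misalignment relative to the segment axes, temperature
drift, packet loss, and operator-to-operator variability beyond the noise
scale. Field performance rests on the published validation trials, not on
the synthetic round trips.

## Numerical and protocol constants

| Parameter | Default | Unit | Why |
|---|---|---|---|
| sampling rate | 50 | Hz | acquisition rate of the hardware protocol |
| sync `max_skew` | 0.5/rate | s | one round-robin polling cycle |
| complementary α | 0.98 | - | ~1 s accel time constant at 50 Hz |
| quasi-static band | ±30% of g | - | accepts slow motion, rejects bursts |
| gravity | 9.81 | m/s² | standard gravity |
| risk bands | 20, 45 | deg | three-level scheme of the field study |
| cut threshold | 2 | m/s² | well between noise floor and 8 m/s² bursts |
| cut `min_gap` | 0.5 | s | cuts are seconds apart in the protocol |
| segment lengths | 0.18, 0.26 | m | adult forearm/hand defaults, per-operator config |
| ZUPT rest rule | <2 deg/s, ±0.3 m/s², ≥0.2 s | - | conservative stillness detector |

Test and acceptance problem sizes are deliberately modest - 1000 random
transforms, 100 seeded noisy trials, four operators' pruning sessions
(~56 s of 50 Hz data each) - chosen so the full suite reruns in well under a
minute while still exercising every stochastic claim at its stated
confidence.

## Known limitations

* Euler-rate integration treats gyro channels as Euler-angle rates; for
  sustained large multi-axis rotations a quaternion or Jacobian formulation
  would be more faithful. The public contract (Euler degrees) would not
  change.
* Yaw accuracy is bounded only by gyro quality and session length; sessions
  should start from rest, and long recordings should be segmented.
* Dead-reckoned positions are provided for inspection but are not drift-free
  between rest windows; no reported quantity uses them.
* The config file dialect is YAML (`load_config()`), with sections
  `fusion`, `arm`, `risk`, `synth` and strict unknown-key rejection.

## Worked example

```{r, eval = FALSE}
sc  <- pruning_scenario(operator = 1)
sim <- generate_pruning_session(sc, noise = noise_model(seed = 11))
ang <- wrist_angles(sim$session)
ev  <- detect_cut_windows(sim$session$streams$S2, expected_count = 21)
rec <- representative_angles(ang, ev)
risk_frequency_table(data.frame(
  axis = rep(c("X", "Y", "Z"), each = nrow(rec)),
  angle_deg = c(rec$x, rec$y, rec$z)))
```
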