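---
title: "Muscle-driven planar gait analysis with gaitsim: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle-driven planar gait analysis with gaitsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsim)
```

# The problem

Walking loads the knee far beyond body weight: the muscles that hold the
limb up press the femur onto the tibia, so the compressive tibiofemoral
force (CTF) peaks at roughly 2–3 times body weight (BW) in healthy
children.  Comparing obese and normal-weight children requires the whole
muscle-driven chain: joint kinematics from markers, net joint moments from
the equations of motion, a resolution of muscle redundancy, and a joint
reaction balance that includes the muscle forces.  `gaitsim` implements
that chain for a reduced sagittal-plane model, together with a synthetic
gait generator that stands in for motion-capture data, induced
acceleration analysis of muscle function, and the cohort statistics
(group *t*-tests, speed–load regression).

# The model

## Skeleton

A planar 9-degree-of-freedom linkage: pelvis translation (tx, ty), a
head–arms–trunk (HAT) segment rotating about the pelvis point
(`pelvis_tilt`), and per side a revolute hip, knee (flexion/extension
only) and ankle.  Hip and knee flexion are positive, ankle dorsiflexion is
positive; reported knee moments can be read extension-positive by sign
flip (stated in the output `conventions` field).  Both hip joints coincide
with the pelvis point — a standard planar simplification.

Segment lengths are fixed fractions of stature (thigh 0.245, shank 0.246,
foot 0.152, HAT 0.400), masses fixed fractions of body mass (HAT 0.678,
thigh 0.100/side, shank 0.0465/side, foot 0.0145/side), centers of mass
and radii of gyration from standard anthropometric tables.  Scaling is
exactly linear: masses and maximal muscle forces with body mass, geometry
with stature, inertias with mass x length^2 — which is what makes the
normalized (xBW) knee load invariant under pure mass scaling, the
mechanism behind the absolute-versus-normalized contrast between obese
and normal-weight groups.

## Muscles

Eight lumped Hill-type muscle–tendon groups per leg: gluteus maximus,
iliopsoas, hamstrings (biarticular), rectus femoris (biarticular), vasti,
gastrocnemius (biarticular), soleus, dorsiflexors.  The default muscle
model is rigid-tendon and activation-linear, `F = a * f_max`: the
optimization below is stated purely on activations, and no
force–length–velocity data exist for this population.  Moment arms are
signed constants (vasti 0.042 m at the knee, gastrocnemius 0.020 m knee /
0.048 m ankle, hamstrings 0.055 m hip / 0.030 m knee, soleus 0.048 m,
dorsiflexors 0.037 m, gluteus maximus 0.060 m, iliopsoas 0.045 m at a
1.50 m reference stature, scaled with height); an `arm_poly` hook allows
angle-dependent arms.  Maximal isometric forces are standard
musculoskeletal-model totals normalized per kilogram (vasti 60 N/kg,
soleus 47, hamstrings 34, gastrocnemius 30, iliopsoas 29, dorsiflexors 22,
rectus femoris 16).  Two deliberate planar compensations: gluteus maximus
(36 N/kg) folds in the sagittal capacity of the posterior gluteus medius,
which has no frontal-plane actuator to live in here, and the hamstrings
value counts only the hip-extending heads.  With this sizing each group
can produce roughly twice its peak required moment in normative gait, so
reserve actuators stay numerically silent.

# The synthetic gait generator

The generator emulates an instrumented gait lab: it produces marker
trajectories (18 markers: 4 pelvis, 2 per thigh and shank, 3 per foot,
with 2 mm Gaussian noise by default), ground reaction forces and centers
of pressure per foot, and event times, for subjects drawn from truncated
normal anthropometry distributions (±2.5 sd) matching the reference cohorts
(normal-weight 43.1 ± 10.5 kg, 1.506 ± 0.060 m, 1.22 ± 0.08 m/s; obese
75.1 ± 11.0 kg, 1.554 ± 0.049 m, 1.10 ± 0.08 m/s; three trials each).

## What is prescribed

* Joint-angle templates over the gait cycle: hip flexion +30° → −10° →
  +30°; knee flexion 5° → 18° (15% GC) → 5° → 60° (73% GC) → 5°; ankle
  0° → +10° → −15° (60% GC) → 0°.  The hip template is interpolated with a
  periodic cubic spline (two interior knots, cannot ring); knee and ankle
  are interpolated linearly and smoothed with a circular Gaussian kernel
  (sd 2% GC) before the periodic spline fit — exact linear interpolation
  has slope discontinuities, i.e. unbounded accelerations, and would break
  the C1 periodicity the pipeline requires.
* Cadence from speed: `cadence = 43 * speed + 65` steps/min; stance is the
  first 60% of the cycle, contralateral offset 50%, so double support
  occupies 0–10% and 50–60% GC.
* Pelvis translation: mean forward speed, a vertical sinusoid of amplitude
  0.02 m at twice the stride frequency (the double-bump source) whose
  minimum lags heel strike by 4.5% of the stride (real centers of mass
  bottom out during weight transfer, not at contact), and a fore-aft
  oscillation built from six harmonics of the step frequency fitted to the
  physiological braking/propulsion profile (braking trough ~13% GC,
  propulsion peak ~48–50% GC, zero net impulse; amplitude set so the
  braking trough is `pelvis_fore_aft_amp * (4*pi/T)^2`, default 0.014 m
  ≈ 0.19 BW).  A single sinusoid cannot place braking at 13% and
  propulsion at 49% — they would be forced 25% apart.
* A constant forward trunk lean (default 5°, normative posture), applied
  to the HAT with the relative hip angle compensated so absolute leg
  kinematics stay on the template.

## What is derived: dynamic consistency by construction

The total ground reaction force is not prescribed; it is computed from
whole-body Newton–Euler mechanics, `F(t) = sum_i m_i (a_i(t) - g)`, with
all segment accelerations available in closed form (every segment angle is
a fixed linear combination of the coordinates).  It is split between feet
with a cosine ramp across double support.  Two allocation refinements keep
per-foot signals physiological without touching any balance:

* The fore-aft component is re-allocated per foot from canonical
  braking/propulsion lobes plus a load-share-weighted correction that sums
  exactly to the net — in double support the two feet carry opposite-sign
  shear, which a single split ratio cannot represent.  Both components act
  at ground level, so no moment balance changes.
* The whole-body *moment* balance is closed by solving a small periodic
  pelvis-tilt oscillation (Fourier harmonics in the stride frequency,
  damped fixed-point iteration with the whole-body inertia about the
  pelvis as gain) such that the center of pressure follows a physiological
  roll-over template (fast heel→midfoot, midfoot dwell, forefoot by heel
  rise; monotone anchors in stance progress).  Trunk sway is the body's
  angular-momentum regulator, and the solved oscillation is ±1–2°.  The
  non-periodic (DC) remainder goes into a constant shared COP shift,
  typically 1–3 cm.

The result: inverse dynamics on a noise-free generated trial returns
pelvis residual forces and moments at machine precision, and the COP
advances monotonically heel to toe.  This replaces a residual-reduction
step — the data are consistent by construction, and `residual_report()`
serves as the diagnostic (pass thresholds 2% BW / 2% BW·m).

## The obesity adaptation

`apply_obesity_adaptation()` flattens the loading-response knee-flexion
excursion by `1 - 0.2 * severity` and damps the vertical pelvis
oscillation by `1 - 0.15 * severity` (default severity 1 for the obese
group); the slower self-selected speed is a cohort property.  This encodes
the observed obese strategy: walk slower and flatter to limit normalized
joint load.

## What a green test does and does not establish

The generator reproduces the *structure* of gait-lab data — periodic
kinematics, double-bump vertical GRF averaging to body weight,
braking/propulsion shear, monotone COP, event timing — and it is exactly
dynamically consistent, which real data never are.  It does not emulate
soft-tissue artifact, marker occlusion, force-plate targeting errors,
inter-subject waveform variability beyond anthropometry and speed, or
frontal/transverse-plane motion.  Green pipeline tests therefore establish
internal correctness of the mechanics, not agreement with any individual
child's data.

# The analysis pipeline

**Inverse kinematics** solves a per-frame weighted least squares of model
marker positions against measurements by Gauss–Newton with analytic
Jacobians, warm-started from the previous frame; non-converged frames are
flagged and interpolated, and a trial with more than 5% flagged frames is
rejected.  **Smoothing/differentiation** applies a zero-phase second-order
Butterworth low-pass (forward–backward, odd-reflection padding,
steady-state initial conditions; default cutoff 6 Hz, standard gait
practice) followed by cubic-spline differentiation.  **Events** are 20 N
threshold crossings of the vertical GRF; on this generator's cosine
weight-transfer tail the detected toe-off sits ~1.3% GC before the true
60% value, which the tests account for.  **Inverse dynamics** is computed
in generalized coordinates, `tau = M(q) qdd + b(q, qd) - Q_gravity -
Q_grf`: joint-coordinate entries are net internal moments and the pelvis
entries are the residuals; intersegmental forces come from subtree force
balances.  Forward dynamics with the same matrices inverts it to below
1e-6 rad/s², the consistency oracle in the tests.

**Static optimization** minimizes `sum(a^2) + w * sum(r_hat^2)` subject to
moment equilibrium per joint coordinate and `0 <= a <= 1`, where `r` are
reserve moments guaranteeing feasibility and `w = 1000` by default.  The
reserves are eliminated by substitution, so equilibrium holds to machine
precision by construction, and the remaining strictly convex
box-constrained quadratic program is solved by projected Newton with a
backtracking line search (the Newton system is solved in stacked
least-squares form, which halves the condition number exponent; L-BFGS-B
is a fallback).  `r_hat` is the reserve normalized by subject mass
relative to the 43.1 kg reference subject: with raw reserves the solution
would not be exactly invariant under mass scaling, and the invariance is a
property the pipeline promises.  Frames are solved independently (no
activation dynamics), warm-started along the trial.

**Joint reaction analysis** solves the planar force balance of the
shank+foot subsystem for the knee reaction, with the forces of the muscles
crossing the knee applied along attachment-geometry lines of action:
quadriceps via the patellar tendon onto the tibial tuberosity (aimed at a
patellar point fixed in the femur), hamstrings at their tibial insertion
aimed at the ischial origin, gastrocnemius acting on the calcaneus from
its femoral origin.  Uniarticular ankle muscles are internal to the
subsystem and cancel exactly, as they must.  Compression is the projection
on the tibia long axis (knee to ankle); shear is reported as a secondary
output.  The reaction is affine in the muscle-force vector, so group
contributions — computed by force-nulling, not re-optimization — superpose
exactly onto the total.

**Induced acceleration analysis** solves, per frame and per muscle, the
constrained equations of motion with only that muscle's generalized force
applied, mapping the resulting accelerations to the COM through the COM
Jacobian.  The stance-foot constraint is a kinematic pin at the material
point currently under the COP.  The pin is driven at that point's measured
acceleration (a "moving pin"): on dynamically consistent data the
constraint force then reproduces the measured GRF exactly, so the source
decomposition (muscles + gravity + velocity + reserves + residuals) closes
on the measured COM acceleration to solver precision.  The classical
perturbation variant integrates the full constrained model forward 0.01 s
with and without each muscle (RK4, pin target frozen over the interval)
and reports `2 * delta(COM position) / dt^2`; it agrees with the matrix
method to within a few percent RMS and converges to it as dt shrinks.

**Cohort statistics** follow peak-then-average: per-trial stance peaks are
averaged within subject, then group means and sds are formed, each subject
normalized by its own body weight.  The group comparison uses a
pooled-variance Student *t*-test by default, with Welch behind a flag —
the original analysis does not say which variant was used, and recomputing
the published demographic rows from printed summaries is consistent with
the pooled form (stature: p = 0.102 from rounded summaries vs 0.103
printed).  The speed–load relation is ordinary least squares of
per-subject peak CTF (xBW) on self-selected speed.

# Worked defaults and tunables

| Parameter | Default | Units | Why |
|---|---|---|---|
| filter cutoff | 6 | Hz | standard gait marker smoothing |
| event threshold | 20 | N | standard force-plate contact threshold |
| reserve weight `w` | 1000 | (mass-normalized N·m)^-2 | reserves engage only at muscle saturation |
| marker noise sd | 0.002 | m | typical optical capture residual |
| pelvis vertical amplitude | 0.02 | m | stated double-bump source |
| pelvis vertical phase | 0.045 | stride fraction | COM minimum lags heel strike |
| fore-aft amplitude | 0.014 | m | braking trough ≈ 0.19 BW |
| trunk lean | 5 | deg | normative forward lean |
| stance fraction | 0.6 | – | self-selected speed |
| cadence model | 43 v + 65 | steps/min | pediatric cadence–speed relation |
| IAA horizon dt | 0.01 | s | standard short-horizon perturbation interval |
| truncation | 2.5 | sd | no non-physical subjects |

# Known limitations

* Sagittal plane only: no frontal-plane moments, no varus/valgus, no
  medial/lateral compartment split, no gluteus medius as an abductor.
* The stated vertical pelvis oscillation (0.02 m at twice the stride
  frequency) is stronger than typical measured COM excursion; it holds
  about 1.2 BW on the trailing forefoot through 45–55% GC, so the
  pre-swing CTF peak (a quadriceps–gastrocnemius co-contraction, the same
  recognized second-peak mechanism) exceeds the first
  peak and the stance maximum lands near 3.2 xBW at ~50% GC, above the
  2.1–3.0 BW in-vivo envelope.  The first peak, at contralateral toe-off,
  is ~2.5 xBW — matching the reported group value.  Halving the
  oscillation amplitude restores first-peak dominance, but the amplitude
  is part of the stated world and is not moved.
* At the first CTF peak sample (10% GC) the hamstrings contribution
  slightly exceeds the quadriceps contribution (0.85 vs 0.50 xBW);
  quadriceps dominates from 12% GC onward.  Both underlying moments are
  within physiological ranges.
* Rigid tendon, activation-linear force; no activation dynamics between
  frames; straight-line muscle paths (single patellar via-point).
* The generator's feet are not kinematically welded to the ground: contact
  consistency is enforced through the force and moment balances, not
  through foot-flat constraints, so foot markers may drift a few
  centimeters relative to a fixed plate.

# Reproducing the cohort-scale run

```{r, eval = FALSE}
wf <- gait_waveforms()
nw <- run_cohort_pipeline(cohort_spec("normal", seed = 42), wf)
ob <- run_cohort_pipeline(cohort_spec("obese", seed = 42), wf)
compare_cohorts(ob, nw)
speed_load_regression(c(nw$per_subject$speed, ob$per_subject$speed),
                      c(nw$per_subject$peak_ctf_bw,
                        ob$per_subject$peak_ctf_bw))
```

`scripts/acceptance.R` wraps exactly this computation (plus the obesity
adaptation and peak extraction) and writes the four headline quantities as
JSON; the test suite asserts every invariant described above.
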