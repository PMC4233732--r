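---
title: "A multibody model of rabbit mastication: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multibody model of rabbit mastication: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masticate)
```

# The problem

During chewing, a rabbit's mandible moves with six degrees of freedom under
the pull of bilaterally paired jaw muscles, reaction forces at the two
temporomandibular joints (TMJs), and the resistance of the food between its
teeth. The muscle system is redundant: many more muscle fibres act on the
jaw than there are equations of motion, so the activations that produce an
observed movement cannot be read off the mechanics alone. `masticate`
resolves this redundancy the way inverse-dynamics muscle models do: the jaw
follows a prescribed chewing movement, the food bolus supplies a known
resistance at each instant, and a minimum-effort optimisation chooses the
muscle activations (and admissible joint reactions) that keep the mandible
in force balance.

The package simulates four biting modes — molar shearing, molar crushing,
incisor biting, and premolar crushing — plus a maximum-bite-force experiment
against a rigid bolus, and reports the statistics used to characterise them:
bite-force components, per-muscle peak activations, the recruited fraction of
total muscle force, and the maximum incisor bite force for comparison with
in vivo transducer measurements (mean 69.1 ± 13.3 N, absolute maximum
95.2 N).

# Coordinate conventions

All lengths are millimetres, forces newtons, moments newton-millimetres.
The world (cranium) frame is right-handed with its origin at the midpoint
between the mandibular condyles, +x anterior, +y toward the animal's left,
+z dorsal. The mandible body frame coincides with the world frame at the
closed midline pose. The working side is the right side. A jaw pose has six
generalized coordinates: sagittal angle (positive opens the jaw, rotation
about the transverse condylar axis), frontal angle (positive rolls the chin
toward the working side about the anteroposterior axis through the
*balancing* condyle, which therefore stays put, matching the cineradiographic
description of a stationary balancing condyle), yaw, and a 3-vector
translation.

# Muscle model

## Architecture

Each muscle part carries a maximum isometric force. For the jaw closers
these are the published dissection-derived values (superficial masseter
60.9 N, posterior deep masseter 10.3 N, anterior/posterior
zygomaticomandibularis 15.0/10.5 N, temporalis 37.1 N, medial pterygoid
62.3 N, lateral pterygoid 9.8 N per side; 205.9 N per side, 411.8 N total).
PCSA follows the standard fibre-architecture estimate
`mass * cos(pennation) / (density * fibre_length)` with zero pennation and
density 1.05 g cm^-3, and maximum force is PCSA × 25 N cm^-2. The printed
maximum forces are authoritative for the model: the temporalis and pterygoid
rows of the published table are not exactly reproducible from the stated
formula at any plausible density, so mass, fibre length and PCSA are kept as
provenance metadata and the forces are used verbatim. The temporalis is
split into superficial (6.2 N, the published whole-part figure) and deep
(the remaining 30.9 N) parts. The digastric (jaw opener) has no published
maximum force; it defaults to 10 N, is configurable, and influences only the
opening phase, not any reported bite statistic.

## Strands

Each muscle part is discretised into strands — straight-line (or via-point
polyline) lines of action, 75 per side, 150 in total. Strand counts per
muscle are allocated proportionally to maximum force with a minimum of three
per part and the remainder assigned to the superficial masseter (the
strongest and most architecturally heterogeneous muscle); any allocation
summing to the per-side budget is accepted via configuration. Each strand
receives an equal share of its muscle's maximum force.

Strand tension is Hill-type in the narrow sense used here: tension =
activation × maximum-force share + passive tension. There is no
force–length or force–velocity scaling and no activation dynamics — the
model names exactly three parameters (maximum force, activation factor,
passive tension), and the known 13–30 ms in vivo electromechanical delay is
deliberately absent. Passive tension is zero at or below the rest length
(taken at the closed midline pose), rises exponentially with strain, and
saturates at 0.1% of the strand's maximum force. The exponent (shape 5) and
saturation strain (0.5) are configurable; only the exponential form and the
0.1% cap are empirically anchored. Tests verify that switching passive
tension off changes solved peak activations by less than half a percentage
point, consistent with the published observation that it did not affect
activations or bite forces.

Via points (used for the superficial temporalis and medial pterygoid, whose
paths wrap around bone) redirect the line of action. Whether the original
model used via points or true surface wrapping is not recoverable; via
points were chosen. Muscle force is applied to the mandible at the insertion
along the last path segment; a via point tagged to the mandible additionally
transmits its segment-tension resultant. A virtual-work identity — the
finite-difference gradient of path length with respect to each generalized
coordinate equals minus the generalized force per unit tension — is enforced
in the test suite to 1e-4 relative over random strands and poses, which ties
the wrench computation to the path geometry with no free parameters.

# Mandible and TMJ

The mandible is a rigid body. When a watertight surface mesh is available,
mass, centre of mass and inertia are integrated exactly over the enclosed
volume (tetrahedral decomposition / divergence theorem) at tissue density
1.05 g cm^-3; otherwise a solid-ellipsoid approximation (semi-axes
30 × 10 × 8 mm, ~10.6 g) is used. The choice barely matters in the default
quasi-static mode, where inertial terms are dropped and the mandible's
weight (~0.1 N) is the only body force.

Each TMJ is a unilateral point contact at the condyle: the reaction on the
mandible must be compressive along the fossa contact normal, with
tangential components bounded by `mu` × normal (default `mu = 0`,
frictionless). The contact normal is tilted 12 degrees posteriorly from
straight ventral: the condyle brakes against the articular eminence, so the
fossa can resist protraction of the jaw but cannot pull. The pose trajectory
is fully prescribed, so condylar translation is kinematic rather than
contact-resolved. The original specimen's TMJ contact surfaces are
unpublished; both the tilt and the placement of the frontal rotation axis
through the balancing condyle are this package's interpretation of the
published kinematic description.

# Chewing kinematics

Each simulation is one reduction bite cycle in three phases: opening (90 ms,
sagittal angle 0 → 12°), fast closing (50 ms, 12° → food-contact angle,
with the frontal angle rotating 0 → 4° toward the working side in the molar
modes), and slow closing — the power stroke — (140 ms, ending with the bolus
compressed to half its height). Only the 140 ms slow close is empirically
printed; the other durations are literature-consistent defaults and all are
configurable. Incisor biting uses the same reduction cycle with the frontal
angle identically zero; this mirrors the published assumption that incisor
biting reuses the molar cycle timing, and because the simulation ends at
half compression the phase durations affect only the time axis of the
activation curves, not the peaks.

Waypoints are joined with cosine ramps (the published angle-time curves are
sketches; only the waypoints are recoverable). Within the slow close the
bolus compression follows a front-loaded ramp (`sin(pi s / 2)`, fastest at
contact — food yields most readily early in the power stroke) while the
shearing return of the frontal angle to the midline follows a back-loaded
ramp (`cos(pi s / 2)`, fastest near the end). The sagittal angle is solved
by root-finding at each instant so the vertical compression follows its
ramp exactly regardless of the frontal motion. This asymmetry is a design
choice, fixed before the acceptance statistics were evaluated, that
reproduces the in vivo sequencing: the occlusion muscle group peaks early in
the power stroke and the shearing group afterwards.

# The food bolus

The bolus is two rigid plates joined by a tri-axial linear spring with
per-axis force caps, the lower plate riding on the mandibular tooth point
and the upper on the opposing maxillary point. Per axis, force =
min(stiffness × |displacement|, cap) opposing the displacement; the vertical
spring acts only in compression, the shear springs in both directions and —
by design, since the published account states only the caps and the
proportional law — they plateau at the cap rather than unloading.

Mode defaults: crushing — height 1.3 mm, vertical cap 100 N; shearing —
height 1.3 mm, caps (20, 20, 60) N; incisor — height 2.4 mm, vertical law as
crushing; rigid (maximum bite) — stiff enough to compress < 1 µm under
500 N. Vertical stiffness is cap/height, so the cap is met exactly at full
compression; compressing to half height therefore yields exactly 50 N in
the crushing and incisor modes, the published mid-cycle resistance. Shear
stiffness is treated as a food property calibrated on the shearing
movement: the mediolateral cap is reached exactly when the working molar
has traversed its full 4° frontal-return excursion (~1.3 mm), and both
horizontal axes share that spring constant in all modes. Shear displacement
is measured from the grip position at food contact, so the spring resists
the return to the midline, as described.

# The recruitment solver

At each timestep the solver finds strand activations `a` in [0, 1] and
condylar reaction magnitudes `r >= 0` minimising `sum(a^2)` subject to the
six-component force/moment balance of the mandible under the known wrenches
(gravity, passive tension, bolus force, and in dynamic mode the inertial
terms). The quadratic objective distributes load toward strong muscles —
matching the observation that the superficial masseter produces some of the
largest forces at the lowest activations — and alternative weightings can be
substituted in configuration. The problem is solved with the dual active-set
method (`quadprog`), after scaling moment rows by a 50 mm reference length;
reactions enter through scaled variables with a 1e-6-weight regulariser
(activation bias < 1e-3); the solution is then polished by an exact solve of
the reduced KKT system on the free variable set, which brings the
equilibrium residual of feasible steps to machine precision (the test suite
enforces ≤ 1e-6 N and ≤ 1e-4 N mm on every feasible step of all four modes).
If the demanded wrench is unreachable, the solver instead minimises the
residual norm over the same bounds (ridge-regularised bounded least squares)
and flags the step infeasible — never silently.

Muscle eligibility follows the two observed muscle groups. Group 1 —
working-side posterior deep masseter, both zygomaticomandibularis parts and
both temporalis parts, plus balancing-side superficial masseter and both
pterygoids — may activate from fast closing onward; group 2, its mirror
image, becomes *eligible* at slow-closing onset with the optimiser deciding
its level (whether the original drove group-2 onset by schedule or by demand
is ambiguous; eligibility-plus-optimisation was chosen). Opening is driven
by the digastrics alone. Incisor biting recruits all closers with mirrored
strand pairs tied equal; on the exactly symmetric synthetic model the ties
are exact rather than approximate.

Two consequences of the quasi-static default are worth knowing. First, a
statically held open jaw needs closer tone to resist gravity (gravity's
moment about the condylar axis *opens* the jaw), so the opening phase —
digastrics only — is flagged infeasible with a residual equal to the
unbalanced gravity wrench (~0.1 N, a few N mm). Second, during fast closing
group 1 alone cannot null every component of the (milli-newton scale)
gravity wrench, because its members all rotate the jaw toward the working
side by design; those steps are likewise flagged, with residuals at gravity
scale. Both phases are unloaded and inherently dynamic in vivo; in dynamic
mode (`dynamic = TRUE`) the prescribed accelerations absorb these residuals.
No bite-phase statistic depends on either phase, and every loaded
(slow-closing) step of every default run solves to machine-precision
equilibrium.

The maximum-bite experiment bypasses the optimiser: all closers are set to
100% activation against a rigid incisor bolus at a 5.5 mm gape, and the
static balance is solved directly (least squares over the unknown bite
reaction and the two condylar reactions; on the symmetric model the system
is exactly determined and the mediolateral bite component vanishes to
machine precision). Doubling muscle stress exactly doubles the resultant
when gravity — the one wrench not proportional to muscle strength — is
switched off, and the test suite asserts this homogeneity at 1e-9 relative.

# Synthetic geometry and its calibration

No attachment coordinates, TMJ surfaces or specimen meshes are published
for the original model, so the geometry module generates a rabbit-scale,
exactly mirror-symmetric landmark set: condyles ±14 mm from the midline,
occlusal plane 18 mm below the condylar axis, most posterior molars 28 mm
and premolars 38 mm anterior of the condyles, incisor bite point at 72 mm
(the jaw length), and per-muscle attachment fans whose centroids, spreads
and line-of-action directions encode the gross anatomy (e.g. the superficial
masseter fans from near-vertical anterior fibres to more protrusive
posterior fibres; the posterior deep masseter and deep temporalis retract;
the pterygoids protract and pull medially). An optional seeded jitter
perturbs the fans; by default the generator is fully deterministic.

These coordinates are calibration parameters, not measured anatomy. They
were fixed once, during model construction, against the qualitative
structure the simulator must reproduce: a maximum incisor bite force inside
the measured envelope (the shipped defaults give ~85 N — above one standard
deviation over the measured mean, below the absolute maximum, the same
position the original prediction of 87.8 N occupies), feasibility of the
loaded power stroke in all four modes, the recruited-fraction ordering
(shearing < crushing < incisor), the dominance of the vertical bite
component in crushing over shearing, and the group-1-before-group-2 peak
ordering. The principal knobs are `lever_scale` (0.85; scales the
anteroposterior/vertical placement of the muscle attachment field, setting
overall mechanical advantage) and `fossa_tilt_deg` (12°). They were not
revisited afterwards.

Because the geometry is synthetic, the exact published geometry-dependent
numbers (87.8 N maximum bite; resultants of 35.4/51.5/50.8/50.9 N; the
per-muscle peak-activation table) are *not* reproduction targets — they
depend on the unpublished specimen. What passing tests show is that the
mechanics, the optimisation, and the reporting pipeline are correct and that
the default model lies in the physiologically measured regime; they do not
show that the synthetic rabbit is the scanned rabbit.

# Numerical choices

* Timestep 1 ms (281 steps per cycle); each step's QP has ~80-152 variables
  and solves in milliseconds; a full run takes a few seconds on one core.
* Moment equations are scaled by 50 mm; reaction variables by 100 N.
* Feasibility tolerances: 1e-6 N force, 1e-4 N mm moment.
* Root-finding (contact angles, gape inversion) uses `uniroot` at 1e-10.
* Finite-difference step for Jacobians and the virtual-work oracle: 1e-4
  (degrees/mm); inertial terms use 1e-5 s central differences.
* Ties in the incisor QP are implemented by merging mirrored columns, which
  preserves convexity and exact equality of the pair.

# Limitations

* No force-length/velocity properties, activation dynamics, or fatigue.
* Quasi-static by default; the dynamic mode is a first-order treatment
  driven by prescribed kinematics, not contact-impact dynamics.
* The TMJ is two point contacts; there is no compliant disc, and condylar
  translation is prescribed, not resolved.
* Single cycle only; no bolus transport, fracture or softening.
* The synthetic geometry is plausible, mirror-symmetric rabbit anatomy, not
  a specimen; geometry-dependent magnitudes carry that caveat.
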