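---
title: "Models and methods behind hemigait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hemigait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`hemigait` re-creates, at desk scale, the computational workflow used to
predict walking after internal hemipelvectomy with custom prosthesis
reconstruction: personalized-model calibration, synergy-based neural
control, direct-collocation gait tracking and prediction, and a virtual
psoas-strength sweep. This vignette explains the models the package
implements, the tunable parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical choices behind the
solvers. Everything quantitative stated here is computed by the package's
own tests or scripts.

## The musculoskeletal model

A `walker_model` is a branched kinematic tree rooted at a floating pelvis.
Each segment attaches to its parent through an ordered chain of one-DOF
transforms (translations along, and rotations about, axes fixed in the
running joint frame), so a 6-DOF ground joint is three translations
followed by a Z-X-Y rotation sequence, matching the usual gait-model
convention (x forward, y up, z toward the operated right side; radians and
SI units internally, degrees only in MOT files).

Muscles are rigid-tendon Hill-type actuators. The tendon is fixed at its
slack length, so fiber kinematics follow algebraically from muscle-tendon
length through a constant-height pennation model, and tendon force is

F = f_max [ a f_L(l') f_V(v') + f_P(l') ] cos(alpha),

with normalized fiber length l' and velocity v'. The curve shapes are not
printed in the source literature, so the package pins standard forms and
exposes every constant in `hill_curves()`: a Gaussian active force-length
curve `exp(-(l'-1)^2 / 0.45)`, an exponential passive curve that is zero at
and below optimal length, and a hyperbolic force-velocity curve with
maximum shortening velocity 10 optimal fiber lengths per second and an
eccentric plateau of 1.4. Tests pin these constants, so changing them is a
deliberate act.

Muscle-tendon geometry is represented natively by *surrogate polynomials*:
muscle-tendon length is a polynomial in the spanned joint angles (full
degree-3 basis by default, config-overridable), and the moment arm about a
coordinate is minus the analytic partial derivative of length. The
derivative identity therefore holds by construction and is spot-checked by
finite differences over Latin-hypercube pose sets. There is no via-point or
wrapping geometry: surrogates *are* the geometry at this scale.

Excitation-to-activation dynamics are first order with separate activation
and deactivation time constants, an electromechanical delay (linear
interpolation into the past signal, padded with the first sample), an EMG
scale factor, and an exponential non-linearisation
`a' = (exp(A a) - 1)/(exp(A) - 1)` with shape factor A in [-3, -0.01]
(A = -0.01 is treated as the linear limit). The discrete update integrates
the linear ODE exactly for an input varying linearly across the step, which
is unconditionally stable; the step guard `dt < min(tau)/2` protects the
fidelity of the activation/deactivation switching, not stability.

## Foot-ground contact

Each foot carries a rearfoot and a toes grid of viscoelastic elements
(2x3 + 2x2 per foot by default). An element produces a normal force
`F_n = k <delta> (1 + c delta_dot)`, clamped at zero, where `<delta>` is a
softplus-smoothed positive part of penetration (half-width 0.1 mm) so
collocation sees a C1 force across the contact boundary, and a shear force
`F_n (mu_d tanh(|v|/v_t) + mu_v |v|)` opposing slip — the continuous
stick-slip law with transition velocity v_t = 0.05 m/s. Defaults are
k = 20 kN/m, c = 1.5 s/m, mu_d = 0.8, mu_v = 0.5 s/m; the source study
calibrated but did not print its contact values, so these are declared
fixture defaults, chosen soft enough that the ground-reaction profile stays
representable on desk-scale collocation meshes (element stiffness and
load-transfer ramp width together set the highest harmonic in the GRF).
The static-friction hump of fuller stick-slip models is deliberately
omitted.

## Skeletal dynamics and the inverse formulation

Inverse dynamics is a recursive Newton-Euler pass over the tree,
vectorised over time samples, with contact wrenches applied to the feet.
The generalized forces at the six (three, for the planar fixture) floating
-base coordinates are the *pelvis residual loads*; they vanish for a
dynamically consistent motion and all collocation problems drive them to
zero as path constraints. All problems use the inverse formulation: the
states are joint positions, velocities and accelerations, the controls are
joint jerks (a triple-integrator chain per coordinate) plus synergy
activations, and muscle forces never enter the dynamics loop — they enter
through the separate moment-matching constraint. This mirrors how the
original workflow kept the optimal control problems tractable, and it makes
the defect constraints exactly linear.

## Neural control

Lower-extremity activations are factorized by non-negative matrix
factorization (Frobenius multiplicative updates, seeded random restarts,
best of ten by default) into six unit-norm synergy vectors per body side
and non-negative time-varying synergy activations. Missing-muscle
estimation exploits the linearity of joint moments in activations at fixed
kinematics: the weights of unmeasured muscles solve a non-negative least
squares with an activation-magnitude penalty (default 1e-2) and a
head-similarity penalty tying heads of one anatomical muscle together
(default 1e-1); the weights are unstated in the source, and are exposed as
arguments. Contralateral mirroring enforces periodicity, fits a Fourier
series over two tiled cycles (10 harmonics by default), evaluates it
half a cycle later, and then adjusts per-muscle scale, time delay and an
*aperiodicity* term — implemented as an additive linear-in-time drift,
zero-mean over the cycle, the minimal parameterization that lets a
periodic estimate fit an aperiodic target (the term is named but never
defined in the source literature). The adjustment is bounded
(scale in [0.5, 2], |delay| <= 0.1 s, |aperiodicity| <= 0.2) and returns
the initial estimate with a failure flag if the optimizer does not
converge. Note that at the activation bounds the drift term is
structurally unidentifiable (the clamp absorbs it), which is why the
recovery tests operate on traces lifted away from 0 and 1.

## Calibration

EMG-driven calibration adjusts, per muscle, the EMG scale factor, delay,
activation time constants, shape factor, and optimal-fiber-length and
tendon-slack-length multipliers (bounded to [0.75, 1.25]; the source
bounds are unstated) by bound-constrained Levenberg-Marquardt so model
moments reproduce inverse-dynamics moments over all trials jointly. Peak
isometric strengths are never design variables — they come from
height/weight regression in the original workflow and are carried by the
fixtures directly. Muscle-head reduction evaluates all heads at full
activation over 1000 Latin-hypercube poses (bounds inflated ~10% beyond
the range of motion), solves the inner strength re-optimization exactly by
non-negative least squares (moments are linear in strength), and keeps the
best admissible subset. "Approximately equal spacing" is interpreted as:
subsets retaining the first and last head with pairwise index gaps
differing by at most one; an exhaustive-enumeration mode exists and is the
oracle route in the tests.

## Direct collocation

All five problem formulations (contact calibration, neural calibration,
verification tracking, free-time verification prediction, and treatment
prediction) share one transcription: states on the mesh nodes of a
compressed Hermite-Simpson scheme, jerk and synergy-activation controls on
the nodes, optional static parameters (contact scales), and the final time
when free. Because the dynamics are pure integrator chains, the defect
constraints are exactly linear in the variables at fixed final time, and
the solver treats them — together with state periodicity (all coordinates
except the forward pelvis translation) and the average-speed constraint
`displacement = speed x T` — as hard linear equalities satisfied at every
iterate through KKT steps. The node-local nonlinear constraints (pelvis
residuals, synergy moment matching, activation bounds for treatment
problems, ground-reaction periodicity) are penalty terms whose weights
escalate until the unweighted feasibility tolerances are met (residuals
1 N / 1 N m RMS, moment match 2.5 N m RMS, periodicity 1e-3 rad). The
objective Jacobian is built by grouped finite differences exploiting
node-locality (one evaluation per state role and node group), which keeps
the Gauss-Newton normal matrix block-sparse and the KKT solves fast.
Tracking weights normalize each channel by its cycle standard deviation;
the absolute weights are package defaults (the source values are
unpublished) recorded in `ocp_spec()`.

Three numerical choices deserve note. First, initial guesses are built
from one band-limited (truncated Fourier) representation of the reference
kinematics, from which positions, velocities, accelerations and jerks are
all derived analytically — interpolating each state independently onto a
coarse mesh aliases the high harmonics and violates the defects by orders
of magnitude. Second, coordinates that no muscle spans (the reduced 3-D
fixture leaves the subtalar and hip-rotation coordinates passive) carry
explicit reserve-torque controls tracked toward the reference cycle's
inverse-dynamics torques: an untracked reserve is a free ideal actuator
that the optimizer exploits (in early experiments it rolled the foot tens
of degrees to fake abduction support). Third, treatment problems bound the
free final time to ±15% of the pre-surgery period; without the bound the
optimizer drifts toward slow cadences that cheapen the jerk cost.

Problem sizes in the tests are N = 32 mesh intervals for the planar
fixture and N = 16-24 for the 3-D fixture, with a few dozen Gauss-Newton
iterations per solve; these are the package's desk-scale choices and are
stated in the tests that use them. At these budgets the planar tracking
problem reproduces the generator's joint angles to about a quarter of a
degree RMS and its ground reactions to 6-14 N RMS; longer budgets keep
converging on the ground reactions (the contact stiffness makes them the
slowest channel), which is why the tests assert 1 degree and 15 N.

## The synthetic-data generator

`generate_gait()` manufactures the study conditions: a near-periodic cycle
at the self-selected 1.4 m/s (stride time 1.1 s, hence stride length
1.54 m), bilateral kinematics, contact-model ground reactions,
inverse-dynamics-consistent joint moments, activations generated from a
known 6-per-side synergy basis, and EMG obtained by inverting the
activation dynamics plus seeded noise (5% multiplicative + 0.02 additive
by default). It works in four stages:

1. **Trajectory construction.** Foot poses are prescribed directly (stance
   fraction 0.65, smooth load-transfer ramps spanning 15% of the cycle,
   heel and toe rockers so the center of pressure travels heel to toe,
   swing clearance with a plateaued height bump), the pelvis follows a
   nominal path, and exact closed-form leg inverse kinematics give the
   joint trajectories. Swing-phase ankle angles are filled by a clipped
   Hermite interpolant rather than foot-levelling, which would demand
   over a radian of dorsiflexion and passively load the plantarflexors.
2. **Residual zeroing.** Per-sample pelvis (and lumbar) deviation
   channels, low-harmonic stance micro-slip, stance drift and contact
   depth/pitch scalars are adjusted by a damped Gauss-Newton (Marquardt
   scaling, step caps, curvature penalties on the posture channels) until
   the pelvis residual loads essentially vanish; the bundles used in the
   tests reach ~0.02-0.2 N and N m RMS, well inside the 1 N consistency
   contract, and the vertical impulse matches body weight times stride
   time to a fraction of a percent.
3. **Synergy-structured activations.** Per node, synergy activations solve
   a non-negative least squares matching the inverse-dynamics moments at
   the actuated coordinates, with a template prior, a preference for
   low-activation solutions, and escalating penalties enforcing a <= 1.
   The fixture's muscle strengths and hand-structured synergy weights are
   sized so this is feasible: moment-match RMS is ~0.01 N m (planar) and
   ~1.1 N m (3-D) against the 2 N m contract.
4. **EMG synthesis.** Per muscle, activation dynamics are inverted (de-non
   -linearise, recover the ODE input from the derivative, undo scale and
   delay) and seeded noise is added.

What the generator emulates: periodic treadmill-like gait at the study's
speed, the data channels the workflow needs, the missing-EMG pattern (no
contralateral-leg or trunk EMG), and left/right symmetry with explicit
asymmetry knobs. What it does not: marker trajectories, soft-tissue
artifact, non-stationarity across strides, spontaneous motor variability,
and human-scale joint moments — the flat-footed, long-stride reduced
walker needs larger moments than human gait, and the fixture muscle
strengths are sized to its own demands (several-fold supra-physiological).
Passing tests therefore demonstrate the *methods* are correct and
internally consistent at desk scale, not that the fixtures reproduce human
magnitudes; the package's metabolic costs, in particular, are fixture-scale
numbers.

Two fixture-design resolutions matter for interpretation. The 3-D
fixture's subtalar and hip-rotation coordinates are unactuated (passive):
with them actuated, six synergies per side are dimensionally unable to
match fourteen moment channels pointwise, an honest constraint of
synergy-limited control at this muscle count. And the anatomical roster
keeps every muscle named in the default resection scenario (all hip
abductor heads, iliacus, rectus femoris, tensor fascia latae, the small
external rotators, and most operated-side trunk muscles, with a few
erector spinae / multifidus heads remaining), so virtual surgery exercises
the same pattern as the clinical scenario it models.

## Clinical measures

Spatial symmetry is operated step length over stride length, temporal
symmetry the same in time; 0.5 is perfect symmetry. The printed clinical
convention that a longer operated step gives a value *below* 0.5 is
internally inconsistent with that ratio; the package implements the ratio
as defined and surfaces the convention note in the documentation only.
Stance width is the lateral heel-to-heel distance "when each foot is flat
on the ground": with rockered feet the two feet are never flat
simultaneously, so the package takes each foot's mean heel position over
its own foot-flat window (sole within ~3 degrees of level and vertical
load above 30% body weight). Metabolic cost follows the Bhargava-style
muscle energetics model — activation heat, maintenance heat with the
piecewise fiber-length dependence, shortening/lengthening heat, and
positive mechanical work rate — with muscle mass
`rho (f_max / sigma) l_opt`, sigma = 0.25 MPa, rho = 1059.7 kg/m^3, and
the basal term off by default. Cost of transport divides the cycle's
metabolic cost by body mass times the stride length of the analyzed cycle.

## Known limitations

The collocation solver is a purpose-built constrained Gauss-Newton, not an
interior-point NLP code: it reports unweighted feasibility against stated
tolerances and refuses success otherwise, but offers no global-optimality
or mesh-refinement machinery. Post-surgery prediction problems — where the
seed violates the moment-matching constraints badly because the abductors
are gone — converge slowly at desk scale. At the suite budgets the
maintained-psoas treatment solve reaches dynamical consistency (pelvis
residuals ~1 N) and reproduces the clinical direction (wider stance,
operated-side trunk lean), but its synergy moment match plateaus around
3 N m against the package's 2.5 N m success tolerance, so the sweep labels
it failed; full convergence needs a several-fold larger iteration budget.
Weak-psoas scenarios may fail outright, exactly as the weakest-psoas
scenarios failed to converge in the clinical study this package's workflow
models. The 101-point cycle convention, the 6-per-side
synergy count, the resection roster, and the psoas sweep values
(0/50/100/150%) are fixed by that workflow; essentially everything else
(curve constants, weights, penalties, mesh sizes, noise levels) is a
documented package default.
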