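---
title: "Reconstructing movement as optimal control: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing movement as optimal control: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
models, the optimization, the synthetic data, and the design decisions taken
where the design was genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The reconstruction problem

Optical motion capture gives marker trajectories; force plates give ground
reaction forces (GRFs). Classical inverse analysis estimates generalized
coordinates per frame (inverse kinematics, IK), filters them, and computes
joint moments (inverse dynamics, ID). Because each frame is fit
independently and kinematics and kinetics are never reconciled, the result
is dynamically inconsistent: a fictitious 6-DoF force/moment pair at the
pelvis (the residuals) absorbs the disagreement.

The package's core instead reconstructs the motion as an optimal control
simulation: find state and control trajectories of a musculoskeletal model
that minimize a weighted sum of tracking error and effort while satisfying
the model dynamics exactly (to solver tolerance). Two tracking modes exist:

- **marker tracking** — track the measured 3D marker positions and GRFs
  directly; and
- **coordinate tracking** — track pelvis translations, angles estimated by
  IK, and GRFs.

Marker tracking avoids propagating IK errors and the accumulation of
per-joint angle errors down the kinematic chain, at the cost of a harder
optimization (marker positions are nonlinear in the states). Reference data
are deliberately **not** low-pass filtered before tracking: the simulation
itself acts as a physical filter through the dynamics and effort terms.

## Model class

A model is a rooted tree of single-DoF joints. The first six DoFs are the
global pelvis coordinates: three translations, then three rotations with the
vertical-axis rotation first, so pelvis obliquity and tilt remain
interpretable independent of heading. Segments carry mass, center of mass
and inertia; markers and contact points are rigidly attached to segment
frames.

- **Multibody dynamics** are formulated implicitly,
  `f(x, xdot, u) = 0`, with the generalized forces evaluated by a recursive
  Newton-Euler pass. The residual blocks are: kinematic identities
  (`qdot - dq/dt`), equations of motion (gravity, contact, muscle, passive,
  actuator loads), muscle activation dynamics and muscle contraction
  dynamics. State `x = (q, qdot, a, s)`, control `u = (n_e, m)` with neural
  excitations `n_e` and normalized actuator torques `m`.
- **Contact** is penetration-based and smooth everywhere: vertical force
  `k * sp(d)^p * (1 + c * penetration velocity)` with a softplus-smoothed
  depth `sp(d)` (smoothing width 0.1 mm), and tanh-style velocity-smoothed
  Coulomb friction bounded by `mu` times the vertical force. A single
  vertical offset of all contact points (shoe sole thickness) is calibrated
  during standing.
- **Muscles** are Hill-type with a series-elastic tendon, expressed as
  implicit residuals. Activation follows first-order dynamics with smoothly
  switched activation (10 ms) and deactivation (40 ms) time constants. The
  contraction residual balances an exponential tendon force against
  active (Gaussian force-length, sigmoidal force-velocity) plus passive
  fiber forces; a small fiber damping term (0.1) keeps the implicit
  equation solvable for the fiber velocity at every state. Muscle-tendon
  lengths are polynomials in the joint angles; moment arms are the negative
  partial derivatives of length. A rigid-tendon switch exists for debugging.
- **Passive joint moments** are near-zero inside the configured range of
  motion and stiffen exponentially beyond it, plus light linear damping.
- **Torque actuators** apply `gain * m` at selected DoFs. Controls are
  normalized by a maximum-torque gain (toy model: 300 N m) so the default
  effort weighting — meant for dimensionless neural excitations and small
  arm torques — weighs them on a comparable scale.

Angle unit is radians internally; degrees and millimeters appear only at
file interfaces and in the tracking objective, whose weights are expressed
per mm^2, deg^2 and (BW%)^2.

## Objective, constraints and weights

The objective is `J = J_tra + J_mus + J_tor + J_reg`:

- `J_tra`: per data type `j`, `W_j / (N N_j) * sum (y - yhat)^2`, in mm
  (markers, translations), deg (angles) and body-weight percent (GRFs).
  Occluded samples contribute zero without changing the normalization.
- `J_mus`: volume-weighted cubed neural excitations, mean over nodes and
  muscles.
- `J_tor`: mean squared torque controls.
- `J_reg`: mean squared temporal state/control differences, scaled by
  `(N - 1) / T^2`, which regularizes towards smooth trajectories.

Default weights (running: marker 1e-2 mm^-2, GRF 1e-3 (BW%)^-2, translation
1e-3 mm^-2, angle 1e-1 deg^-2, effort 1 and 1e-1, regularization 1e-3;
standing uses GRF 1e-2 and no regularization) are the field's standard
weight set for this problem class and are exposed through
`objective_weights()`.

Dynamics enter as equality constraints via backward Euler,
`f(x[k+1], (x[k+1] - x[k]) / h, u[k+1]) = 0` for every interval. No initial
state, periodicity or task constraint is imposed — this is what makes
arbitrary (including change-of-direction) motions reconstructable. Because
the first node would otherwise be underdetermined, a forward-Euler closure
`f(x[1], (x[2] - x[1]) / h, u[1]) = 0` is added with the kinematic-identity
rows of the six global pelvis coordinates removed, so global motion is not
restricted; together the two first-node equations imply constant state and
control velocities between nodes 1 and 2. To keep that boundary assumption
out of the analysis, ten context samples are prepended before the motion of
interest (`prepend_context()`), and evaluation uses the motion of interest
only.

## Solving the nonlinear program

No off-the-shelf sparse NLP solver is available to the package, so it ships
its own, built for this problem family:

- **Transcription.** One node per data sample (175 Hz; GRF decimated from
  1750 Hz without pre-filtering). Variables are states and controls at all
  nodes; constraints are the backward-Euler blocks plus the first-node
  closure.
- **Derivatives.** Objective gradients are analytic; the tracking
  Gauss-Newton Hessian uses per-node marker/GRF Jacobians computed by
  central differences in compiled code. The constraint Jacobian uses
  central differences compressed by a 3-coloring over nodes (a block only
  touches two adjacent nodes), so one Jacobian costs six residual-stack
  evaluations per variable column instead of one per variable.
- **SQP iteration.** A Gauss-Newton Hessian (exact for the quadratic
  terms), sparse KKT systems solved in O(N) by a block-tridiagonal
  factorization in a node-interleaved ordering, an add-only active set for
  the simple bounds, Levenberg damping, and adaptive row/column
  equilibration (the exponential tendon and the stiff contact otherwise
  push the KKT matrix beyond what sparse LU pivoting tolerates).
- **Globalization.** A filter line search in the Fletcher-Leyffer style —
  a trial point is accepted when it improves either feasibility or the
  objective — with a second-order correction step and a
  feasibility-restoration step. An l1 merit function was tried first and
  deadlocks on the strongly curved constraint manifold of stiff contact:
  every objective-improving step slightly violates the dynamics, so an
  exact-penalty merit rejects all of them.
- **Progressive horizon.** The reconstruction is solved over a growing time
  window (10 nodes per stage, nodes more than 25 behind the front frozen at
  their current values), warm-starting each stage from the previous one,
  followed by a full-horizon polish. The recording's lead-in starts near
  the standing pose, so each stage is a small, well-conditioned
  perturbation; this follows the homotopy that the data themselves provide.
- **Termination.** Converged when the scaled KKT error is below `tol`
  (default 1e-4) and the unscaled constraint violation below
  `constraint_tol` (default 0.001); additionally, once feasible, the solver
  stops when the objective has been flat for 40 iterations
  (`stalled_progress`). In practice the Gauss-Newton dual error plateaus
  around a few 1e-4 while the dynamics are satisfied to ~1e-6 or better;
  results report the achieved scaled NLP error.

The standing calibration solves the same structure at a single node with
`f(x, 0, u) = 0`, the regularization omitted, and the vertical contact
offset as a free variable. It is solved from 10 random restarts (seeded;
the seed and all per-restart outcomes are recorded) and the lowest
objective wins, ties going to the lowest restart index. Because truly
uniform random poses almost never reach the data basin through the
constraint manifold, each random draw is first pulled toward the data by a
few unconstrained Gauss-Newton steps on the kinematic tracking term; the
restarts keep their diversity in the remaining variables. Fiber lengths are
initialized near tendon-slack consistency with the drawn pose — the
exponential tendon makes inconsistent draws numerically useless.

The initial guess for a reconstruction is the standing solution tiled over
all nodes, which is feasible by construction (an equilibrium satisfies every
backward-Euler block exactly).

## Inverse pipeline

IK minimizes the equally-weighted squared marker distances per frame
(Gauss-Newton; warm-started from the previous frame by default, which does
not change the optimum — set `warm_start = FALSE` for strict per-frame
independence). ID applies measured GRFs at their centers of pressure and
reports the full 6-DoF pelvis imbalance as residual forces and moments.
Velocities and accelerations come from 2nd-order central differences
(one-sided at the edges). The 3rd-order dual-pass Butterworth filter
(default cutoff 15 Hz) applies the nominal cutoff per pass without -3 dB
compensation, mirroring common practice; `correct_cutoff = TRUE` switches
the compensation on. The filter uses odd-reflection padding, and whole
recordings are filtered before the motion of interest is extracted — IIR
edge transients otherwise dominate the residuals.

## Synthetic study conditions

The generator emulates the study's measurement setup on a reduced model: a
12-DoF body (pelvis/trunk root, two legs with hip yaw, hip pitch, knee
pitch), 14 markers at 175 Hz, two force plates at 1750 Hz, a static N-pose
trial, marker noise (2 mm per axis), a segment-coherent sinusoidal
soft-tissue artifact (5 mm at 1.5 Hz on the leg segments; the phenomenon is
documented for real data, the sinusoid is this package's model of it), and
a 12 mm shoe-sole offset of the contact points. Three tasks exist:
straight (bounce in place), curved (35 deg commanded turn) and direction
change (130 deg commanded hip-yaw stroke, yielding a 60-80 deg heading
change against planted feet).

Choices worth knowing:

- Reference motions come from a backward-Euler rollout (Newton-solved per
  step) under proportional-derivative torques toward task pose scripts plus
  scripted low-level excitations. Because the rollout uses the same
  discretization as the reconstruction, the truth satisfies the collocation
  constraints to ~1e-10 and ground-truth recovery is a well-posed check.
- Both feet stay in ground contact; there is no flight phase. A
  planted-feet pivot needs torsional grip, hence four contact points per
  foot (toe and heel pairs) and a wide hip-yaw range; the turn loses
  roughly half the commanded stroke to foot twist creep, like a shoe
  pivoting on a court.
- The standing pose stacks the legs vertically over fore-aft symmetric
  contact, so standing needs essentially no joint torque; this makes the
  static fixture the optimum of the standing calibration problem and the
  offset/pose recovery exact rather than biased by the effort terms.
- Pose scripts start and end with zero velocity and the controller keeps
  derivative gains below the delay-stability limit of the low-inertia DoFs;
  early versions without this produced impulsive or ringing accelerations
  that no smooth reconstruction should reproduce.
- 1750 Hz GRFs are evaluated from linearly interpolated states, consistent
  with backward Euler's piecewise-linear state assumption; plate centers of
  pressure and vertical free moments come from the contact model's force
  distribution.
- Trials carry 10 lead-in and 10 trailing samples around the motion of
  interest: the lead-in feeds the first-node closure, the tail keeps filter
  transients of the inverse pipeline away from the analyzed span.

What passing tests on these fixtures do **not** show: real soft tissue
artifact is broadband and pose-dependent, real running has flight phases and
impacts, real marker sets have 42 markers on more segments, and real models
have an order of magnitude more DoFs and muscles. The fixtures exercise the
algorithms, not human variability.

A deliberate property of the direction-change task: a fast pivot has high
joint accelerations, so the default regularization weight smooths the
reconstruction measurably away from the truth there (a degree-scale effect,
visible in the acceptance report as the difference between the straight-task
recovery error and the direction-change marker RMSD). The simulation acting
as a physical filter is a defining property of the method.

## Problem sizes and tolerances used by the tests

Unit tests run on trials of 60-80 nodes; the reconstruction checks use a
60-node motion of interest for dynamic consistency and recovery, and five
40-node trials for the marker-vs-coordinate comparison (the reproduction
script uses 30-node trials for the same comparison), with standing
calibrations shared across trials (the static fixture does not depend on
the motion seed). These sizes keep a full reconstruction in the tens of seconds
to about a minute on one core while preserving every property under test.
Finite-difference steps are 1e-5 (constraint Jacobian, central), 1e-6
(signal Jacobians, central); the KKT (2,2) block carries a -1e-10
regularization; equilibration floors are 1 to avoid amplifying quiet rows.

## Known limitations

- The Gauss-Newton Hessian omits constraint curvature, so the scaled dual
  error plateaus around a few 1e-4 on marker-tracking problems; dynamics
  feasibility still reaches ~1e-6. Exact Lagrangian Hessians (as
  AD-based implementations use) would converge past this.
- The solver's iteration counts on marker tracking are several times those
  of coordinate tracking, consistent with the harder nonlinearity of
  marker positions in the states.
- Muscle redundancy in the toy model is minimal (four mono-articular hip
  muscles); recruitment-level conclusions need richer muscle sets.
- C3D input is not supported; TRC and STO/MOT are the interchange formats.
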