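---
title: "Methods: forward indentation model and slope-ratio calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward indentation model and slope-ratio calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuecal)
```

This vignette documents the modelling choices behind `tissuecal`: the
constitutive law, the finite-element forward model, the slope-ratio inverse
procedure, the synthetic-data generator, and the numerical decisions that a
user extending or auditing the package should know about.

## Constitutive model

The lumped soft tissue (skin, fat and muscle homogenised into one volume
between skin surface and bone) is an isotropic, uncoupled Neo-Hookean
solid with strain-energy density

$$\Psi = C_1(\bar I_1 - 3) + \tfrac12 K (\ln J)^2 ,$$

where $\bar I_1 = J^{-2/3}\,\mathrm{tr}(F^{\mathsf T}F)$ is the first
invariant of the deviatoric right Cauchy–Green tensor and
$J = \det F$. The volumetric term is taken literally as $(\ln J)^2$ with
the natural logarithm. All quantities use a consistent MPa / mm / N
system.

Parameters:

* `c1` (MPa) — the single free coefficient. Shear modulus $\mu = 2C_1$;
  at an effective Poisson ratio of 0.5 the implied small-strain Young's
  modulus is $E = 6 C_1$ (`effective_modulus()` /
  `c1_from_modulus()` implement $C_1 = E / (4(1+\nu))$ both ways).
  The default starting value 0.01 MPa corresponds to a literature modulus
  of 0.060 MPa for limb soft tissue.
* `k` (MPa) — bulk-modulus-like penalty enforcing near-incompressibility.
  It is not fitted: it tracks `c1` through `k = k_ratio * c1`.
* `k_ratio` — default 1000. The sensitivity sweep
  (`k_ratio_sensitivity()`) shows the trade-off: at 100 the maximum
  element volume change on a phantom indentation is a few percent, at
  1000 it drops below 1% (the package's acceptance guardrail), at 10000
  below 0.3% at the cost of stiffer, slower Newton systems and a few
  percent more reaction force. Ratios far above 10⁴ invite
  ill-conditioning.
* `nu_effective` — bookkeeping value (default 0.5) used *only* in the
  modulus conversions; actual compressibility is governed by `k`.

The Cauchy stress and the spatial/material tangents are the analytic
derivatives of $\Psi$; both are verified against finite differences of the
energy in the test suite (`cauchy_stress()` to 1e-5 relative on 100 random
admissible states, the assembled stiffness likewise on small meshes).

## Forward model

`solve_indentation()` is a total-Lagrangian displacement-driven solver:

* **Elements.** 10-node quadratic tetrahedra (4-node linear supported),
  standard displacement formulation, 4-point Gauss quadrature. A mixed
  (three-field) formulation is deliberately *not* implemented: with
  quadratic tetrahedra no volumetric locking was observed in the
  verification problems, and the package instead monitors locking
  explicitly through `max_volume_change()` (the maximum of
  $|J-1|\times100$ over elements and increments). This is a major
  complexity reduction with a testable guardrail; if a use case drives
  the guardrail above ~1% at `k_ratio = 1000`, the mesh should be
  refined.
* **Contact.** Node-to-analytic-rigid-plane penalty contact against the
  flat rectangular probe face (default 50 mm × 10 mm; the physical probe
  footprint is configurable). The gap is the signed distance from a skin
  node to the face plane; the normal penalty force is
  $k_\mathrm{pen}\max(0, -g)$ with auto-penalty
  $k_\mathrm{pen} = \texttt{penalty\_scale} \cdot c_1 \cdot h$
  (`penalty_scale` default 100, $h$ the characteristic element length
  $(\bar V_e)^{1/3}$). Frictionless by construction — the contact force
  has no tangential component. The penalty weight is tapered to zero
  over the outer 10% of each footprint half-length with a cubic
  smoothstep: a hard footprint cutoff makes the residual discontinuous
  when a penetrated node slides across the rectangle edge, which
  reliably defeats Newton's method; the taper restores continuity at the
  cost of a slightly soft footprint boundary.
* **Alternative contact mode.** `prescribed_patch` moves the skin nodes
  under the footprint rigidly with the probe. The constraints are then
  material-independent, so by homogeneity of $\Psi$ in $(C_1, K)$ the
  reaction force at any increment is *exactly* linear in `c1` when
  `k = k_ratio * c1` — the property that makes the slope-ratio update a
  one-step method in the idealised case, and a cheap mode for tests.
* **Increments and Newton.** The probe advances in `n_increments` equal
  steps (default 100, i.e. 0.01 of the total displacement each).
  Each increment is solved by Newton's method with the consistent
  tangent, a backtracking line search on the residual norm (factors
  $2^0 \dots 2^{-5}$), and a trust-region-style cap of $0.2h$ on the
  largest displacement-update component — near-incompressibility makes
  plain full-step Newton diverge even at small strain increments. If an
  increment still fails (element inversion or stalled line search), the
  step is halved, down to 1/64 of an increment; beyond that the solver
  returns a partial result with `failed = TRUE` rather than an
  exception. Convergence: relative residual below `newton_tol`
  (default 1e-6) against the increment's initial residual.
* **Reaction force.** Reported as the component of the total contact (or
  patch-constraint) force along the displacement axis. Whether a
  resultant magnitude or an axial component is the right reduction is
  ambiguous in general; the component is the package's choice and the
  two coincide for probe motion along the face normal. The simulated
  curve always includes the zero state.
* **Coordinates.** Right-handed, mm. No gravity prestrain (the unloaded
  configuration is the reference), no viscoelasticity, no anisotropy,
  no layered tissue — all out of scope.

`surface_fields()` post-processes a converged increment into a von Mises
(effective) stress map (volume-weighted quadrature-average stresses of
adjacent elements, reported at skin nodes) and a contact-pressure map
(nodal normal contact force over tributary boundary area; zero outside
the active set, non-negative by construction).

## Slope-ratio calibration

`calibrate()` implements the inverse procedure:

1. Fit the experimental curve with a least-squares line through the
   origin: $s_\mathrm{exp} = \sum d_i F_i / \sum d_i^2$.
2. Simulate at the current `c1` (with `k = k_ratio * c1`). The simulated
   total displacement is sized at `sim_displacement_factor` (default
   1.5) times the experimental displacement span so that after cropping
   the full experimental window is covered; the factor is configurable
   because how much margin is needed depends on the preload.
3. `crop_align()`: drop simulated samples whose force is below the
   experimental starting (preload) force — the experimental probe was
   already in contact when recording began; re-zero displacement at the
   first retained sample; trim samples beyond the experimental span.
   If no simulated sample reaches the preload, an
   "insufficient simulated displacement" error asks for a longer
   simulation.
4. Fit the cropped simulated curve — also with a zero intercept, by
   default. Only the experimental fit is unambiguous on this point; the
   package forces the origin on both because the re-zeroing in step 3
   makes the origin physically meaningful, and the choice is switchable
   (`sim_zero_intercept = FALSE` uses an ordinary affine fit).
5. Update $C_1 \leftarrow C_1 / (s_\mathrm{sim}/s_\mathrm{exp})$ and
   repeat until $|s_\mathrm{sim}/s_\mathrm{exp} - 1| < \texttt{tol}$
   (default 0.025, the 2.5% criterion), measuring the mismatch relative
   to the experimental slope.

Why it works: for a displacement-driven FE problem with coupled
$K = \texttt{k\_ratio}\cdot C_1$, the reaction force — hence the slope —
is exactly proportional to $C_1$ when the crop threshold is zero
(homogeneity of degree one of $\Psi$), so one update solves the problem
in exact arithmetic from any starting guess. A nonzero preload couples
the crop window to $C_1$ and makes $s_\mathrm{sim}(C_1)$ mildly
nonlinear; the iteration is then a contraction near the fixed point
whenever the local elasticity of $s_\mathrm{sim}$ with respect to $C_1$
lies in $(0, 2)$, which holds comfortably for indentation-like responses
(verified numerically on the surrogate in the test suite). In practice
2–4 forward evaluations suffice, counting the final verifying one.

`calibrate_brent()` is the traditional baseline: Brent's bracketing root
finder (`stats::uniroot`) on $s_\mathrm{sim}(C_1) - s_\mathrm{exp}$ over
a default bracket $[c_1^{(0)}/20,\; 20\,c_1^{(0)}]$. Every forward
evaluation counts as one iteration, and — for comparability — the method
is credited with convergence at the first evaluation whose slope ratio
meets the same 2.5% criterion. Because the two bracket-end evaluations
can never satisfy the criterion, Brent needs at least three evaluations;
the slope-ratio method never needed more on any tested problem. The
baseline's exact tolerances and bracket are a package choice, so Brent
iteration counts are comparable only qualitatively across
implementations. `percent_difference()` uses the symmetric
(mean-denominator) definition $|a-b| / \frac{a+b}{2} \times 100$ when
comparing the two methods' fitted coefficients.

## Synthetic data

The package is testable end to end without any external dataset:

* `make_limb_phantom()` — an annular cylinder of flesh around a rigid
  bone, meshed by Kuhn subdivision of a structured cylindrical grid
  (conforming, including the circumferential seam), promoted to tet10 on
  request. Defaults (outer radius 40 mm, bone radius 19 mm) give a
  21 mm soft-tissue thickness — the scale of an adult upper-leg
  indentation site — so experimental indentation depths of roughly
  10–30% of the tissue thickness are exercisable. `bone_fixed` is the
  inner surface, `skin_surface` the outer.
* `surrogate_forward()` — the analytic stand-in
  $F(d) = c_1\,a\,(d + b\,d^2)$, exactly linear in `c1` by construction
  (mirroring the FE property) with quadratic stiffening $b$ emulating
  indentation nonlinearity. The geometry scale $a = 300$ N/(MPa·mm)
  puts slopes in the observed N/mm range for limb tissue.
* `synth_experiment()` — evaluates a forward model at a known `true_c1`,
  discards the pre-contact portion below `preload_force` (default
  0.14 N, a typical recorded starting force), re-zeroes displacement
  and adds i.i.d. Gaussian force noise. Deterministic given `seed`.

What the generator does *not* emulate: real cadaver geometry, probe
tilt and rotation during freehand motion, displacement (motion-capture)
noise, viscoelastic rate effects and layered-tissue inhomogeneity. True
measurement-noise magnitudes for instrumented-probe indentation are not
well established; the defaults (noise of ~1–2% of peak force in tests)
are placeholders and are flagged as such in the configuration. Passing
recovery tests on synthetic data therefore demonstrates correctness of
the estimation machinery, not field accuracy on real limbs.

## Verification protocols and problem sizes

* **Homogeneous oracle.** `uniaxial_response()` solves the
  one-element uniaxial problem ($\sigma_\mathrm{lat} = 0$) semi-
  analytically by scalar root finding on the package's own stress
  function — independent of the FE path. FE compression of a unit cube
  with roller symmetry planes reproduces it to solver precision
  (homogeneous states are exactly representable by the elements); the
  acceptance test asserts 1%.
* **Patch test.** Affine boundary displacements reproduce the
  homogeneous deformation and a constant volume ratio on a multi-element
  quadratic mesh to 1e-8.
* **Mesh convergence.** `mesh_convergence()` runs an identical
  indentation on a coarse→fine mesh family and reports, per mesh, the
  average percent force change against the two next-finer meshes,
  $m_i = \mathrm{mean}_{j\in\{i+1,i+2\}} |F_i-F_j|/F_i \times 100$;
  a mesh is accepted when $m_i < 5\%$. The last two rows are undefined
  (`NA`). Published presentations of this protocol do not pin down the
  averaging convention, and plausible variants differ by a few percent
  on the same forces; the formula above is the package's definition and
  the one its tests freeze. Coarser meshes respond stiffer, so reaction
  forces decrease monotonically toward the converged value.
* **Sizes.** The shipped tests and acceptance checks run phantoms of
  roughly 300–2300 quadratic tetrahedra with 5–10 displacement
  increments and cube meshes of 3×3×3 cells — sizes chosen so the whole
  suite verifies the qualitative physics (trends, guardrails,
  closed-form agreement) in minutes on one CPU. Production calibrations
  would use the default 100 increments and meshes passed through the
  convergence protocol; absolute reaction forces from cadaver-geometry
  studies are not reproducible on phantoms and are never asserted.

## Known limitations

* Penalty contact admits small interpenetration (force /
  $k_\mathrm{pen}$ per node); very soft materials with deep indentation
  may need a larger `penalty_scale`.
* The displacement formulation relies on the volume-change guardrail
  instead of a mixed formulation; `k_ratio` far beyond 10⁴ degrades
  conditioning before it improves incompressibility.
* The probe is a flat rectangle translated without rotation; curved
  probe faces and freehand tilt histories are not modelled.
* Single-parameter fitting only: the uniqueness of the fit is exactly
  what the one-coefficient model buys; multi-parameter laws (Ogden,
  Mooney–Rivlin) are out of scope.
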