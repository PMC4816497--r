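---
title: "Immersed boundary-finite element mechanics of the left ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immersed boundary-finite element mechanics of the left ventricle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cardioib` simulates the mechanics of the human left ventricle (LV) as a
fluid-structure interaction problem: a hyperelastic, orthotropic,
actively contracting muscle wall immersed in (and filled with) a viscous
incompressible fluid. This vignette is the package's account of the
model, its numerical treatment, and the judgement calls behind both.

## The coupled model

The immersed boundary (IB) formulation treats the muscle and the blood
as one incompressible continuum with density $\rho$ and viscosity
$\mu$, evolved on a fixed Cartesian grid:

$$\rho\left(\frac{\partial u}{\partial t} + u\cdot\nabla u\right)
  = -\nabla p + \mu\nabla^2 u + f^s, \qquad \nabla\cdot u = 0,$$

where $f^s$ is the Eulerian image of the structural force. The
myocardium is described on a Lagrangian tetrahedral mesh with reference
coordinates $X$, current positions $\chi(X,t)$, deformation gradient
$F = \partial\chi/\partial X$ and $J = \det F$. The weak-form
Lagrangian force density $F^s$ satisfies, for all test functions $V$
(not vanishing on the boundary),

$$\int_U F^s\cdot V\,dX = -\int_U P^s : \nabla_X V\,dX
  \;+\; \text{boundary loading terms},$$

and is exchanged with the grid through a regularized delta function:
forces are spread to the grid, and the structure moves with the
interpolated velocity field. Because $\nabla\cdot u = 0$, the structure
is incompressible in the continuum limit; a volumetric penalty (below)
reinforces this at the discrete level.

### Passive elasticity

The passive response is the orthotropic invariant-based law with
fibre ($f_0$), sheet ($s_0$) and sheet-normal material axes:

$$W = \tfrac{a}{2b}\!\left(e^{b(I_1-3)} - 1\right)
  + \sum_{i=f,s}\tfrac{a_i}{2b_i}\!\left(e^{b_i(I_{4i}^\ast-1)^2}-1\right)
  + \tfrac{a_{fs}}{2b_{fs}}\!\left(e^{b_{fs}I_{8fs}^2}-1\right),$$

with $I_{4i}^\ast = \max(I_{4i}, 1)$ so the collagen-fibre families
store energy only in extension (their derivative at $I_{4i}=1$ is taken
as zero, one-sided from below, so the stress is continuous). We write
the isotropic term shifted by its reference value so that
$W(\mathbf I) = 0$; the constant does not affect stresses. The working
first Piola-Kirchhoff stress is

$$\tilde P^p = \frac{\partial W}{\partial F}
  + \left\{-a e^{b(I_1-3)} + \beta_s \log I_3\right\} F^{-T},$$

which vanishes identically in the reference configuration. The
$\beta_s\log I_3$ term (default $\beta_s$ = 100 kPa) is a *numerical*
volumetric penalty: the Lagrangian velocity interpolant is not exactly
divergence-free, and without the penalty the element-wise $J$ drifts
until elements invert. Defaults (healthy ventricle, kPa):
$a = 0.24$, $b = 5.08$, $a_f = 1.46$, $b_f = 4.15$, $a_s = 0.87$,
$b_s = 1.6$, $a_{fs} = 0.3$, $b_{fs} = 1.3$.

Infarct heterogeneity enters through the extent-of-infarction field
$M(X)\in[0,1]$: the passive material response (including the
pressure-like reference term, but *not* the $\beta_s$ penalty, which is
a discretization device rather than a material property) scales by
$(1+49M)$ — a fully infarcted point is 50-fold stiffer — and the active
tension scales by $(1-M)$ — the core is non-contractile. In the MI
parameter preset the anisotropic moduli $a_f, a_s, a_{fs}$ are
additionally scaled by $C_a = 7.5$ throughout the wall.

### Active tension

Active stress is a rank-one fibre tension,
$P^a = J\,T\,F(f_0\otimes f_0)$, equivalently a Cauchy stress
$T\,f\otimes f$ along the deformed fibre. $T$ comes from a
cellular-scale contraction model with three stages: calcium binds
troponin with a tension-dependent off-rate; a cooperatively activated
tropomyosin gate $z$ opens toward a length-dependent half-activation;
and three fading-memory crossbridge variables modulate tension under
changing stretch (shortening reduces force, stretch transiently raises
it). The model's length dependence gives a saturated isometric tension

$$T_{max}(\lambda_f) = T_{ref}\,(1 + \beta_0(\lambda_f - 1)),
  \qquad T_{ref} = 56.2 \text{ kPa},\ \beta_0 = 4.9,$$

valid for $\lambda_f \in [0.8, 1.15]$; $\lambda_f = 1$ corresponds to
the resting sarcomere length ($\approx 2.0\,\mu$m) and
$\lambda_f = 1.15$ to the maximum ($\approx 2.3\,\mu$m). The gate is
normalized by its own fully loaded steady state $z_{max}(\lambda)$,
computed as the exact root of the gate kinetics at full troponin
loading (rather than a linearized closed form), which makes the
relation above exact under saturating calcium. With the contractility
scale $T_{scale}$ — the one free parameter adjusted during volume
matching — the healthy calibration $T_{scale} = 3.0$ yields 168.6 kPa
at the resting length and 292.5 kPa at the maximum length; the patient
calibration $T_{scale} = 5.5$ yields 309.1 and 536.3 kPa.

```{r}
library(cardioib)
isometric_steady_tension(1.00, T_scale = 3.0)  # 168.6 kPa
isometric_steady_tension(1.15, T_scale = 5.5)  # 536.3 kPa
```

Contraction is driven by a prescribed, spatially uniform calcium
transient (baseline 0.01 uM, peak 4.35 uM, 60 ms to peak). For the
steady end-systolic protocols the calcium is raised to its peak and
held; for twitch studies `isometric_twitch()` runs the full waveform.
Note that the 4.35 uM peak does not fully saturate the gate — the
printed isometric maxima above refer to saturating calcium, which is
what `isometric_steady_tension()` uses.

The contraction ODEs are integrated point-wise with exact exponential
updates for the linear (stiff) binding and fading-memory equations and
explicit Euler for the gate, substepped to at most 30 us — first-order
overall, with fixed points independent of the step size, so steady
tensions are integrator-exact.

## Synthetic anatomy

The Lagrangian anatomy is an idealized truncated-ellipsoid LV: the wall
between two prolate spheroids truncated by a basal plane, meshed by a
structured transmural-meridional-azimuthal lattice split into
tetrahedra with the Freudenthal pattern (globally conforming, also
across the azimuthal seam) and collapsed onto the axis at the apex. A
mild anti-clustering of the meridional spacing toward the apex keeps
the collapsed polar elements from degenerating into slivers. Default
desk anatomy: endocardial radius 2 cm, wall 1.1 cm, apex-to-base 6 cm,
truncation 2 cm above center — unloaded cavity 56.5 ml, wall volume
about 103 ml, consistent with a human LV early in diastole.

Fibre and sheet axes follow the rule-based construction: in the local
circumferential/longitudinal/transmural triad, the helix angle rotates
linearly from $-60^\circ$ (endocardium) to $+60^\circ$ (epicardium) and
the sheet angle from $-45^\circ$ to $+45^\circ$, as functions of the
transmural coordinate $e$. On generated meshes $e$ is the exact lattice
coordinate; on imported meshes it is approximated by the distance ratio
to the tagged endo/epi surfaces (adequate for convex walls; a harmonic
interpolant would differ only in strongly non-convex geometry).

The regional division uses seven short-axis slice planes, equally
spaced from the basal plane toward the apex, with points assigned to
the nearest plane; slices 1-5 carry six 60-degree segments (inferior
septal through anterior septal) and the two apical slices four
90-degree segments. The anterior azimuth is configurable.

The synthetic infarct is the intersection of the wall with an
apically-elongated ellipsoidal ball centred on the septal wall, sized
by bisection to a requested volume fraction (default 60%). The extent
field is $M = 1$ in the core and decays linearly with the exact
point-to-triangle distance to the core's boundary over the border-zone
thickness $\ell_{bz}$ (default 10 mm).

## Discretization and coupling

* **Grid.** Staggered MAC grid, face velocities and cell pressures,
  isotropic spacing. Desk preset: $32\times32\times40$ cells at
  $\Delta x = 15/32$ cm (a $15\times15\times18.75$ cm box); the cluster
  preset keeps $96\times96\times128$ at 0.156 cm.
* **Fluid step.** Explicit two-stage midpoint update:
  second-order upwind-biased advection, central diffusion, then an
  exact discrete projection. The pressure Poisson problem is solved by
  geometric multigrid (red-black Gauss-Seidel, full-weighting
  restriction) to an absolute tolerance that keeps the post-projection
  divergence below $10^{-9}$. Box boundaries combine zero normal
  traction with zero tangential velocity (pressure zero on the
  boundary); a periodic mode exists for solver verification.
* **Structure.** Linear tetrahedra, total-Lagrangian assembly
  $G_a = -\sum_e V_e P_e \nabla\phi_a$; endocardial pressure as a
  follower traction on the deformed surface; a basal penalty tethers
  axial and circumferential (not radial) displacement of the basal
  ring, with stiffness density $2\times10^6$ dyne/cm$^3$ per cm chosen
  so basal in-plane motion stays near 1% of the wall thickness under
  inflation.
* **Transfer.** The four-point regularized delta kernel mediates both
  directions. Forces are sampled on per-element interior barycentric
  lattices whose order is chosen so the deformed point spacing is at
  most $\Delta x/2$ (at least two points per mesh width); weights are
  equal and sum to the element volume, exact for the element-wise
  affine integrands. Velocities are delta-interpolated *at the same
  points* and projected onto the nodal basis with the lumped mass,
  making the transfer pair exactly adjoint in the discrete power
  identity. This consistency is not cosmetic: with plain nodal velocity
  interpolation the coupled scheme pumps energy and blows up at a rate
  independent of the time step.
* **Coupled step.** Midpoint scheme: positions advance half a step with
  the start-of-step velocity; all Lagrangian forces are evaluated and
  spread once, from the midpoint configuration; the fluid advances a
  full step; positions complete the step with the time-averaged
  velocity.

### Numerical choices and degenerate inputs

Time steps are stability-limited by the elastic (chiefly penalty and
active-tension) wave speeds on the smallest elements: the desk presets
use $4\times10^{-4}$ s in both phases (verified stable with margin),
while the cluster presets keep $1.22\times10^{-4}$ s (diastole) and
$3\times10^{-5}$ s (systole). Advective CFL and viscous limits are
checked every step and violations name the limiting constraint.
Non-positive $J$ anywhere aborts with the offending element. Structure
points within the kernel support of the box boundary are an error.

Two desk-scale relaxations are part of the protocol configuration and
documented here deliberately:

* **Quasi-static relaxation** (`damping`, default 35/s in desk presets,
  0 in cluster presets): an exponential bulk friction on the velocity
  field. The inflation and contraction protocols seek *static*
  equilibria; physical blood viscosity damps the post-ramp inertial
  ringing over minutes of simulated time, whereas near-critical
  friction reaches the same equilibrium in a few hundred milliseconds.
  The friction is divergence-preserving and vanishes at the
  equilibrium, which it therefore does not shift.
* **Steadiness tolerance** (`steady_eps`, desk 0.25% over 50 ms,
  cluster 0.1%): at roughly two grid cells across the wall the
  regularized interface leaks cavity volume slowly (about 2.5 ml/s
  during a pressurized hold, under 1% per thousand steps); the desk
  tolerance sits just above this floor.

Related resolution artifacts at desk scale: element-wise $|J-1|$ stays
below 5% in the bulk of the wall during inflation (95th percentile) but
reaches ~9% in boundary-layer elements; and longitudinal mechanics are
the weak direction: the end-systolic volume stays above the *unloaded*
volume against the full 150 mmHg afterload and the ventricle even
elongates slightly during ejection, so mean longitudinal strain is
positive at desk scale. (Rule-based fibre models are known to
under-predict long-axis shortening even at full resolution; the coarse
grid amplifies this.) The circumferential, radial, fibre and rotation
observables retain their physiological structure. These effects shrink
with grid refinement and are absent from the cluster-scale regime the
simulator's defaults are calibrated to emulate.

## Protocols and estimation

Diastole ramps the endocardial pressure smoothly (cosine ramp, 0.15 s)
to the end-diastolic value (8 mmHg healthy / 16 mmHg patient presets)
and holds until the cavity volume is steady; systole ramps to the
end-systolic pressure (150 / 110 mmHg) over 0.05 s while calcium rises
to its peak, and ends at the steady end-systolic state. Volume targets
are matched by bisection: `estimate_t_scale()` exploits that
end-systolic volume decreases monotonically in $T_{scale}$;
`estimate_mi_passive_scale()` scales $(a_f, a_s, a_{fs})$ jointly
against an end-diastolic volume target — a reproducible analogue of a
manually directed passive-parameter search, mirroring the structure of
the $C_a$ scaling. Both stop when the achieved volume is within 5% of
the target. Estimation is sequential: the passive scale against the
EDV first, then $T_{scale}$ against the ESV.

```{r}
bm <- build_model(default_config("desk-healthy"))
ed <- run_diastole(bm$model, bm$protocol)
fit <- estimate_t_scale(bm$model, ed, bm$protocol,
                        target_esv = 0.7 * ed$volume)
```

## Post-processing

Cavity volume applies the divergence theorem to the deformed
endocardial surface closed by its planar basal cap. Strains are
Green-Lagrange, $E = (F^TF - I)/2$, relative to the unloaded
(early-diastolic) reference configuration — the reference-state choice
matters and is stated wherever strains are reported — projected onto
the reference cylindrical frame about the long axis (circumferential,
radial, longitudinal) and onto the fibre axis. Fibre stress projects
the structural Cauchy stress $(1/J)P F^T$ onto the deformed unit fibre
direction, with an optional fluid-pressure term for coupled analyses.
Rotation is the mean azimuthal angle change of each slice between
end-diastole and end-systole. `regional_tables()` aggregates any field
as mean and SD per (slice, segment) and per longitudinal level (basal =
slices 1-2, middle = 3-5, apical = 6-7).

## What the synthetic setting does and does not show

The generator emulates the *conditions* of a subject-derived study —
wall volumes, cavity volumes, pressures, fibre architecture, a 60%
septal-apical infarct with a 10 mm border zone — on an idealized
geometry at desk resolution. Passing tests demonstrate that the
constitutive models, the coupling operators and the estimation
machinery behave correctly and reproduce the calibrated cell-level
tensions exactly; they do not demonstrate subject-specific accuracy of
strain magnitudes, which at desk resolution are compressed relative to
cluster-scale values (e.g. apical rotation ~11 degrees rather than 16,
radial thickening well below the imaging-derived 0.6). Known
limitations shared with the modelled framework: no valves, no
electrophysiological propagation (spatially uniform calcium), no
pericardium, no residual stress, rule-based rather than imaged fibres,
and a basal plane tethered in-plane.

## Problem sizes used by the tests

Unit tests run on coarse meshes (edge 1.0-0.55 cm, hundreds to a few
thousand tetrahedra) and small grids; the solver-verification decay
study uses $8^3/16^3/32^3$ periodic grids; the coupled acceptance runs
use the full desk preset (32x32x40 grid, ~4300 tetrahedra, ~150k
interaction points) — one diastole plus a handful of systoles for the
estimation study and one infarcted cycle.
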