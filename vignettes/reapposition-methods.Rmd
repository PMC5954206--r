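---
title: "Computing flap re-apposition pressures for type-B aortic dissection"
author: "reappose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing flap re-apposition pressures for type-B aortic dissection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a Stanford type-B aortic dissection the intimal layer of the aorta tears
and separates, so that a flap of inner wall divides the vessel into a true
lumen (TL) and a blood-filled false lumen (FL). Endovascular repair pushes
the flap back against the FL wall with a balloon or stent so that the
vessel regains a single lumen. The engineering question this package
addresses is: **how much radial pressure, beyond the aortic pressure, must
an expansion device exert to fully re-appose the flap?** Too little and the
FL stays patent; too much and the over-stretched wall is at risk of further
injury.

`reappose` answers this with a finite-strain contact model of the dissected
cross-section: an anisotropic hyperelastic description of the three tissue
layers (intimal flap, FL wall, TL wall), a static aortic pressure applied
to both lumens, and a rigid, displacement-driven circular expansion member
that is grown until the flap is re-apposed. The radial re-apposition
pressure is the average contact pressure on the member — the simulation
analog of the bench quantity "balloon pressure minus aortic pressure at
confirmed apposition".

## The constitutive model

Each tissue layer follows the dispersed two-fiber-family structural model
(Gasser–Ogden–Holzapfel form),

$$\Psi = C_{10}\,(I_1 - 3) \;+\; \frac{k_1}{2k_2}\sum_{i=4,6}
  \left[e^{k_2 E_i^2} - 1\right],\qquad
  E = \kappa\,(I_1-3) + (1-3\kappa)\,(I_4-1),$$

with an isotropic neo-Hookean ground matrix ($C_{10}$, Pa), two symmetric
collagen families at $\pm\alpha$ from the circumferential axis with
stiffness $k_1$ (Pa) and exponent $k_2$, and a dispersion parameter
$\kappa \in [0, 1/3]$ ($\kappa = 1/3$ is isotropic dispersion, at which
point $\alpha$ has no effect). The fiber term is active only in extension
($E > 0$). Both families share
$I_4 = \lambda_c^2\cos^2\alpha + \lambda_a^2\sin^2\alpha$ in the
circumferential–axial plane, so they enter as a single term with doubled
weight.

The package ships the measured per-pig parameter sets for the mid and
distal flap (five and four pigs) and the single TL-wall / mid-FL-wall /
distal-FL-wall set (`aorta_materials()`). Two conventions had to be fixed:

* **Fiber angle reference.** The angle is taken from the circumferential
  axis, the standard convention for this model family and the one used in
  the package formulas throughout. The alternative (axial-reference)
  reading was evaluated and rejected: it strips the mid FL wall of its
  circumferential stiffening and drives simulated re-apposition pressures
  three orders of magnitude above the tens-of-mmHg scale of the validated
  results.
* **Fit stress measure.** Planar-biaxial rigs report force per deformed
  cross-section, so the regression target is the in-plane Cauchy stress
  pair under incompressible plane stress,
  $\sigma_{cc} = \lambda_c\,\partial\hat\Psi/\partial\lambda_c$ with
  $\lambda_r = 1/(\lambda_c\lambda_a)$ eliminated.

## Parameter estimation and the synthetic-data generator

`fit_goh()` estimates $(C_{10}, k_1, k_2, \alpha, \kappa)$ by multi-start
Nelder–Mead on a smooth reparameterization (logs for the stiffness-like
parameters, scaled logistic for $\alpha$ and $\kappa$), with seeded
Latin-hypercube starting points and simplex restarts from each incumbent
optimum. On noise-free data this drives the stress residuals to machine
level; with noise, $\alpha$ and $\kappa$ are jointly weakly identified
(near $\kappa = 1/3$ the response is independent of $\alpha$, and $k_1$
trades off against both), so the reliable contract is stress-space
recovery rather than recovery of every parameter.

Because the original biaxial curves live in an unavailable appendix,
`generate_biaxial_dataset()` emulates them: three stretch-ratio protocols
(1:1, 1:0.75, 0.75:1 — a typical planar-biaxial design), fifteen stretch
levels up to 1.30 per protocol, and multiplicative Gaussian noise
$\sigma \mapsto \sigma\,(1 + cv\,z)$. Multiplicative rather than additive
noise because biaxial stresses span orders of magnitude over the stretch
range. All draws are seeded and reproducible, and the generator restores
the caller's RNG state. `generate_material_variants()` provides the seeded
±uniform parameter perturbations used as documented surrogates for the
unavailable per-sample wall variations in the sensitivity study.

## Geometry

The cross-section is an idealized annulus. Over the dissected sector
(55% of the circumference by default, within the experimental 50–60%
range) the wall is split into the intimal flap (inner) and the FL wall
(outer), meeting the undissected TL wall at the dissection ends; the two
crack faces start in zero-gap apposition. A half model with x-symmetry is
used. Quadrilateral meshes keep at least two element rows through the
flap.

The **unloaded lumen radius is not a measured quantity**. Typical porcine
descending-thoracic diameters (about 18 mm mid, 14 mm distal) describe the
pressurized vessel, and treating them as unloaded dimensions pushes the
soft distal FL wall past a ballooning limit point below 140 mmHg — far
outside the stretch range covered by the biaxial characterization. The
unloaded radii are therefore calibrated once so that the simulated
re-apposed inner diameter at 100 mmHg with the pig-1 parameter sets
reproduces the pressurized dimensions: 7.26 mm (mid) and 5.55 mm
(distal). Every result object carries this assumption as
`assumed_lumen_radius`.

## The two-step contact simulation

Step 1 (`pressurize()`) ramps a follower pressure to the static aortic
value. Both lumens are pressurized: on the bench the lumens communicate
through the entry and re-entry tears. This choice is load-bearing — if
only the TL is pressurized, the pressure pins the flap against the FL wall
throughout and the re-apposition pressure is trivially zero at every
aortic pressure. With both lumens loaded the wall dilates away from the
flap (which carries no net pressure), the characteristic gap opens, and a
genuine re-apposition pressure emerges. The TL-only mode is retained as
`pressurize_fl = FALSE`.

Step 2 (`expand_member()`) grows the rigid member incrementally,
with frictionless penalty contact on the three pairs (member–flap,
member–TL wall, flap–FL wall), until every flap outer node is within
`g_tol` (default 1% of flap thickness) of the FL wall, then refines the
termination radius by bisection to ~1 µm-scale resolution. The radial
pressure is the area-weighted mean contact pressure over the member's
contacting surface (averaging over the full member surface is available
as `avg_over = "full"`).

Numerical choices that matter:

* **Elements.** Total-Lagrangian Q1 quadrilaterals with selective reduced
  integration: matrix + fiber terms at 2×2 Gauss points, the volumetric
  penalty $U = (K/2)(J-1)^2$ with $K = 10^4 C_{10}$ at the centroid only.
  This avoids volumetric locking (the 2D counterpart of hybrid
  reduced-integration bricks) while the compressible neo-Hookean coupling
  term $-2C_{10}\ln J$ keeps the reference state stress-free. $|J-1|$ at
  the volumetric quadrature points stays below $10^{-3}$.
* **Contact.** Node-to-segment penalty with stiffness
  $100 \times 2C_{10}^{max}/h$, averaged nodal normals on the master chain
  (a continuous normal field prevents force-direction flips where the
  conforming crack discretizations coincide), and the shared crack-tip
  node excluded from the slave set.
* **Nonlinear solver.** Newton iterations on bilateral contact springs
  over an active set updated in-loop with hysteresis (tension nodes
  released, penetrating nodes added), a displacement-capped nonmonotone
  line search, and adaptive Levenberg damping of the iteration matrix for
  the snap-through phases of the slack, pressure-neutral flap. Damping
  modifies only the iteration, never the converged solution.
* **Rigid-mode control.** The half model retains a vertical translation
  mode until member contact supports it; tiny grounded springs
  ($10^{-8} C_{10}^{max}$ per node) regularize it and carry negligible
  force at convergence. The follower pressure exerts exactly zero net
  vertical force on a surface whose endpoints lie on the symmetry plane.
* **Sweep chaining.** `run_sweep()` solves the expensive slack-flap phase
  once at the lowest pressure; each later point continues from the
  previous fully-apposed equilibrium (raise pressure with the member held,
  adjust the member, re-bisect). The end state is path-independent for
  this frictionless elastic model, so chained and standalone points agree
  to the discretization's contact resolution.

## Verification

The solver is verified against closed forms on intact rings: thin-wall
pressurization reproduces the Laplace hoop stress $p\,r/t$ (deformed
geometry) within 2%, and rigid-member expansion of an unpressurized ring
reproduces the thin-wall hyperelastic pressure–radius relation within 3%.
External work matches stored strain energy within 1% along the
quasi-static path. The constitutive implementation is checked against
symbolic evaluations of the closed form and against numeric
differentiation of the energy at 100 random states per tissue row
(relative $10^{-6}$), and the plane-strain consistent tangent against
finite differences (relative $10^{-4}$).

## Problem sizes

The reference discretization is h = 0.3 mm (the mesh-convergence study
compares 0.3 mm against 0.2 mm and finds the mid-region radial pressure at
100 mmHg to change by well under 2.5%). The test suite runs its
simulation studies at a scaled problem size — h = 0.45 mm for the sweeps
(0.5 mm for the sensitivity arms) with the re-apposition tolerance at 5%
of flap thickness, commensurate with the coarser surface faceting — chosen
as a package decision so the whole suite stays lightweight; the
acceptance script under `scripts/` uses the reference sizes. At the
scaled sizes the termination state carries a contact-resolution noise of
order 0.5–1 mmHg, which can show up as sub-mmHg non-monotonicities
between adjacent 10-mmHg sweep points that are absent at the reference
discretization, and the thinnest flap row (0.29 mm) may fail to meet the
apposition criterion at all because the mesh faceting is comparable to
the gap tolerance.

## What the synthetic studies do and do not show

The synthetic biaxial data reproduce the statistical structure the fit
assumes (exact model stresses, multiplicative noise, the default protocol
family). They do not emulate specimen mounting artifacts, preconditioning,
shear protocols, or model misspecification, so parameter-recovery results
bound what is achievable under ideal conditions. In particular, at 2%
noise the $k_1$–$k_2$–$\kappa$ ridge makes $k_1$ genuinely
non-identifiable for the near-isotropic rows (the global optimum sits far
from the generating $k_1$ while matching the stresses closely); $C_{10}$
is recovered within a few percent.

## Known limitations

* The frictionless node-to-segment contact admits families of nearby
  slip-state equilibria; at the reference mesh the radial pressure at a
  given aortic pressure can vary by several percent with the continuation
  history (standalone versus chained sweeps). Sweeps therefore use one
  fixed chaining path, and differences between adjacent 10-mmHg points
  that are smaller than this resolution should not be over-interpreted.


* The cross-section (plane-strain) reduction replaces the prismatic 3D
  geometry with z-constrained ends. All reported outputs are
  cross-sectional quantities, but genuinely 3D effects (end restraint,
  axial prestretch, tapering) are absent.
* The flap's dissection-induced shortening and residual stress are not
  modeled; the reference configuration is stress-free.
* The measured parameter tables place most fiber families near the axial
  direction (under the circumferential-reference convention), which
  limits circumferential collagen engagement; together with the 2D
  reduction and the calibrated radii this makes the distal model stiffer
  relative to mid than the validated study reports, so the distal-below-
  mid ordering of radial pressures is not reproduced and the
  diameter–pressure curve flattens only weakly.
* Spiral dissections, multiple re-entries, balloon-catheter hardware and
  pulsatile loading are out of scope.

## A worked run

```{r example}
library(reappose)

flap <- aorta_materials("flap")$mid_flap_1
walls <- aorta_materials("wall")
geom <- dissection_geometry("mid", flap_thickness = flap$thickness)
mats <- list(flap = flap, fl_wall = walls$mid_fl_wall,
             tl_wall = walls$tl_wall)

res <- run_reapposition(geom, mats, p_aorta = 100)
print(res)

sweep <- run_sweep("mid", flap)
print(sweep)
plot(sweep)
```
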