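# reappose

Computational biomechanics of intimal-flap re-apposition in Stanford
type-B aortic dissection.

A dissection splits the aortic wall into a true lumen (TL) and a false
lumen (FL), separated by an intimal flap. Endovascular repair pushes the
flap back against the FL wall with a balloon or stent; the clinically
relevant quantity is the **radial re-apposition pressure** — the pressure
the device must exert *beyond* the aortic pressure to restore a single
lumen. `reappose` computes it with a finite-strain plane-strain contact
model of the dissected porcine thoracic cross-section, for static aortic
pressures of 70–140 mmHg and for the mid and distal dissection regions.

The package has three parts:

1. **Constitutive model.** The dispersed two-fiber-family
   (Gasser–Ogden–Holzapfel) strain-energy function
   `Ψ = C10 (I1 − 3) + k1/(2 k2) Σ_{i=4,6} [exp(k2 E_i²) − 1]` with
   `E = κ (I1 − 3) + (1 − 3κ)(I4 − 1)`, evaluated under incompressible
   biaxial plane stress and, for the solver, under near-incompressible
   plane strain with a consistent tangent (`goh_energy()`,
   `biaxial_cauchy_stress()`, `plane_strain_stress_tangent()`). Measured
   per-pig parameter tables for the flap and wall layers ship with the
   package (`aorta_materials()`).
2. **Parameter estimation.** `fit_goh()` recovers GOH parameters from
   planar-biaxial stress–stretch data by multi-start Nelder–Mead with a
   bounded reparameterization, returning a classed fit with the usual
   `coef`/`predict`/`residuals`/`summary`/`simulate`/`plot` methods.
   `generate_biaxial_dataset()` builds seeded synthetic biaxial datasets
   for simulation studies.
3. **Re-apposition simulation.** `run_reapposition()` meshes the
   dissected cross-section (`dissection_geometry()`,
   `build_cross_section()`), pressurizes both lumens with a follower
   load (`pressurize()`), and grows a rigid expansion member under
   frictionless penalty contact until the flap is fully re-apposed
   (`expand_member()`). `run_sweep()`, `run_sensitivity()` and
   `run_mesh_convergence()` orchestrate the pressure-ladder, wall-material
   and mesh studies; `write_vtk()` exports states for inspection.

## A worked example

```r
library(reappose)

flap  <- aorta_materials("flap")$mid_flap_1   # measured mid-region flap, pig 1
walls <- aorta_materials("wall")
geom  <- dissection_geometry("mid", flap_thickness = flap$thickness)
mats  <- list(flap = flap, fl_wall = walls$mid_fl_wall, tl_wall = walls$tl_wall)

res <- run_reapposition(geom, mats, p_aorta = 100)   # ~2 min at h = 0.3 mm
print(res)
#> Re-apposition at 100 mmHg aortic pressure
#>   radial pressure: 58.49 mmHg   member radius: 8.971 mm
#>   final inner diameter: 17.94 mm   converged: TRUE
#>   (assumed unloaded lumen radius: 7.26 mm)
```

The radial pressure (here ≈ 58 mmHg) is the average contact pressure on
the expansion member at the smallest radius that presses every flap node
onto the FL wall — the extra pressure a device must supply at 100 mmHg
aortic pressure. The final diameter is the re-apposed inner diameter; the
assumed unloaded radius is flagged because it is a calibrated model
assumption, not a measured quantity.

A full pressure ladder for one flap row (here at the lighter problem size
the test suite uses):

```r
sw <- run_sweep("mid", flap, h = 0.45, options = solver_options(g_tol = 0.05))
print(sw)
#> Re-apposition sweep: mid region, flap 'mid_flap_1' (h = 0.45 mm)
#>  p_aorta_mmhg radial_pressure_mmhg final_diameter_mm
#>            70             47.27104          16.95201
#>            80             47.96712          17.19033
#>            90             53.00337          17.56598
#>           100             56.73891          17.89418
#>           110             59.29202          18.22248
#>           120             62.46657          18.58301
#>           130             65.37186          18.94357
#>           140             70.27370          19.33307
#>   mean radial pressure 57.80 mmHg, slope 0.332 mmHg/mmHg
#>   (assumed unloaded lumen radius: 7.26 mm)
```

Radial pressure rises monotonically with aortic pressure — the central
behavior of the validated model — because a higher pressure dilates the
wall further, and re-apposing the flap onto the larger circumference
stretches it into its stiff collagen regime.

The methods vignette (`vignettes/reapposition-methods.Rmd`) documents the
model, the conventions adopted where the source data are ambiguous, the
solver design, and known limitations.

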