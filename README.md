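# lvhelix

Finite-element biomechanics of the fetal left ventricle (LV) as a function
of its myocardial **helix-angle fiber architecture**.

The myocardium is a helically wound fiber continuum: fibers run
left-handed at the epicardium, near-circumferential at mid-wall and
right-handed at the endocardium. In the fetus this architecture is still
being laid down, and which biomechanical signal guides that remodeling is an
open question. `lvhelix` operationalizes the simulation side of that
question: it parameterizes the transmural fiber field by the transmural-mean
helix angle and the epicardial-to-endocardial difference,

```
epicardial angle  = tau_bar - tau_diff / 2
endocardial angle = tau_bar + tau_diff / 2        (linear across the wall)
```

simulates cardiac cycles of idealized fetal LVs under that field, and maps
whole-chamber biomechanics over the (tau_bar, tau_diff) plane to locate the
configurations that are optimal under four criteria: maximum stroke work,
maximum volume-averaged myofiber stress, minimum deformational
strain-energy burden, and minimum transmural strain variance.

## What is inside

* **Geometry** — idealized half-prolate LV walls meshed with curved 10-node
  tetrahedra: the symmetric fetal reference (16.00 x 13.40 mm cavity, 3 mm
  wall) and volume-matched hypertrophic / long / hemisphere / wide variants
  (closed-form matching, within 2%), an asymmetric "regular" shape with a
  leaning apex, and an adult-scale prolate. Gmsh-dialect mesh I/O.
* **Fiber fields** — harmonic transmural coordinate, rule-based local
  frames with apex regularization, linear helix profiles.
* **Constitutive models** — Fung transversely isotropic passive law
  `W = C/2 (e^Q - 1)`; calcium-activation active tension
  `P_act = T0_LV Ca0^2/(Ca0^2 + ECa50(l)^2) Ct(t, l)` with the
  three-branch cosine activation clock and length-dependent relaxation.
* **FE mechanics** — total-Lagrangian quasi-static solver (RcppArmadillo
  kernels, sparse Cholesky), penalty incompressibility (det F within 1%),
  follower cavity-pressure loading with analytic volume Hessian,
  volume-constrained solves via a bordered Newton with the cavity pressure
  as the constraint multiplier, and backward-displacement unloaded-state
  recovery.
* **0D circulation** — closed-loop fetal network (elastance chambers,
  ductus arteriosus, foramen ovale, placenta, lungs; diode valves) with
  exact-by-construction blood-volume conservation and global
  resistance/compliance scale factors; couples to the FE LV once per macro
  step.
* **Analyses** — stroke work, peak myofiber stress, deformational burden,
  transmural strain variance, global circumferential/longitudinal strains,
  FE-vs-echo strain error, spline-interpolated helix maps with located
  optima, and SSIM between maps.
* **Synthetic data** — smoothed periodic volume waveforms (no isovolumetric
  plateaus; fetal EDV 2.2 ml / 400 ms and adult presets) and seeded
  synthetic echo strains, so the whole chain runs without any external data.

## Worked example

One volume-constrained cycle of the symmetric fetal LV at the
literature-average helix configuration (tau_bar = 10, tau_diff = 123), on a
reduced-resolution mesh (330 elements; drop `n_trans`/`n_long`/`n_circ` for
the >= 2500-element default):

```r
library(lvhelix)

mesh   <- generate_idealized_lv(lv_geometry_spec("symmetric"),
                                n_trans = 1, n_long = 6, n_circ = 10)
fibers <- build_fiber_field(mesh, helix_config(10, 123))
wave   <- generate_volume_waveform(waveform_spec())   # EDV 2.2, ESV 1.2 ml, 400 ms
cycle  <- run_volume_constrained_cycle(mesh, fibers, passive_params(),
                                       active_params(), wave,
                                       solver_config(steps_per_cycle = 25))
print(cycle)
#> LV cycle [volume_constrained]: 25 steps, EDV 2.200 ml, ESV 1.200 ml, SV 1.000 ml
#>   peak pressure 40.99 mmHg, stroke work 3.5530 mJ
```

The chamber tracks the prescribed waveform exactly (stroke volume
1.0 ml = EDV − ESV) and develops a physiological fetal peak pressure
(~41 mmHg; invasive fetal measurements are in the low-to-mid 40s). The four
optimality metrics of this beat:

```r
str(compute_biomech_metrics(cycle)[1:4])
#> List of 4
#>  $ stroke_work         : num 3.55      # mJ, PV-loop area
#>  $ peak_myofiber_stress: num 15        # kPa, temporal peak of wall-averaged fiber stress
#>  $ deform_burden       : num 0.0676    # kPa, |ED->ES| change of mean strain-energy density
#>  $ strain_variance     : num 9.47e-05  # fiber-strain variance, mid-ventricular slab
```

Sweeping those metrics over a (tau_bar, tau_diff) grid and locating optima
is `run_sweep()` (see `analysis/04_helix_maps.R`); the numbered scripts
under `analysis/` walk the full study: geometry family, single case,
circulation + coupled cycle, helix maps with SSIM between the two cycle
drivers, and the strain-matching analysis.

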