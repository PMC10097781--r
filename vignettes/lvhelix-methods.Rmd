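---
title: "Helix-angle biomechanics of the fetal left ventricle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helix-angle biomechanics of the fetal left ventricle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lvhelix` simulates the beating fetal left ventricle (LV) as a function of
its myocardial fiber architecture, and asks how the transmural helix-angle
configuration shapes whole-chamber biomechanics: stroke work, myofiber
stress, the strain-energy cost of deformation, and the transmural
homogeneity of fiber strain. This vignette is the package's own account of
its models, parameters, numerical choices and limitations.

## The model chain

### Geometry

Idealized LVs are half-ellipsoidal shells truncated by a flat base plane at
z = 0, apex toward negative z. The fetal reference ("symmetric") cavity is a
half prolate ellipsoid of 16.00 mm cavity length and 13.40 mm basal cavity
width with a 3 mm wall; the outer surface is the same ellipsoid with every
semi-axis grown by the wall thickness, so the wall is 3 mm thick at the
equator and at the apex. The alternative shapes deform this reference at
fixed cavity volume, solved in closed form from V = (2/3)*pi*a*b^2:
doubled wall (hypertrophic), 1.5x length with the radius solved for volume
(long), a half sphere (hemisphere), and an oblate half ellipsoid whose
length-to-radius ratio is the reciprocal arrangement of the symmetric
prolate (wide). The asymmetric "regular" shape (18.75 x 15.40 x 3 mm, a
physiological late-gestation LV) adds a medial apex lean implemented as a
smooth shear in x proportional to (z/z_apex)^2 - a unit-Jacobian map, so
wall and cavity volumes are preserved exactly. The adult variant scales the
prolate to 85 x 45 x 9 mm.

A note on volumes: the printed symmetric dimensions give a geometric cavity
volume of about 1.50 ml, while the prescribed fetal end-diastolic volume is
2.2 ml. The generator deliberately treats the printed dimensions as the
reference-state (unloaded) geometry and leaves end-diastole to the
prescribed waveform or circulation - the wall inflates to EDV during the
simulated cycle rather than being drawn at it.

Meshes are 10-node quadratic tetrahedra built from a structured parametric
grid (transmural x meridional x circumferential), extruded into prisms and
split into tetrahedra with the smallest-global-index diagonal rule, which
guarantees a conforming triangulation; midside nodes are placed through the
parametric surface map, so elements are curved and the divergence-theorem
cavity volume agrees with the closed form to well under 0.1%. The default
resolution yields at least 2500 elements; all structured counts can be
overridden, which the test suite uses to keep runtimes short.

### Fiber architecture

The helix configuration is the pair (tau_bar, tau_diff): the epicardial
fiber angle is tau_bar - tau_diff/2 and the endocardial angle
tau_bar + tau_diff/2, varying linearly across the wall,

alpha(e) = tau_bar + (e - 1/2) tau_diff,

with e the transmural coordinate (0 at the epicardium, 1 at the
endocardium). That direction convention makes the endpoint formulas a single
linear rule. e is computed as a harmonic (Laplace) field with Dirichlet data
on the two surfaces - the standard rule-based realization - and the local
frame at each quadrature point is t = -grad(e)/|grad(e)| (endo-to-epi),
l the projection of the apex-to-base axis orthogonal to t, and c = l x t.
Positive helix angles rotate the fiber from c toward l, i.e. toward a
right-handed endocardial helix. At the apex the longitudinal projection
degenerates; quadrature points inside an apex cap (default 2% of cavity
length) inherit the frame of the nearest regular point. The fiber triad is
f = cos(alpha) c + sin(alpha) l, s = t, n = f x s; the transverse angle is
fixed at zero, so f lies in the wall-tangent plane.

### Passive and active myocardium

Passive myocardium is the transversely isotropic Fung-type law

W = C/2 (exp(Q) - 1),
Q = b_ff E_ff^2 + b_xx (E_ss^2 + E_nn^2 + E_sn^2 + E_ns^2)
  + b_fx (E_fn^2 + E_nf^2 + E_fs^2 + E_sf^2),

with E the Green-Lagrange strain in the fiber frame. The exponent carries an
overflow cap (default Q <= 50) that fails loudly rather than clipping
silently, because bad Newton iterates otherwise explode the exponential.
Defaults (C = 2 kPa, b_ff = 8, b_xx = 2, b_fx = 4) are a surrogate set from
the Guccione-family cardiac literature, intended to be replaced when
subject-calibrated stiffnesses are available, and every value is a plain
argument.

Active tension acts along the fiber,

P_act = T0_LV * Ca0^2 / (Ca0^2 + ECa50(l)^2) * Ct(t, l),

with the three-branch activation clock Ct = (1 - cos omega)/2 (rise over
[0, t0), fall over [t0, t0 + t_r), zero after), relaxation duration
t_r = m*l + b, and length-dependent calcium sensitivity
ECa50 = Ca0_max / sqrt(exp(B_len (l - l0)) - 1), the formulation of the
cited calcium-activation model family. Sarcomere length is l = l_ref *
lambda_f with lambda_f the fiber stretch (the model family states the
dependence, not the formula; the linear map is the simplest consistent
choice, with l_ref configurable, default 1.85 um). Fetal timing: t0 = 140.5
ms on a 400 ms cycle; the relaxation line (m = 87.5 ms/um, b = -75 ms) is
scaled down from adult-cycle values so relaxation completes in mid-diastole,
and T0_LV defaults to 40 kPa, inside the reported fetal range of 23.9-59.2
kPa; a calibration routine adjusts T0_LV to a measured peak pressure by
monotone root finding. Below the calcium law's domain (l <= l0) the solver
uses the law's continuous limit P_act = 0 (ECa50 diverges there); the
user-facing activation functions treat it as a domain error instead, which
is the honest contract for direct evaluation.

### FE mechanics

Quasi-static, total-Lagrangian, 10-node tetrahedra with 4-point quadrature.
Incompressibility is imposed with a strong volumetric penalty
U(J) = kappa/2 (J - 1)^2 (default kappa = 2000 kPa) in a one-field
displacement formulation, rather than the two-field
displacement/pressure-multiplier formulation more common in cardiac codes.
The trade was deliberate: one field keeps the assembly and the sparse
symmetric solves simple, and at the loads of this problem (cavity pressures
below about 7 kPa, active stresses of tens of kPa) the measured det(F)
stays within 1% of unity at every quadrature point - the same tolerance a
multiplier formulation would be held to - while the thick-sphere oracle
shows the penalty does not stiffen the response (agreement within 2%, with
quadratic-tetrahedra locking not observable at these strains). The
hydrostatic pressure, when wanted, is -dU/dJ.

The cavity pressure is a follower load: the external work is p*V(u) with
V(u) the volume enclosed by the deformed endocardial surface and the basal
plane, so the load vector is p dV/du and the tangent carries the analytic
volume Hessian d2V/du2 (both surface integrals; the Hessian term is what
makes Newton quadratic here - without it the iteration stalls near
convergence). Volume-constrained solves treat p as the Lagrange multiplier
of V(u) = V_target and solve the bordered Newton system by two back-solves
per iteration, with a backtracking line search on the augmented residual
(bounded non-monotone acceptance at small steps, since strictly monotone
backtracking stalls on the sharply nonlinear activation states) and volume
substepping on failure. The cycle drivers additionally split a time step
recursively when its solve fails, ramping activation and volume together -
needed during rapid relaxation, where tension collapses within one step. Boundary conditions: basal nodes fixed
longitudinally (free in-plane), plus a weak epicardial Robin spring
(default 0.05 kPa/mm) that removes the remaining in-plane rigid modes; the
spring value is configurable since the physical analogue (surrounding
tissue) is soft and only its order of magnitude matters.

The unloaded (zero-pressure) reference is recovered from a loaded geometry
by the backward-displacement fixed point: inflate the current guess to the
end-diastolic pressure, subtract the mismatch with the target geometry, and
rebuild the fiber field on the updated guess. Each iterate inflates from
rest (warm-starting across iterates was found to destabilize Newton). Four
iterations typically reach a nodal RMS below 0.1% of the cavity radius and
round-trip the cavity volume within 0.5%.

### Circulation and cycle drivers

The closed-loop fetal circulation is a Pennati-family network: four
elastance chambers, compliant arterial/venous/organ compartments including
the ductus arteriosus, foramen ovale, lungs and placenta, and valves as
ideal diodes with small forward resistances. It is integrated as
compartment-volume ODEs (lsoda); since every flow is computed once and
enters one source and one sink, total blood volume is conserved exactly by
construction of the vector field, and the integrator drift is at rounding
level. Defaults are a documented surrogate set tuned to late-gestation
physiology (peak LV pressure about 43 mmHg, EDV about 2.2 ml, EDP about 5
mmHg, arterial 42/31 mmHg at a 400 ms cycle); the recalibration mechanism
of the model - a global resistance scale factor and a global compliance
scale factor - is exposed as `apply_scale_factors()`. Twelve cycles reach
periodic steady state (cycle-to-cycle EDV change well below 1%).

Two cycle drivers exist. The volume-constrained driver prescribes a
smoothed periodic volume waveform (no isovolumetric plateaus, emulating
echo-derived volume curves) and solves the volume-constrained FE problem at
each of the default 50 steps per cycle; the input mesh is taken as the
unloaded state at one third of the diastolic duration, the pressure
minimum, and the simulation starts and ends there. The coupled driver
warm-starts the circulation with an elastance LV, then exchanges once per
macro step: the circulation advances at the FE pressure and returns the new
LV volume; the FE solves for the new pressure (optional fixed-point
sub-iterations with relaxation guard against exchange oscillation).
Isovolumetric phases emerge from the valve diodes. The two drivers agree on
stroke work within about 10% on the same geometry and volume excursion,
the scalar analogue of the map-level agreement the package's SSIM
comparison quantifies.

### Metrics and maps

Stroke work is the shoelace area of the (V, p) loop (mmHg*ml -> mJ by
0.1333224), cross-checked against the trapezoidal time integral of p dV.
Myofiber stress is the Cauchy stress projected on the deformed, normalized
fiber direction, volume-averaged with current-volume weights; its temporal
peak is reported (a second Piola-Kirchhoff variant would be the natural
alternative; Cauchy was chosen as tension per current area). The
deformational burden is the absolute ED-to-ES change of the volume-averaged
passive strain-energy density W against the unloaded reference -
"amplitude", hence the absolute value, and passive W only, since it is the
deformation energy the law defines. Transmural strain variance is the
unweighted variance of fiber-direction Green-Lagrange strain (ES vs ED) in
a mid-ventricular slab (plane at 50% cavity length, half-width 5%). Global
strains are volume-weighted wall averages of the ES-vs-ED relative strain
projected on the push-forwarded longitudinal/circumferential directions,
and the FE-vs-echo strain error is
ER = (eps_long_FE - eps_long_echo)^2 + (eps_circ_FE - eps_circ_echo)^2 on
fractions. ED and ES are identified as the maximum- and minimum-volume
states, which is robust to waveform phase conventions.

Metric maps over (tau_bar, tau_diff) interpolate grid values with
tensor-product natural cubic splines (exact at nodes); optima are found by
multi-start bounded quasi-Newton refinement inside the grid hull with a
boundary flag when the optimum sits on the hull edge, and a flat-map guard.
The default grid is the swept range [-90, 180] degrees at 15 degree
spacing; the spacing is a user choice with a documented default, since no
canonical grid exists. SSIM between two maps uses joint min-max normalization, a 3x3
Gaussian window (sigma = 1 node, renormalized at borders) and the standard
stabilization constants; since SSIM admits many windowing conventions,
these defaults are declared here.

### Synthetic data

The waveform generator emulates temporally smoothed, echo-derived volume
curves: a raised-cosine ejection and a biphasic (E/A) raised-cosine filling
blended C1, periodic, with max exactly EDV and min exactly ESV and no
isovolumetric plateaus. Fetal defaults: EDV 2.2 ml, ESV 1.2 ml (stroke
volume about 1 ml), 400 ms cycle, ejection 40% of the cycle, A-dominant
filling (early fraction 0.45) as in fetal diastole; the adult preset is
EDV 132 ml, stroke volume 81.8 ml, 800 ms. The diastolic shape parameters
are plausible rather than fitted to any particular recording.
Synthetic "echo" strains are the true FE strains plus i.i.d. Gaussian noise
with a seed, the minimal model needed to exercise ER; real image-derived
strains carry spatially correlated, tracking-dependent errors that this
generator does not emulate, so passing the strain-matching round trip shows
the machinery recovers the generating configuration under well-behaved
noise, not that it is robust to echo artifacts.

## What the tests do and do not show

The suite verifies closed forms, conservation laws, oracle agreement
(thick-sphere inflation, RC decay, concentric-sphere Laplace), round trips
(unloaded state, mesh I/O, strain matching) and invariances (objectivity,
transverse isotropy, rotation of metrics) on reduced-resolution meshes -
typically a few hundred elements and 20 steps per cycle, against the
defaults of 2500+ elements and 50 steps. Those sizes were chosen so the
full suite runs in minutes; the quantities asserted are resolution-robust
at the stated tolerances (the cavity-volume and oracle checks are repeated
at two resolutions to confirm). What no desk-scale test shows: agreement
with patient-specific geometries and waveforms, which require the external
archive of segmented LVs; the package treats those reproductions as
optional and out of its test scope.

## Known limitations

Linear transmural helix profiles only, uniform over the wall; transverse
angle fixed at zero; no sheetlet kinematics, no orthotropy, no
viscoelasticity, no inertia; no right ventricle or pericardial contact; the
circulation has fixed topology (no shunt-closure transition, no
autoregulation); penalty incompressibility trades a hard constraint for a
stiff term, so det(F) is controlled to about 1% rather than machine
precision; and all constitutive and circulation defaults are surrogate
literature values, intended to be overridden when calibrated parameters are
available.
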