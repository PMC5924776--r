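---
title: "Methods: the cross-bridge distribution engine and the ventricle model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cross-bridge distribution engine and the ventricle model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in `myolv`, the
assumptions behind them, the numerical choices, and the places where the
design was genuinely open and a decision had to be made.  No empirical
result is stated here that the package's tests and
`scripts/acceptance.R` do not themselves compute.

## 1. The half-sarcomere engine

### State and kinetics

The cellular unit is a half-sarcomere characterised by its length
`hsl` (nm), the activated binding-site fraction `N(t)`, and the
bound-head fraction `A(x_i, t)` over 21 cross-bridge strain bins
`x_i = -10, ..., +10` nm (1 nm wide).  Myosin heads cycle between a
detached pool `D(t) = N(t) - sum_i A(x_i, t)` and the bound bins:

    dA(x_i)/dt = k1(x_i) dx D(t) - k-1(x_i) A(x_i)

with strain-dependent rates

    k1(x)  = Ck(sign x) exp(-k_cb x^2 / (2 kT))      [s^-1 nm^-1]
    k-1(x) = kd(sign x) + kdb(sign x) x^4            [s^-1]

The Boltzmann factor concentrates attachment near zero strain; the
quartic detachment term removes highly strained heads rapidly in either
direction.  `k1` is a density and is multiplied by the 1 nm bin width to
give a per-bin flux (dimensional consistency of the bin equations).

The activated-site fraction follows

    dN/dt = a_on [Ca](N_ov - N) - a_off (N - N_b)
            + k_plus N_b - k_minus (N_ov - N)

where `N_ov(hsl)` is the filament-overlap fraction, `N_b = sum A` the
bound fraction, `k_plus` recruits further sites in proportion to bound
heads (positive cooperativity), and `k_minus` de-activates in
proportion to the *inactive* pool (negative cooperativity, as the
model is stated).  Three clamps keep the bookkeeping physical:
`N >= 0`, `N >= N_b` (equivalently `D >= 0`), and `N <= max(N_ov, N_b)`.

**A structural consequence worth knowing.**  Because the `k_minus`
sink is proportional to `N_ov - N`, a rested half-sarcomere activates
only when `a_on [Ca] > k_minus`; below that calcium the clamp holds
`N = 0` exactly.  Together with the strong positive feedback
`k_plus N_b` (for the shipped rate sets `k_plus sum_i k1/k-1` exceeds
`a_off`), the steady force-calcium relation of those parameter sets is
switch-like: zero tension below the threshold (around pCa 6.1-6.2) and
a near-saturated bound fraction above it.  The Hill fits of such curves
return very large coefficients, and the steady saturated tension
(about 300-350 kPa) is far above a typical intact-muscle plateau.
These are faithful consequences of the stated equations and rate
constants; the single-element summaries the package reports should be
read with that regime in mind.  The alternative cooperativity sinks
(`coop_form = "active"` or `"unbound"` in `active_params()`) remove
the hard threshold and are provided for structural sensitivity
analysis; they do not change the saturated tension.

### Interfilamentary movement

When the half-sarcomere length changes by `dx` in a step, the bound
distribution is displaced by `dx/2` (linear interpolation onto the
fixed grid; `shift_fraction` switches to the full `dx` for sensitivity
checks).  Mass carried past either end of the grid is dropped - heads
pulled to extreme strain detach.  This carries the velocity dependence
of force: rapid shortening sweeps the distribution toward negative
strains and transiently lowers (and can sign-invert) the stress sum.

### Stress

    T = rho k_cb sum_i A(x_i) (x_i + x_ps)

with `rho = 6.9e16 m^-2`, `k_cb = 1e-3 N/m`, and the power-stroke
offset `x_ps = 5` nm.  `T` is forced to zero once the sarcomere is at
or below `sl_floor = 1200` nm.  Negative totals during rapid
shortening are permitted by default (`clamp_negative_stress` opts out),
since the distribution sum genuinely goes negative under fast sweeps
and clamping would hide that.

### Numerics

* Bound bins: classical RK4 with step-doubling error control, absolute
  tolerance `1e-8` per bin, starting from the stability limit of the
  stiffest bin (`k-1` reaches `~5e5 s^-1` at `x = +-10` nm with the
  shipped `kdb` values) and subdividing up to 1024 sub-steps.
* Activation: forward Euler at the macro step, then the clamps.
* In the ventricle solver the kinetics co-step at one quarter of the
  mechanics step (adaptively halved further if the error control
  cannot reach tolerance during rapid shifts); at 1 ms mechanics steps
  this keeps the RK4 controller inside its sub-step cap.
* `kT` defaults to body temperature (`1.381e-23 J/K x 310 K`); the
  cellular summaries are interpreted as in-vivo-temperature values.
* The overlap function is a piecewise-linear trapezoid with knots at
  600, 850, 1170, 1500 nm (configurable): zero where the stress floor
  lives, full overlap on a plateau that contains the 2300 nm-sarcomere
  protocols.

## 2. Cellular protocols

* `run_isometric()` integrates to a tension plateau (chunked
  steady-state detection on `|dT|`) at fixed length; saturating calcium
  defaults to pCa 4.5.
* `run_force_pca()` computes steady tensions over pCa 7.5-4.5 (rested
  start at each level) and fits the Hill equation by nonlinear least
  squares in log-calcium space with a free plateau amplitude (a
  bounded quasi-Newton pre-fit makes the fit robust on switch-like
  curves, then Levenberg-Marquardt polishes).
* `run_ktr()` releases the length by 20% - the shift drives all bound
  heads off the grid - holds 20 ms, restretches, and fits
  `T(t) = T_ss - (T_ss - T0) exp(-ktr t)`.  The release and restretch
  are ramped over a few macro steps (about 2 ms) so each per-step
  shift stays within the grid span; this is quasi-instantaneous
  relative to the recovery.  The "low calcium" level for the minimum
  redevelopment rate is the lowest pCa whose steady tension reaches 5%
  of the plateau (configurable), since only "low" is specified.
* `run_twitch()` drives the engine with a calcium transient; the
  unloaded variant finds, each step, the length change at which the
  active stress balances a vanishing load (velocity-capped).  The
  model contains no parallel elastic element, so an unloaded
  half-sarcomere shortens to the zero-overlap floor and does not
  re-lengthen; re-lengthening in the ventricle comes from the
  surrounding passive tissue and the prescribed filling.

## 3. Passive material and total stress

The passive myocardium is the transversely isotropic exponential law

    W = C/2 (exp(Q) - 1),
    Q = b_f E11^2 + b_t (E22^2 + E33^2 + E23^2 + E32^2)
        + b_fs (E12^2 + E21^2 + E13^2 + E31^2)

with `b_f = 18.48`, `b_t = 3.58`, `b_fs = 1.627` and `C = 0.262` kPa,
axis 1 the fiber direction.  The second Piola-Kirchhoff stress is the
analytic derivative (`S_ij = C e^Q b_ij E_ij`), verified against a
finite-difference gradient in the tests.  Near-incompressibility uses
the penalty energy `kappa/2 (J-1)^2` with `kappa = 1000` kPa by
default - a standard, testable choice that keeps the stress symmetric.
The law acts on the total strain (no isochoric split), matching the
historical implementation of this material.

Active stress enters as a Cauchy-like uniaxial stress along the
deformed fiber direction, with 25% of the fiber value along each
cross-fiber direction, pulled back to the reference configuration as
`S_act = J T sum_d c_d (d0 x d0)/lambda_d^2`.  The stress measure used
for this coupling is a documented convention, not a stated fact of the
original formulation.

## 4. The ventricle model

`build_lv_mesh()` generates an idealized truncated prolate ellipsoid
(endocardial radii 3.2 mm, long semi-axis 6.4 mm, wall 2 mm -
rat-scale), hexahedral, three transmural element sheets labelled
endo/mid/epi, eight circumferential and six longitudinal element rows,
the last row collapsing onto the apex pole (collapsed hexahedra keep
positive Jacobians at the Gauss points).  Layers carry helix angles
+60/0/-60 degrees (endo/mid/epi) and initial sarcomere lengths
1780/1850/1910 nm.  Segments are 90-degree quadrants with the septal
quadrant centred on the -x axis - an idealized mesh has no right
ventricle to anchor an anatomical convention, so this one is fixed and
documented.

`solve_cycle()` advances one millisecond at a time:

1. element fiber stretch from the last converged displacements sets
   each element's half-sarcomere length (`hsl = hsl0 lambda_f`),
2. the batched kinetics step produces the element active stresses,
3. a Newton solve finds displacements and the cavity pressure - a
   Lagrange multiplier enforcing the prescribed cavity volume
   (`V_target` integrates the flowrate with per-step Simpson
   quadrature).

The cavity volume is a divergence-theorem surface integral over the
deformed endocardium closed by a basal-cap fan; its analytic gradient
supplies both the constraint row and the (follower) pressure load, and
its analytic Hessian the load stiffness.  Elements use selective
reduced integration (volumetric penalty at the centre point) against
locking.  The element tangent is a compiled forward-difference of the
element force - consistent to ~1e-7, giving quadratic Newton
convergence.  Basal nodes move radially in the basal plane only
(normal and circumferential motion fixed), which also pins the
in-plane rigid modes; a quasi-static implicit solve replaces explicit
dynamics, since the loading is slow and the pressure-volume and strain
outputs are the quantities of interest.  Load increments that fail to
converge are substepped (volume and tension ramped together), and
Newton directions backtrack on element inversion.

The study conditions shipped as defaults: cycle period 0.17 s
(rat-scale heart rate), ejection fraction 0.6, isovolumic windows 8%
of the cycle, filling 40%, ejection 30%, diastasis the remainder; the
stroke volume is carried by sin^2 lobes so the flowrate integrates to
zero exactly.  The calcium transient is a two-exponential template
(baseline 100 nM, peak 1 uM) whose time constants are 10/50 ms at a
0.34 s reference cycle and scale with the period (at 0.17 s: 5/25 ms),
onset at the start of isovolumic contraction.  The default
end-diastolic volume for a simulation is chosen so the end-systolic
volume returns to the unloaded cavity volume (`edv = V0/(1 - ef)`),
making the prescribed loop self-consistent from an unloaded start.

What the synthetic fixtures do *not* emulate: image-derived
animal-specific geometry, regionally varying activation, the right
ventricle and pericardial constraints, and beat-to-beat variability.
Passing the cycle-property tests therefore demonstrates internal
consistency of the solver and the coupling, not agreement with any
particular animal's data.

### Post-processing

End-systolic strains are Green strains of the relative deformation
from the end-diastolic frame, rotated into local
circumferential/longitudinal/radial axes; the
circumferential-longitudinal shear angle is
`asin(2 E_cl / sqrt((1+2E_cc)(1+2E_ll)))`.  Regional summaries average
over the four quadrants of the mid-ventricular third of the mid-wall
layer; the shear angle is computed element-wise and then averaged
(`angle_of_means` switches to the alternative).  Re-lengthening onset
is the time of minimum sarcomere length searched from ejection onset
to the end of the cycle, so post-systolic shortening delays the onset
but the short lengths at the start of filling do not masquerade as
one.

## 5. Parameter estimation

The estimation procedure is a hybrid: simulated annealing (geometric
cooling with ratio 0.9, 20 proposals per stage, Gaussian proposals at
10% of each range reflected at the bounds, parameters scaled to the
unit box) locates the promising region; a sequential response-surface
method refines it.  Each response-surface iteration fits a full
quadratic surrogate by least squares to a Latin-hypercube design of
`2 d^2 + 1` points (plus the incumbent); the surrogate is fitted on a
log scale while the objective spans more than three decades across the
region - which keeps it informative far from the optimum - and on the
linear scale near the bottom, where a quadratic is exact.  The
surrogate minimiser is accepted through a short backtracking line
search from the incumbent (full steps overshoot curved narrow
valleys), and the region then contracts when the minimiser is
interior, or pans and re-expands when it sits on the boundary, letting
the search stride along nearly flat valleys.  A pure-contraction pass
and a final Nelder-Mead simplex descent polish the last digits - the
simplex stage is an addition to the annealing + response-surface
pipeline, adopted because the surrogate machinery localises the
optimum efficiently but converges slowly in its final phase, while a
simplex in a smooth basin goes to machine precision.  The whole
procedure runs a small number of independent chains (deterministic
streams derived from the master seed) and keeps the best, the standard
guard against an unlucky trajectory.  The organ-scale objective sums
squared absolute strain-component errors over all nine tensor slots at
>= 250 mid-layer points plus squared relative errors at six pressure
points.  All randomness is seeded; equal seeds reproduce trajectories
exactly.

`recover_parameters()` is the validation harness: it generates targets
from known parameters with a single-element isometric twitch forward
model, runs the hybrid on a parameter subset, and reports recovery
errors as fractions of the search ranges plus a one-at-a-time
sensitivity ranking (the calcium-activation rate dominates, consistent
with the model's structure).  Two design points matter for
identifiability.  First, the harness transient (peak 800 nM, time
constants 4/12 ms) keeps the twitch below the cooperative latch
threshold: a latched trace is nearly binary and carries almost no
parameter information.  Second, the forward trace includes two brief
release-restretch events at different activation levels: at fixed
length the deactivation rate and the cooperative recruitment act only
through one effective combination (the bound fraction sits at its
quasi-steady ratio to the detached pool), so a plain twitch cannot
separate them; emptying the bound pool at two different activation
states can.  The problem sizes used in the shipped tests - a
four-parameter recovery with a few thousand forward evaluations, and
144-element ventricle runs of two cycles - were chosen as the smallest
sizes that exercise every coupling in the pipeline.

## 6. Known limitations

* The two-state scheme has no explicit power-stroke state; the
  switch-like steady activation described in section 1 is a property
  of the stated activation equation with the shipped rate sets.
* Calcium is spatially uniform; no feedback from shortening onto the
  transient.
* The idealized ellipsoid with a fixed basal plane stiffens the base
  relative to an image-derived geometry with a free base; basal
  re-lengthening timing is sensitive to this.
* Trilinear hexahedra with a penalty formulation are adequate at the
  shipped resolutions but are not a locking-free mixed formulation.
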