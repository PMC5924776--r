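# myolv

Cardiac contraction from the half-sarcomere to the left ventricle, in R.

`myolv` implements a coupled cellular-to-organ model of systolic
contraction for computational cardiac mechanics: a two-state
cross-bridge *distribution* model of the half-sarcomere — calcium
activation with cooperative feedback, strain-dependent attachment and
detachment over 21 cross-bridge strain bins, and displacement of the
bound distribution by filament sliding (velocity dependence) — embedded
as the active stress law in a quasi-static hexahedral finite-element
model of an idealized left ventricle with a Guccione passive law,
driven through full cardiac cycles by a prescribed volumetric flowrate.
It is aimed at researchers in myofilament biophysics and ventricular
mechanics who want a transparent, scriptable implementation of this
model class.

## The model in brief

At each material point the bound-head distribution `A(x_i, t)` over
strain bins `x_i = -10..10` nm obeys

    dA(x_i)/dt = k1(x_i) Δx D(t) − k−1(x_i) A(x_i, t)
    k1(x)  = C_k exp(−k_cb x² / 2kT),   k−1(x) = k_d + k_db x⁴
    D(t)   = N(t) − Σ_i A(x_i, t)

with the activated-site fraction

    dN/dt = a_on [Ca](N_ov − N) − a_off (N − N_b) + k_plus N_b − k_minus (N_ov − N)

clamped so that `N ≥ N_b ≥ 0`. Length changes displace `A` by half the
half-sarcomere length change (linear interpolation; off-grid mass
detaches), and the fiber stress is

    T = ρ k_cb Σ_i A(x_i)(x_i + x_ps),

zero below a sarcomere length of 1.20 µm. The ventricle adds this `T`
(plus 25% in each cross-fiber direction) to the transversely isotropic
exponential passive stress `W = C/2 (e^Q − 1)` and solves quasi-static
equilibrium with the cavity pressure as the Lagrange multiplier of the
prescribed cavity volume. A hybrid simulated-annealing +
sequential-response-surface optimizer estimates the ten contractile
rate constants from strain and pressure targets.

See `vignettes/myolv-methods.Rmd` for the full account, including the
numerical schemes and the design decisions.

## Worked example

Single-element protocols for the first optimized rate-constant set:

```r
library(myolv)
p <- optimized_cases(1)
run_isometric(p)
#> isometric protocol: SL 2300 nm, [Ca] 3.16e+04 nM
#>   plateau tension 352.59 kPa (converged)
run_force_pca(p)
#> force-pCa protocol at SL 2300 nm (13 levels)
#>   plateau 352.59 kPa, pCa50 = 6.113, Hill n = 50.845
```

The plateau tension is the steady isometric stress at saturating
calcium (pCa 4.5) and a sarcomere length of 2300 nm; `pCa50` and the
Hill coefficient summarise the steady force–calcium curve. With these
published rate constants the curve is switch-like (the cooperative
feedback saturates the bound fraction above an activation threshold
near pCa 6.1), which is why the fitted Hill coefficient is large — see
the methods vignette, section 1, for the analysis.

A full cardiac cycle of the idealized rat-scale ventricle:

```r
m     <- build_lv_mesh()                                   # 144 hexahedra
drive <- make_flowrate(period = 0.17, edv = cavity_volume(m) / 0.4, ef = 0.6)
ca    <- make_calcium(period = 0.17, peak = 1000, baseline = 100,
                      onset = drive$phases$start[2])        # IVC start
cyc   <- solve_cycle(m, drive, ca, passive_params(), optimized_cases(1))
plot(cyc, "pv")                                             # PV loop
relengthening_onset(cyc)                                    # per-element timing
```

Configuration files (see
`inst/extdata/example-config.yaml`) load with `read_config()`;
`fit_contraction()` / `recover_parameters()` run the parameter
estimation, and `write_vtk()` exports meshes and fields for ParaView.

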