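# piezodome

Membrane-mechanics model of the **membrane footprint** of the Piezo ion
channel, and of its consequences for mechanosensitive gating.

Piezo1 curves the lipid bilayer around it into a dome (spherical cap, area
390 nm², closed-state radius of curvature 10.2 nm). Because the surrounding
membrane attaches smoothly to the dome, the channel also deforms the
bilayer *outside* its own perimeter. `piezodome` computes the
minimum-energy shape of that deformation under Helfrich elasticity,

```
GM = (Kb/2) ∫ (c1 + c2)² dA  +  γ ΔA ,
```

with bending modulus `Kb`, tension `γ`, principal curvatures `c1, c2`, and
in-plane area decrease `ΔA` — both in the small-gradient (Monge)
approximation, `h(r) = C·K0(r/λ)` with decay length `λ = √(Kb/γ)`, and by a
full nonlinear arclength shape-equation solver valid at the large slopes of
a highly curved dome, for infinite membranes and finite clamped
compartments. Combining the footprint energy with the dome terms
(`G = GDP + GDb + GDγ + GM`) and a two-state Boltzmann equilibrium
`Po/(1−Po) = exp(−ΔG/kBT)` yields tension-dependent gating energies,
activation curves and tension sensitivities.

The package is aimed at membrane biophysicists and channel physiologists
who want quantitative footprint energetics for curved inclusions without
writing a shape-equation solver themselves.

## Worked example

The closed Piezo dome under a modest physiological tension
(γ = 0.1 kBT/nm² ≈ 0.41 mN/m):

```r
library(piezodome)

cap <- cap_geometry(10.2, 390)    # closed Piezo dome
cap
#> <cap_geometry> R = 10.2 nm, area = 390 nm^2
#>   alpha = 1.1556 rad (66.2 deg), r0 = 9.3332 nm, height = 6.0853 nm
#>   projected area = 273.66 nm^2, excess area = 116.34 nm^2

fp <- solve_footprint(cap, membrane_spec(20, 0.1))
fp
#> <footprint_profile> arclength-relaxation (infinite membrane)
#>   R = 10.2 nm, A = 390 nm^2, Kb = 20 kBT, gamma = 0.1 kBT/nm^2
#>   GM = 30.19 kBT (bending 8.916 + tension 21.28), excess area 212.8 nm^2
```

The dome stores 116 nm² of excess area, and its footprint — which reaches
several decay lengths (λ = 14 nm here) beyond the 9.3 nm contact radius —
another 213 nm², at an energetic cost of 30 kBT. `autoplot(fp)` draws the
cross-section; `tidy(fp)` returns the profile as a tibble.

Gating, with the protein offset calibrated so the channel gates at
γ½ = 0.05 kBT/nm²:

```r
sc <- gating_scenario(cap, cap_flat(390), membrane_spec(20))
sc$delta_gdp <- calibrate_delta_gdp(sc, gamma_half = 0.05)   # 174.1 kBT
gating_curve(sc, c(0.02, 0.05, 0.08), models = "with_footprint")
#>   gamma model          d_gdb d_gdgamma  d_gm      d_g      po d_dg_dgamma
#>    0.02 with_footprint -150.     -2.33  -9.16  1.26e+1 3.21e-6       -471.
#>    0.05 with_footprint -150.     -5.82 -18.3  -1.07e-14    0.5        -386.
#>    0.08 with_footprint -150.     -9.31 -25.8  -1.09e+1     1.0        -347.
```

At the midpoint the footprint term (−18.3 kBT) is three times the dome's
own tension term (−5.8 kBT): most of the tension sensitivity of this
channel comes from membrane it does not even occupy. Comparing against
`models = "dome_only"` shows the footprint left-shifting and steepening the
activation curve.

A command-line front end wraps the same functions:

```sh
exec/piezodome geometry  --R 10.2 --A 390 --out geometry.csv
exec/piezodome footprint --R 10.2,15.3,20.4 --gamma 0.1 --out energies.csv
exec/piezodome gating    --Rc 10.2 --Ro flat --gamma 0.02,0.05,0.08 \
                         --calibrate 0.05 --out gating.csv
```

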