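---
title: "The membrane footprint of the Piezo dome: model, solvers, and gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The membrane footprint of the Piezo dome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(piezodome)
```

## The physical model

Piezo1 is a trimeric mechanosensitive ion channel whose transmembrane arms
do not lie in a plane: embedded in a lipid bilayer, the channel curves the
surrounding membrane locally into a dome projecting into the cell.
`piezodome` models the energetics of this membrane–protein system with
three ingredients.

**The dome.** The mid-bilayer surface of the channel plus its enclosed
lipids is idealized as a spherical cap of fixed area $A = 390\,\mathrm{nm^2}$
and radius of curvature $R$ ($R_c = 10.2\,\mathrm{nm}$ in the closed
conformation). All contact-line quantities follow in closed form
(`cap_geometry()`): the cap half-angle $\alpha$ from
$A = 2\pi R^2(1-\cos\alpha)$, the contact radius $r_0 = R\sin\alpha$, and
the excess area $\Delta A = A - \pi r_0^2$, the in-plane area the dome gives
up by being curved. We treat $A$ as exactly conserved between conformations
and expose it as a parameter; a flat open state is a dedicated type
(`cap_flat()`) with all membrane terms identically zero rather than a
large-$R$ numerical limit. Caps are restricted to $\alpha \le \pi/2$: the
closed state sits at $\alpha \approx 66^\circ$, safely sub-hemispherical,
and beyond the hemisphere the contact-line geometry ceases to be
single-valued, so such inputs are rejected rather than silently mishandled.

**The membrane.** The surrounding bilayer is a Helfrich surface with
bending modulus $K_b$ (default $20\,k_BT$, typical of phosphatidylcholine
bilayers) under lateral tension $\gamma$. The deformation energy of the
*membrane footprint* — the deformed annulus outside the dome perimeter — is

$$G_M = \tfrac{1}{2} K_b \int (c_1 + c_2)^2\, dA \; + \; \gamma\, \Delta A_M ,$$

with $c_{1,2}$ the principal curvatures of the mid-bilayer surface and
$\Delta A_M$ the decrease of in-plane area relative to the flat state.
Gaussian-curvature and spontaneous-curvature contributions are omitted: the
former is a boundary constant by Gauss–Bonnet at fixed topology, the latter
assumes symmetric lipid compositions. All internal units are $k_BT$ and nm,
so the mechanics is free of physical constants; the only conversion,
$1\,k_BT/\mathrm{nm^2} = 4.114\,\mathrm{mN/m}$ at 298 K, lives at the I/O
boundary and uses the exact SI Boltzmann constant.

**Gating.** The total energy of a conformation is
$G = G_{DP} + G_{Db} + G_{D\gamma} + G_M$: an unknown protein term, the dome
bending energy $G_{Db} = 2 K_b A / R^2$ (about $2.4\pi K_b$ for the closed
dome), the tension work $G_{D\gamma} = \gamma \Delta A$, and the footprint
term. Differencing open minus closed gives the gating energy
$\Delta G(\gamma)$, and a two-state Boltzmann equilibrium
$P_o/(1-P_o) = e^{-\Delta G/k_BT}$ gives the activation curve.

## Solving for the footprint shape

The minimum-energy footprint solves the Euler–Lagrange (shape) equation of
$G_M$. The package implements the two classical routes and uses each as a
check on the other.

### Small-gradient (Monge) solution

For small membrane slopes the shape equation linearizes to
$K_b \nabla^4 h = \gamma \nabla^2 h$ for the height $h(r)$. The unique
axisymmetric solution that is bounded, decays to a flat far field, and
carries no net vertical force (a free-floating dome exerts none) is

$$h(r) = C\, K_0(r/\lambda), \qquad \lambda = \sqrt{K_b/\gamma},$$

the modified Bessel function of the second kind; the constant and
logarithmic/$I_0$ modes are excluded by boundedness, far-field flatness,
and the force-free condition. $\lambda$ is the characteristic decay length
of membrane shape deformations — 14 nm at $K_b = 20\,k_BT$,
$\gamma = 0.1\,k_BT/\mathrm{nm^2}$, larger than the channel itself. The
amplitude follows from slope matching at the rim. We match
$|h'(r_0)| = \tan\alpha$, the true meridional slope $dh/dr$ of the cap;
matching $\sin\alpha$ (the slope against arclength) is exposed as an option
because either convention is defensible within the small-gradient error.
Whenever the matched slope exceeds 0.3 the solution is flagged: the closed
Piezo dome has $\tan\alpha \approx 2.27$, far outside the linear regime,
which is precisely why the nonlinear solver below is the authoritative
engine. The energy is evaluated by adaptive quadrature on
$[r_0, r_0 + 20\lambda]$ at $10^{-10}$ relative tolerance; the exponential
tail beyond is negligible.

### Nonlinear arclength solution

At large slopes the surface is parametrized by its tangent angle $\psi(s)$
against arclength $s$ along the meridian, with $r' = \cos\psi$,
$h' = -\sin\psi$ (heights positive toward the cell interior, the side the
dome bulges into, and gauged to zero at the flat far field),
$c_1 = \psi'$, $c_2 = \sin\psi/r$. The stationarity condition is the
axisymmetric Helfrich shape equation at zero pressure and zero spontaneous
curvature,

$$\nabla^2 H = \frac{\gamma}{K_b} H - 2H\,(H^2 - K),$$

with $H$ the mean and $K$ the Gaussian curvature and $\nabla^2$ the surface
Laplacian $H'' + (\cos\psi/r) H'$.

**Infinite membranes.** The first-order system in $(r, \psi, H, H')$ is
solved by damped-Newton relaxation on a trapezoidal collocation mesh with an
analytic block Jacobian and sparse LU factorization. Working in
tension-scaled variables ($s/\lambda$, $r/\lambda$, $H\lambda$) makes the
problem depend only on $r_0/\lambda$ and $\alpha$, so a single continuation
in $r_0/\lambda$ (halving steps, warm-started) reaches the stiff low-tension
regime; a secondary continuation in the contact angle is the fallback if the
initial guess fails. Boundary conditions are smooth attachment at the rim
($\psi(0)=\alpha$, $r(0)=r_0$) and asymptotic flatness ($\psi = 0$, $H = 0$)
at a cutoff $s_{\max} = \max(12\lambda,\, 5 r_0)$; the cutoff error enters
as the squared tail amplitude, $\sim e^{-2 s_{\max}/\lambda}$, far below the
$10^{-10}$ residual tolerance, and doubling the cutoff changes $G_M$ by less
than 0.1%. The mesh (600 intervals by default) is geometrically graded with
inner scale $\min(r_0/\lambda, 1)$ so that the catenoid-like neck region is
resolved even when $\lambda \gg r_0$. The height decouples and is recovered
by quadrature afterwards. The discrete residual of the converged iterate is
reported in the diagnostics and is typically at machine level.

The choice of relaxation over shooting is deliberate: the linearized
operator has a growing $e^{+s/\lambda}$ mode that amplifies shooting errors
by $e^{s_{\max}/\lambda} \sim e^{12}$, while the global Newton system is
well conditioned. Correctness is established by residual checks and by
cross-validation rather than by comparison with any particular reference
scheme: in the small-slope regime ($R = 100$ nm) the arclength and Monge
energies agree to better than 1%, and at high curvature the Monge energy
bounds the arclength energy from above, the documented bias of the
linearization.

**Finite compartments.** Real membranes are corralled by cytoskeletal
attachments at spacings of tens of nm. A compartment clamps the membrane to
planarity at an unconstrained arc length $L$ beyond the dome rim
(diameter $S \approx 2(r_0 + L)$, i.e. $S \approx 30$ and $40$ nm for
$L = 5$ and $10$ nm). Here the energy functional is minimized directly over
tangent-angle profiles on a uniform mesh with hard endpoint constraints
$\psi(0)=\alpha$, $\psi(L)=0$ (L-BFGS-B, multistart with a recorded seed,
lowest-energy candidate returned). Direct minimization is preferred to a
boundary-value solve here because only the rim constraints are physically
prescribed; the remaining natural boundary conditions then emerge from the
variational principle instead of being guessed. Since the dome's vertical
position is free and the energy depends only on $\psi(s)$, pinning the rim
height in addition to the rim slope is a pure gauge fixing — the
"clamped" and "slope-only" variants coincide identically in this
parametrization, which is why no separate option exists. The two engines
agree: a compartment of $L \approx 10\lambda$ reproduces the
infinite-membrane energy to within 2%.

**Zero tension and the catenoid.** On an infinite membrane, $\gamma \to 0$
makes the footprint approach a catenoid, the minimal surface with
$c_1 + c_2 = 0$ everywhere and first integral $r\sin\psi = r_0\sin\alpha$
($\approx 8.54$ nm for the closed dome). Its bending integrand vanishes
identically, so $G_M \to 0$ even though the membrane remains strongly
curved — the physical origin of the diverging tension sensitivity at low
tension. Exactly zero tension is refused for the infinite problem (no
finite-energy minimizer with a flat far field exists; thermal fluctuations
would in any case forbid it) and `catenoid_reference()` provides the
analytic limit instead; inside a compartment $\gamma = 0$ is admissible and
costs pure bending energy, because the planarity clamp frustrates the
catenoid.

### Numerical cross-checks worth knowing about

The envelope identity $dG_M/d\gamma = \Delta A_M$ (differentiating the
minimized energy with respect to tension at the minimizer) holds to a few
parts in $10^5$ on the default mesh and is the package's sharpest internal
consistency check — it is sensitive to any error in the shape equation, the
boundary conditions, or the quadrature, and the tension sensitivities of
gating are computed through it. Bending-energy scale invariance
(lengths $\times k$, $\gamma / k^2$ at fixed $K_b$ leaves $G_M$ unchanged)
holds to $10^{-6}$.

## Gating energetics

`gating_scenario()` pairs a closed and an open cap with a membrane and a
protein offset $\Delta G_{DP}$. Because $\Delta G_{DP}$ is unknown — and
therefore the absolute gating tension is *not* a model prediction — the
package calibrates it from a user-chosen midpoint tension
(`calibrate_delta_gdp()`); the offset enters additively, so the calibration
is exact rather than iterative. What *is* predicted, and what the tests
assert, is the differential effect of the footprint: it shifts the
activation curve toward smaller tensions, steepens it, makes the tension
sensitivity $|d\Delta G/d\gamma|$ grow without bound as $\gamma \to 0$
(the dome-only sensitivity is the constant $\Delta(\Delta A)$), couples the
midpoint to the bending modulus $K_b$, and is suppressed by small membrane
compartments most strongly at low tension, where $\lambda$ is large and the
footprint no longer fits the corral. Open probabilities are evaluated in
the log domain (`plogis`), stable for $|\Delta G|$ of hundreds of $k_BT$.

```{r gating-example, eval = FALSE}
sc <- gating_scenario(cap_geometry(10.2), cap_flat(), membrane_spec(20))
sc$delta_gdp <- calibrate_delta_gdp(sc, gamma_half = 0.05)
curve <- gating_curve(sc, seq(0.01, 0.12, by = 0.005))
autoplot(curve)                      # Po, with vs without footprint
autoplot(curve, "sensitivity")
```

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| dome area $A$ | nm² | 390 | measured closed-dome area; held constant across conformations |
| closed radius $R_c$ | nm | 10.2 | measured closed-conformation curvature |
| bending modulus $K_b$ | $k_BT$ | 20 | typical PC bilayer; varied 10–40 to probe lipid-composition effects |
| tension $\gamma$ | $k_BT$/nm² | — | 0.1 is a modest physiological value; lysis near 3.5 |
| compartment $L$ | nm | ∞ | 5–10 nm mimics cytoskeletal corrals of 30–40 nm diameter |
| mesh intervals | — | 600 (infinite), 80 (finite) | energies converged to ≲$10^{-4}$ relative; residuals at machine level |

The test suite runs the solvers at 300/60 intervals, where single solves
take tens of milliseconds and all asserted tolerances retain an order of
magnitude of margin.

## Limitations

The dome is a perfect spherical cap: deviations of the real channel
geometry change footprint energetics quantitatively, not the mechanism.
Only axisymmetric shapes are considered; no thermal fluctuations, no
Gaussian or spontaneous curvature terms, no protein flexing,
no channel–channel interactions, and a deliberately minimal two-state
gating scheme — inactivation, voltage dependence, and tether forces are out
of scope. Tensions are uniform and externally imposed. The compartment
model clamps slope and height at a sharp rim; real cytoskeletal
attachments are softer constraints, so the computed compartment effects are
upper bounds of a sort.
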