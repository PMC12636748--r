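---
title: "Modeling embedded air printing in yield-stress support baths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling embedded air printing in yield-stress support baths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(airprint)
```

## The problem

Embedded air printing deposits air — rather than a material ink — inside a
yield-stress support bath: a nozzle translates through the gel while exuding
air behind it. Whether the deposited air survives as a continuous channel or
breaks into discrete bubbles is decided by a competition between surface
tension, which wants to minimize interfacial area, and the bath's yield
stress, which can arrest non-spherical shapes indefinitely. `airprint`
implements a two-dimensional computational model of this process: a
Cahn–Hilliard diffuse interface for the air/gel order parameter coupled to
incompressible variable-viscosity creeping flow with a regularized
Herschel–Bulkley constitutive law, plus the shape metrics, closed-form
printing theory and printability classifiers that surround it.

## Constitutive model

The gel is an incompressible Herschel–Bulkley fluid,
$\tau = \tau_y + K\dot\gamma^n$ above yield. The stress singularity at
$\dot\gamma = 0$ is removed by Papanastasiou exponential regularization,

$$\mu(\dot\gamma) \;=\; K\dot\gamma^{\,n-1} \;+\;
  \frac{\tau_y}{\dot\gamma}\bigl(1 - e^{-m\dot\gamma}\bigr),$$

so the unyielded material behaves as a very viscous fluid with plateau
viscosity $\tau_y m$ (plus the power-law term). The default regularization
time scale is $m = 1000$ s; the zero-shear divergence of the power-law term
for $n<1$ is capped at $\mu_{\max} = 10^6$ Pa s. Both are configurable in
`hb_params()`. Air is Newtonian ($\mu_{air} = 1.8\times10^{-5}$ Pa s).

The choice of $m$ matters quantitatively in the scenarios: the plateau
viscosity sets how fast "solid" gel creeps. For the bath to hold features in
place over a simulated second, the plateau only needs to exceed roughly
$10^3$ Pa s; the default $m$ gives $10^5$ Pa s for a 100 Pa yield stress,
comfortable margin without conditioning trouble (the viscous solve is a
sparse direct factorization, insensitive to contrast).

A dedicated 1D solver, `channel_flow_profile()`, integrates the same law in
a pressure-driven channel by damped Picard iteration on a finite-volume
tridiagonal system; for $n = 1$ it reproduces the classical Bingham plug
profile, which is one of the package's validation anchors.

## Phase-field model

The air/gel interface is carried by a conserved order parameter
$\phi \in [-1, 1]$ (air $+1$, gel $-1$) with volume fractions
$(1 \pm \phi)/2$ and Cahn–Hilliard dynamics

$$\partial_t \phi + \nabla\cdot(u\,\phi) =
  \nabla\cdot\bigl(M\,\nabla\psi\bigr), \qquad
  \psi = -\nabla\cdot(\epsilon_{pf}^2\nabla\phi) + (\phi^2-1)\phi,$$

with capillary width $\epsilon_{pf}$ and mobility
$M = \chi\,\lambda/\epsilon_{pf}^2$. The mixing energy density is
calibrated to the physical surface tension by the sharp-interface relation
$\lambda = (3/\sqrt 8)\,\sigma\,\epsilon_{pf}$; the package validates this
by measuring the line tension of a relaxed planar interface (it matches
$\sigma$ to about 1%) and the equilibrium profile width
($\sqrt2\,\epsilon_{pf}$ to within 5%).

Two symbols deserve comment. In the source formulation of this model family
the mobility prefactor is written as a product of a "tuning parameter" and
$\lambda/\epsilon_{pf}^2$; the tuning parameter is sometimes denoted by the
same letter as surface tension, which is dimensionally untenable inside a
mobility. `airprint` keeps them separate: `sigma` (N/m) enters the energy
calibration and the capillary force; `chi_mob` (m^3 s/kg) tunes the
mobility. Scenario constructors choose
$\chi = v\,\epsilon_{pf}^3/\lambda$ (equivalently $M = v\,\epsilon_{pf}$
with $v$ the characteristic speed), which keeps interfacial relaxation in
step with advection — the standard interface-Peclet compromise: much larger
and the interface over-coarsens small features; much smaller and advection
shreds the profile.

The time stepper is a linearly stabilized semi-implicit spectral scheme
(stabilization constant 2, biharmonic term implicit), so the stiff
interfacial terms impose no step restriction; only the advective CFL limit
is enforced, with an error that names the admissible step. On periodic
grids the k = 0 mode is untouched by transport, which conserves total
$\phi$ to machine precision; closed (no-flux) boundaries are realized by an
even mirror extension (cosine basis), which conserves equally well. $\phi$
is never clamped during evolution; clamping happens only inside
`volume_fractions()`.

Finite interface thickness has one consequence the tests account for: a
small body of radius $R$ in a large domain slowly loses area to the bulk
(the finite-Cahn-number analogue of Ostwald dissolution), at a rate
controlled by $\epsilon_{pf}\kappa$ and the mobility. The scenario defaults
resolve deposited features by at least 8–10 cells and keep runs to a few
passage times so this leak stays within a few percent; the
deposition-slice sweep uses a finer grid (192 cells across 6 nozzle
diameters) for the same reason.

## Flow solver

Momentum is solved on a periodic staggered (MAC) grid with an incremental
pressure-correction projection:

1. implicit variable-viscosity viscous step per velocity component,
   $(\rho/\Delta t + \rho\beta\chi_{mask} - \nabla\cdot\mu\nabla)u^* = rhs$,
   assembled as a sparse SPD matrix and solved by CHOLMOD Cholesky
   factorization (refactored on a configurable cadence, with the viscosity
   field Picard-lagged in between);
2. FFT Poisson projection using the discrete five-point symbol, which makes
   the discrete divergence match the prescribed injection source to
   machine precision;
3. the zero-total-flux gauge: the k = 0 velocity mode is removed each step.
   A periodic box has no walls, so the net force of a penalized moving
   nozzle would otherwise accelerate the whole bath; the gauge represents a
   bath anchored by distant walls.

The component-wise $\nabla\cdot(\mu\nabla u_i)$ form (rather than the full
symmetric stress divergence) keeps the operator SPD per component; the
difference term is localized at the diffuse interface and is absorbed into
the model's interface-thickness error budget. Inertia is retained as an
option but the scenarios run in Stokes mode: at these scales the Reynolds
number is of order $10^{-5}$, and the scheme's steady states satisfy the
variable-viscosity Stokes system exactly, so time stepping doubles as a
robust relaxation iteration. Density is uniform in the solver (creeping
flow, gravity off by default — printed bubbles are drag-stabilized;
buoyancy can be switched on through `flow_control(gravity=)`).

Surface tension enters as the potential-form continuum surface force
$f = (\lambda/\epsilon_{pf}^2)\,\psi\,\nabla\phi$ evaluated on the faces,
discretely balanced against the pressure gradient; a static bubble
reproduces the 2D Laplace jump $\sigma/R$ to a few percent with spurious
currents in the $\mu$m/s range.

The nozzle is a Brinkman-penalized moving mask (implicit diagonal term, so
the penalization can be stiff), with air injected in a kernel behind the
mask:

* the conversion source turns gel into air at a rate whose integral is
  exactly twice the 2D area rate (air fraction bookkeeping is exact by
  construction — the source is rescaled each step against the computable
  $\sum\phi\,\nabla\cdot u$ budget);
* a matching divergence source supplies the displaced volume, balanced by
  a uniform compensation across the box;
* the deposition kernel is elongated backward along the air jet and
  weighted toward gel-occupied cells, so fresh air lands at the trailing
  end of the deposit instead of chasing the nozzle, and a soft Brinkman
  drive gives the exuded air its backward dispense momentum.

A short lead-in (default 4 nozzle diameters) precedes the measured path in
`simulate_print()`: the deposition takes a few diameters of travel to reach
its traveling steady state, and channel metrics are evaluated inside the
measured window only.

Two further ingredients close the loop between the model and the printing
regimes:

* **Dispensing noise.** The air supply rate is modulated by a seeded AR(1)
  fluctuation (default relative amplitude 0.2, correlation time one nozzle
  passage), emulating the flow-rate fluctuations of a real dispenser. This
  is the seed for the capillary dynamics: in a weak bath the ripples are
  amplified by transverse-capillary drainage until the deposit pinches
  into bubbles, while a yield-stress bath freezes them into a small width
  CV. Everything is reproducible from the job's seed.
* **The zero-total-flux gauge.** A periodic box has no walls; the net
  force of a penalized moving nozzle would accelerate the whole bath
  (k = 0 mode), which no viscosity damps. Removing the mean velocity each
  step represents a bath anchored by distant walls, and is essential for
  the deposit to be laid down rather than entrained.

The regime split follows the process conditions it does in practice:
bubbles print in weak baths at slow nozzle speeds (order 100 mm/min),
where capillary drainage of the deposit outruns the nozzle and the supply
drips; channels print at tens of mm/s where deposition outruns
capillarity or the yield stress arrests it. The bundled dichotomy checks
use exactly those two operating points.

## Printing theory and regimes

Three closed-form quantities organize the scenarios:

* printability number $PN = \dfrac{Q/(\pi d^2/4)}{v}$ — dispense speed
  over nozzle speed;
* theoretical channel diameter $D = \sqrt{4Q/(\pi v)} = d\sqrt{PN}$ —
  volume conservation for an inflated cylinder;
* plastocapillary number $Y = \tau_y R/\sigma$ — yield stress against the
  capillary stress at radius $R$. Channels are predicted stable for
  $Y \ge Y_{crit}$, with $Y_{crit} = 0.1$ by default (an
  order-of-magnitude plastocapillary threshold, configurable; the radius
  convention, rather than diameter, is a package choice).

The regime taxonomy M1/M2/M3 is operationalized in `classify_regime()`:
recovery below 80% (gel tearing, poor self-healing) marks M3; otherwise
$Y \ge Y_{crit}$ marks channel-stable M2 and smaller $Y$ bubble-forming M1.
The recovery statistic is the ratio of steady-torque plateaus of the
two-pass gel tearing test; the plateau estimator is the mean of the final
half of each pass, robust to start-up transients. (The alternative — peak
force — was rejected because peaks are dominated by the initial yielding
event rather than by the recovered structure.)

## Scenario geometry: planar trails and the deposition slice

The virtual experiments run in 2D. That choice has one structural
consequence: a planar trail conserves *area*, so its width scales like
$PN\cdot d$, while the real channel's diameter scales like $d\sqrt{PN}$ —
the two agree only at $PN = 1$. The package therefore separates concerns:

* `simulate_print()` (planar) reproduces morphology: bubble breakup vs.
  uniform channels, uniformity CVs, neighbor disturbance;
* `simulate_deposition_slice()` runs the plane transverse to the motion,
  where the deposited area per unit path length $Q/v$ is the conserved
  quantity; the relaxed (or arrested) body's diameter is the quantitative
  comparison against $D = d\sqrt{PN}$, and `run_pn_sweep()` sweeps it over
  PN via flow rate or nozzle speed.

"Permanent" deformation in `run_neighbor_disturbance()` means persisting
after five viscous relaxation times ($t_v = w\,\mu(v/d)/\sigma$) with the
nozzle withdrawn; the deformation ratio is the minimum local width inside
the disturbed window over the mean width of the undisturbed far segments
of the same snapshot. The self-controlled nominal matters: the whole
channel drifts slowly in width (finite-interface leakage), and comparing
against the far field of the same state cancels that common mode. The
measurement locus — the minimal-width cross-section — is a package
convention, since no standard exists.

## Materials catalog

The built-in catalog spans the taxonomy with one recipe per regime and four
intermediates (values representative of silicone/gelatin support baths;
yield stress and consistency rise monotonically M1 → M3, M3 carries a high
storage modulus):

| name | tau_y (Pa) | K (Pa s^n) | n | G' (Pa) |
|------|-----------|------------|------|---------|
| M1   | 2   | 5  | 0.60 | 30   |
| M1A  | 6   | 8  | 0.55 | 60   |
| M1B  | 15  | 12 | 0.50 | 120  |
| M1C  | 30  | 15 | 0.45 | 250  |
| M1D  | 60  | 18 | 0.42 | 450  |
| M2   | 100 | 20 | 0.40 | 800  |
| M2B  | 250 | 30 | 0.40 | 1500 |
| M3   | 400 | 60 | 0.35 | 8000 |

All share density 1000 kg/m^3 and surface tension 0.025 N/m against air.
At the reference channel radius of 0.5 mm these give $Y$ from 0.04 (M1,
collapses) through 2 (M2, stable): the dichotomy the simulations exhibit.
Amplitude-sweep (storage modulus) data is carried as a catalog annotation
only; oscillatory rheology is not simulated.

## Problem sizes and run times

The study conditions used by the scenario defaults: planar prints on a
256 x 128 grid covering 20 x 10 nozzle diameters (d = 1 mm resolved by
12.8 cells, $\epsilon_{pf} = 2\Delta x$), nozzle speed 20 mm/s, PN = 1,
a 10-diameter measured path after a 4-diameter lead-in; deposition slices
on 192^2 over 6 diameters; neighbor disturbance at 100 mm/s with a 0.5 mm
nozzle and channel. A planar print takes a few minutes on one core; a
slice about one; the full acceptance suite under twenty. These sizes were
chosen as the smallest that keep the finite-interface artifacts (profile
width, curvature-driven leakage) within the tolerances the tests assert.

## Synthetic printability data

`generate_printability_data()` emulates the schema of the public
printability tables: yield stress, reference viscosity (at 0.01 1/s — the
flow-curve convention adopted for the catalog's reference viscosity) and
nozzle diameter, with a binary label. Ground truth is the physics rule:
printable iff $Y \ge Y_{crit}$ (using the nozzle radius) and the reference
viscosity is below a tearing threshold (default $3\times10^4$ Pa s, the
midpoint between the catalog's M2 and M3 reference viscosities). Features
are log-uniform over $\tau_y \in [1, 10^3]$ Pa,
$\mu \in [10, 10^6]$ Pa s, $d \in [100, 2000]$ um — ranges bracketing
soft embedded-printing baths and practical nozzles. Optional label noise
flips labels independently.

What the generator does *not* emulate: correlated features (real
formulations co-vary yield stress and viscosity), measurement error in
rheometry, nozzle-type effects (the underlying study holds nozzle type,
speed and flow rate constant, so they are not features), or the size and
exact ranges of the real dataset. Passing classifier tests therefore
demonstrates that the pipeline recovers a known boundary from
schema-compatible data — not that the paper's empirical accuracies are
reproduced.

Note one structural property: with both clauses active the printable set
is an intersection of half-spaces in log-feature space, which a linear
model cannot represent exactly — logistic regression tops out around 85%
there, while trees and kernel machines track the corner. The
"all families recover the boundary" checks accordingly use the Y-limited
configuration (viscosity range below the tearing threshold), where the
truth is a single plane and every family can express it.

Training standardizes log10 features with statistics from the training
folds only, uses stratified k-fold CV (5 folds by default — no protocol is
prescribed by the source study), and fixes all seeds; runs are
deterministic end to end.

## Numerical choices, edge cases, limitations

* Time steps: advective CFL factor 0.15 against the larger of nozzle and
  dispense speed; transients at mask edges are absorbed by sub-stepping
  the explicit advection. The quiescent CH default step is
  $0.2\,\epsilon_{pf}^2/M$. Relaxation phases with the nozzle withdrawn
  use a three-fold larger step (the implicit solver is unconditionally
  stable and the advective limit is far away).
* Mobility is scenario-scaled: printing runs tie $M = \chi\lambda/
  \epsilon_{pf}^2$ to the nozzle/dispense speed (the interface is
  continuously advected at that scale near the tip), while the
  neighbor-disturbance scenario ties it to the squeeze-flow scale (a few
  percent of the nozzle speed) — there the fast flow near the mask
  carries no interface, and an over-large mobility would erode the
  pre-laid channel by pure interfacial diffusion (curvature-driven
  evaporation-condensation), a Cahn-Hilliard artifact independent of
  the bath rheology.
* Viscosity floor `mu_floor` (default 0.01 Pa s in scenarios) raises the
  air-side viscosity in the momentum solve; it suppresses spurious
  currents in the bubble interior and is orders of magnitude below any gel
  viscosity of interest.
* Degenerate inputs error early with named reasons: non-finite shear
  rates, nozzle outside the domain, collision gaps, single-class training
  data, empty CSV tables.
* Body extraction uses 4-connectivity so near-touching bubbles stay
  distinct; labels order deterministically (area, then centroid x).
  Perimeters come from marching-squares contours (binary masks are lightly
  smoothed first; the estimator carries a ±5% bias budget, visible in the
  square's circularity).
* Limitations: strictly 2D (planar + transverse-slice; no axisymmetric or
  3D runs), no thixotropy or viscoelasticity (M3's elastic tearing is
  represented only through the recovery statistic and catalog
  annotations), no compressibility of air, no adaptive meshing, periodic
  boundaries only in the flow solver (closed boxes are emulated by margin
  and the zero-flux gauge). Snapshots are written as RDS plus CSV rather
  than HDF5.

## Reproducing the headline behaviors

```{r}
library(airprint)
mats <- materials_catalog()

# bubble/channel dichotomy (Y = 0.04 vs 2 at R = 0.5 mm)
sim_m1 <- simulate_print(print_job(mats$M1))
sim_m2 <- simulate_print(print_job(mats$M2))

# PN sweep in the deposition slice vs D = d sqrt(PN)
sw <- run_pn_sweep(c(1, 2, 4), mats$M2)

# neighbor disturbance over gaps
res <- run_neighbor_disturbance(mats$M2, gap = 5e-4)

# classifier bank on synthetic data
bank <- train_classifiers(generate_printability_data(500, seed = 7,
                                                     viscosity_range = c(10, 2e4)))
summary(bank)
```

Every number the package claims is recomputed either in the test suite
(`tests/testthat`) or by `scripts/acceptance.R`; the vignette states no
result beyond what those scripts measure.
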