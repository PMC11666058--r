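---
title: "Modelling bacterial reshaping of nutrient plumes around sinking particles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bacterial reshaping of nutrient plumes around sinking particles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumequench)
```

## The model

Sinking marine particles — phytoplankton cells, fecal pellets, marine-snow
aggregates, oil droplets — leak dissolved organic matter and trail a
comet-shaped eutrophic plume. Free-living bacteria cluster around such
particles and consume the leaking nutrients, and when their uptake is fast
relative to the plume's dissipation they measurably shrink ("quench") the
plume. `plumequench` couples two ingredients at the single-particle scale:

1. **A data-derived bacterial distribution.** The bacterial concentration
   around the particle, normalized by the ambient value and by the particle
   radius, is represented by an exponential radial distribution function
   (RDF)
   $$B(r) = \beta_0 + \beta_m \exp\!\left[-\left(\frac{r-1}{d_s}\right)^n\right],$$
   with ambient baseline $\beta_0$, peak excess $\beta_m$ at the particle
   surface $r = 1$, accumulation length $d_s$ (in particle radii), and shape
   exponent $n$ ($n=1$ exponential, $n=2$ Gaussian-like). `rdf_preset()`
   ships parameter sets fitted to published microfluidic and individual-based
   simulation data, plus the two hypothesis-testing scenarios (strong and
   weak clustering) and a uniform distribution.

2. **A physics-based nutrient field.** In the particle frame, the steady
   dimensionless nutrient concentration $C$ obeys an
   advection–diffusion–uptake balance
   $$\mathrm{Pe}\, \mathbf{v}\cdot\nabla C \;=\; \nabla^2 C \;-\;
     \mathrm{Da}\, B(r)\, a(C)\, C,$$
   with the creeping-flow (Stokes) velocity past a rigid sphere,
   the Péclet number $\mathrm{Pe} = R_P v_\infty / D$ (advection vs
   diffusion) and the Damköhler number
   $\mathrm{Da} = (R_P^2/D)\, B_\infty \alpha_S$ (uptake vs diffusion).
   The affinity factor is $a = 1$ for linear (unsaturable) uptake — the
   default, matching the headline transport-limited configurations — or
   $a = K_S/(K_S + C)$ for Michaelis–Menten kinetics. The surface carries
   either a prescribed concentration $C_S = 1$ (transport-limited
   dissolution, the default) or a prescribed flux (active exudation); the
   far field is the background, $C = 0$.

The bacterial field is an *input*, not a solved quantity: the model targets
the regime where chemotaxis is faster than uptake
($\tau_C < \tau_U < \tau_{PLM}$), so the clustered distribution is
quasi-static while the nutrient field adjusts. Transient fully coupled
bacteria–nutrient dynamics ($\tau_C \sim \tau_U$) are out of scope, as are
inertial flow corrections (scenarios with $\mathrm{Re} \ge 1$ are flagged,
not solved differently) and turbulence.

## Microzone metadata

Two scalars summarize a clustered distribution. The **microzone radius**
is where the excess concentration falls to a reference level
$\beta_{ref}$ (default 0.1, i.e. 10% above baseline):
$R_M = 1 + d_s\,[\ln(\beta_m/\beta_{ref})]^{1/n}$. The **hotspot index**
is the volume average of $B$ over the fluid shell $1 \le r \le R_M$
(the particle interior is excluded; this convention reproduces the
published metadata values):
$h_e = \int_1^{R_M} B r^2 dr \big/ \int_1^{R_M} r^2 dr$, with $h_e =
\beta_0$ for uniform bacteria.

```{r}
microzone_metrics(rdf_preset("strong"))
```

Note one known quirk: for the fecal-pellet parameter set the defining
equation gives $R_M = 2.29$ while the published table prints 2.2; the
printed hotspot index (3.0) is consistent with 2.29, and this package
follows the equation. The amino-acid-bead row similarly prints $R_M = 2.5$
where the equation gives 2.45.

## Fitting RDFs to digitized profiles

`fit_rdf()` performs constrained nonlinear least squares (bounded
Levenberg–Marquardt via minpack.lm) of the RDF against `(r, b)` profiles
digitized from published figures, with bounds $\beta_0, \beta_m \ge 0$,
$d_s > 0$. Initialization is deterministic — baseline from the median of
the outer 20% of the profile, peak from the first point, accumulation
length from the 37%-decay radius — with three fixed perturbed restarts;
the best residual wins and ties break toward the smaller $d_s$, so
identical inputs give bitwise-identical fits. The shape exponent is either
held fixed (default $n = 1$, the value established by steady-state
chemotaxis theory) or selected from the discrete candidates
$\{3/5, 4/5, 1, 2\}$ by best residual; continuous optimization of $n$ is
deliberately avoided because the exponent is weakly identified on noisy
profiles. Flat profiles (no excess signal) return a flagged
non-identifiable result rather than a silent success. $\beta_0$ is not
constrained to 1: published observation windows are often small, which
depresses the apparent baseline; the consistency condition $\beta_0 = 1$
applies only to unbounded domains.

## Numerical scheme

The solver discretizes the axisymmetric $(r, \theta)$ domain with a
body-conforming stretched grid: radial nodes in geometric progression from
the surface (finest spacing at $r = 1$, where the uptake boundary layer
lives) and angular nodes on a cosine map clustering at both poles, which
refines the wake ray $\theta = \pi$ where the plume length is measured.
Diffusion uses conservative central differences with the $r^2$ and
$\sin\theta$ metric factors evaluated at half-nodes — the zero-area polar
faces regularize the axis automatically. Advection is discretized in
non-conservative form (the Stokes field is analytically divergence-free)
with third-order upwind-biased four-point stencils built from
finite-difference weights on the non-uniform grid, degrading to first-order
upwind at the node layers adjacent to boundaries. The sparse linear system
is solved directly, so repeated runs are bitwise identical; saturable
uptake is handled by Picard iteration on the affinity factor with
under-relaxation 0.7, tolerance $10^{-8}$ on the maximum update, and a cap
of 200 iterations.

**Outer boundary.** Truncating the domain with a hard zero visibly distorts
the algebraic $1/r$ tail that defines the undisturbed plume, so two
far-field treatments are provided. For advective problems, faces where the
free stream enters ($v_r < 0$) carry $C = 0$ and faces where it exits carry
zero radial gradient. For nearly diffusive problems ($\mathrm{Pe} < 0.1$)
a radiation condition $\partial(rC)/\partial r = 0$ is used instead; its
discrete form is exact for $C \propto 1/r$. The outer radius defaults to an
adaptive rule: start from $\max(30,\, 4 L_{est})$ with $L_{est}$ a
closed-form plume-length estimate, then double the domain (re-solving)
until the plume length changes by less than 1%.

**Accuracy.** At $\mathrm{Pe} = 0$ the solver reproduces the two closed
forms — $C = 1/r$ at $\mathrm{Da} = 0$ and the screened field
$C = e^{-\sqrt{\mathrm{Da}\,\beta_0}(r-1)}/r$ for uniform uptake — to well
under 1% maximum error, and the associated Sherwood numbers
($1$ and $1 + \sqrt{\mathrm{Da}\,\beta_0}$) to under 2%. At the headline
quenching conditions ($\mathrm{Pe} = 20$, $\mathrm{Da} = 1.6$, strong
clustering) the plume length and volume change by less than 1% when node
counts double in both directions.

**Monotonicity and the maximum principle.** Higher-order upwind schemes
are not monotone: the computed fields show truncation-level undershoots
(below about $10^{-4}$ on the $C_S = 1$ scale at the default resolutions,
shrinking under refinement) in the far wake where the solution is
essentially zero. The test suite therefore bounds maximum-principle and
pointwise-comparison violations at $10^{-4}$ rather than at the linear
solver's (machine-precision) residual; plume metrics are insensitive to
these wiggles because they are measured at the $C_{det} = 0.1$ level.

## Plume metrics

All observables use the detection threshold $C_{det} = 0.1$ by default.
The plume length $L_{plm}$ is the outermost radius on the wake ray where
$C$ crosses $C_{det}$ (the profile need not be monotone near the particle
at high Pe), located by linear interpolation in $C$. The plume volume
$V_{plm}$ integrates the indicator $H(C - C_{det})$ over the whole fluid
domain — including upstream — with sub-cell linear interpolation of the
threshold crossing along each ray. Quenching factors compare a consumed
solve against a zero-uptake reference *on the same grid* (so ratios are
not polluted by discretization differences): $E_L = L^0/L$,
$E_V = V^0/V$, with relative changes $\Delta = 1 - 1/E$ (exact for
volume, the lower bound of the definition for length). The nutrient
exposure $c^*$ is the $B$-weighted average of $C$ over the microzone
shell, sharing the shell quadrature with the hotspot index. Fluxes
$Q_{As}(r)$ integrate the combined advective and diffusive radial flux
$\mathrm{Pe}\,v_r C - \partial C/\partial r$ over spheres; the Sherwood
number is $Q_{As}(1)/(4\pi C_S)$, the dissolution enhancement $E_{dis}$
is its ratio to the zero-uptake value, and the degradation efficiency
$E_{degr}(r) = 1 - Q_{As}(r)/Q_{As}(1)$ is the fraction of the release
consumed within radius $r$.

A finding worth knowing when interpreting sweeps: at strong uptake
($\mathrm{Da} = 1.6$, strong clustering) the length quenching factor is
*not* monotone in Pe in this implementation. The quenched plume length
saturates near the microzone edge while the undisturbed length grows with
Pe, so $E_L$ rises to a maximum (≈12 near $\mathrm{Pe} \approx 20$) before
advection outruns uptake and $E_L$ falls toward high Pe. At normal uptake
($\mathrm{Da} = 0.16$) $E_L$ decreases monotonically with Pe, matching the
qualitative expectation that slender fast plumes are harder to quench. The
volume quenching factor is monotone decreasing in Pe in both regimes, with
its maximum at the slowest sinking speeds.

## Dimensional analysis and particle screening

`particle_scenario()` converts laboratory units (radius in mm or µm,
sinking velocity in m/d, diffusivity in cm²/s, abundance in cells/mL,
affinity in pL/(cell·s)) to CGS and derives
$\mathrm{Pe}$, $\mathrm{Da}$, $\mathrm{Re}$ and the timescales
$\tau_D = R_P^2/D$, $\tau_A = R_P/v_\infty$,
$\tau_U = 1/(B_\infty \alpha_S)$, $\tau_{PLM} = \min(\tau_A, \tau_D)$.
An explicitly supplied $\tau_U$ wins over the abundance × affinity
derivation. Seawater density (1.025 g/cm³) and viscosity (0.01 g/(cm·s))
are package defaults for the Reynolds number, exposed as arguments.
`reshaping_screen()` applies the quick scaling test
$\mathrm{Pe}/\mathrm{Da} < 100$ and $\mathrm{Da} > 10^{-4}$ for whether
uptake can reshape the plume before it dissipates; it was derived for
uniformly distributed bacteria and becomes conservative as clustering
strengthens.

Aggregate records (equivalent sphere diameter, sinking velocity) are
classified with half-open intervals — small $[0, 0.3)$, medium
$[0.3, 0.8)$, large $[0.8, \infty)$ mm; velocities low $[0, 20)$, moderate
$[20, 100)$, high $[100, 300)$, very high $[300, \infty)$ m/d — so every
record lands in exactly one class. Three representative classes mark where
reshaping is meaningful; the rest are excluded with recorded reasons
(inertial flow for large fast particles, low counts for medium slow ones,
low Damköhler number for small fast ones, negligible reshaping above
300 m/d).

`batch_quench()` evaluates quenching over record tables either by direct
per-record solves or, by default, by interpolation on a log-spaced
$(\mathrm{Pe}, \mathrm{Da})$ lookup grid. Interpolation uses tensor
natural cubic splines in log space on a 9 × 6 grid: plain bilinear cells
at this density leave 2–3% errors against direct solves (log $E_L$ is
strongly curved near its Pe maximum and in the Da direction at high Pe),
while the spline keeps the disagreement well under 1%.

## Synthetic data

The generators exist so every pipeline stage is testable without
downloads; they are pure functions of their parameters and a seed.
`synth_profile()` emulates digitized bacterial accumulation profiles:
radii on $[1, r_{max}]$ and concentrations on the RDF curve under
multiplicative lognormal noise — chosen as the default because digitized
cell-count data have spread roughly proportional to level — with an
additive Gaussian option for robustness checks (negatives clipped at zero
with a warning). The recovery experiment frozen into the tests fits a
200-point profile at noise $\sigma = 0.1$ and recovers
$\{\beta_m, d_s\}$ within 10%. `synth_particles()` emulates aggregate
size–velocity scatter with diameters log-uniform on 0.05–5 mm and
velocities on a power law $SV = 50\, ESD^{0.8}$ m/d with lognormal scatter
0.5 — values chosen once to populate the observed axes ranges and all
three representative classes; they are fixtures emulating the shape of
published aggregate datasets, not estimates of real aggregate statistics.
Consequently, passing batch-pipeline tests demonstrate correct
classification, scaling and interpolation machinery, not agreement with
any published per-class quenching statistics, which would require the
original observational datasets.

## Problem sizes used in the checks

The packaged tests solve on grids between 100 × 40 and 320 × 128 nodes
with outer radii 40–80 particle radii, sized so the full suite runs in a
few minutes while keeping every oracle comparison comfortably inside its
tolerance; the reproduction script uses the default 220 × 96 resolution
with adaptive outer radii for the nine-point Péclet sweep. All solver
runs are deterministic; seeds enter only through the synthetic-data
generators.

## Known limitations

- Steady, axisymmetric, creeping flow only; no inertial or turbulent
  corrections, no time-dependent solves, no coupled bacterial transport.
- The RDF family is monotone; banded or non-monotone bacterial
  distributions are out of scope.
- Dilute-suspension assumption: one particle in an unbounded fluid, valid
  for low particulate volume fractions.
- The lookup grid assumes the quenching factors vary smoothly in
  $(\log \mathrm{Pe}, \log \mathrm{Da})$; ranges must cover the records,
  and `--exact` per-record solves remain available where that is in doubt.
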