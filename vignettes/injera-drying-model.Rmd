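---
title: "Coupled heat and mass transfer modelling of injera convective drying"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled heat and mass transfer modelling of injera convective drying}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injeradry)
```

## The problem

Injera is a fermented teff flatbread with roughly 61% water. It spoils
within days at ambient conditions, and convective hot-air drying is the
standard preservation route. `injeradry` models the tunnel-drying of a
single injera disk as a coupled moisture-energy problem in a porous
slab: moisture diffuses through the pore space, evaporates through a
non-equilibrium source term, and leaves through a convective boundary
layer whose transfer coefficients come from flat-plate correlations. On
top of the PDE simulator the package provides the standard
drying-analysis toolkit: thin-layer kinetics fits (Henderson-Pabis,
Page, two-term), goodness-of-fit statistics and model ranking,
slope-method effective moisture diffusivity, a balanced two-factor ANOVA
for factorial drying studies, and a seeded synthetic tunnel-dryer data
generator.

## Model

### Governing equations

On a 1D through-thickness grid (coordinate $z$, thickness $L$, top face
exposed to the air stream, bottom face on a mesh tray and treated as
insulated) the package solves

$$\frac{\partial c}{\partial t}
  = \frac{\partial}{\partial z}\!\left(D \frac{\partial c}{\partial z}\right)
  - E, \qquad
(\rho C_p)_\mathrm{eff} \frac{\partial T}{\partial t}
  = \frac{\partial}{\partial z}\!\left(k_\mathrm{eff}
  \frac{\partial T}{\partial z}\right) - H_\mathrm{evap} M_v E,$$

where $c$ (mol m$^{-3}$) is the moisture concentration, $T$ (K) the
temperature, and $E \ge 0$ (mol m$^{-3}$ s$^{-1}$) the local evaporation
rate. Evaporated moles are accounted as leaving the domain (the run
report closes the moisture balance over boundary flux plus evaporation;
closure is exact to solver precision). An optional Darcy advection term
is available but off by default: no internal pressure equation is posed,
so there is no pressure field to drive it.

### Evaporation source

The default rate law is the relaxation form

$$E = K_\mathrm{vap}\,\bigl(c - a_w(X_{db})\,c_{v,sat}(T)\bigr)^+ ,$$

which drives the moisture field toward its equilibrium vapour value
$a_w c_{v,sat}$. Because $c$ exceeds $a_w c_{v,sat}$ by three orders of
magnitude for almost the entire run, this produces first-order
falling-rate kinetics with rate constant $\approx K_\mathrm{vap}$ — the
behaviour that thin-layer models describe. An alternative
`"pore_equilibrium"` split ($E = K_\mathrm{vap}(a_w c_{v,sat} - c_v)$
with $c_v = \varepsilon S_g a_w c_{v,sat}$ the pore-gas vapour share) is
selectable through `solver_settings(vapour_split=)`.

Evaporation is one-way: both laws are clamped at zero (condensation is
not modelled, matching the monotone drying curves the apparatus
records).

### Properties

All mixture properties derive from the wet-basis composition (water,
carbohydrate, protein, fat, fiber, ash) through the Choi-Okos component
polynomials shipped as a plain-text table
(`inst/extdata/component_properties.csv`, user-overridable): density by
the harmonic (series) rule, specific heat by mass-fraction weighting,
conductivity by volume-fraction weighting. As the sample dries, the
local composition is rescaled (fixed dry-matter ratios, water fraction
from the local dry-basis moisture), so properties evolve with the state.

The remaining closures are: the water-activity isotherm
$a_w(X_{db}) = \exp(-0.0267 X_{db}^{-1.656} +
0.0107 e^{-1.287 X_{db}} X_{db}^{1.51})$; a six-term saturation-pressure
correlation with $c_{v,sat} = p_{v,sat}/RT$; the gas-phase effective
diffusivity $D = D_{va}\,\varepsilon^{3/4} S_g^{10/3}$; relative
permeabilities $k_{wr} = ((S_w - S_{ir})/(1 - S_{ir}))^3$ and
$k_{gr} = 1 - 1.1 S_w$ (thresholds at $S_w = S_{ir}$ and $S_w = 1/1.1$);
and the irreducible saturation
$S_{ir} = (2.88/T_0)\,(\ln 1/\varepsilon)^{0.48}$.

Two details of the effective thermal properties are genuinely ambiguous
in the source literature of this model family, so both readings are
implemented and selectable (`mixture_rule = "as_printed"` (default) or
`"corrected"`): whether the solid is weighted by $\varepsilon$ or
$1-\varepsilon$ in $k_\mathrm{eff}$, and the sign/weighting of the fluid
contribution in $(\rho C_p)_\mathrm{eff}$. At the study conditions the
two choices differ by far less than the other model uncertainties.

### Boundary transfer

The air-side coefficients use flat-plate correlations with the
flow-aligned sample diameter ($L_c = 0.3$ m) as characteristic length:

$$h_T = \frac{2 k_\mathrm{eff}}{L_c}\,
  \frac{0.3387\,Re^{1/2} Pr^{1/3}}{(1 + (0.0468/Pr)^{2/3})^{1/3}}
  \quad (Re < 5\times10^5), \qquad
h_m = \frac{D_a}{L_c}\,(2 + 0.552\,Re^{1/2} Sc^{1/3}).$$

At the dryer conditions $Re \approx 10^4$, safely laminar. The surface
moisture flux is $h_m (C_s - C_a)$ with the surface vapour concentration
at local vapour-liquid equilibrium, $C_s = a_w(X_{db,s})
c_{v,sat}(T_s)$, and $C_a = (RH/100)\,c_{v,sat}(T_\mathrm{air})$; the
latent heat of surface evaporation is charged to the surface energy
balance. This flux is the model's "constant-rate" channel: it stays
nearly constant until the surface water activity finally collapses.

## The two identified constants

Two constants of the model have no measured value and were identified
once, from reported observables, then frozen as package defaults:

* **Slab thickness (3.9 mm).** The nominal sample description (3 cm
  thick, 30 cm diameter) is internally inconsistent with the recorded
  ~100 g sample mass — at the computed mixture density such a disk
  would weigh over 2 kg — and with the latent-heat budget: drying a
  3 cm inventory in ~2 h would require several kW m$^{-2}$, far beyond
  what the boundary-layer correlation can deliver. The thickness is
  therefore treated as millimetre-scale (the scale of the flatbread
  itself) and set to the largest value for which the simulated product
  temperature never falls below its initial value: thicker slabs
  produce evaporative undercooling of several kelvin at the low-power
  condition (323.15 K, 0.25 m s$^{-1}$), contrary to the monotone
  temperature rise the study reports.
* **Evaporation rate constant ($K_\mathrm{vap} = 1.35\times10^{-4}$
  s$^{-1}$).** Fixed by one-point calibration: root finding on the
  simulated drying time so that the reference condition (333.15 K,
  0.5 m s$^{-1}$, RH 11%) reaches MR = 0.03 at the reported 125 min
  (`calibrate_kvap()` reproduces this). The value is of the same order
  as the reported Henderson-Pabis rate constant (0.0189 min$^{-1}$ =
  $3.15\times10^{-4}$ s$^{-1}$), as it must be for a relaxation-type
  source. A sensitivity ladder is available as `kvap_sensitivity()`;
  the drying time responds nearly inversely to $K_\mathrm{vap}$ on
  this scale, and values beyond $\sim 10^{-3}$ s$^{-1}$ are thermally
  inadmissible (the latent sink would exceed the convective heat
  supply and crash the temperature field).

Everything else at the other conditions is a prediction of the
calibrated model, not a fit. With these defaults the model predicts
~157 min to MR = 0.03 at 323.15 K / 0.5 m s$^{-1}$ (reported: about
150 min; the model's boundary flux inherits the full
Clausius-Clapeyron temperature sensitivity of $c_{v,sat}$, which is
somewhat stronger than the reported temperature effect), and strictly
shorter drying times at higher air temperature and velocity, with exact
moisture-balance closure.

## Numerics

Finite volumes, vertex-centred, with harmonic averaging of the face
diffusivity and conductivity. Time stepping is backward-Euler
(L-stable) on the diffusion/conduction operators and trapezoidal on the
evaporation source and boundary fluxes; the trapezoidal treatment of
the source is what keeps the first-order decay accurate at the default
$\Delta t = 60$ s (halving the step changes MR(t) by under 0.1%,
comfortably inside the documented independence threshold of five-minute
steps). The property nonlinearity is resolved by damped Picard
iteration (tolerance $10^{-6}$, up to 200 iterations, relaxation 0.5);
the surface water-activity feedback is additionally Newton-linearised
in the surface concentration, without which it limit-cycles. Steps
where the liquid-saturation front unlocks a fresh cell ($S_w$ dropping
below 1 switches $D$ from zero to gas scale) are the expensive ones
(~100 iterations).

Verification: against the analytic Fourier-series solution of the
constant-$D$ slab with a fixed surface concentration
(`diffusivity_model = "constant"`, `surface_model = "dirichlet"`), the
solver is accurate to well under 1% at a tenth of the diffusion time
and shows second-order spatial convergence (observed orders 1.9-2.0).
Grid convergence of the full nonlinear drying problem is slower and
non-monotone at the 1% scale because the saturation-front position is
grid-quantised; the packaged default of 61 nodes carries roughly 1%
discretisation error in the drying time, smaller than the model-form
uncertainties discussed above. Negative concentrations below
$10^{-9} c_0$ abort the step; tiny negatives are clipped with a
warning. Temperatures are kept inside the validity window of the
saturation correlation (273-473 K) with explicit range errors rather
than silent extrapolation.

## Kinetics and statistics

Thin-layer fitting works in minutes (the PDE solver works in seconds;
the conversion happens at the module boundary and the time unit is
recorded in curve metadata). Fits use Levenberg-Marquardt least squares
with documented starting values (Henderson-Pabis $(1, -0.02)$; Page
$(-0.02, 1)$; two-term $(0.7, -0.02, 0.3, -0.005)$). Ranking is by
descending $R^2$ (the squared Pearson correlation) then ascending RMSE;
fits whose $R^2$ differ by less than $10^{-3}$ — below the precision at
which these statistics are usually tabulated — are treated as tied and
the model with fewer parameters wins. On simulated curves the Page
model tends to rank first: the simulated curve has an early
constant-rate period (boundary-flux controlled), which Page's $t^n$
with $n > 1$ captures and a pure exponential cannot.

Effective moisture diffusivity uses the first-term Fickian slab slope
method: least-squares slope of $\ln \mathrm{MR}$ against time (seconds)
over the window MR $\in [0.05, 0.7]$, then
$D_\mathrm{eff} = |k| L^2/\pi^2$ with half-thickness $L = 0.015$ m (the
method's conventional two-sided-exchange geometry; window and $L$ are
arguments). The two-factor ANOVA computes its sums of squares from
first principles for balanced designs (`stats::aov` serves as the
oracle in the test suite) with mean drying rate over the first 60 min
as the response variable.

## Synthetic tunnel-dryer data

`generate_experiment()` emulates the measurement structure of the
apparatus: ~100 g sample, continuous balance record (1 min default,
0.1 g balance-grade noise), centre temperature every 15 min with 1 K
thermocouple noise, at a configured air condition. The truth curve is
either a full simulation or a closed-form kinetics model; with zero
noise the output equals the truth exactly, and everything is a
deterministic function of the seed. What the generator does *not*
emulate: sensor drift, ambient humidity fluctuations, sample shrinkage,
or lateral non-uniformity of the air field — so recovery tests on
synthetic data demonstrate statistical correctness of the fitting
chain, not fidelity of the physical model to real injera.

## Known limitations

* Sample shrinkage, case hardening, glass transition and sorption
  hysteresis are not modelled.
* The geometry is 1D through-thickness; lateral (radial) gradients from
  the developing boundary layer are not represented, and the transfer
  coefficients are uniform over the face.
* The reported bulk specific heat (3676 J kg$^{-1}$K$^{-1}$) and
  conductivity (0.34-0.37 W m$^{-1}$K$^{-1}$) of the fresh sample are
  not recoverable from the stated mixing rules with standard component
  correlations (the package computes ~3190 and ~0.53); these are
  surfaced as warnings by `check_reported_properties()`, not asserted.
* The printed initial concentration (49,750 mol m$^{-3}$) implies a
  water saturation slightly above 1 at the stated porosity; the
  saturation is clamped and the value is kept as the default initial
  condition for fidelity.

## A worked run

```{r, eval = FALSE}
library(injeradry)

setup <- drying_setup()            # packaged defaults: 333.15 K, 0.5 m/s
curve <- simulate_drying(setup)
attr(curve, "drying_time_min")     # 125.0
attr(curve, "balance")$closure     # 1.0

fits <- rank_models(curve)
fits[[1]]$model                    # "page" (see ranking note above)
fit_kinetics(curve, "henderson_pabis")$R2   # 0.973

effective_diffusivity_slope(curve) # 1.02e-8 m^2/s
```
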