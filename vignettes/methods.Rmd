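---
title: "Model description and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model description and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`orchardsim` simulates one growing season of a peach tree as a collection of
fruiting units (FUs) — fruit-bearing shoot assemblies placed explicitly in
the crown — exchanging carbon and water with whole-tree compartments (old
wood, water sprouts, coarse and fine roots). The model couples five
sub-systems: canopy radiation interception, a sunlit/shaded leaf energy
balance with Jarvis stomatal conductance, steady-state water transfer through
the axis network, source–sink carbon allocation with degree-day-driven
potential growth, and a biophysical fruit model (turgor-driven expansion and
a four-pool sugar metabolism). This vignette records the science, the
defaults, and the design decisions a maintainer would want to know.

## Radiation interception

Each FU is a turbid ellipsoid with a spherical leaf-angle distribution
(direct-beam extinction coefficient $k = 0.5/\sin\beta$ at solar elevation
$\beta$). For a parallel beam, the chord lengths across the projected disk of
any ellipsoid are distributed as $L\sqrt{1-\rho^2}$, which gives a
closed-form disk-averaged interception fraction
$f(x) = 1 - 2\,[1-(1+x)e^{-x}]/x^2$ with $x = k\Lambda L$ ($\Lambda$ = leaf
area density, $L$ = central chord); a unit test verifies this against a
$10^5$-ray Monte-Carlo integration. The beam reaching an FU is first
attenuated through every other ellipsoid it crosses (chords from a ray cast
through the canopy) and through the crown envelopes of the eight neighbouring
trees placed at the 4 m × 5 m periodic spacing. Representing neighbours as
whole-crown envelopes with tree-average leaf area density, rather than as
full per-FU copies, keeps the periodic-shading idea at a ninth of the cost;
at these LAIs the difference is within the turbid-medium approximation
itself. Diffuse sky radiation is integrated over three zenith sectors (times
four azimuths). Sunlit leaf area is the leaf area still reached by the
un-attenuated beam, and sunlit leaves receive $k$ times the beam flux per
unit leaf area on top of the diffuse field.

The shortwave split (PAR 0.48 / NIR 0.52 of global) and leaf absorptances
(0.85 PAR, 0.20 NIR) are standard values, configurable in the
`radiation` parameter block. Net radiation per FU is
$R_n = \mathrm{PAR} + \mathrm{NIR} + \mathrm{TIR} - 2\sigma T_\mathrm{leaf}^4 A$,
with thermal input from sky (Brunt clear-sky emissivity), soil (defaulting to
air temperature) and surrounding foliage, view-factor weighted.

## Energy balance, stomata and water transfer

For every daylight hour each FU is split into a sunlit and a shaded pool and
$R_n = S + \lambda E$ is solved for leaf temperature with a safeguarded
Newton iteration (residual tolerance 0.01 W, bracket air temperature
± 20 °C). Stomatal conductance follows the multiplicative Jarvis model
$g_s = g_{s,\max} f_1(\mathrm{PAR}) f_2(D) f_3(T) f_4(\psi_\mathrm{leaf})$.
The calibrated parameter pairs fix the slope and midpoint of each factor but
not its functional form; the forms used here are monotone, bounded
reconstructions ($1-e^{-a x}$ for light, logistics for the rest) chosen so
each factor approaches 1 in benign conditions. They are isolated in
`stomatal_conductance()` so alternatives can be swapped.

Water flow is steady state each hour (no capacitance, matching the hourly
resolution): the flow through each axis equals the summed transpiration of
downstream FUs, and the potential drops by flow × length / conductivity,
with conductivity scaling with axis diameter as $k_h = a_k d^{2.5}$
($a_k = 5\times10^{-3}$, set so an unstressed midday tree drops well under
0.3 MPa from collar to stem). The leaf potential falls below the stem
potential by at most 0.447 MPa, linearly in transpiration up to a reference
rate (the transpiration of a fully sunlit leaf at saturating light, 30 hPa
VPD and unstressed water status, computed once per run). The boundary
condition is the collar potential, reconstructed from predawn and midday
values: constant at night and half-sine between sunrise (6 h), the 14 h
trough and sunset (20 h).

Leaf temperature and water potential close through an outer fixed point:
a damped start-up step (damping 0.5) followed by componentwise secant
(Steffensen) acceleration, safeguarded by the damped step wherever the
secant denominator degenerates. The iteration stops when the fixed-point
residual is below 2 × 10⁻⁴ MPa and 0.005 °C (typically 3–4 iterations);
these tolerances are set so the converged state agrees with a direct
simultaneous root-find of the stacked residuals to within
10⁻³ MPa / 0.01 °C, which the acceptance suite verifies on a two-FU tree
over a full diurnal course. The inner leaf-temperature Newton iteration
uses an analytic residual slope (radiative, sensible and latent terms) with
a bisection safeguard. Non-convergence after 50 iterations is an error
carrying the last residuals.

## Carbon supply and demands

Light-saturated photosynthesis responds to leaf water potential as
$P_{\max} = P_{\max,0}\,[1 - e^{B_h (A_h + 1/\psi_\mathrm{leaf})}]$, clamped
at zero below $\psi = -1/A_h = -2.74$ MPa where the raw expression turns
negative. With the calibrated $A_h = 0.3647$ and $B_h = 6.3667$, the factor
is still 61% at the potential where vegetative growth stops (−1.949 MPa) —
the source/sink asymmetry at the heart of the virtual experiment. Gross
assimilation applies an exponential-saturating light response (quantum
efficiency 0.06 mol mol⁻¹) separately to the sunlit and shaded pools.
$P_{\max,0}$ defaults to 0.02 mmol CO₂ m⁻² s⁻¹ (20 µmol), a typical
light-saturated rate for well-lit peach leaves. Maintenance respiration uses
per-compartment coefficients at 20 °C with Q10 = 2, integrated hourly.

Potential organ growth follows the logistic thermal-time law
$\Delta DM = RGR^{ini}\, Im^{-1} f(dd)\, DM\, (1 - DM\,Im^{-1}/DM^{max})\,
f(\psi)\,\Delta dd$ with the organ-specific degree-day windows, and
$f(\psi)$ linear between $\psi_{min} = -1.949$ and $\psi_{max} = -1.378$ MPa
(fruits use the same law with $Im$ and $f(\psi)$ fixed at 1: their dry
growth responds to water only through carbon supply and water inflow).
Two readings of this law required a decision:

* **Organ counts.** The growth parameters are per organ (one leafy shoot,
  one water sprout, one fruit); a fruiting unit carries `n_shoots` shoots
  (5–12 in the synthetic tree) and the tree carries `n_sprouts` water
  sprouts (100 by default), mirroring how the crop load is `n_fruits` per
  FU. Treating the 4.65 g shoot ceiling as a whole-FU mass would leave the
  tree with ~0.5 m² of leaf area, contradict the observed one-third
  water-sprout share of leaf area, and shrink vegetative sinks below 1% of
  the carbon budget. With counts, the tree reaches LAI ≈ 1.5 and a balanced
  budget.
* **Which daily $\psi$ enters $f(\psi)$.** The thresholds were estimated
  against midday pressure-chamber measurements, so the daily minimum
  (midday) leaf potential is the default statistic
  (`growth$psi_stat = "midday_min"`); the transpiration-weighted daytime
  mean remains available as `"daytime_mean"`.

The root–shoot imbalance is $Im = (\text{shoot mass}/\text{fine-root
mass})/\text{target ratio}$ (target 5 g g⁻¹), clamped to [0.2, 5], so
$Im = 1$ at equilibrium; fine-root demand restores the target ratio given
the shoots' potential. Daily allocation runs in priority order:
maintenance first (mobilizing up to 10% of reserve pools per day when
assimilate falls short — reserves buffer maintenance only and never fund
growth, so a day of zero assimilation with sufficient reserves leaves all
masses unchanged); then vegetative growth (leafy shoots, water sprouts,
fine roots); then fruit growth; each sink attracts carbon in proportion to
demand × distance⁻¹ (Euclidean distances between FU centroids, tree
compartments at the collar) under an iterative water-filling that never
exceeds a sink's demand or a source's supply. Growth pays an 18% carbon
cost. Surplus is stored passively in reserves up to 20% of the compartment
dry mass; overflow accrues to perennial structure (old wood and coarse
roots, 2:1). The daily ledger closes to better than 10⁻⁹ relative by
construction, and the acceptance suite verifies it across all thirteen
scenarios.

## Fruit growth and sugars

Fruit volume obeys $dV/dt = A\,L(\psi_{stem} - \psi_f) - T$ with
$\psi_f = P_f - \pi_f$. The vascular exchange term $A\,L$ is a single
allometric coefficient (0.012 g h⁻¹ MPa⁻¹ at 1 g fresh mass, exponent 2/3),
skin transpiration is surface × VPD with a permeation coefficient, and the
osmotic pressure follows van't Hoff over the four sugar pools plus a
constant 0.25 MPa for other osmolytes. Turgor uses a quasi-steady,
plastic-only Lockhart closure: while $P_f$ exceeds the 0.2 MPa yield
threshold the irreversible expansion $V\phi(P_f - Y)$ absorbs the net
inflow ($\phi = 0.01$ MPa⁻¹ h⁻¹); below it the turgor settles where inflow
balances transpiration (constant volume), clamped at zero turgor under
severe deficit (net shrinkage). The elastic term of the full biophysical
model is omitted — dilution drives the osmotic dynamics — and the closed
form is verified against a bisection oracle. Stone mass follows a
saturating share of fruit dry mass (ceiling 3.87 g); flesh water volume is
flesh fresh minus dry mass at unit density.

Phloem carbon enters the flesh as sucrose (share $k_1 = 0.3573$) and
sorbitol; sucrose hydrolyses at $k_2(t) = e^{-K_{2,1}(t - K_{2,2})}$
(1 day⁻¹ at $t = K_{2,2} = 74$ days after bloom, capped at 5 day⁻¹ for
early-season stability), split 50:50 on a carbon basis into glucose and
fructose (equimolar hydrolysis); sorbitol converts to fructose ($K_3$) and
glucose ($K_5$); glucose and fructose leave the soluble pools at
$k_4 = K_{4,1} \times$ fruit relative growth rate. The system is integrated
with classical RK4 at 0.1-day steps, pools clamped at zero, and the
exported-carbon integral recovered from the pool balance so that carbon is
conserved to machine precision. Constant-coefficient steady states match
the closed forms within 0.1%.

## Synthetic forcing and tree

The generator emulates a semi-arid season: clear-sky radiation from solar
geometry with atmospheric transmissivity 0.75, sinusoidal diurnal
temperature with seeded day-to-day noise, humidity anti-correlated with
temperature, light wind. The seasonal temperature profile is scaled so the
150-day season accumulates exactly 2,625 degree-days above the 7 °C base —
the harvest anchor — which also means short test seasons are thermally
compressed by construction. The water-potential boundary holds the
no-stress (NS) treatment at −0.3 MPa predawn / −0.7 MPa midday all season;
LS/MS/SS decline deterministically after day 47 (the mid-pit-hardening
treatment onset for an end-of-April bloom) toward −0.7/−1.5, −1.2/−2.2 and
−1.8/−2.8 MPa respectively, with a 20-day time constant — magnitudes in the
range produced by 7.2/3.6/1.8 mm day⁻¹ drip irrigation under ~11 mm day⁻¹
evaporative demand. The deterministic curves guarantee the ordering
NS ≥ LS ≥ MS ≥ SS at every date.

The synthetic tree carries 80 FUs in a 1.6 m × 2.6 m crown at 4 m × 5 m
spacing, 280 fruits, 5–12 shoots per FU and 100 water sprouts in a
crown-top unit whose leaf area follows the sprout pool mass. What the
generator does *not* emulate: cloudy-sky radiation statistics, rain events,
within-season thinning or pruning, and measured within-treatment
replication. Passing tests on this forcing demonstrate internal consistency
and the direction of stress responses, not site-level predictive skill.

## The thirteen-scenario experiment

`run_scenarios()` crosses the three deficit profiles with four limitation
hypotheses — none, photosynthesis-only ($f(\psi)$ forced to 1),
growth-only ($P_{\max}$ forced to $P_{\max,0}$), both — plus the
well-watered control, all on identical weather. Water transfer, stomata and
fruit water inflow always respond to the potential field; the hypotheses
wire only the two limiting functions. Percentage changes versus the control
are computed at harvest for carbon assimilation, vegetative dry-mass growth,
fruit dry and fresh mass, dry matter content, fresh-basis sugar
concentration, per-fruit sugar content (mass), and perennial growth
(structural growth plus net reserve change, since reserves live in the
perennial organs). Under no stress the leaf potential never crosses
$\psi_{max}$, so the growth-only hypothesis reproduces the no-limitation
run exactly — a regression fixture in the test suite.

## Calibration utilities

`rrmse()` and `criterion_a()` implement the goodness-of-fit score (RMSE
over the observation mean) and the variance-weighted global criterion over
leafy-shoot, water-sprout and fruit dry masses (variances taken over all
observation cells per variable — the per-date alternative is not
implemented). `fit_potential_growth()` extracts a 90%-quantile envelope per
100-dd bin (each bin evaluated at its mean dd) and fits the closed-form
logistic trajectory in transformed thermal time by Nelder-Mead on
log-parameters. `fit_psi_thresholds()` wraps the full season simulator:
Nelder-Mead on a logistic reparameterization enforcing
$\psi_{min} < \psi_{max} < 0$, five seeded starts with incumbent restarts,
minimizing the global criterion. `fit_sugar_params()` does the same for the
six sugar parameters against pool trajectories. Nelder-Mead settings
default to relative tolerance 10⁻⁶ and 500 iterations (the threshold fit
uses 40 per pass, restarted, because each evaluation is a full season run).

## Problem sizes and numerical choices

The shipped tests and the acceptance checks use: the full 80-FU tree over
150 days for the thirteen-scenario suite; a two-FU tree over one diurnal
course for the solver-equivalence oracle; a 6-FU tree over a 100-day
(thermally compressed) moderate-stress season for the threshold-recovery
experiment with 2% observation noise — the moderate treatment is the
informative one, because it sweeps the leaf potential slowly through the
threshold window while severe stress spends most days below it, where the
growth response is flat in the thresholds; and a 60-day trajectory at
half-day integration steps for the sugar-parameter recovery. These sizes were chosen as the smallest
problems on which each property is informative. Known limitations: sorbitol
dynamics follow the cited pool structure even though that structure is
known to track observed sorbitol poorly; the canopy is static in geometry
(ellipsoids do not grow); fruit drop, pruning and multi-year carry-over are
out of scope; and the simulated sensitivity magnitudes depend on the
synthetic severity profiles — only orderings and directions are asserted.
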