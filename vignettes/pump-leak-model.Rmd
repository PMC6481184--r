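---
title: "The pump-leak flux-balance model behind pumpleak"
author: "pumpleak authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pump-leak flux-balance model behind pumpleak}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`pumpleak` simulates the balance of Na^+^, K^+^ and Cl^-^ fluxes, cell
water volume and membrane potential in an animal cell suspended in a fixed
bath, in the classical pump-leak tradition of whole-cell ion homeostasis
models (the red-cell lineage of Lew and Bookchin and its successors). The
state variables are the intracellular ion contents; everything else —
concentrations, volume, membrane potential — follows from two physical
constraints that must hold at every instant:

* **macroscopic electroneutrality**: the net charge carried across the
  membrane by all pathways together is zero, which determines the
  membrane potential; and
* **osmotic balance**: a distensible cell takes the water volume at which
  total internal osmolyte concentration equals the external osmolarity.

Three content rate equations drive the dynamics (fluxes per ml of cell
water, time in minutes):

$$\frac{dNa_i}{dt} = V\left\{\frac{p_{Na}\,u\,([Na]_i e^u - [Na]_o)}{1-e^u}
  - \beta [Na]_i + J_{NC} + J_{NKCC}\right\}$$

with the analogous equation for K^+^ (pump term $+\beta [Na]_i/\gamma$,
cotransport $J_{KC} + J_{NKCC}$) and for Cl^-^ (channel term of valence
$-1$, cotransport $J_{NC} + J_{KC} + 2J_{NKCC}$). Here $u$ is the
dimensionless membrane potential, $U = 26.7\,u$ mV at 37 °C.

The pathway kinetics:

* **Channels** follow Goldman–Hodgkin–Katz constant-field
  electrodiffusion with one integral permeability coefficient per ion
  (`pna`, `pk`, `pcl`, min^-1^). The implementation uses the valence $-1$
  GHK form for Cl^-^, $p\,u\,(c_i - c_o e^u)/(1-e^u)$: this is the form
  whose sign convention (inward positive) is consistent with the cation
  form and with the net/unidirectional flux decomposition the package
  reports.
* **The Na^+^/K^+^ pump** is first-order in intracellular Na^+^: efflux
  $-\beta[Na]_i$, coupled K^+^ influx $\beta[Na]_i/\gamma$ with
  stoichiometry $\gamma = 1.5$ (3 Na out : 2 K in). The rate coefficient
  may decline linearly, $\beta(t) = \max(0, \beta_0 - k_b t)$, the
  behaviour observed for the pump during staurosporine apoptosis.
* **Cotransporters** (NC, KC, NKCC) are electroneutral and driven by the
  transmembrane products of their substrate concentrations, e.g.
  $J_{NC} = i_{NC}([Na]_o[Cl]_o - [Na]_i[Cl]_i)$.

The membrane-impermeant osmolytes (amount $A$, mean valence $z$) are
derived once from the initial state so that both constraints close
exactly — $A/V = kv\,\Sigma_{ext} - ([Na]_i+[K]_i+[Cl]_i)$ and
$z = ([Cl]_i - [Na]_i - [K]_i)/(A/V)$ — and are then frozen. Freezing is
an explicit approximation: measured impermeant-anion contents change
little over a four-hour apoptosis time course (∼3 %), but the model will
not track processes that consume or release impermeant osmolytes.

## Parameters that matter

| name | meaning | units | typical value |
|------|---------|-------|---------------|
| `pna`, `pk`, `pcl` | integral channel permeability coefficients | min^-1^ | 0.004, 0.01–0.03, 0.01–0.07 |
| `beta` | pump rate coefficient | min^-1^ | 0.029–0.039 |
| `gamma` | pump Na/K stoichiometry | — | 1.5 |
| `kb` | linear pump decay | beta units min^-1^ | 0 or 6.8e-5 |
| `inc`, `ikc` | NC / KC cotransport rate coefficients | ml µmol^-1^ min^-1^ | 3e-6 – 3e-5 |
| `inkcc` | NKCC rate coefficient | ml^3^ µmol^-3^ min^-1^ | 0 |
| `kv` | "new"/"old" external osmolarity ratio | — | 1 |
| `hp` | internal steps between output samples | — | 100–1000 |

`kb` is nominally printed in min^-1^ in the original file layouts; since
it subtracts from `beta` (itself min^-1^) per minute, its effective unit
is beta-units per minute. The package keeps the label but documents the
meaning here and in `?membrane_params`.

A worked standard cell (`fixture_scenario("table2_balance")`) starts at
Na 33, K 152, Cl 45 mM in a 310 mOsm medium and relaxes to a balanced
state near U −44.7 mV, Na 38, K 147, Cl 45.1 mM, V/A 12.51 ml mmol^-1^,
with OSOR ≈ 3.76 — the configuration used throughout the tests.

## Numerical choices

* **Integration** is fixed-step explicit Euler, default `dt = 0.01` min.
  The minute-scale dynamics of this model are non-stiff at published
  parameter values; the test suite includes a step-halving check
  (`dt` 0.02/0.01/0.005) asserting endpoint agreement within 0.05 mM. If
  a step would drive a content negative the simulator stops with advice
  to reduce `dt` rather than silently clamping.
* **Membrane potential** is treated as instantaneous (zero-capacitance
  formulation): capacitive charging is orders of magnitude faster than a
  minute, so `u` is re-solved at every step instead of integrated.
  `solve_potential()` scans $u \in [-8, 2]$ for a sign change of the
  total charge flux and bisects to $|\Delta u| < 10^{-10}$; the
  integration loop warm-starts a Brent solve (tolerance $10^{-12}$) in a
  narrow bracket around the previous root and falls back to the full
  scan if the local bracket fails. Tests assert bracket-independence of
  the root and the Nernst limit when only one ion is permeant.
* **GHK at small |u|** switches to the analytic $u \to 0$ limit
  ($p(c_o - c_i)$ for the net fluxes) below $|u| = 10^{-6}$ to avoid
  0/0; the branch join is continuous to ∼10^-5^ relative.
* **Degenerate inputs**: with no charge-carrying pathway at all (all
  channel permeabilities and the pump zero) the potential equation is
  satisfied identically and the simulator keeps the previous potential
  instead of failing, so all-zero-parameter runs are exact no-ops. An
  initial state whose osmolytes meet or exceed the external osmolarity
  (A/V ≤ 0) is rejected as an invalid configuration.
* **Schedules** apply instantaneously at their event time, never before;
  an override of `beta` resets the reference from which the `kb` decay
  is measured.
* The t = 0 row of a time course reports zero concentration derivatives
  by convention (there is no preceding step to difference);
  `detect_balance()` therefore ignores that row whenever later samples
  exist.

## The apoptosis schedule

The packaged `table4_apoptosis` scenario encodes the staurosporine
apoptosis fit for U937 cells: from the balanced baseline (Na 32, K 117,
Cl 40 mM, U −29.9 mV), at t = 0 the pump begins its linear decline
(`kb = 6.8e-5`) while pK rises to 0.03, pNa falls to 0.003 and pCl rises
to 0.068; after the first half hour pK steps back down to 0.02. The
half-hour placement of the second event is the package's reading of the
published fitted trajectory: with it, every reported time point (10, 20,
30, 60, 120, 210, 240 min) is reproduced to the printed precision,
whereas placing the step at 60 min distorts the 60–120 min segment. The
run ends at Na ≈ 51.5, K ≈ 96.7, Cl ≈ 24.0 mM with the cell still far
from balance (net Na^+^ gain ≈ 0.163 µmol min^-1^ ml^-1^), the signature
of ongoing apoptotic ion redistribution at 4 h.

## Fitting and the OSOR filter

The published workflow identifies channel/transporter changes by trial
simulation against measured ion time courses, with one decisive extra
observable: OSOR, the ratio of ouabain-sensitive to ouabain-resistant
Rb^+^(K^+^) influx, which pins down the pump's share of K^+^ influx.
`fit_parameters()` formalizes this: a coarse grid over the stated bounds
followed by Nelder-Mead refinement of the sum-of-squares misfit, with
candidates whose simulated OSOR falls below a user-supplied `osor_min`
rejected outright. Two deliberate choices:

* **Derivative-free search.** The misfit surface has poorly conditioned
  curvature (parameters trade off strongly in some regions), so no
  gradient or Hessian method is promised; the grid stage guards the
  simplex against local traps, and the returned optimum is never worse
  than the best grid point.
* **No default `osor_min`.** The published account calls certain fits
  "unacceptably low" in OSOR without quantifying the threshold; it is a
  judgement about the measurement, so the package requires the user to
  supply it (0 disables the filter). The OSOR denominator includes K^+^
  influx through KC and NKCC when those are active, not only channels;
  in every published configuration they are zero, so the conventions
  coincide.

`make_synthetic_observations()` supports recovery tests: it samples a
simulated trajectory and adds independent Gaussian noise per ion and
time point. That emulates unbiased assay scatter of a few mM, which is
the right scale for flame-photometry-derived concentrations; it does
*not* emulate correlated errors from a shared water-content denominator,
drift between parallel samples, or the fact that contents per g protein
are more reliable than concentrations. Passing recovery tests therefore
show identifiability of the parameters under honest noise, not
robustness to systematic measurement error.

The test suite exercises recovery on a 40-min window with observations
every 5 min and `dt = 0.05`: small enough to run in seconds, long enough
that `pk` and `pcl` have distinguishable signatures. Noiseless data
recover both within 2 %; Gaussian noise of 2 mM loosens recovery to
within ∼15 %.

## Conversion utilities

`water_from_density()` (buoyant density → ml water per g protein),
`ion_content_units()` (content / water → mM) and `pump_beta_from_rb()`
(ouabain-sensitive Rb^+^ influx + Na content → beta) mirror the
measurement pipeline that produces the model's inputs. The Rb scaling
admits two readings of "proportions of [Rb]~o~ and [K]~o~": the default
`"total"` convention treats Rb^+^ and K^+^ together as the pump's cation
substrate (scale (rbo+ko)/rbo); `"k_only"` scales by ko/rbo. The choice
is returned as an attribute on the result so downstream code can see
which was used.

## Known limitations

* Monovalent ions only: no Ca^2+^, H^+^ or HCO~3~^-^ handling, no pH or
  signalling coupling.
* One integral coefficient per ion per pathway class; no per-isoform
  channel resolution and no multi-site pump kinetics.
* $A$ and $z$ frozen at t = 0; slow impermeant-osmolyte changes are not
  tracked.
* Explicit Euler with a fixed step; pathological parameter sets (orders
  of magnitude above published permeabilities) may need a smaller `dt`.
* External medium composition is fixed during a run except through `kv`;
  media as listed are not themselves charge-balanced, which the model
  never requires.

## Session

```{r}
library(pumpleak)
tc <- simulate_cell(fixture_scenario("table2_balance"))
tail(as.data.frame(tc), 1)
```
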