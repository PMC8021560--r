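---
title: "Modelling trace-metal speciation in anaerobic digestion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trace-metal speciation in anaerobic digestion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracedigest)
```

## The problem

Methanogenic consortia need iron, nickel and cobalt as enzyme cofactors,
but a digester is an aggressive scavenging environment: biogenic sulfide
precipitates metals as FeS/NiS/CoS, carbonate and phosphate minerals
compete for them, chelators (EDTA) and volatile fatty acids complex
them, and the large surface inventory of biomass, inert solids and FeS
particles sorbs them. What the organisms actually see — the bioavailable
fraction — is the residual of all those fluxes. `tracedigest` assembles
the whole network as one stiff ODE system so that methane production and
metal partitioning can be simulated together, in batch or continuous
operation.

## Model structure

The state vector tracks 137 components: the ADM1 soluble and particulate
pools (organics in gCOD/L), an inorganic suite (carbonate, ammonium,
phosphate, sulfide, sulfate and EDTA ladders; Fe, Ni, Co, Ca, Mg as
divalent cations; all in M), 15 metal–ligand complexes, 13 mineral
precipitates, four headspace gases, and one free plus several occupied
binding-site pools per adsorbing surface. The registry
(`build_default_registry()`) carries, for each component, its phase,
unit, charge and elemental content, and for each of the 211 reactions a
sparse stoichiometry; elemental conservation therefore holds *reaction
by reaction* and is asserted at build time. The default inventory is
42 sorption/desorption pairs (7 biomass guilds × 5 metals, inert × 5,
FeS × Ni and Co), 13 precipitation/dissolution pairs and 15 complexation
reactions.

### Biochemistry

The ADM1 cascade uses the standard mesophilic parameter set with three
deliberate departures, each a substrate/community characterisation
rather than a new mechanism:

* `k_dis = 0.25 /d`. Disintegration of the composite is the
  rate-limiting first step for complex feedstocks; the faster benchmark
  value floods the weakly buffered batch system (6 mM ammonium, 4 mM
  carbonate) with acids faster than the small inoculum (0.12 gCOD/L per
  guild) can consume them.
* The acetoclastic pH band is 5.0–6.5 (lower-side Hill inhibition on
  [H⁺]). Batch operation at the tabulated alkalinity settles near pH
  6.2–6.4 once the biogas CO₂ equilibrates, which is within the working
  range of Methanosarcina-dominated communities; the conservative 6–7
  band would hold the population ~90 % inhibited at its own steady
  state.
* Composite fractions `f_sI = 0.15, f_ch = 0.205, f_pr = 0.185,
  f_li = 0.26, f_xI = 0.2` characterise a moderately degradable mixed
  substrate; they set the full-conversion methane plateau of the batch
  scenarios (≈ 2.5 × 10⁻² M over 100 d at 2 gCOD/L).

Disintegration releases sulfur as HS⁻ and phosphorus as HPO₄²⁻ (their
dominant forms at digester pH) at per-gCOD coefficients, zero by default
for the batch scenarios (metals arrive as initial conditions) and set to
the feed characterisation for the continuous case. Metal bio-uptake is
proportional to the acetate + hydrogen uptake rates (coefficients
5 × 10⁻⁷ / 5 × 10⁻⁸ / 5 × 10⁻⁹ mol per gCOD for Fe/Ni/Co, the order of
typical biomass metal contents), with a Monod guard (`K = 10⁻⁸ M`) so an
exhausted pool cannot be driven negative.

### The dose–response factor

Methanogenic uptakes are multiplied by
`I(x) = (a1 x + a2)/(x² + b1 x + b2)` per trace metal, where `x` is the
free ion plus its EDTA complex — sorbed and precipitated metal is not
bioavailable. The constructor `dose_response_constants(x_opt, breadth)`
yields a curve that equals 1 exactly at the optimum and stays near 1
over a `breadth`-fold band either side. The defaults peak at the
batch optima (Fe 10⁻⁴, Ni 10⁻⁵, Co 10⁻⁷ M) with per-metal widths
(Fe 300, Ni 15, Co 50): the scenario sweeps show methane production
nearly insensitive to Fe dose over two orders of magnitude, strongly
responsive to Ni, and mildly responsive to Co, and a single narrow curve
cannot reproduce that pattern.

### Acid–base and pH

All 15 conjugate pairs relax kinetically,
`ρ = k_AB([HA] − [A⁻][H⁺]/Ka)`, with `k_AB = 10⁵ /d`: ladders
equilibrate in ~1 s of simulated time, far below every other timescale,
while keeping the Jacobian numerically benign (at 10⁸ /d the
finite-difference Jacobian of the stiff solver loses the micro-molar
ladder species to cancellation and integration stalls; results are
insensitive across 10⁴–10⁶ /d). The proton is not a state: pH comes from
the charge balance `Σ z_i c_i + [H⁺] − Kw/[H⁺] = 0`, a closed-form
quadratic since every ion is explicit. Activities equal concentrations;
pKa values are single-temperature constants.

### Minerals

Precipitation uses the saturation driving force,
`ρ_prec = k_prec (√Ω − 1)²` for `Ω > 1`; dissolution
`ρ_dissol = k_dissol X_p (1 − Ω)` for `Ω < 1`, so the two are mutually
exclusive and both vanish smoothly at `Ω = 1`. Solubility products are
stated in the classic lattice convention (e.g. FeS 10⁻¹⁸·¹ against
S²⁻). Internally each IAP is evaluated on the dominant protonation form
(HS⁻, HCO₃⁻, HPO₄²⁻) with the matching Ka folded into an operational
Ksp and an explicit [H⁺] power — chemically identical at ladder
equilibrium, but conditioned on ~mM state variables instead of the
10⁻¹⁴ M lattice anions. No nucleation lag or seed-surface dependence is
modelled.

### Complexation

Each complex follows `ρ = k1[Me][L] − (k1/K)[MeL]`. Two numerical
design choices matter:

* The EDTA ligand is HEDTA³⁻, the dominant uncomplexed form between the
  last two pKa values (6.16, 10.26), with operational stability
  constants (log K 7.1 / 9.0 / 8.3 / 3.6 / 2.5 for Fe/Ni/Co/Ca/Mg) that
  preserve the binding order Ni > Co > Fe > Ca > Mg. On the EDTA⁴⁻
  scale the free ligand sits at 10⁻¹³–10⁻¹⁶ M with forward constants up
  to 10¹⁸ M⁻¹d⁻¹, and the integration becomes tolerance-dependent; the
  HEDTA³⁻ scale keeps the partition and the pH coupling (through the
  ladder) while remaining integrable.
* `k1 = max(10⁸, K × 1/d)`: every complex dissociates at ≥ 1/d.
  Without this floor the weakly bound Ca/Mg-EDTA complexes capture the
  shared ligand pool during start-up and release it over hundreds of
  days, freezing the partition far from the K-ordered equilibrium.

Only the EDTA complexes count towards the bioavailable `x` of the
dose–response factor; VFA complexes are weak (log K ≤ 1.4) and
transient.

### Sorption

The binding-site model is bilinear: `ρ_ads = K_a/d · k_ads · X_free ·
S_Me` and `ρ_des = K_a/d · k_des · X_occ`, all metals drawing on one
free-site pool per surface. Site densities are 2 × 10⁻³ mol/g for
biomass and inert surfaces and 2 × 10⁻⁵ mol/g for FeS; dry mass is
gCOD/1.42 for biomass (C₅H₇O₂N), 1:1 for inerts, and 87.9 g/mol × molar
FeS. Free sites are created in proportion to surface growth
(biomass yield, the inert fraction of disintegration, FeS
precipitation) and destroyed — with immediate release of any bound
metal — by biomass decay and FeS dissolution, so the invariant
`free + Σ occupied = δ × dry mass` holds to solver precision at all
times. Equilibrium constants are ~5 × 10⁵ M⁻¹ for Fe, 3 × 10⁴ for
Ni/Co and 3 × 10² for Ca/Mg (`k_des = 10 /d`), placing the inert-bound
iron fraction near the 45–70 % range across the organic-loading ladder
while letting Ca/Mg act as mass competitors rather than dominant
occupiers.

### Reactor and numerics

`simulate_reactor()` integrates the assembled system with the
variable-order BDF solver (`deSolve::vode`), `rtol = 10⁻⁷`,
`atol = 10⁻¹²`, and a restart-on-stall guard: if the error test wedges
at a sharp chemistry switch (a mineral exhausting, the gas vent
opening), integration restarts cold from the last accepted state.
Rates are always evaluated on the non-negative part of the state, so
sinks shut off smoothly as pools empty; the rarely triggered negativity
floor logs any discarded flux (`glance(traj)$clipped_flux`). The
headspace is ideal gas at constant volume with an orifice outflow
`q_gas = k_p (P − P_atm)`, `k_p = 200 L/(bar·d)` — sized for bench-scale
headspaces of a fraction of a litre. Initial states are pre-equilibrated
analytically (acid–base ladders at pH 7, the metal–EDTA partition by a
shared-ligand root solve) and an inert counter-ion closes the initial
charge balance, standing in for the counter-ions of the dosed salts.
Halving both tolerances moves the 40-day methane answer by < 0.1 %.

## Scenario presets and what they emulate

`build_scenario()` reproduces five batch families over a common base
state (0.75 L working volume, 0.25 L headspace, 35 °C, 100 d): the
organic-loading ladder (1–5 gCOD/L), one-metal-at-a-time dose ladders
for Fe/Ni/Co, a joint Ca–Mg ladder, an EDTA ladder (10⁻⁵–10⁻⁴ M) and
binding-site-density ladders for the three surface classes. These are
*in-silico* experiments: they emulate the idealised, perfectly mixed,
single-substrate digester of the model world. Passing their checks shows
the network reproduces the published partitioning logic — it does not
validate the model against measured speciation, which remains scarce.

`build_continuous_case()` emulates a bench CSTR digesting food waste
(4 L total, 1 L headspace, 37 °C, OLR 1.45 gVS/L/d, HRT 50 d, 120 d
horizon). The feed is characterised from its proximate analysis: total
COD 450 mg per g wet weight with TS 28.1 % and VS 95.5 % of TS gives
1.68 gCOD/gVS; protein COD follows TKN (3.77 % of TS at 0.007 mol
N/gCOD), the remaining degradable COD splits 75/25 between carbohydrate
and lipid, and 20 % is inert (f_sI = f_xI = 0.10) — food waste is highly
degradable. Feed sulfur and phosphorus are 6 × 10⁻⁷ and 6 × 10⁻⁸
mol/gCOD; feed trace metals are small residuals (Fe 2 × 10⁻⁸,
Ni 2 × 10⁻⁹, Co 2 × 10⁻¹⁰ mol/gCOD) and no EDTA is present. Following
the operating protocol of the comparison experiment, the reactor is
first spun up for 150 d on the same loading with trace metals
supplemented (the dose–response factor held flat — supplemented
operation is by construction at the optimum), and the starvation run
departs from that steady state with a metal-free feed. The starvation
dose–response optima are pinned at 1.2 × the spun-up bioavailable
levels with a narrow plateau (`breadth = 2`): free metals in a
continuous digester sit orders of magnitude below batch dosing levels
because the large inert surface pool buffers them, so the batch optima
cannot apply. With this calibration the yield holds ≈ 0.43–0.44 L
CH₄/gVS and fails after roughly two retention times as the metal
inventory washes out, precipitates with biogenic sulfide and is taken
up. Free Fe and Ni decline monotonically throughout; free Co dips,
rebounds transiently while the collapsing biomass releases its sorbed
cobalt, and then resumes washout — a decay-release signature of the
failure transition.

## Known limitations

* Concentrations stand in for activities; no ionic-strength correction.
* Single-temperature constants (35/37 °C treated alike).
* No sulfate reduction biology; sulfate participates in the charge
  balance only.
* Metals are divalent only — no redox speciation (Fe³⁺), no
  co-precipitation or solid solutions; FeS is the only sorbing mineral.
* The universal-binding-site assumption ignores functional-group
  chemistry (carboxyl/sulfhydryl/phosphoryl) on purpose.
* EPS/SMP storage pools and amino-acid-bound metal sources are out of
  scope.
* The continuous-case calibration (feed metal residuals, starvation
  optima) is a qualitative reproduction of one experiment, not a
  validated parameterisation.

## Problem sizes used by the test-suite and acceptance runs

Batch scenarios integrate 137 states over 100 days (a few seconds
each); the continuous case runs a 150-day spin-up plus a 120-day
starvation horizon (well under a minute). Property tests use reduced
closed systems (single pairs, single surfaces, abiotic mixtures) where
algebraic oracles are exact.
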