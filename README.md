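# tracedigest

Trace metals decide whether an anaerobic digester thrives or starves:
Fe, Ni and Co are obligatory cofactors of the methanogenic enzyme
machinery, yet almost all of the metal inventory in a digester is locked
up in sulfide/carbonate/phosphate minerals, in EDTA and volatile-fatty-acid
(VFA) complexes, and on the surfaces of biomass, inert solids and FeS
particles. `tracedigest` is a three-phase kinetic simulator for exactly
this problem: it couples the IWA Anaerobic Digestion Model No. 1 (ADM1)
biochemistry to a full trace-metal speciation network and predicts, over
time, both methane production and the partitioning of each metal among
its chemical pools.

The package is aimed at researchers in anaerobic digestion and
environmental biotechnology who want to explore trace-element dosing,
bioavailability and starvation scenarios *in silico*.

## The model

For every soluble component `S_i`, particulate `X_i`, precipitate
`X_p,i`, binding site and headspace gas the simulator integrates a mass
balance of the form

    d(V_liq S_i)/dt = q_in S_in,i − q_out S_i
                      + V_liq [ Σ_j δ_ij ρ_A,j − ρ_T,i
                      + Σ_j α_ij ρ_bio,j + Σ_j β_ij ρ_cmplx,j
                      + Σ_j γ_ij (ρ_prec,j + ρ_dissol,j)
                      + Σ_j ε_ij ρ_s,j ]

with reaction families:

* **Biochemical** (`ρ_bio`): the ADM1 disintegration → hydrolysis →
  acidogenesis → acetogenesis → methanogenesis cascade with first-order
  biomass decay. Disintegration releases S, P and metals at configurable
  per-gCOD coefficients; metal bio-uptake is tied to the acetate and
  hydrogen uptake rates. Methanogenic rates carry an extra dose–response
  factor `I(x) = (a1·x + a2)/(x² + b1·x + b2)` per metal, with
  `x = free + EDTA-complexed` metal — stimulating up to an optimum and
  inhibiting beyond it; surface-sorbed metal is never bioavailable.
* **Acid–base** (`ρ_A`): 15 kinetic conjugate pairs (VFAs, carbonate,
  ammonium, phosphate, sulfide, sulfate, EDTA), with pH solved
  algebraically from the charge balance at every evaluation.
* **Complexation** (`ρ_cmplx`): 15 metal–ligand complexes (5 × Me-EDTA,
  10 × Me-VFA), `ρ = k1[Me][L] − (k1/K)[MeL]`, the reverse rate closed by
  the stability constant.
* **Precipitation/dissolution** (`ρ_prec`, `ρ_dissol`): 13 sulfide,
  carbonate and phosphate minerals, switched by the saturation state
  `Ω = IAP/Ksp`; `ρ_prec = k_prec(√Ω − 1)²` when supersaturated,
  `ρ_dissol = k_dissol·X_p(1 − Ω)` when undersaturated.
* **Sorption/desorption** (`ρ_s`): the binding-site model — 42 reversible
  pairs (7 biomass guilds × 5 metals, inert × 5, FeS × Ni/Co), with free
  sites generated at the site density `δ` (mol sites/g) as surfaces grow
  and destroyed (releasing their metal) as surfaces decay or dissolve.
* **Gas transfer** (`ρ_T`): two-film transfer of H₂, CH₄, CO₂ and H₂S to
  a headspace vented through a pressure-relief closure.

Batch and continuous (CSTR) reactors are supported; stiff integration
uses the variable-order BDF solver from `deSolve`.

## A worked example

Simulate the base batch scenario (2 gCOD/L composite feed, 0.75 L
working volume, 100 days) and report the day-100 speciation:

```r
library(tracedigest)

traj <- run_scenario(1, 2)      # scenario family 1, run 2 (X_c = 2 gCOD/L)
glance(traj)
#> # A tibble: 1 x 6
#>   t_end n_components pH_final cum_ch4_M cum_ch4_L clipped_flux
#> 1   100          137     6.26    0.0246     0.467            0

speciation_fractions(traj) |>
  tidyr::pivot_wider(names_from = pool, values_from = fraction)
#> # A tibble: 3 x 9
#>   metal    free biomass  inert sulfide carbonate phosphate  edta     vfa
#> 1 Fe    0.176   12.4    56.4        0         0         0   31.1 8.1e-5
#> 2 Ni    0.00712  0.0929  0.137      0         0         0   99.8 1.7e-6
#> 3 Co    0.0355   0.174   0.681      0         0         0   99.1 6.4e-6
```

Read: after 100 days the digester has produced 0.0246 mol CH₄ per litre
of reactor liquid (0.47 L of gas at 35 °C); over half of the iron ends
bound to inert surfaces while nickel and cobalt ride almost entirely on
EDTA — the partitioning pattern that controls their bioavailability.

`autoplot(traj)` draws the methane and pH trajectories,
`plot_speciation()` the stacked partition chart, and `tidy(traj)` returns
the full trajectory as a long tibble. `run_continuous_case()` reproduces
a 120-day bench CSTR digesting food waste with no trace-metal dosing:
the specific methane yield holds a plateau near 0.43 L CH₄/gVS and then
collapses as the metal inventory washes out.

A thin command line is included:

```sh
Rscript -e 'tracedigest::run_cli()' run-scenario --scenario 2ni --run 1 --out results/
```

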