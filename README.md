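# aromflux

Constraint-based flux and metagene analysis for a facultative
aromatic-compound degrader.

Facultative anaerobes that degrade aromatic compounds switch between
denitrification and O2 respiration, and between oxygen-sensitive
anaerobic ring-reduction pathways and O2-dependent ring cleavage.
Understanding such an organism quantitatively takes three connected
calculations, and this package implements all of them as one tested
pipeline for modellers and microbial physiologists:

1. **Constraint-based metabolic modelling.** A stoichiometric model
   (metabolites, reactions, bounds, categories) with JSON/TSV/SBML
   input, validation, and elemental/electron balance checking. Flux
   balance analysis maximizes the biomass flux v_bio subject to
   steady state S·v = 0 and bounds l ≤ v ≤ u; flux variability analysis
   reports per-reaction [min, max] at fixed optimum; split-ratio
   analysis gives each reaction's percent contribution to a metabolite's
   turnover; activity tables, variation decomposition and Ward
   clustering compare conditions. The LP solver is a built-in
   bounded-variable two-phase simplex with Bland's rule, validated
   against an exhaustive vertex-enumeration oracle that ships with the
   package.
2. **Metagene expression types.** Non-negative matrix factorization
   T ≈ W·S of a column-normalized gene × condition transcript matrix
   (optionally log(1+c)-transformed first), with uncentered explained
   variance per condition and the selection rule: the smallest number of
   components m explaining ≥ 90% of every condition's variance.
3. **Growth stoichiometry.** μ from the ln(OD) slope, t_D = ln2/μ,
   oxygen-by-difference elemental composition (ash 12.03 wt%), degrees
   of reduction (γ = 4C + H − 2O − 3N + 6S − charge), C/C carbon
   yields, and electron-ledger predictions of nitrate (5 e⁻) or O2
   (4 e⁻) consumption.

Seeded generators (a carbon- and electron-balanced facultative-anaerobe
toy network, planted low-rank lognormal transcript matrices, exponential
growth curves) make the whole pipeline testable offline with known
ground truth.

## Worked example

```r
library(aromflux)

model <- make_toy_model()
cond  <- toy_conditions()[["acetate-aerobic"]]
sol   <- solve_fba(apply_condition(model, cond))
sol$objective_value                      # 0.6375813  (growth rate, h^-1)
biomass_carbon_yield(sol, apply_condition(model, cond))
                                         # 63.75813   (% substrate C in biomass)
split_ratios(model, sol, "atp_c")
#> Split ratios at atp_c (acetate-aerobic) - turnover 33.89 mmol/gDW/h
#> producers:            flux fraction
#>   ATPS               30.27    89.31
#>   TCA                 3.62    10.69
#> consumers:
#>   BIOMASS            25.50    75.25
#>   NGAM                8.39    24.75
```

The numbers mean: with acetate uptake capped at 10 mmol gDW⁻¹ h⁻¹ and
O2 open, the cell grows at 0.64 h⁻¹ and retains 64% of the consumed
carbon; 89% of its ATP comes from the ATP synthase and the rest from
substrate-level phosphorylation, while maintenance claims a quarter of
the ATP spend.

The full analysis sequence lives in `analysis/` and writes its tables
under `results/`:

```sh
Rscript analysis/01_build_model.R         # build + audit the network
Rscript analysis/02_fba_conditions.R      # FBA/FVA across 4 conditions
Rscript analysis/03_flux_analysis.R       # split ratios, activity, clustering
Rscript analysis/04_metagenes.R           # NMF metagene selection
Rscript analysis/05_growth_stoichiometry.R
```

Step 2 prints, per condition, e.g. `acetate-anaerobic mu = 0.4675 h^-1,
C/C yield = 46.8 %` against `acetate-aerobic ... 63.8 %` — the P/O
advantage of oxygen respiration. Step 3 finds the two-group cut of the
flux clustering separating oxic from anoxic conditions, and step 4
recovers the planted five metagene components with matched cosine
similarities ≥ 0.978.

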