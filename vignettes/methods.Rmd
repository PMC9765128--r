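---
title: "Methods: constraint-based fluxes, metagene factorization and growth stoichiometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based fluxes, metagene factorization and growth stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices
behind `aromflux`. The package implements the computational core of a
systems-level analysis of a facultative anaerobic bacterium that degrades
aromatic compounds with either nitrate (denitrification) or molecular
oxygen as the terminal electron acceptor: constraint-based flux analysis
of a stoichiometric metabolic model, post-hoc flux analytics,
non-negative matrix factorization (NMF) of transcript matrices into
metagene expression types, biomass-composition assembly from sequence
data, and growth-stoichiometry calculations. Because the corresponding
experimental data live in external repositories, every analysis here runs
on seeded synthetic data whose generating truth is known; the vignette
states explicitly what those generators do and do not emulate.

## Constraint-based model and flux balance analysis

A model is a list of metabolites (with compartment, elemental formula and
charge) and reactions (signed stoichiometry, flux bounds in
mmol gDW^-1 h^-1, gene associations, and a category: enzymatic,
transport, boundary, biomass, maintenance or definition). Flux balance
analysis maximizes the biomass reaction flux subject to steady state
`S v = 0` and the bounds. With the substrate uptake fixed at its measured
limit, maximizing the biomass *rate* coincides with maximizing the
biomass *yield*, which is the intended objective; this is the standard
reading when simulated cultivations are parameterized by measured
consumption rates.

Key conventions:

* **Exchange reactions** touch exactly one external metabolite with
  coefficient −1; uptake is negative flux, so a condition opens an
  exchange by setting its lower bound to minus the uptake maximum.
* **Conditions** name one carbon source and one acceptor. Exactly one
  acceptor exchange is open; the other is closed to `(0, 0)`. The
  acceptor exchanges are located by metabolite formula (NO3 vs O2), so
  condition objects do not hard-code model-specific identifiers. Models
  may flag oxygen-sensitive reactions (e.g. an ATP-dependent class I
  aromatic ring reductase); aerobic conditions close them, mirroring the
  O2 lability of those enzymes.
* **Maintenance.** Non-growth-associated maintenance (NGAM) is a fixed
  ATP-hydrolysis flux, default 8.39 mmol gDW^-1 h^-1;
  growth-associated maintenance (GAM), default 59.81 mmol gDW^-1, lives
  inside the biomass reaction. Both are configuration values in the
  E. coli tradition of genome-scale models, surfaced in every condition
  object and report rather than buried in code.
* **Degeneracy.** Single FBA flux vectors are not unique. All activity
  statements therefore use flux-variability ranges (per-reaction min/max
  flux at `objective >= fraction x optimum`, default fraction 1 with a
  1e-9 numerical slack), never one solution. A reaction is *active* in a
  condition when its range exceeds 1e-6 mmol gDW^-1 h^-1 in absolute
  value.

### The linear-programming core

No linear-programming package is part of this package's dependency
stack, and FBA/FVA subproblems are small but frequently degenerate, so
the solver is written for robustness: a two-phase primal simplex on
bounded variables with Bland's rule (which excludes cycling) and a full
QR refactorization of the basis at every iteration, so the basic solution
is recomputed from scratch each step and floating-point drift cannot
accumulate. Feasibility tolerance is 1e-9. For validation the package
also ships an independent brute-force oracle, `enumerate_vertices()`,
which constructs *every* vertex of the flux polytope by basis
enumeration; on random networks of up to a dozen reactions the simplex
objective and all FVA ranges are required to agree with the oracle to
1e-6. The two routes share no code beyond the problem definition.

### Split-ratio analysis

At steady state a metabolite's production equals its consumption. The
split ratio of a reaction at a node is its fractional contribution to
that turnover, with reversible reactions assigned to the producing or
consuming side by the *sign of their flux*, not their declared direction.
Producer and consumer fractions each sum to 100% by construction; the
tests assert this to 1e-6 at every internal node of every optimum.

### Clustering and variation decomposition

Condition flux profiles are clustered with Euclidean distance and Ward
linkage (`ward.D2`) after dividing each condition's flux vector by its
substrate carbon uptake — without that normalization the metric is
dominated by uptake magnitudes rather than pathway usage. Both metric and
linkage are arguments. The flux-variation share of a reaction group is
its summed max-minus-min flux across conditions over the total; groups
must not overlap, and an all-constant matrix yields flagged `NA` shares
rather than 0/0.

## Biomass assembly

Monomer compositions are estimated from sequence: DNA by the
double-stranded GC convention (dAMP = dTMP = (1−GC)/2, dGMP = dCMP =
GC/2, computed from one strand ignoring N, hence strand-symmetric), RNA
from the transcribed strand of predicted gene sequences (a documented
choice — a whole-genome estimate is also defensible, but gene-based
matches what the transcripts actually are), and protein from pooled,
length-weighted residue frequencies over all predicted proteins.
Macromolecular class masses (g/gDW) ship as an editable configuration
table following the E. coli convention (protein 0.55, RNA 0.205, ...)
and are never hard-coded in logic. Monomer coefficients use
*polymerized* residue masses (free monomer minus water) so that the
assembled biomass reaction consumes exactly 1 g of precursors per unit
flux; the ledger is checked to 1% and then normalized exactly.

## Growth stoichiometry

The growth rate is the least-squares slope of ln(OD) against time;
without an explicit window the longest contiguous stretch of at least
three points with R^2 >= 0.98 is used (ties to the higher R^2), and the
chosen window is reported. Doubling time is ln 2 / mu, undefined when mu
is not positive.

The oxygen content of dried cells is derived by difference,
`O = 100 − C − H − N − 12.03` wt%, with the 12.03 wt% ash constant
(which includes S) taken as fixed. Degrees of reduction use the
CO2/H2O/NH3 reference: gamma = 4C + H − 2O − 3N + 6S − charge, so acetic
acid is 8, benzoic acid 30 and CO2 exactly 0. The electron ledger then
predicts acceptor demand: dissimilated electrons = substrate electrons −
biomass electrons, divided by 5 for nitrate (full denitrification
NO3^- → ½N2, matching a NarGHI → NirS → NorBC → NosZ chain) or 4 for O2.
A nitrite-only variant (2 e^-) is available because nitrite transients
are routinely measured. The C/C yield is the molar carbon in formed dry
mass over the molar carbon in consumed substrate, in percent; for any
closed experiment yield and dissimilated share sum to 100%.

## Metagene factorization

Transcript matrices are prepared by column normalization so each
condition sums to 1; in log mode `log(1 + c)` is applied entrywise
*first*, then columns are normalized. That order reconciles the two
published conventions (a log transform of copy numbers, and columns
summing to one) and is stated prominently because the two orders do not
commute. The log transform exists to keep the lognormal upper tail —
the few highly expressed genes — from dominating the variance.

NMF minimizes the Frobenius loss with the classical multiplicative
updates, which keep `W` and `S` non-negative and never increase the
loss; the best of `restarts` (default 10) random initializations is
kept, and results are deterministic given `(seed, restarts)`.
Convergence is declared at a relative loss change below 1e-6 (checked
every 10 iterations) within 2000 iterations, else flagged.

Explained variance is **uncentered** (`1 − ||T−WS||² / ||T||²`, per
condition and in total): a non-negative factorization has no intercept,
so centering would compare the model against a baseline it cannot
represent. A centered variant is available behind a flag for sensitivity
analysis. Component selection takes the smallest m whose fit explains at
least 90% (configurable) of every condition's variance, scanning ranks
with a shared seed for comparability. Component-recovery checks match
fitted to planted components by best permutation over cosine
similarities (exhaustive for the small m used here).

## Synthetic data: what it emulates, and what it does not

**Toy network** (`make_toy_model()`): an acetate-like C2 and a
benzoate-like C7 substrate; an anaerobic branch that invests ATP and
reductant to reduce the aromatic ring before beta-oxidation-like
breakdown, versus an O2-consuming ring cleavage; a lumped TCA-like
oxidation; a glyoxylate-shunt bypass supplying the C4 biomass precursor;
NADH dehydrogenase, a quinone pool, a denitrification lump
(2 NO3^- + 5 QH2 → N2) and a terminal oxidase; ATP synthase at 3 charges
per ATP; NGAM; PHB storage; a biomass drain consuming acetate units, C4
precursor and ATP. Electron carriers carry their electrons as an
H2-equivalent formula, so carbon *and* electron conservation of every
enzymatic/transport reaction are verifiable by the package's own
checkers — and are verified, independently of the generator, in the
tests. The chain stoichiometries are parameterized by P/O ratios
(default 2.0 for O2, 1.0 for nitrate), which plants the aerobic growth
advantage and the oxic/anoxic clustering signature. The network is a
~27-reaction cartoon: it has no gluconeogenesis, pentose-phosphate,
nitrogen/sulfur assimilation or transhydrogenase reactions, and its C/C
yields (46–64% across the four shipped conditions) sit above measured
values for real organisms because the lumped catabolism wastes no
carbon on biosynthetic overflow.

**Transcript matrices** (`make_transcript_counts()`): gene i belongs to
one of `m_true` modules and carries a lognormal baseline copy number
(meanlog 3, sdlog 1); module k's score row is `1 + boost` on its own
round-robin condition group and 1 elsewhere; multiplicative Gaussian
noise (relative sd `noise_sd`, default 0.01) is added and clipped at
zero. Because the module indicators sum to the all-ones vector, the
noise-free matrix has *exact* rank `m_true`. The boost default of 6 was
chosen once, at design time: the planted factors of a shared-baseline
design are identifiable only when the boost dominates the baseline (the
mixing ambiguity of exact NMF factorizations scales like
base/(base+boost)), while per-condition log-count marginals must remain
consistent with a Normal; boost 6 with sdlog 1 satisfies both at the
default matrix size. The generator does not emulate sequencing-depth
variation, gene-length effects, overdispersed technical replicates, or
genes belonging to several modules — passing recovery tests therefore
show the *procedure* is sound, not that real transcriptomes are this
easy.

**Growth curves** (`make_growth_curve()`): exact exponential OD with
multiplicative readout noise; substrate drawn down so the noise-free
carbon ledger closes exactly at `yield_true`; acceptor series from the
electron ledger; curves truncate (flagged) at substrate exhaustion. The
default experiment (mu 0.25 h^-1, yield 42%, 8 mM of a C2 substrate, 21
samples over 12 h, 2% noise, OD-to-CDW slope 0.35 g L^-1 OD^-1) is a
realistic bench-scale batch culture. Lag and stationary phases, gas
exchange and evaporation are not modelled.

## Problem sizes and numerical settings

The shipped analyses and checks use: 20 random networks of 7–10
reactions for oracle equivalence (exhaustive vertex enumeration is
O(2^n) and is kept to sizes where it is instant); the 27-reaction toy
network across 4 conditions for conservation, activity, split-ratio and
clustering checks; 500-gene, 10-condition transcript matrices over 20
seeds per planted rank (2, 3 and 5) for NMF recovery; and 50 simulated
growth experiments at 2% noise for stoichiometry recovery. LP
feasibility tolerance is 1e-9, the zero-flux reporting threshold 1e-6,
NMF tolerance 1e-6, and all generators are bit-reproducible per seed.

## Known limitations

* The simplex refactorizes densely at every iteration; it is built for
  hundreds of variables, not tens of thousands. Genome-scale models load
  and validate fine, but FVA on them is slow by design honesty rather
  than impossible.
* `select_components()` refits from rank 1 upward; for data whose
  selected rank is large this is quadratic in the rank. The scan reuses
  one seed per rank — a deliberately simple, reproducible rule.
* The SBML importer reads Level 3 core species/reactions plus charges
  and formulas; it does not interpret fbc flux-bound parameters or gene
  products, and maps boundary-condition species to auto-created
  exchanges.
* Electron-ledger acceptor predictions assume complete denitrification
  to N2 (or the explicit nitrite-only option) and no fermentative
  products; organisms that secrete intermediates will consume less
  acceptor than predicted.
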