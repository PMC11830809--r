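---
title: "Electron accounting for cathodic enrichment reactors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron accounting for cathodic enrichment reactors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocathode)
```

## The problem

Enrichment experiments on polarized cathodes ask whether an environmental
community can grow on electrode electrons. The observable evidence is
indirect: a current trace, concentration changes of a handful of
metabolites, COD, qPCR copy numbers, biofilm microscopy, and amplicon
profiles. None of these alone separates electrotrophy from fermentation of
the yeast extract that almost every medium contains, or from oxidation of
soluble donors such as formate and thiosulfate. The discriminating quantity
is the electron balance: coulombs available from each candidate donor
versus coulombs embodied in the products. This vignette documents the
models and procedures the package uses, the parameters that matter, and the
design decisions taken where conventions genuinely diverge.

## Coulomb arithmetic

A chronoamperometry trace is read as a left-continuous step function:
`|I(t)| = |I_n|` on `[t_n, t_{n+1})`. Charge over a window is the
left-rectangle sum `sum(|I_n| (t_{n+1} - t_n))`. The rule was chosen over
the trapezoid because it is the convention of the discrete approximation
this analysis standardizes on, it makes integration exactly additive over
adjacent windows, and it is exact for piecewise-constant currents sampled
at their breakpoints; the trapezoid rule serves as an independent test
oracle, against which the left-rectangle sum agrees within 0.1% on smooth
traces sampled at 1 s. Cathodic currents are recorded negative by
potentiostats, so every statistic is defined on magnitudes; all results are
invariant under a sign flip of the whole trace.

Three per-trace statistics matter downstream:

* **j₁ₕ** — |j| at exactly 3600 s, linearly interpolated between bracketing
  samples. It is the abiotic baseline: after one hour the capacitive
  transient has settled but growth has not yet contributed. Interpolation is
  needed because "exactly one hour" must have a defined value between
  samples.
* **Biocoulombs** — `sum over t_n >= 3600 of max(0, |j(t_n)| - j1h) * A *
  (t_{n+1} - t_n)`. Accrual starts at one hour, not zero: the statistic is
  then exactly zero for any flat abiotic trace, which is the property that
  makes it a usable activity indicator. Whether the first hour should
  accrue at all is unresolvable without raw reference traces; starting at
  1 h is the conservative choice and is applied uniformly.
* **Fold increase** — max |j| after the first hour divided by j₁ₕ, with the
  earliest attaining time. A zero baseline yields a missing ratio rather
  than infinity.

## Electron equivalents, CE, and the donor budget

For organics CxHyOz the electron content on full oxidation to CO₂/H₂O is
`ne = 4x + y - 2z`, equivalently four electrons per O₂ in the balanced
combustion — the identity the test suite checks by balancing oxygen
independently for all eight registered acids. Inorganic donors carry
registered half-reaction counts (H₂: 2; thiosulfate → sulfate: 8;
Fe(III) → Fe(II): 1). COD interconverts at 8 g O₂ per mol e⁻, so the
registry maintains `cod_gO2_per_mol = 8 ne` exactly.

Coulombic efficiency is `CE% = F ne d[P] V / Q x 100` per product, with
deltas taken as final minus initial timepoint (intermediate points are
reported, not fit). Per-product CEs are summed into the total; a total over
100% is flagged as evidence of a non-cathode donor.

The budget's four donor terms:

* **Cathode**: total integrated charge over the run — not biocoulombs —
  because the CE denominator is the full current integral. Biocoulombs feed
  the activity score instead; both are emitted so the distinction is
  auditable.
* **Formate**: net consumption × 2 F / mol. Net production routes to the
  product side.
* **Thiosulfate**: accepted as a donor only under concomitant,
  near-stoichiometric sulfate production — produced sulfate within ±50% of
  2 mol per mol thiosulfate consumed by default. The tolerance is
  configurable because "almost stoichiometric" has no canonical number;
  ±50% is wide enough to survive ion-chromatography noise on mM-scale
  deltas yet rejects sulfate-consuming (acceptor) reactors outright.
* **Yeast extract**: COD_initial − (COD_final − COD of secreted acids),
  floored at zero, converted at 8 g COD per mol e⁻. Subtracting product COD
  first prevents counting secreted acids as residual substrate. A COD
  increase sets a carbon-fixation flag and contributes nothing donor-side.

Classification: `cathode_sufficient` when product coulombs ≤ cathode
coulombs; `multi_donor_electrofermentation` when products exceed the
cathode but are covered by the summed donors; `donor_deficit_flag`
otherwise. Acceptor consumption (nitrate, sulfate-as-acceptor, Fe(III))
stays descriptive: adding it to the donor side would conflate respiration
with electron supply. Anion loss across the exchange membrane is a known
negative bias on donor-side estimates; it is not modeled.

Iron reduction gets a consistency check rather than a budget entry:
complete conversion of ferrihydrite to magnetite caps Fe(II) at one third
of total iron, so fractions ≤ 1/3 + 0.05 are labelled magnetite-consistent
(the 0.05 slack absorbs ferrozine-assay uncertainty; no published tolerance
exists).

## Hydrogen evolution feasibility

With the SHE convention E° = 0 at every temperature, the HER equilibrium
potential at a hydrogen threshold pressure is
`E = -(RT ln10/F) pH - (RT/2F) ln(p_H2)`; temperature enters only through
RT/F. The threshold p_H₂ — the partial pressure below which hydrogenotrophs
cannot grow — is metabolism- and temperature-specific and rarely published
directly, so the package calibrates it by inverting the Nernst expression
at known (E, pH, T) anchors; calibration round-trips to machine precision.
The shipped per-temperature table is calibrated from potentials published
at pH 4.5 (−0.038 V at 30 °C, −0.104 V at 75 °C), with the 55 °C row the
geometric mean of the calibrated pressures; it is an editable table
precisely because users with direct threshold concentrations should replace
it. Feasibility is `E_cathode <= E_HER - overpotential`, default
overpotential 0.2 V — the order of magnitude of HER kinetic losses on plain
graphite; it is a flag threshold, not a kinetic model (no Butler–Volmer
treatment, no activity corrections).

## Activity score and community normalizations

Five indicators — biofilm (0–5), bacterial qPCR, archaeal qPCR, produced
organic acids (sum of positive deltas, mM), biocoulombs — are combined by
dividing each continuous indicator by its across-reactor maximum (an
all-zero column scores 0) and biofilm by its scale maximum of 5, then
summing. Totals are bounded in [0, 5], components are scale-invariant, and
exactly one reactor attains 1 on each informative indicator. The score is
comparative by construction: it ranks reactors within an experiment and
carries no absolute meaning across experiments.

Amplicon tables are normalized to a fixed depth (default 100,000 reads);
samples below the threshold are excluded with a recorded reason, and
exclusion is monotone in the threshold. The default is proportional
rescaling, not rarefaction: "normalized to N reads" does not by itself
name a subsampling procedure, and proportional scaling is deterministic and
preserves proportions exactly. Seeded subsampling without replacement is
provided for parity with common practice and is reproducible under a fixed
seed.

Universal 16S primers can miss archaea entirely while qPCR shows them
dominant. The qPCR projection displays each bacterial taxon at
`relative% x f`, `f = bact/(bact + arch)`, plus one pooled archaeal block
of `100 (1 - f)`%, conserving the 100% total. The archaeal side is a single
block because primer-invisible taxa cannot be resolved. Projection is
applied after rank aggregation and the minimum-abundance legend filter
(default 1% in at least one sample; optional top-n truncation), so the
filter operates on within-domain proportions — the order matters and is
fixed here. Ordination (MFA/NMDS) is deliberately out of scope; the package
exports the standardized indicator matrix and normalized abundance tables
that external tools consume.

## The synthetic generator

The generator exists so every stage can be validated against known ground
truth without access to raw instrument data. It is budget-consistent, not
kinetic: no growth or electron-transfer mechanism is modeled.

* **Trace**: `|i(t)| = baseline + plateau * logistic(t; midpoint, rate)`,
  with the plateau rescaled so the discrete integral of the biotic term
  equals the scenario's cathode draw exactly; optional multiplicative
  Gaussian noise; recorded cathodic-negative.
* **Chemistry**: product deltas invert the CE formula so that
  `sum(F ne d[P] V) = efficiency x sum(donor draws)` exactly; formate and
  thiosulfate trajectories realize their draws (with 2:1 sulfate
  co-production); COD endpoints are consistent with the yeast-extract draw,
  product CODs, and any configured biomass gain. Trajectories follow the
  same logistic ramp, sampled daily.
* **Biology**: lognormal qPCR copies around configured log10 medians, one
  multinomial draw per sample over the scenario's taxon profile, ordinal
  biofilm scores.

Randomness is scoped: each reactor derives its own substreams from
`(master_seed, reactor_id)`, so datasets are reproducible and independent
of reactor order, and generation never perturbs the caller's RNG state.

Preset magnitudes are set once from the ranges reported for 6-day cathodic
enrichments — fold increases between 1 and 17, total produced acids below
2.9 mM, 16S copies up to ~10¹⁰/cm², depths between 500 and 300,000 reads —
with donor draws of 200 C (electrotroph, efficiency 1), 100 + 150 + ~772 C
(electro-fermenter, 0.8), 200 C yeast extract (fermenter, 0.85), and 700 C
formate (methylotroph, 0.85). Noise defaults are 5% relative sd on current
samples (SNR 20), 5% CV on concentrations, 0.005 g O₂/L sd per COD
measurement, and 0.3 sd on log10 qPCR copies — typical instrument
performance for potentiostats, HPLC/IC at mM scale, cuvette COD kits, and
qPCR respectively.

What the generator does *not* emulate — and therefore what passing recovery
tests do not show about real data: membrane crossover losses, pH drift and
speciation, abiotic formate decomposition at high temperature, biofilm
detachment transients, chimeras and primer bias in sequencing, and any
correlation structure between indicators beyond the shared budget. Recovery
rates on synthetic data are a validity check of the arithmetic and the
classification logic, not a sensitivity claim for real reactors.

## Numerical choices and degenerate inputs

* F = 96,485 C/mol, R = 8.314 J/(mol K); SI units internally, mM / g O₂/L /
  days only at the I/O boundary.
* j₁ₕ with no sample at 3600 s: linear interpolation; trace shorter than
  1 h: error.
* Zero baseline: fold increase reported missing, never infinite. Zero
  cathode charge: CE reported missing.
* All-zero indicator column: activity component 0 for every reactor rather
  than 0/0.
* Zero qPCR signal in both domains: sample flagged, not projected.
* Degenerate windows, non-monotone timestamps, negative concentrations,
  biofilm outside 0–5, unknown acceptor tokens: rejected at construction
  with messages naming the offending row or the allowed values.
* Problem sizes in the shipped tests and acceptance script: traces sampled
  at 120 s over 6 days (4,321 points), 100 synthetic experiments of 5
  reactors for the noisy recovery estimate, 10 for the noiseless one —
  sizes at which the recovery proportion's sampling error is small against
  the 90% acceptance margin.

## Known limitations

The budget is endpoint-based: it cannot see transient production/
reconsumption cycles within the run. The cathode term includes the abiotic
baseline charge, which slightly inflates the denominator of CE in weakly
active reactors (the biocoulombs column quantifies exactly this gap). H₂
feasibility is an equilibrium statement with a lump overpotential, not a
rate prediction. The thiosulfate stoichiometry gate is binary; partial
sulfur cycling (e.g. to elemental sulfur) would be scored as "not a donor".
Proportional depth normalization produces fractional counts, which is
intentional for display purposes but means downstream tools expecting
integers should use the subsampling mode.
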