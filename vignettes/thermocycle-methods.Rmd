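---
title: "Methods: thermodynamic cycles for copper-peptide thermochemistry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic cycles for copper-peptide thermochemistry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuabthermo)
```

## The model

`cuabthermo` turns per-species quantum-thermochemistry components into
aqueous reaction free energies and electrochemical observables for
copper-peptide coordination equilibria, with the copper/amyloid-beta
model-ligand system as its packaged worked example. The thermodynamic
cycle is the standard one: compute everything in the gas phase, transfer
each species into water with a solvation free energy, and read off the
aqueous reaction free energy as

$$\Delta G_{(aq)} = \Delta G_{(g)} + \Delta\Delta G_{solv}.$$

### Species free energies

For each species the gas enthalpy is assembled from a composite electronic
energy and vibrational corrections,

$$H_{(g)} = E_{comp} + 0.9806\,ZPE + H_{therm},\qquad
E_{comp} = E_{MP2/SB} + E_{B3LYP/LB} - E_{B3LYP/SB},$$

all in hartree and converted at 1 hartree = 2625.50 kJ/mol. The composite
scheme approximates a large-basis MP2 energy by adding the B3LYP
basis-set extension to a small-basis MP2 calculation; it recovers
dispersion that B3LYP misses while keeping the large-basis cost at the
cheaper level. Only the zero-point energy is scaled (by the conventional
harmonic factor 0.9806); the thermal enthalpy correction and the
entropies are used as computed.

The entropy receives two additive corrections before forming
$G_{(g)} = H_{(g)} - T S$:

* **conformational mixing**, $R\ln(n)$, where $n$ is a rotamer-count
  estimate of the number of thermally accessible conformers — a cheap
  surrogate for a conformational ensemble average; and
* **standard state**, $R\ln(1/24.46)$ = −26.58 J mol⁻¹ K⁻¹, converting
  the 1 atm ideal-gas convention to 1 M (+7.93 kJ/mol in $G$ at
  298.15 K). It is applied to every species, including water: the water
  concentration convention is carried entirely by water's experimental
  solvation free energy, so adding the term uniformly keeps the
  bookkeeping composable (it can be disabled per run by overriding
  `standard_volume = 1`).

Solvation free energies come from upstream continuum (IEFPCM) runs and
enter as data. Two experimental overrides are always applied:
$\Delta G_{solv}(H^+) = -1107$ kJ/mol, and $-16.2$ kJ/mol for water (a
value that folds in water's 55.6 M concentration, which is why released
waters never attract an extra concentration term). The electron is a
pure bookkeeping pseudo-species with zero energy everywhere.

Whether the 1 M standard-state term should also be carried by the
proton's gas free energy, or regarded as absorbed into the −1107 kJ/mol
convention, is not decidable from the packaged reaction-level data (which
starts from reaction sums); the package computes the proton like any
other species and documents the ambiguity here rather than guessing. None
of the shipped results depend on it.

### Reactions, pH, and electrochemistry

Reaction-level quantities are Hess sums (products minus reactants) of the
per-species values, over explicitly balanced stoichiometries: element
counts must conserve and charge must conserve with electrons counted at
−1 on the reactant side. The five reported columns are ΔH(g), −TΔS(g),
ΔG(g), ΔΔG_solv and ΔG(aq).

The pH enters only through the explicit operation
`ph_adjust(dG, n, pH)` = $\Delta G - n\,RT\ln(10)\,\mathrm{pH}$ for $n$
net released protons (−39.96 kJ/mol per proton at pH 7), never silently.
Reduction potentials follow

$$E^\circ = -\frac{\Delta G_{(aq)} - \Delta G_{SHE}}{F},\qquad
\Delta G_{SHE} = -418\ \text{kJ/mol},$$

with the electron ignored on both sides. Any half reaction that takes
copper from +2 to +1 receives an empirical +57 kJ/mol correction (once
per electron) before conversion; it absorbs the correlation error in the
second ionization energy of copper at this level of theory and shifts
every such potential by exactly −0.591 V. The correction is described
upstream as enthalpic, but with entropy unchanged its free-energy effect
is identical, so the package applies it to ΔG(aq); this convention
reproduces every potential derivable from the packaged table's
uncorrected column. Conditional potentials use the Nernst form with
$Q = 10^{\mathrm{pH}\cdot n}$ for $n$ consumed protons:
$E^{\circ\prime} = E^\circ - 0.4141\,n$ V at pH 7. Binding constants and
pKa values are the closed forms
$\log_{10}K = -\Delta G/(RT\ln 10)$ and $pK_a = \Delta G/(RT\ln 10)$,
with $RT\ln 10 = 5.708$ kJ/mol.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `temperature` | 298.15 | K | all thermal terms ("298 K" convention) |
| `zpe_scale` | 0.9806 | — | harmonic ZPE scaling |
| `standard_volume` | 24.46 | L/mol | 1 atm → 1 M entropy term |
| `dGsolv_proton` | −1107 | kJ/mol | experimental proton solvation |
| `dGsolv_water` | −16.2 | kJ/mol | experimental water solvation (55.6 M folded in) |
| `dG_SHE` | −418 | kJ/mol | SHE half-reaction reference |
| `cu_redox_correction` | +57 | kJ/mol | Cu(+2→+1) correlation correction |
| `hartree_to_kjmol` | 2625.50 | kJ/mol | energy conversion (not stated upstream; CODATA value, configurable) |

All constants live in one `cu_constants()` object and are overridable per
run; derived quantities (RT ln10, the 0.4141 V proton term) are computed
on demand and never stored rounded.

## The packaged dataset and its audit

The 45 packaged reactions carry the five printed columns at 0.1 kJ/mol
precision. Two identities should hold per row: ΔG(g) = ΔH(g) + (−TΔS(g)),
and ΔG(aq) = ΔG(g) + ΔΔG_solv − 39.96·n for the n protons a non-reduction
row releases (reduction rows store the unadjusted value; their pH
handling lives in E°′, and the +57 correction is not folded in). The
audit (`check_internal_consistency()`) verifies both identities at a
0.15 kJ/mol tolerance — 0.1 kJ/mol printed precision plus headroom for
chained rounding — and scans for duplicated rows. Exactly three rows
fail and are shipped as annotated anomalies rather than corrected:

* `EEq16a`: ΔH + (−TΔS) misses ΔG(g) by 6.2 kJ/mol;
* `EEq16c`: the identity holds only with the proton moved to the other
  side — a direction/sign inconsistency, matching a sign discrepancy
  between the printed equation and its table row (the product name in
  that row also looks like a typo for the Asp1-imidazole complex);
* `EEq29a`: numerically duplicates the imidazole-association row
  `EEq26`, which is incompatible with its reduction stoichiometry, so no
  potential is derived from it.

Two reduction rows as printed also drop an imidazole product that their
element balance requires; the machine-readable stoichiometries store the
balanced reading while `reaction_string` keeps the printed text. The
model-species compositions used for balance checking were assigned once
from the structure names and are bookkeeping metadata, not measured data.

Comparisons against printed values round half-away-from-zero to the
printed precision and use tolerances of 0.15 kJ/mol, 0.015 V and 0.1
log-unit (1 kJ/mol for the one value printed only as an integer at
pH 6). The printed site pKa values (13, 10, 11) require species-level
data that is not part of the reaction-level table, so they are not
regenerated; the pKa conversion is pinned by closed-form tests instead.

## The synthetic generator

`generate_species()` emulates the statistical shape of a real
species-level input table: electronic energies of order −10³ hartree (so
a hartree/kJ confusion fails tests by five orders of magnitude), ZPE in
(0.02, 1) hartree, thermal corrections in (0.002, 0.1) hartree, gas
entropies in (100, 1000) J mol⁻¹ K⁻¹, conformer counts 1–8, and
solvation free energies in (−1200, 0) kJ/mol whose magnitude increases
with charge² in disjoint bands (neutral < |q|=1 < |q|=2), as continuum
models predict for small ions. `generate_reactions()` builds each
product's composition from its reactants' total minus emitted waters and
protons, so balance holds by construction; a requested fraction are
one-electron copper reductions. All draws come from one seeded RNG and
the seed is recorded in every output header; a given seed is
byte-reproducible.

What the generator does **not** emulate: correlations between energy
components of related species (each species is drawn independently),
realistic conformer ensembles, or the near-cancellation between ΔG(g)
and ΔΔG_solv that real charged reactions show. Passing synthetic tests
therefore demonstrates correct arithmetic, bookkeeping and
serialization — not chemical accuracy, which is carried by the packaged
dataset comparisons.

The brute-force oracle (`oracle_reaction_thermo()`) recomputes every
reaction quantity in one naive, self-contained loop that shares no code
with the engine; tests require agreement within 1e−9 kJ/mol over 500
seeded reactions. Test problem sizes (25-species tables, 100-reaction
batches, 1000-draw property loops) keep the whole suite under half a
minute while exercising every code path.

## Numerical choices and edge cases

* Unicode minus signs (U+2212) and typeset spaces are accepted in all
  numeric input cells — the source tables use them — and normalized to
  ASCII; output is always ASCII, locale-independent.
* Reactions auto-cancel species appearing on both sides; identity
  reactions yield exact zeros; reversal negates every field.
* `reverse_reaction()` refuses reduction half-reactions (the electron
  cannot move to the product side in this representation); reversal
  antisymmetry for them is still guaranteed by the linearity of the Hess
  sum and is tested through the chemical rows.
* An empty reaction file is reported as "no work", not an error.
* Malformed species rows are rejected with the file, row number, column
  and violated invariant named.
* The packaged table is integrity-checked (row count and a checksum over
  all energy columns) at load time.

## Known limitations

Kinetics, activity coefficients beyond the ideal-dilute pH term,
multi-temperature scans and any quantum-chemistry step are out of scope.
The ±15 kJ/mol accuracy expected of the upstream aqueous free energies
(and the ~0.1 V it implies for potentials) is inherent to the method, not
to this implementation; the package's own arithmetic is exact to
floating-point precision.
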