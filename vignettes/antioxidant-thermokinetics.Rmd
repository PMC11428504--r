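---
title: "Antioxidant thermochemistry and kinetics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antioxidant thermochemistry and kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscav)
```

## The model

A phenolic antioxidant ArOH can neutralise a free radical by three
thermodynamically distinct routes, each decomposable into enthalpic steps
evaluated from the enthalpies of the parent, its phenoxyl radical ArO·,
phenolate ArO⁻ and radical cation ArOH·⁺, plus three reference species:

* HAT — one concerted step, costed by the O–H bond dissociation enthalpy
  `BDE = H(ArO·) + H(H·) − H(ArOH)`;
* SET-PT — electron loss then proton loss, costed by
  `IP = H(ArOH·⁺) + H(e⁻) − H(ArOH)` and
  `PDE = H(ArO·) + H(H⁺) − H(ArOH·⁺)`;
* SPLET — proton loss then electron loss, costed by
  `PA = H(ArO⁻) + H(H⁺) − H(ArOH)` and
  `ETE = H(ArO·) + H(e⁻) − H(ArO⁻)`.

Because all three routes start at ArOH and end at ArO·, the sums satisfy
exact Hess identities: `IP + PDE = PA + ETE = BDE + C` with
`C = H(H⁺) + H(e⁻) − H(H·)` a phase-only constant. The package exploits
this twice: `check_hess_closure()` validates any descriptor table against
both identities, and the synthetic generator uses them to complete
partially specified targets.

The preferred mechanism compares the *committing* step of each route —
the minimal-site BDE for HAT, IP for SET-PT (site-free), and the
minimal-site PA for SPLET — and takes the argmin. Exact ties resolve in
the fixed priority HAT > SET-PT > SPLET and are flagged; the rule is a
deliberate design choice, since the comparison the classification mirrors
is stated without tie behaviour in the antioxidant literature.

Kinetics uses conventional transition state theory over a bimolecular PES
profile (separated reactants, pre-reaction complex RC, transition state,
post-reaction complex PC, separated products):
`k = σ κ (k_B T/h) exp(−ΔG‡/RT)`, with the Wigner tunnelling correction
`κ = 1 + (1/24)(h c ν̃ / k_B T)²` from the TS imaginary wavenumber ν̃.

## Conventions and tunable parameters

* **Units.** All energies are kcal/mol internally; hartree inputs are
  converted once at the file boundary with the CODATA-derived factor
  627.5094740631 kcal·mol⁻¹·hartree⁻¹. Wavenumbers are cm⁻¹,
  temperatures K.
* **Temperature** defaults to 298.15 K; **standard state** is 1 M, so a
  bimolecular TST rate constant carries units M⁻¹ s⁻¹ with no further
  conversion. Gibbs inputs referenced to 1 atm can opt into the
  `RT ln(R'T)` correction in `tst_rate()`.
* **Energy reference for kinetics.** ΔG‡ and ΔG are referenced to the RC
  by default (`activation_free_energy()`, `reaction_free_energy()`), with
  separated reactants/products selectable. A TS below its RC is flagged
  barrierless, not rejected.
* **σ and κ** default to 1 and are always carried in the output, so no
  degeneracy or tunnelling correction is ever applied silently. When a TS
  record carries an imaginary wavenumber, `rate_table()` computes κ by
  the Wigner formula.
* **Reference enthalpies.** H(H·), H(H⁺) and H(e⁻) per phase close the
  descriptor equations. Published solvation values for the proton and
  electron vary by convention, but the composite `C` is pinned by the
  bundled anthocyanin table itself (the spread of IP + PDE − BDE across
  its 19 rows per phase is only 0.1 kcal/mol), so the bundled defaults
  are calibrated to those observed constants — 313.33 (gas), 53.97
  (water), 47.02 (ethanol) kcal/mol — with the gas-phase H(H·) at the
  conventional electronic-plus-thermal value and the proton/electron
  split marked nominal in the provenance column. Any other level of
  theory is supported by loading a replacement table with
  `read_reference_enthalpies()`.
* **Closure tolerances.** 0.3 kcal/mol for printed one-decimal tables
  (four rounded summands), 1e-9 for species sets built in code.
* **Rendering.** Energies print at one decimal, rounded half away from
  zero to match the reference tables (base `sprintf` rounds half to even,
  which would misrender e.g. 86.25); rate constants print as a
  two-decimal mantissa with an explicit power of ten; absent values
  render "not computed".

## The bundled data

Two reference tables are transcribed verbatim from the published study of
the five grape-skin anthocyanin-3-O-glucosides: the 57-row descriptor
table (19 site rows × 3 phases) and the four-reaction ·OH H-abstraction
kinetics table for Pt-3-O-glc, plus the double-HAT channel costs for the
Pt-3-O-glc 4′-O radical. Two transcription caveats are preserved rather
than edited: (i) the source's table prints the Cy-3-O-glc gas-phase 4′-OH
BDE as 94.0 while its ranking text quotes 89.8 — both variants ship
(`table1_descriptors()` and `quoted_bde_ranking()`), and ranking runs
on whichever table it is given; (ii) the published absolute rate
constants are ~340× above plain TST at the printed barriers with
σ = κ = 1, implying degeneracy/tunnelling/reference conventions the
source does not state. The `k_ref` column is therefore treated as a
reference for *ordering* only; recomputed rate constants are always
labelled with their explicit σ/κ settings and never presented as a
reproduction of the published magnitudes.

## The synthetic generator

`make_species_set()` inverts the descriptor equations: parent at a base
enthalpy (default −1000 kcal/mol — arbitrary, since every descriptor is
invariant under a uniform enthalpy shift, a property the tests exercise),
radical at base + BDE − H(H·), cation at base + IP − H(e⁻), anion at
base + PA − H(H⁺). Targets given only as two-step pairs are completed
through the Hess identities; conflicting routes (beyond `tol`) reject the
row by name. `make_pes()` does the analogue for reaction profiles: RC a
configurable complexation energy (default 2 kcal/mol) below the separated
reactants, TS at RC + barrier, PC at RC + reaction energy.

The generator emulates *self-consistent* thermochemistry with optional
independent Gaussian noise on enthalpies (seeded, Mersenne-Twister with
inversion normals, fixed so seeds reproduce across platforms) — the
simplest stand-in for method error. It does not emulate the correlated
errors of a real DFT functional across related species, conformational
spread, or anharmonicity; passing round-trip tests therefore demonstrates
that the pipeline's algebra and bookkeeping are exact, not that any
particular level of theory is accurate. Regenerating the printed
Pt-3-O-glc block requires `tol = 0.3`, because one-decimal rounding makes
the printed rows violate the exact Hess identity by up to ~0.1 kcal/mol:
a rounded table is not exactly constructible from any single species set,
which is itself a useful illustration of the closure check.

## Problem sizes and determinism

The validation workload is deliberately small: the 57-row fixture, a
1000-row randomized round trip for the generator (machine-precision
recovery), 200 Monte-Carlo replicates for the noise model (the sd of a
descriptor under enthalpy noise σ is √2·σ, the difference of two
independent Gaussians), and 8-point grids for the TST monotonicity and
Eyring cross-check properties. Everything fixture-derived is
deterministic; every randomized check is seeded, and report writing is
byte-stable across reruns.

## Known limitations

* Descriptors come only from supplied thermochemistry or fixtures — no
  structure-based estimation, conformer search, or solvation modelling.
* Mechanism classification is purely thermodynamic; kinetic competition
  between routes is out of scope beyond the TST module.
* Tunnelling is Wigner-only (the correction named by the methodology this
  package post-processes); Eckart or small-curvature corrections are not
  implemented.
* Glycoside OH sites are representable but excluded from default
  descriptor enumeration, reflecting their inertness in the systems the
  bundled data covers; pass `exclude_pattern = "^$"` to include them.
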