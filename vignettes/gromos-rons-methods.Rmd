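---
title: "Methods: the GROMOS-RONS model and how ronsff evaluates it"
author: "ronsff authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the GROMOS-RONS model and how ronsff evaluates it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ronsff)
```

## The model and its assumptions

`ronsff` implements a united-atom GROMOS-type force field for fifteen
reactive oxygen and nitrogen species.  The functional form is the classical
GROMOS one: quartic bond stretching ¼K_b(b²−b₀²)², cosine-harmonic angle
bending ½K_θ(cos θ−cos θ₀)², harmonic impropers ½K_ξ(ξ−ξ₀)² (force constant
per rad², the deviation wrapped into (−180°, 180°]), proper dihedrals as a
cosine series ΣK_i[1+cos(m_iφ−φ₀ᵢ)] or a Ryckaert–Bellemans (RB) polynomial
ΣC_i cosⁱ(φ−180°), and pairwise Lennard-Jones plus Coulomb interactions.
The model's assumptions are those of the GROMOS family: fixed atom-centered
point charges (no polarization, no virtual multipole sites), nonpolar
hydrogens folded into heavy atoms, and bonds intended to be constrained at
b₀ — bond force constants in the database are placeholders and
`molecule_energy()` assigns constrained bonds zero energy regardless of the
instantaneous length.

Two conventions matter for reproducibility and are fixed at the interface:
dihedrals are signed IUPAC angles (φ = 0 at cis) in (−180°, 180°], and all
quantities use nm, kJ/mol, degrees and elementary charges, with the Coulomb
prefactor 1/(4πε₀) = 138.935458 kJ·mol⁻¹·nm·e⁻².

## The parameter database

The database bundles, as versioned structured text under
`inst/extdata/gromos_rons/`:

* the four RONS-specific nonbonded atom types (OP, OO, OQ, NQ) with √C₆ and
  up to three √C₁₂ repulsive slots plus modified 1–4 constants;
* the standard 53A6 partner-type constants the selection matrix refers to
  (only O, OM, NR, OW and the LJ-null polar H are engaged by the bundled
  species themselves);
* the two-sided C₁₂ slot-selection matrix.  For a pair (i, j) the cross
  C₁₂(i,j) is the product of one √C₁₂ slot of each type; the left half of
  the matrix selects i's slot, the right half j's.  Both halves are
  preserved verbatim, including their few asymmetric rows (P, SI, CL, BR),
  which are *not* redundant: the two halves answer different questions
  (which slot of the row type vs. which slot of the column type).  The
  OP–OQ pair resolves to slots (2, 3), the single pair for which the third
  OQ slot exists;
* the fifteen molecular topologies (atoms, charges, constrained bonds,
  angles, impropers, dihedral series), plus the quantum-reference charges
  kept as provenance-only metadata.

`validate_database()` asserts every structural invariant — mass
assignments, positive repulsion except for LJ-null types, full matrix
coverage with indices that resolve, combination-rule symmetry, net charges
equal to the formal charge to 10⁻⁶ e, disjoint exclusion/1–4 lists, and no
bond carrying both a GROMOS and an RB dihedral.

One transcription decision is worth recording: the ONOO⁻ nitrogen charge is
printed with a missing equals sign ("N q − 0.064 e"); it is read as
q = −0.064 e, the only reading for which the net charge is exactly −1
(−0.335 − 0.064 + 0.013 − 0.614).  Similarly, the HOONO N–O–O–H torsion is
printed as four terms all with multiplicity 1; it is interpreted as a
Fourier series with multiplicities 1, 2, 3, 4.  Under that reading the
torsion has its perp minimum near 91° and the classical conformer table is
reproduced quantitatively (see below); under the literal all-m=1 reading
the series collapses to a single cosine with no perp minimum at all,
contradicting the published conformer geometries.

## Exclusions and 1–4 interactions

Nonbonded bookkeeping is derived from the bonded graph, never stored:
first and second neighbors are excluded; third-neighbor pairs become
explicit 1–4 pairs with modified C₁₂ (and full charges — GROMOS modifies
only the repulsion) when the central bond of the connecting path carries a
cosine-series dihedral, and are fully excluded (both LJ and Coulomb) when
it carries an RB dihedral.  The RB reading of "excluded" as covering the
Coulomb part too is a deliberate choice; both halves of the 1–4 interaction
are generated or suppressed together.  Types absent from the modified 1–4
table fall back to their standard first-slot constants, the GROMOS
convention for non-carbon types; the polar H stays LJ-null everywhere.

## The rigid-bond geometry engine

Minimization operates in internal coordinates rather than Cartesian
constraint projection: a deterministic Z-matrix is derived from the bond
tree (breadth-first from atom 1), bonds stay exactly at b₀, and the free
variables are the placement angles and dihedrals — exactly 3N−6−(bonds)
degrees of freedom for these acyclic molecules.  Cartesian coordinates are
rebuilt by the natural-extension reference frame, so constraint
satisfaction is exact by construction, which is both simpler and more
robust than SHAKE-style projection for molecules of at most six atoms.

The optimizer is BFGS (`stats::optim`) with a fixed start, relative
tolerance 10⁻¹⁵, an iteration cap of 10⁴ and no randomness; convergence is
declared only when the numerically evaluated gradient norm falls below
10⁻⁶ kJ·mol⁻¹·deg⁻¹, and non-convergence is flagged on the result, never
silent.  Selected dihedrals can be pinned exactly (removed from the
variable set) or restrained harmonically.  Because the objective is smooth
and low-dimensional, tie-breaking never arises.

## The HOONO conformer table

The eight HOONO conformers start from the quantum-reference internals.
The all-planar conformers (cis-trans, trans-cis, trans-trans) are started
exactly at 0°/180° dihedrals, where the torsional gradient vanishes by
symmetry, and minimize freely; so do cis-cis, cis-perp and trans-perp,
whose perp minima the classical torsion genuinely possesses.  Two rows are
*restrained* stationary points:

* **cis-gauche** is not a stationary point of the classical surface — a
  free minimization from the gauche start slides into the perp basin
  (NOOH → 91°, ΔE → 1.40 kJ/mol).  It is therefore pinned at the
  quantum-reference dihedrals (ONOO = −7.5°, NOOH = 53.9°), which mirrors
  the calibration protocol of restraining the classical model to the
  quantum geometry; the resulting ΔE = 3.50 kJ/mol.
* **perp-perp** has its O–N–O–O dihedral on the barrier between the cis
  and trans basins; the quantum value (81.9°) lies on the *downhill flank*
  of the classical barrier (the bare-torsion stationary point is at
  arccos(−15.2364/105.8096) ≈ 98.3°), so pinning there would report an
  arbitrary slope point.  The spec pins perp-perp at the classical
  stationary region instead (ONOO = 95°, NOOH = 100.5°), i.e. at the
  classical model's own transition-state geometry, giving ΔE = 55.1
  kJ/mol.

A free minimization that drifts more than 30° from its start is flagged as
a basin escape in `conformer_table()` output.

## Thermodynamic post-processing

`ti_integrate()` integrates the two decoupling legs (Coulomb first, then
LJ) by composite trapezoid on the grids as given — the 21- and 51-point
lambda schedules these datasets come with argue for grid-faithful
integration rather than refitting; Simpson quadrature is available for
uniform odd-count grids.  The solvation free energy is the negated sum of
the two integrals, and the reported per-leg contributions carry the same
sign convention so the total is their exact sum.

The gas-phase trans-to-cis isomerization free energy ΔG_i of nitrous acid
is "read off" the O–N–O–H torsional potential.  Two readings are
implemented because the phrase is ambiguous: the default `minima` mode
(V at the cis minimum minus V at the trans minimum, 1.556 kJ/mol for
HNO₂) and a `boltzmann` mode (−RT ln of the ratio of basin partition
functions, integrating the bare torsion over each half-range).  With the
`minima` reading the two-conformer weighted hydration free energy

$$\Delta G_w = \Delta G_{w,trans} - RT\,\ln
  \frac{1 + e^{(-\Delta G_i + \Delta G_{w,trans} - \Delta G_{w,cis})/RT}}
       {1 + e^{-\Delta G_i/RT}}$$

evaluates to −17.02 kJ/mol from ΔG_w,trans = −18.0 and ΔG_w,cis = −11.2
at 298 K; the `boltzmann` mode converges to the `minima` mode as T → 0 and
is retained as an option rather than a default.  R = 8.314462618×10⁻³
kJ·mol⁻¹·K⁻¹ and T defaults to 298 K throughout.

## Topology emission

The emitter writes GROMACS-dialect text in C₆/C₁₂ form — converting to
σ/ε would destroy the multi-slot C₁₂ semantics — and writes every pair in
the selection matrix as an explicit `[ nonbond_params ]` row, because no
single combination rule can express the slot selection.  1–4 pairs are
likewise written explicitly with their pair-specific parameters.  Numbers
are formatted with `%.10g`, so re-parsing reproduces the database values
exactly and emission is byte-stable under write → read → write.  The 54A7
variant applies the bundled ion-row overrides and lipid-type renames and
differs from 53A6 only in those rows.  The reader targets exactly this
dialect, re-derives exclusions from the parsed bonded graph, and rejects
unknown directives and non-integer charge sums loudly.

## Solution analyses and the synthetic fixtures

`compute_rdf()` histograms minimum-image pair distances in orthorhombic
boxes and normalizes by the ideal-gas expectation per frame; the default
bin width of 0.002 nm resolves first-minimum positions.
`first_shell_cutoff()` smooths with a fixed three-bin moving average — a
deterministic, documented choice — and returns the first local minimum
after the global peak.  `degree_of_ionization()` counts an ion as paired
when at least one counterion lies within the cutoff; alternative
coordination-count definitions are out of scope.

The fixture generator emulates exactly the statistical structure each
analysis needs: Poisson-uniform particles (flat RDF), a simple-cubic
lattice (known neighbor shells), and ion/counterion configurations with an
exactly constructed paired fraction.  It does not emulate liquid
structure, solvent-shared ion pairs, or concentration-dependent screening
— so passing tests demonstrate the estimators' correctness, not the force
field's solution behavior, which requires external molecular-dynamics
sampling that this package deliberately does not perform.

## Numerical choices and problem sizes

Grids and sizes used by the tests and the acceptance script are small by
design and stated here as the package's own choices: torsional argmin
localization uses a 0.01° grid; torsional scans use 1–10° grids;
oracle-equivalence checks compare the energy model against a brute-force
pair enumeration on 100 random conformations per species at 10⁻⁹ relative
tolerance; RDF fixtures use a few hundred particles over a handful of
frames.  Everything is deterministic except the fixture generator and the
random-conformation tests, which run under fixed seeds.

## Known limitations

* **Peroxynitrite cis/trans ordering.**  The adjusted O–O–N–O dihedral
  potential places trans 15.0 kJ/mol above cis with a ≈ 92 kJ/mol barrier,
  mirroring the ab initio picture.  In the *full* gas-phase model,
  however, the 1–4 Coulomb repulsion between the two negatively charged
  terminal oxygens (−0.335 e and −0.614 e; +102 kJ/mol at the compact cis
  minimum vs. +81 kJ/mol at trans) overwhelms that preference and places
  trans 10.2 kJ/mol *below* cis.  This is an intrinsic property of the
  point-charge parameter set under the stated 1–4 rule, not an evaluation
  artifact — the energy model matches an independent brute-force oracle to
  10⁻⁹ — and it matters only for gas-phase conformer populations; in
  solution the torsional barrier keeps the two states kinetically separate
  anyway.
* Gas-phase, single-molecule evaluation only: no periodicity, cutoffs or
  mean-field solvent; condensed-phase observables require exporting the
  topologies to an external engine.
* The conformer machinery assumes acyclic molecules (true of all fifteen
  species) and does not search conformer space globally; the conformer
  list is user-specified.
* Partner-type constants beyond those engaged by the bundled species are
  carried for emission completeness; computed energies of the fifteen
  species never depend on them.
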