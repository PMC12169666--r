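# ronsff — a GROMOS-compatible force-field toolkit for reactive oxygen and nitrogen species

Reactive oxygen and nitrogen species (RONS) — H₂O₂, O₂, HO₂·, HO·, O₃,
N₂O₄, ·NO₂, ·NO, HOONO, HNO₃, HNO₂ and the NO₃⁻, NO₂⁻, ·O₂⁻ and ONOO⁻
anions — drive redox biology, plasma medicine and atmospheric chemistry,
but standard biomolecular force fields do not cover them.  `ronsff` bundles
a validated, machine-readable united-atom GROMOS-type parameter set for
these fifteen species and the machinery to use, check and export it.

## The model

The potential energy is the GROMOS functional form:

- bonds (used with length constraints): V = ¼ K_b (b² − b₀²)²
- angles: V = ½ K_θ (cos θ − cos θ₀)²
- impropers: V = ½ K_ξ (ξ − ξ₀)², K_ξ per rad²
- proper dihedrals: V = Σᵢ K_i [1 + cos(mᵢ φ − φ₀ᵢ)], or a
  Ryckaert–Bellemans polynomial V = Σᵢ Cᵢ [cos(φ − 180°)]ⁱ
- nonbonded: V = C₁₂/r¹² − C₆/r⁶ + q_i q_j /(4πε₀ r)

C₆ combines geometrically; C₁₂ is special: each atom type carries up to
**three** repulsive √C₁₂ slots, and a two-sided selection matrix picks which
slot of each partner enters a given pair.  First and second bonded
neighbors are excluded; third neighbors (1–4) interact with *modified* C₁₂
when spanned by a cosine-series dihedral and are fully excluded when
spanned by an RB dihedral.  Units everywhere: nm, kJ/mol, degrees, charges
in e; 1/(4πε₀) = 138.935458 kJ·mol⁻¹·nm·e⁻².

On top of the parameter database the package provides:

- `molecule_energy()` — gas-phase energy with a term-by-term breakdown;
- `minimize_rigid_bonds()`, `conformer_table()`, `torsion_scan()`,
  `fit_dihedral_terms()` — a rigid-bond internal-coordinate geometry
  engine for conformer analysis and dihedral calibration;
- `ti_integrate()`, `heat_of_vaporization()`,
  `torsional_isomerization_dG()`, `conformer_weighted_dGw()` —
  thermodynamic post-processing of thermodynamic-integration data;
- `write_species_topology()`, `write_nonbonded_tables()`,
  `read_species_topology()` — a GROMACS-dialect topology emitter with a
  round-trip reader (53A6 and 54A7 variants);
- `compute_rdf()`, `first_shell_cutoff()`, `degree_of_ionization()` —
  solution-structure analyses of coordinate trajectories, plus
  `generate_fixture_frames()` for synthetic test systems.

A thin command-line front end is installed at `exec/ronsff`
(`validate`, `conformers`, `scan`, `ti-integrate`, `write-top`,
`write-nonbonded`, `rdf`, `ionpairs`).

## Worked example

Peroxynitrous acid (HOONO) has two coupled torsions whose interplay
produces eight conformers.  Reproduce the classical conformer table:

```r
library(ronsff)
top <- get_topology("HOONO")
tab <- conformer_table(top, hoono_conformer_specs(top))
tab[, c("label", "delta_e", "ONOO", "NOOH")]
#>          label   delta_e       ONOO          NOOH
#> 1      cis-cis  0.000000    0.00000  0.000000e+00
#> 2   cis-gauche  3.502886   -7.50000  5.390000e+01
#> 3     cis-perp  1.399378   -2.47290  9.103681e+01
#> 4    cis-trans 12.308078    0.00000  1.800000e+02
#> 5    perp-perp 55.108428   95.00000  1.005000e+02
#> 6    trans-cis 25.036982  180.00000 -7.086528e-31
#> 7   trans-perp 13.361344 -179.01866  1.029513e+02
#> 8  trans-trans 20.978522  180.00000  1.800000e+02
```

`delta_e` is the energy (kJ/mol) of each rigid-bond-minimized conformer
relative to the cis–cis global minimum; `ONOO`/`NOOH` are the minimized
dihedrals in degrees.  The planar conformers are stationary by symmetry;
cis-gauche and perp-perp are restrained stationary points (see the
vignette).  The hydrogen-bond-like 1–5 electrostatic contact makes cis–cis
the global minimum, and the perp states sit only 1.4 kJ/mol above it.

The nitrous-acid conformer average works the same way end to end:

```r
dGi <- torsional_isomerization_dG(get_topology("HNO2")$dihedrals[[1]]$c)
conformer_weighted_dGw(dGw_trans = -18.0, dGw_cis = -11.2, dGi = dGi, T = 298)
#> [1] -17.02411
```

Here `dGi = 1.556 kJ/mol` is read directly off the O–N–O–H torsional
potential (trans is the gas-phase minimum), and the weighted hydration
free energy lands at −17.0 kJ/mol.

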