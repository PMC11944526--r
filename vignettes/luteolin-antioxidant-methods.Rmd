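---
title: "Methods: QTAIM topology and antioxidant thermochemistry with phenolox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTAIM topology and antioxidant thermochemistry with phenolox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolox)
```

## Scope and model

`phenolox` implements the post-quantum-chemistry analysis layer of a
density-functional study of a phenolic antioxidant (the flavone luteolin is
the worked system throughout): everything that happens *after* the
electronic-structure program has produced densities, orbital energies and
enthalpies. Five strands are covered.

1. **QTAIM topology.** The electron density ρ(r) is treated as a scalar
   field; bonding is characterised at its (3,−1) stationary points — bond
   critical points (BCPs). At a BCP we collect ρ, the Laplacian ∇²ρ, the
   Lagrangian kinetic energy density G, the potential energy density v, the
   total energy density h = G + v and the covalency ratio |v|/G.
2. **Hydrogen-bond energetics.** Binding energies follow the linear
   density calibration BE = a·ρ + b (kcal/mol); interactions are
   classified from (∇²ρ, h, |v|/G, ρ) into moderate partially covalent
   H-bonds, weak noncovalent H-bonds, van der Waals contacts and covalent
   (shared-shell) bonds.
3. **Conceptual DFT.** From frontier energies, with I = −E(HOMO) and
   A = −E(LUMO): hardness η = (I−A)/2, chemical potential μ = −(I+A)/2 =
   −χ, electrophilicity ω = μ²/2η. The molecular electrostatic potential
   V(r) = Σ Z/|r−r_α| − ∫ρ/|r−r′| feeds a molecular polarity index (MPI),
   the area-weighted mean of |V| over a density isosurface.
4. **NBO E(2).** Donor→acceptor hyperconjugation energies
   E(2) = n·F²/(ε* − ε), reported as positive magnitudes in kcal/mol.
5. **Radical-scavenging thermodynamics.** From per-site enthalpy ledgers:
   BDE (HAT), IP and PDE (SET-PT), PA and ETE (SPLET), all in kcal/mol,
   with the preferred abstraction site the BDE argmin and the preferred
   mechanism the argmin of the compound minima of {BDE, IP+PDE, PA+ETE}.
   The explicit-water effect is summarised by per-site and mean percent
   BDE changes and the change in the *sample* (n−1) standard deviation.

Internal units are Hartree and Bohr everywhere; kcal/mol and Å appear only
at report boundaries (1 Hartree = 627.509 kcal/mol, 1 Bohr = 0.529177 Å).

## Densities: grids and promolecular stand-ins

Self-consistent densities arrive as Gaussian-style cube files. The reader
supports both circulating dialects (positive voxel counts → Bohr, negative
→ Å, negative atom count → single-orbital cube); the writer always emits
Bohr with 17 significant digits so that read/write round trips are
bit-exact in the values.

Because SCF densities are not reproducible at desk scale, the testable
stand-in is a *promolecular* field: a sum of spherical single-exponential
atomic densities ρ_elem(r) = A·exp(−r/λ). The packaged (A, λ) table is a
transparent constant — it gives chemically sensible relative magnitudes and
strict positivity, and is not a physics claim. Promolecular fields are
differentiated analytically; grid fields use separable tricubic
(Catmull–Rom) convolution, which is C¹, interpolating, and differentiated
analytically within cells. The Hessian is the exact second derivative of
the interpolant; it is piecewise continuous, which is sufficient for the
damped Newton search. A one-voxel margin is enforced and extrapolation
refused.

Numerical characteristics worth knowing (all asserted in the test suite at
the stated fixtures): analytic promolecular gradients agree with central
differences at step 1e−3 Bohr to better than 1e−6 relative away from
nuclei; grid-interpolant derivatives reach the same band on fields the
grid actually resolves (the kernel has approximation order 3, so
under-resolved, sharply decaying fields saturate nearer 2e−6); the
interpolant does not go negative on smooth fixtures beyond 1e−12.

## The BCP search

`find_bcp()` runs damped Newton iteration on ∇ρ: tolerance 1e−8 a.u. on
the gradient norm, at most 200 steps, step halving whenever a trial point
would leave the domain, make ρ negative, or grow the gradient norm
ten-fold. Rank and signature come from Hessian eigenvalues with a 1e−10
magnitude threshold. Exponential promolecular atoms have density cusps at
the nuclei (the tangential curvatures diverge), so an iterate entering a
small capture radius (1e−3 Bohr) of a nucleus is reported as a nuclear
attractor — rank 3, signature −3 — rather than letting Newton work on a
singular Hessian. Search seeds are the midpoints of H⋯acceptor pairs
closer than 3.5 Å with donor angle above 90°, bounds that bracket every
tabulated luteolin contact (max length 2.34 Å, min angle 118.4°).

The independent oracle for the finder is geometric: for equal diatomics
the BCP must sit on the bisector plane; for unequal ones a 10⁴-point scan
of ρ along the internuclear axis (with parabolic refinement of the
discrete argmin, which removes the half-spacing quantisation) supplies the
reference position.

## Supplied vs derived topological parameters

When a table supplies G and v (as the packaged luteolin–solvent table
does), the supplied values take precedence; the density-only closed forms
are cross-checks. G from density alone uses the Abramov estimate
G = (3/10)(3π²)^(2/3) ρ^(5/3) + ∇²ρ/6, which lands within 3e−4 a.u. of the
tabulated wavefunction value on the strongest water contact; v then
follows from the local virial relation v = ∇²ρ/4 − 2G.

Two published calibrations of BE vs ρ coexist and must not be mixed. The
published intramolecular regression (slope −223.08, intercept 0.7423)
reproduces the intramolecular H-bond (−8.7 kcal/mol at ρ = 0.0425) but
*not* the solvent-table BE column; refitting BE ~ ρ over the 25 table rows
(`fit_be_coefficients()`) recovers the calibration that table actually
encodes (slope ≈ −332, intercept ≈ −1.06, R² > 0.9999). The ingest
pipeline flags BE cells that differ materially (> 0.1 kcal/mol) from
whichever calibration is configured instead of silently matching either.

Classification thresholds — ρ cutoff 0.015 a.u. between weak H-bond and
van der Waals, ratio bounds 1 and 2 — are fixed constants exposed in the
run configuration. They reproduce both tabulated verdicts for luteolin:
the moderate, partially covalent intramolecular H-bond (ρ = 0.0425,
h = −0.0034, |v|/G = 1.1) and the van der Waals contact in the radical
table (ρ = 0.0121, h = +0.0012, |v|/G = 0.9). Table-matching report mode
rounds a.u. columns to 4 decimals, ratios to 1, BE to 2, half away from
zero.

## MEP, isosurface and MPI

The nuclear term of V(r) is an exact Coulomb sum; the electronic term over
a grid is midpoint quadrature per voxel, with the kernel distance floored
at 0.6 voxel diagonals to regularise the voxel containing the evaluation
point. On a unit Gaussian cloud sampled at 61³ over ±6 Bohr the quadrature
matches −erf(√α·r)/r to 1e−4 a.u. at radii ≥ 2.8 Bohr; closer in, the
singular-voxel regularisation dominates and the stated tolerance is no
longer guaranteed — the acceptance checks therefore probe outside that
radius. Points within 0.05 Bohr of a nucleus are rejected by index.

Isosurfaces are extracted by marching tetrahedra (each voxel split into
six tetrahedra, linear interpolation along edges), yielding triangle
centroids and areas; the default isovalue is 4e−4 electrons/Bohr³, the
customary molecular-surface contour. The MPI is the area-weighted mean of
|V| (reported in kcal/mol); the polar fraction is the percentage of area
with |V| at or above a threshold whose default is the surface-mean |V|
itself — the published polar-area criterion is unstated, so the threshold
is explicit configuration and no published polarity value is treated as a
target. Reproducing published MPI values (12.68 / 23.09 / 8.15 kcal/mol)
requires SCF densities and is out of scope.

## Enthalpy ledgers and the mechanism table

Ledgers are ingested long-format (one species per row) because sites carry
two to four species depending on mechanism. The H•, H⁺ and e⁻ reference
enthalpies are required explicit inputs, never baked-in constants: the
source study does not state the values it used, and every descriptor
depends on them only through the combination
offset = (H_H⁺ + H_e⁻ − H_H•), which fixes both sums via
IP + PDE = PA + ETE = BDE + offset.

That identity is also why the two printed sum columns of the reference
table cannot both be replayed by one consistent ledger: the printed
PA+ETE sits exactly 2.989 kcal/mol above BDE on every row of every
compound, while the printed IP+PDE sits a further constant 0.071 kcal/mol
higher on the luteolin rows (and wildly higher for two of the commercial
additives — offsets 8.8 and 14.3). The replay ledger
(`luteolin_ledger()`) therefore targets the PA+ETE offset; the printed
IP+PDE column ships untouched as fixture data, flagged in the table
header. The sample (n−1) standard deviation is used for the water-effect
dispersion because only that convention reproduces the tabulated 5.04 →
5.40 kcal/mol (population SDs give 4.37/4.68).

## Synthetic generators

All fixtures are generated in code, deterministically from (spec, seed):

* `make_diatomic_density()` — promolecular diatomics whose BCP is known by
  construction (symmetry) or by the stored line-scan oracle;
* `make_ledger()` — inverse-constructed ledgers hitting prescribed BDE/IP/PA
  targets to 1e−10 kcal/mol, with seeded, non-degenerate base enthalpies
  that cancel in every descriptor (the generator restores the caller's RNG
  stream);
* the verbatim reference tables, shipped as commented CSVs with printed
  row labels preserved — including the duplicated "VI" label in the water
  block, disambiguated as `VI_a`/`VI_b`.

What the synthetic fixtures do *not* emulate: SCF densities (no shell
structure, no density depletion in lone-pair regions), solvation, spin
densities, or thermal/vibrational corrections. Green tests therefore
demonstrate the correctness of the *analysis layer* — parsing, topology,
calibration arithmetic, thermochemical bookkeeping and statistics — not
the quality of any electronic-structure model.

## Problem sizes and determinism

The suite runs diatomic topology searches, 41³–61³ grids, 10⁴-point line
scans, and 100-seed ledger batteries; these sizes were chosen as the
smallest at which every stated tolerance is comfortably exercised. All
randomness is seeded; pipeline outputs are byte-identical across repeated
runs with the same configuration.

## Known limitations

* Promolecular densities place diatomic BCPs by construction, but their
  absolute ρ values at BCPs are not comparable to SCF ones; classification
  on promolecular fixtures exercises the rules, not the chemistry.
* The tricubic kernel is C¹: Hessians are discontinuous across cell faces,
  and signature assignments for near-degenerate critical points on coarse
  grids should be treated with caution (the eigenvalue threshold 1e−10 is
  configurable).
* Multi-orbital cube files and wavefunction formats (wfn/wfx) are not
  parsed; ring/cage critical-point enumeration and basin integration are
  out of scope.
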