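---
title: "Structural and thermodynamic analysis of cyclic-nucleotide binding domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural and thermodynamic analysis of cyclic-nucleotide binding domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnbdkit)
```

## Scope and model of the data

`cnbdkit` implements the quantitative analyses used to characterize
cyclic-nucleotide binding domains (CNBDs) from crystal structures and
isothermal titration calorimetry: protein–ligand contact geometry,
least-squares superposition with outlier rejection, torsion-based
conformational classification (cis/trans peptides, syn/anti glycosidic
angles), disulfide-candidate screening, per-residue B-factor profiles,
Matthews/solvent-content arithmetic, reference-model dihedral-restraint
selection, and one-site binding thermodynamics.

The central container is a *tidy atom table*: one row per atom with chain,
residue and atom identifiers, coordinates, occupancy and B-factor.
Everything downstream is a tibble, so results compose with ordinary
`dplyr` verbs and plot with `autoplot()` methods.  Coordinates are parsed by
`bio3d` (PDB and mmCIF); the package adds the crystal metadata (CRYST1 and
`_cell`/`_symmetry` items) that the atom parser does not expose.  Residue
numbering is kept exactly as deposited — author numbering is what published
distance tables and residue labels refer to — and alternate conformers are
retained on input, then reduced deterministically (highest occupancy, ties
broken alphabetically) inside every geometry function.

## Contact geometry

`find_contacts()` reports every protein-atom/ligand-atom pair within a
van-der-Waals reporting cutoff (default 4.0 Å, chosen just above the largest
distance conventionally printed as a van-der-Waals contact in this domain's
literature, 3.9 Å).  A pair is a hydrogen bond when both heavy atoms are
N or O and the distance is at most 3.5 Å.  No angular criterion is applied:
at the resolutions typical of these crystal forms there are no hydrogen
positions to define one, and published tables for this system report
distances only.  Sulfur is handled the way the field reports it: a Cys SG
within 3.5 Å of an N/O partner stays in the van-der-Waals class but is
flagged `extended_hbond`, matching the "extended hydrogen bond" language
used for the SG···N7 interaction with syn-configured purines.

Contacts are annotated with the three-part pocket map of the CNBD:
the phosphate binding cassette backbone amides and the conserved arginine
(site 1, residues 182–185 and 192), the bridging threonine (site 2, residue
193), and the β5 cis-peptide pair docking the purine ring (site 3, residues
172–173, with the hydrophobic neighbours 165 and 175 annotated
`near_site3`).  `pocket_distance_table()` condenses a contact list to the
published row convention, including reporting leucine CD1/CD2 as the minimum
under the key `CD(min)` — the published tables use a bare "CD" label that is
not a standard leucine atom name.

One published table cell (an arginine NH1 listed as contacting a ligand
atom also named "NH1") is chemically impossible for a cyclic nucleotide and
is shipped flagged in `reference_contact_distances()`; comparisons should
measure the coordinates rather than match that cell.

## Torsions and conformational classes

Dihedrals use the standard atan2 construction and are reported in
(−180°, 180°].  Classification windows:

* **omega** (CAᵢ–Cᵢ–Nᵢ₊₁–CAᵢ₊₁): cis when |ω| ≤ 30°, trans when
  |ω − 180°| ≤ 30° (wrapped), else ambiguous.  The 30° half-width is the
  standard crystallographic convention; links across chain breaks
  (C–N > 2.5 Å) are not classified.  Non-proline cis peptides are rare
  enough to be structurally meaningful, so each link carries an
  `involves_proline` flag.
* **glycosidic chi** (O4′–C1′–N9–C4 for purines): syn on the closed
  interval [−90°, +90°], anti otherwise (IUPAC convention).  A 10⁻⁹ degree
  guard keeps fixtures built exactly at ±90° on the syn side of the closed
  boundary despite floating-point wrap; ±90.0001° is anti.

Disulfide candidates are cysteine SG–SG pairs within 4.5 Å by default —
deliberately wider than the 2.05 Å bonded distance, because the interesting
case is a *reduced* pair positioned to form a bond upon oxidation.

## Superposition and restraint selection

`kabsch_fit()` is the closed-form SVD solution with determinant correction;
its RMSD is checked in the test suite against a brute-force
quaternion-parameterized minimization.  `align_with_rejection()` emulates
the outlier-rejecting alignments behind published "equivalent N Cα atoms"
counts: fit, drop pairs deviating more than 2.0 Å, refit, up to 5 cycles.
The exact protocols behind published counts are rarely stated, so matched
counts should be read as soft (±10 residues) and the cutoff and cycle cap
are configurable.  Pairing is by author residue number by default (all the
comparisons this package was built for are within one construct); a
global-sequence-alignment mode covers renumbered chains.

`select_reference_dihedrals()` implements the reference-model restraint
rule used in low-resolution refinement: a torsion from a higher-resolution
reference structure is selected only when the working model already agrees
with it within a threshold, 15° by default — the value used when refining
the lower-resolution structures this package's analyses target.  Deviations
are circular (wrapped to (−180°, 180°]); torsions with two-fold symmetric
termini (Asp χ2, Glu χ3, Phe/Tyr χ2) are compared modulo 180° so a
carboxylate or ring-flip nomenclature difference cannot disqualify an
otherwise identical torsion.

## Crystal arithmetic

`matthews_solvent()` computes the general triclinic cell volume, the
Matthews coefficient V_M = V / (operators × molecules per ASU × MW), and
solvent fraction 1 − 1.23/V_M.  Symmetry-operator counts come from a
built-in table of the space groups common for protein crystals; an unknown
symbol is an error rather than a guess.  For the hexagonal CNBD-A crystal
form (P6₂22, a = b = 107 Å, c = 171 Å, two molecules per asymmetric unit)
a length-based molecular weight for the 136-residue construct
(136 × 111.13 Da; the construct sequence is not part of this package) gives
a solvent fraction of about 0.74 — "over 75 %" at the few-percent
uncertainty a length-based MW carries.  `protein_mw()` accepts the explicit
sequence when available.

## One-site ITC model

`simulate_titration()` implements the single-site total-heat construction:
after injection *i*, with total concentrations Mᵢ (macromolecule) and Xᵢ
(ligand) under the constant-volume displacement-dilution rule,

$$Q_i = \frac{n M_i \Delta H V_0}{2}\left[1 + \frac{X_i}{nM_i} +
\frac{1}{nK_aM_i} - \sqrt{\Big(1 + \frac{X_i}{nM_i} +
\frac{1}{nK_aM_i}\Big)^2 - \frac{4X_i}{nM_i}}\,\right]$$

and the measured heat of injection *i* is
$q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2$.  The default design is
the published one for this system: 15 µM macromolecule, 250 µM ligand,
5 µl injections at 30 °C.  Two constants are not stated in that
publication and are package defaults, both configurable: the active cell
volume (1.43 ml, the nominal volume of the instrument used) and the
injection count (28, which brings the final molar ratio to ≈ 1.65, a
normal endpoint for a sigmoidal isotherm).

`fit_one_site()` minimizes per-injection heat residuals over (n, log Kₐ,
ΔH) with damped least squares (`minpack.lm`), a deterministic automatic
initializer (n = 1, ΔH from the first normalized heat, Kₐ from the width of
the transition region), and honest convergence reporting.  Derived
quantities follow ΔG = −RT ln Kₐ (R = 1.987 cal mol⁻¹ K⁻¹) and
ΔS = (ΔH − ΔG)/T.  The Wiseman c value (n Kₐ M₀) is reported prominently:
at the published design c ≈ 1250 for the tighter ligand, which is beyond
the classical 1–1000 window where Kₐ is well determined — visible in the
fit as a large relative Kₐ standard error under noise.  Parameter-recovery
statements therefore rest on noiseless or low-noise synthetic data, where
the fit recovers generating parameters to 0.1 % across c ∈ {1, 10, 100,
1000}.

A note on published numbers: recomputing ΔS from a published (Kd, ΔH, T)
triple reproduces the published ΔS only to the precision those inputs were
rounded to.  For the tighter ligand here, Kd = 12 nM and
ΔH = −12.5 kcal/mol at 303.15 K give ΔS = −5.0 cal mol⁻¹ K⁻¹ against a
printed −4.7; the package reports the recomputed value.

## Synthetic fixtures

The generator module builds every structural fixture the test surface needs,
offline, from internal coordinates via natural-extension placement
(`place_atom()`), so requested torsions are exact to 10⁻⁶ degree or better:

* `build_dipeptide(omega)` — ideal peptide geometry (N–CA 1.458 Å,
  CA–C 1.525 Å, C–N 1.329 Å) at any omega; used for cis/trans boundary
  tests.
* `build_purine_nucleotide(chi, base)` — planar idealized ribose + purine
  (+ optional 3′,5′-cyclic phosphate) at any glycosidic chi.  The sugar is
  an unpuckered pentagon: the fixtures exist for exact torsions and
  plausible contact geometry, not chemical-grade models.
* `perturb_chain(model, sigma, ...)` — seeded Gaussian coordinate noise
  plus rigid transforms, the oracle substrate for superposition tests
  (post-fit RMSD → σ√3 for isotropic noise).
* `noisy_titration()` — forward-model curves plus seeded Gaussian heat
  noise.

Every stochastic fixture requires a seed and is byte-reproducible from it.
What the fixtures deliberately do not emulate: the real CNBD-A fold, real
crystal packing, correlated coordinate error, or real calorimeter
baselines.  Tests passing on fixtures therefore demonstrate the
correctness of the *measurement machinery*, not agreement with deposited
experimental structures; measurements against the deposited entries run
whenever the user supplies those coordinate files (see
`deposited_structure_path()`), and are reported as failures with
instructions otherwise.

## Numerical choices and edge cases

* Dihedrals on colinear or coincident points raise domain errors rather
  than returning NaN.
* Exactly −180° wraps to +180°; all angle differences are circular.
* Alt-loc reduction is deterministic (occupancy, then alphabetical).
* Rejection that would leave fewer than three pairs raises a
  rejection-collapse error rather than fitting a degenerate system.
* The fitter parameterizes log Kₐ for conditioning and reports standard
  errors from the local quadratic approximation at the optimum; they are
  indicative, not profile-based.
* Problem sizes in the shipped tests (chains of tens to a few hundred
  residues, 200 noisy titration replicates) were chosen as the smallest
  sizes at which the statistical oracles (σ√3 RMSD, median-Kₐ recovery)
  are stable.

## Limitations

* No symmetry expansion or biological-assembly generation: inter-molecule
  contacts are measured between chains as deposited.
* No hydrogen placement, energies, or solvent accessibility.
* The ITC module fits a single-site model only; no blank titration
  subtraction beyond discarding the first injection, no multi-site or
  competitive schemes.
* Matthews solvent content inherits the uncertainty of the supplied
  molecular weight; with a length-based MW it is a few-percent estimate.
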