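---
title: "Computational deep mutational scanning by mutation and minimization"
author: "mumiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational deep mutational scanning by mutation and minimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mumiscan)
```

## The method

Deep mutational scanning (DMS) measures a fitness value for every single
mutant of a protein. `mumiscan` implements the computational counterpart
for binding fitness: starting from one crystal structure of a bound
complex, every single-point mutant of the focal chain is constructed by
backbone-preserving side-chain replacement, relaxed by energy
minimization, and scored by the number of wild-type *dominant interface
hydrogen bonds* the relaxed mutant maintains. The premise, inherited from
mutation–minimization schemes, is that a local side-chain replacement
followed by minimization propagates through the soft degrees of freedom
(torsions, nonbonded contacts) enough to capture the conformational shift
a mutation causes, without running dynamics for every mutant.

For the reference system — the 56-residue B1 domain of streptococcal
protein G (GB1) bound to the IgG-Fc domain — the scan size is
56 × 19 = 1064 mutants; a binding-proximal subset of 14 positions
(14 × 19 = 266) is used for short-dynamics follow-up, of which 5 mutants
fail the excess-energy screen, leaving 261 usable systems. These counts
are reproduced exactly by `enumerateMutations()` book-keeping and are part
of the acceptance checks.

## Geometric definitions

Three definitions drive all scoring; each cutoff is a tunable parameter
with the defaults below.

* **Hydrogen bond** (`hbondCriterion()`): heavy-atom donor–acceptor
  distance ≤ 3.0 Å *and* hydrogen-bond angle ≤ 20°, both inclusive.
  The angle is measured at the **donor**, between the D→H and D→A
  vectors, matching the convention of the common visualization-tool
  plugin; a deviation-from-linearity convention is available via
  `angleConvention = "linearity"` because the donor-vertex choice is a
  convention, not a law.
* **Binding region** (`bindingRegion()`): a focal residue belongs to the
  binding region when any of its heavy (non-hydrogen) atoms lies within
  5 Å of any partner heavy atom. Waters and ions never participate.
* **Surface residue**: relative solvent accessibility (RSA) above 25
  percent. RSA is residue SASA divided by a per-residue reference maximum
  (the theoretical scale of Tien et al. 2013 by default,
  `maxASA("empirical")` to switch), expressed in percent; values above
  100 are possible for extended conformations and flagged rather than
  clipped.

**Occupancy** generalizes detection to ensembles: a residue-moiety pair
(e.g. "27/side chain — 254/side chain") counts as present in a frame when
at least one atomic hydrogen bond matches it, and its occupancy is the
fraction of frames present. A **dominant** bond has occupancy strictly
above 20 percent in the wild-type bound-state reference dynamics. The
package ships the nine-pair wild-type GB1·IgG-Fc reference table
(`gb1InterfaceOccupancies()`) as input data; at desk scale the dominant
set of a single minimized structure is simply its detected interface
bonds.

**Salt bridges** are reported as the distance between the mass center of
the acidic side chain's carboxylate oxygens and that of the basic side
chain's nitrogens (`saltBridgeDistance()`); a 4.0 Å center-of-mass
threshold is a reasonable "formed" classification, but the package
reports distances and leaves classification to the caller.

## Side-chain construction

`applyMutation()` grafts a single template conformer per residue type:
internal coordinates (bond lengths, angles, chi torsions set to the most
common rotamer of standard surveys) are converted to Cartesian positions
in the frame defined by the residue's N/CA/C backbone atoms using the
natural-extension (NeRF) construction. The CB improper dihedral
(C–N–CA–CB = +123.5°) fixes L-chirality; branch offsets for Thr/Ile/Val
were calibrated against crystallographic geometry. No atom outside the
mutated residue moves — the tests assert byte-identical coordinates.

When the grafted rotamer produces heavy-atom contacts below 1.5 Å, chi1
(then chi2) is swept in 30° steps and the clash-minimal conformer kept,
with ties broken by the smallest deviation from the template — a
deterministic, seed-free first aid. Remaining strain is the minimizer's
job, mirroring the method's reliance on relaxation. Proline is grafted
without ring-closure refinement; histidine is built as the neutral
ND1-protonated tautomer by default (`hisTautomer = "NE2"` to switch).

## Polar hydrogens

Crystal inputs carry no hydrogens, but the angle criterion needs them, so
`addPolarHydrogens()` constructs them deterministically: backbone amide H
in the C–N–CA plane opposite the bisector; fixed sp2 hydrogens (Arg, Asn,
Gln, Trp, His) from the local planar geometry; rotatable groups (Ser, Thr,
Tyr, Cys hydroxyls/thiol, Lys and N-terminal ammonium) oriented toward
the nearest acceptor, with ties resolved by lowest residue index then
atom name and a fixed reference orientation when no acceptor exists.
Existing hydrogens are preserved, making the operation idempotent.

## Relaxation backends

The published pipeline solvates each mutant in a cubic box with ≥ 10 Å
padding (so periodic images are ≥ 20 Å apart), 0.15 M KCl and a
three-site water model, then minimizes 10,000 steps in an external MD
engine. `mumiscan` keeps that contract behind two backends:

* **engine** — `buildBox()` constructs the solvated system description
  (lattice-replicated waters pruned at 2.4 Å heavy-atom overlap, ion
  count `round(concentration × volume × N_A)` per species plus
  neutralizing counterions, placed by seeded substitution of waters), and
  a user-registered function (`options(mumiscan.engineBackend = fn)`)
  performs the minimization. Without a registered engine the backend
  errors with instructions. Temperature/pressure settings (310 K, 1 atm)
  concern only the out-of-scope dynamics stages and are recorded for the
  hand-off.
* **fallback** — a built-in vacuum minimizer on a reduced potential, used
  by the tests and desk-scale pipelines: harmonic bonds and angles with
  equilibria taken from the input geometry (ideal by construction for
  template-built structures), 12-6 Lennard-Jones with per-element radii,
  and distance-capped Coulomb on formal charges. Two accommodations give
  the isotropic model the hydrogen-bond behavior the method presumes:
  inter-residue N/O pairs get their LJ minimum at the hydrogen-bonded
  contact distance (2.85 Å) rather than the vdW contact, and every
  hydrogen bond present in the *input* structure is preserved by a weak
  H···acceptor distance restraint plus a donor-vertex angle restraint.
  A mutation that removes a donor removes its restraints, so relaxation
  discriminates exactly where the method expects it to. The inner loop is
  a quasi-Newton descent (L-BFGS-B with analytic gradients) run in
  chunks, so the recorded energy trace is non-increasing; "steps" bounds
  the total iteration count, with an early stop when the per-chunk
  decrease stalls.

Failure handling follows the excess-energy idea: a run is flagged when
its energy is non-finite, exceeds a configurable threshold, or — at the
cohort level in `runMumi()` — exceeds the converged cohort mean by more
than 5 standard deviations. Failures are recorded in the manifest, never
fatal, and excluded pairwise downstream.

Because the bonded equilibria are referenced to the input geometry, a
"minimized" structure is a fixed point of *its own* topology; the tests
verify the fixed-point property on a Lennard-Jones cluster, whose
potential is input-independent.

## Surface areas

SASA is computed by the Shrake–Rupley method with a deterministic
golden-angle spiral point set (960 points per atom by default; doubling
changes totals by < 0.5 % on the fixtures, and an isolated sphere is
within numerical identity of 4π(r+1.4)²). Radii are per-element
(Bondi-type: C 1.70, N 1.55, O 1.52, S 1.80 Å), chosen over atom-type
radii because the atom record model is element-typed; hydrogens are
excluded by the crystal-structure convention. Totals are exactly
translation-invariant and rotation-invariant up to the point-set
discretization (~0.1 %).

## Statistics over ensembles

`hbondOccupancy()`, `bindingProbability()` and `ensembleRsaStats()`
aggregate per frame. For mutant-collection ensembles the denominator is
the number of usable mutants across all positions, so a residue's
binding-region probability aggregates over every substitution everywhere
— the natural reading of a per-residue density over a scan, and a choice
(documented here) the source material leaves open. `compareRsaStats()`
pairs per-residue means and population standard deviations of two
ensembles and reports least-squares R² for both, with optional
allosteric/binding annotation (`gb1AllostericResidues()`).

## Synthetic fixtures and what passing tests show

`makeHelixPeptide()` builds ideal helical backbones; the default torsions
(φ = −58°, ψ = −50°) sit in the alpha basin and were chosen by a design
scan so the i→i+4 amide–carbonyl geometry (2.87 Å, 7.4°) lies safely
inside the criterion — the textbook (−57, −47) pair lands at 3.09 Å with
this bond-geometry set, just outside the 3.0 Å cutoff.
`makeToyDimer()` places donor/acceptor residue pairs at prescribed
distance and donor-vertex angle exactly, returning a manifest the
detector must agree with. `makeJitterEnsemble()` applies i.i.d. Gaussian
coordinate noise — sufficient to exercise occupancy and probability
statistics against binomial expectations, but *not* physical dynamics:
passing these tests demonstrates correctness of the geometry and the
statistics, not force-field realism. Fixtures are byte-identical under a
fixed seed.

## Numerical choices and edge cases

* Cutoff comparisons (3.0 Å, 20°, 5 Å) are inclusive; the dominance
  threshold ("> 20 %") is strict, matching its wording.
* Alternate locations resolve to the highest occupancy, ties to the first
  listed; insertion codes are rejected (the reference system has none,
  and author-numbering pairing stays simple); residues with missing
  backbone atoms are flagged with a warning.
* Residue references use author numbering throughout, never sequential
  indices.
* PDB writing is fixed-column with 3-decimal coordinates; read–write
  round trips are stable to 0.001 Å and ensembles use MODEL/ENDMDL.
* `rmsdHeavy()` defaults to no superposition, because minimization keeps
  the laboratory frame and the raw displacement is the quantity of
  interest; superposition (Kabsch) is a flag.
* Desk-scale problem sizes used by the test-suite and the acceptance
  script: toy complexes of 3–4 residue pairs, 19–57 mutants per scan,
  jitter ensembles of 200 frames, minimizations of 30–100 steps.

## Known limitations

* The fallback potential is a reduced model: no explicit solvent, no
  full partial-charge electrostatics, hydrogen-bond directionality by
  restraint rather than physics. Absolute energies are not comparable
  across systems; only the discrimination between maintained and broken
  interactions is meaningful at desk scale. Full-scale interface bond
  counts, RSA profiles and relaxation RMSDs require an engine backend
  (see `scripts/reproduce_full.R`).
* Parse errors are reported per file, not per line.
* Only single-point mutants are modeled; no backbone-dependent rotamer
  libraries, no repacking of neighbors, no water-mediated bridges,
  no π-interactions, no Lee–Richards surfaces, no mmCIF.
* Trajectory formats beyond multi-model PDB are out of scope; the
  adapter contract is `readPdbEnsemble()`'s return shape — any reader
  producing a `StructureEnsemble` plugs in.

## A worked desk-scale example

```{r example}
td <- makeToyDimer(data.frame(donor = c("S", "A", "W"),
                              acceptor = c("D", "E", "Q"),
                              distance = c(2.9, 2.8, 2.95),
                              angle = c(10, 5, 15)))
sc <- scanComplex(td$structure, focalChains = "A", positions = 1:3,
                  minimization = minimizationSpec(steps = 40))
sc$wtCount                 # bonds the relaxed WT maintains
fitnessValues(sc$fitness)  # maintained-bond counts per mutant
```

The matrix rows show the scan's logic directly: mutating the serine or
tryptophan destroys that position's side-chain donor (count drops to 2),
while position 2 donates through its backbone amino group, which every
substitution except proline preserves.
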