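# mumiscan

Computational deep mutational scanning (DMS) of protein–protein
complexes from a single crystal structure. Experimental DMS measures a
fitness value for every single mutant of a protein; `mumiscan`
implements the structure-based counterpart for *binding* fitness: build
every single-point mutant by backbone-preserving template side-chain
replacement, relax each mutant (mutation + minimization, without
per-mutant dynamics), and score it by the number of wild-type dominant
interface hydrogen bonds the relaxed structure maintains,

> N<sub>HB</sub>(mutant) = |{ (i, j) ∈ WT dominant set :
> d(D<sub>i</sub>, A<sub>j</sub>) ≤ 3.0 Å and θ<sub>D</sub> ≤ 20° }|,

where a *dominant* bond is an interface residue pair with hydrogen-bond
occupancy > 20 % in the wild-type bound-state dynamics, and θ<sub>D</sub>
is the donor-vertex angle between the D→H and D→A vectors. Around this
proxy the package provides the full analysis stack: geometric
hydrogen-bond and salt-bridge detection, occupancy statistics over
ensembles, Shrake–Rupley SASA and relative solvent accessibility (RSA,
percent of a per-residue reference maximum; surface = RSA > 25),
binding-region membership (any heavy atom within 5 Å of the partner) and
per-residue binding probabilities, solvation-box construction with a
pluggable minimization backend, and deterministic synthetic-structure
generators so every stage is testable offline.

The reference study system is the 56-residue B1 domain of streptococcal
protein G (GB1) bound to the IgG-Fc domain: 56 × 19 = 1064 single
mutants; a 14-position binding-proximal subset (266 mutants) for
short-dynamics follow-up, of which 5 fail the excess-energy screen
(261 usable). The package ships the GB1 sequence and the nine-pair
wild-type interface occupancy reference table as input data.

Intended users: structural bioinformaticians and protein engineers who
want a transparent, fully testable scaffold for structure-based mutant
scanning — either with the built-in reduced-potential fallback at desk
scale, or delegating solvated minimization to their own MD engine.

## Worked example

A toy bound complex with three constructed interface hydrogen bonds —
serine hydroxyl, backbone amino group, tryptophan indole — scanned at all
three positions:

```r
library(mumiscan)

td <- makeToyDimer(data.frame(donor    = c("S", "A", "W"),
                              acceptor = c("D", "E", "Q"),
                              distance = c(2.9, 2.8, 2.95),
                              angle    = c(10, 5, 15)))
sc <- scanComplex(td$structure, focalChains = "A", positions = 1:3,
                  minimization = minimizationSpec(steps = 40))
sc$wtCount
#> [1] 3
fitnessValues(sc$fitness)
#>     A C D E F G H I K L M N P Q R  S T V  W Y
#> S1  2 2 2 2 2 2 2 2 2 2 2 2 2 2 2 NA 2 2  2 2
#> A2 NA 3 3 3 3 3 3 3 3 3 3 3 2 3 3  3 3 3  3 3
#> W3  2 2 2 2 2 2 2 2 2 2 2 2 2 2 2  2 2 2 NA 2
```

The relaxed wild type keeps all 3 constructed bonds (`wtCount`). Each
matrix cell is the number of WT bonds the relaxed mutant maintains (`NA`
marks the WT identity): substituting the serine or tryptophan destroys
that position's side-chain donor (2 of 3 bonds left), while position 2
donates through its backbone amino group, which every substitution
except proline preserves (row `A2`: 3, but `A2P` = 2 — proline has no
amide hydrogen). Against a synthetic monotone experiment table the proxy
anti-correlates perfectly:

```r
r <- correlateFitness(sc$fitness, syntheticExperimentTable(sc$fitness))
r$spearman$estimate
#> [1] -1
```

Real experimental tables (`position,wt,mut,ddg`, destabilization
energies capped at 9 kcal/mol) load with `readExperimentTable()`.

## Command line

A thin front end over the same functions ships in `inst/scripts/`:

```sh
mumiscan fixtures  --kind toy_dimer --seed 7 --out fixture.pdb
mumiscan mutate    --pdb fixture.pdb --chain A --positions all --out-dir mutants
mumiscan relax     --pdb mutants/S1W.pdb --backend fallback --steps 1000 --out relaxed.pdb
mumiscan hbonds    --pdb fixture.pdb --between A:B --dmax 3.0 --amax 20 --out report.csv
mumiscan sasa      --pdb fixture.pdb --probe 1.4 --points 960 --out rsa.csv
mumiscan interface --pdb ensemble.pdb --focal A --cutoff 5.0 --out interface.csv
```

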