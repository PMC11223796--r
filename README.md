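# rotafield

Tensorized rotamer-field energies for fixed-backbone protein design.

`rotafield` is an R implementation of a voxelized side-chain energy engine
for protein design. Instead of looping over interacting atom pairs at
runtime, it precomputes, for every rotamer of a backbone-dependent rotamer
library, a *field tensor*: a grid over the residue-local frame that stores,
per voxel and environment atom class, the interaction energy a unit
occupant at that voxel would contribute. At runtime the surroundings of a
target position are histogrammed into an *environment tensor* on the same
grid, and the two are contracted to give the interaction energies in a
single product per term. The package is aimed at structural-bioinformatics
users who want a self-contained, fully testable design engine: library
construction, energy evaluation and the sampling protocols are all
exercised from R or from a small command-line tool.

## The model

The energy of amino acid `X` at position `i` is a sum of five terms:

    dG_total(i) = dG_pp(X_i | phi_i, psi_i) + dG_k + E_lj + E_elec + E_solv

* `dG_pp` — backbone-torsion energy, `-RT log p(phi, psi)` from a periodic
  (von Mises) kernel density estimate over a conformer ensemble of the
  capped amino acid, shifted so the map minimum is 0 (RT = 0.593 kcal/mol).
* `dG_k` — side-chain conformational energy. Conformers are gridded into
  36 backbone bins (6 x 6 tiling of the (phi, psi) torus); within each bin
  side-chain conformations are k-means clustered into k = 100
  representatives and `dG_k = -RT log(N_cluster / N_bin)` is the Boltzmann
  weight of each cluster's population fraction.
* `E_lj`, `E_elec`, `E_solv` — 12-6 Lennard-Jones (Lorentz-Berthelot
  combination, per-voxel clamp), Coulomb with distance-dependent
  dielectric `eps(r) = 4r`, and a Gaussian solvent-exclusion term of
  Lazaridis-Karplus shape. All three are evaluated as tensor contractions
  against the environment histogram; an explicit atom-pair oracle with the
  identical closed forms is shipped for verification.

Because the conformer ensembles behind the library are generated
synthetically (seeded periodic mixtures in internal coordinates, built to
Cartesian by an NeRF chain), every stage of the pipeline is reproducible
and testable without external data.

Four design protocols operate on these energies: deterministic repacking
(`repack`), single-point mutagenesis with an adaptive LJ clash ceiling
(`singlePointScan`), a swarm combinatorial sequence sampler
(`combinatorialDesign`), and sequence-symmetric design
(`symmetricDesign`).

## Worked example

```r
library(rotafield)

## build a small library from synthetic conformer pools
pools <- list(LEU = samplePool("LEU", 2000, seed = 11),
              SER = samplePool("SER", 2000, seed = 12),
              VAL = samplePool("VAL", 2000, seed = 13),
              ALA = samplePool("ALA",  500, seed = 14))
lib <- buildRotamerLibrary(pools, k = 10, seed = 5)

## an ideal helical host peptide, typed against the packaged parameters
s <- buildPeptide(c("LEU", "SER", "LEU", "VAL", "LEU", "ALA", "LEU"),
                  phi = -63, psi = -43)

## five-term energy breakdown over all residues
totalEnergy(s, NULL, lib)
#> EnergyBreakdown over 7 residue(s): total 15.621 kcal/mol; average 2.232 kcal/mol per residue

## swarm design over two mutable positions
spec <- designSpec(repackable = "A:3",
                   mutable = list("A:2" = c("SER", "ALA", "VAL"),
                                  "A:4" = c("LEU", "VAL", "SER")),
                   nPaths = 3, nIters = 3, seed = 41)
combinatorialDesign(s, spec, lib)
#> DesignResult (cs): 1 model(s)
#>    1. avg 0.345 kcal/mol/res  [A:2:SER>ALA,A:4:VAL>LEU]
```

The averages are per-residue energies in kcal/mol over the selected
positions — the size-independent score the protocols rank models by; the
mutation strings are relative to the input structure. `writeOutputs()`
turns a result into one PDB per model, a multi-FASTA and a `summary.csv`.

The same workflows are available from a shell via the bundled CLI
(`inst/cli/rotafield`): `make-pools`, `build-library`, `preprocess`,
`energy`, `repack`, `sp`, `cs`, `sd`. Every run writes a self-describing
output directory with a JSON run log.

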