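---
title: "rotafield: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{rotafield: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rotafield` evaluates protein side-chain energies on a fixed backbone by
contracting precomputed per-rotamer *field tensors* with a voxelized
histogram of the atoms surrounding a target position, and uses those
energies in four design protocols. This vignette explains the model, the
parameters that matter, what the synthetic data generator does and does
not emulate, and the places where the design was genuinely open.

## The energy model

For a residue at position $i$ with amino acid $X$ the engine computes five
additive terms,

$$\Delta G_{total} = \Delta G_{pp}(X\mid\varphi,\psi) + \Delta G_k +
E_{LJ} + E_{elec} + E_{solv},$$

and reports both the per-residue breakdown and the average per-residue
energy over the selection, the latter being comparable across proteins of
different sizes.

**Backbone-torsion term.** A conformer ensemble of the capped amino acid
provides $(\varphi, \psi)$ samples. A product of von Mises kernels
(concentration $\kappa = 1/\sigma^2$, $\sigma$ the bandwidth in radians)
is evaluated on a $5^\circ$ grid over the torus; $\Delta G_{pp} =
-RT\log\hat p$ is shifted so the grid minimum is exactly zero, and lookup
uses bilinear interpolation with periodic wrap-around. Defaults: bandwidth
$15^\circ$, $RT = 0.593$ kcal/mol (298.15 K). The kernels are evaluated in
exp-scaled form so that very tight bandwidths cannot overflow; nodes whose
density underflows are capped at 25 kcal/mol above the minimum with a
warning. Because the map is shifted per amino acid, $\Delta G_{pp}$
differences are meaningful at a fixed position, but comparisons *across*
amino acids inherit the shift — a deliberate normalization that the
samplers account for by always comparing candidates at the same position.

**Side-chain term.** The torus is tiled into 36 half-open $60^\circ \times
60^\circ$ bins ($+180^\circ$ maps to the $-180^\circ$ edge, so the tiling
is exact). Within a bin, side-chain conformations are clustered by k-means
(k = 100 by default) on the flattened Cartesian coordinates of the atoms
beyond CB in the residue-local frame — Cartesian features avoid the
periodicity artifacts $\chi$-space clustering would suffer. Initialization
is seeded k-means++; the representative of each cluster is the *real*
conformer nearest the centroid (ties to the lowest conformer index), so
placed side chains always have physical geometry. $\Delta G_k = -RT\log$
(population fraction); within every bin the Boltzmann weights
$e^{-\Delta G_k/RT}$ therefore sum to one, an identity the tests assert to
$10^{-9}$. $\Delta G_k$ is kept as the raw $-RT\log$ value rather than
re-shifted within bins.

**Interaction terms.** The three environment terms share one closed-form
library: a 12-6 Lennard-Jones with Lorentz–Berthelot combination; Coulomb
with a distance-dependent dielectric $\varepsilon(r) = 4r$ (i.e.
$k_e q_a/(4r^2)$ per unit environment charge); and a Gaussian
solvent-exclusion term of Lazaridis–Karplus shape,
$-[f_a(r)V_t + f_t(r)V_a]$ with
$f_i(r) = \Delta G^{free}_i/(2\pi^{3/2}\lambda_i r^2)\,
e^{-((r-R_i)/\lambda_i)^2}$. The packaged parameter table defines 12
heavy-atom classes (well depth, radius, reference solvation free energy,
correlation length, volume) and per-(residue, atom) classes and partial
charges; it is a self-contained set in the spirit of protein force fields
and is the sole source of parameters for tensors, oracle and typing alike.
Distances are floored near $r = 0$ ($10^{-3}$ Å for LJ, 0.05 Å for the
other terms) and the summed per-(voxel, class) LJ field is clamped at
`maxLjField` (default 10 kcal/mol), so singularities reduce to a
well-defined saturated clash signal.

## Tensors, and how the contraction is evaluated

All precomputed grids live in a canonical residue-local frame (origin CA,
x towards N, $z = \hat x \times (C - CA)$), which is what lets one tensor
be reused at any position of any structure. The default grid is 25 voxels
per axis at 0.8 Å (20 Å extent) centred on CA; atoms outside the grid are
counted but ignored — a documented truncation at $\ge 10$ Å.

`computeFieldTensor()` materializes the dense 4-D tensor (3-D for the
electrostatic term, which factorizes over charge and uses a single
charge-weighted channel — per-class channels would be redundant).
`interactionEnergy()` evaluates the contraction on the *occupied support*
of the sparse environment histogram. The two are algebraically identical
— unoccupied voxels multiply zero — and the test suite asserts three-way
agreement (dense contraction, sparse contraction, snapped atom-pair
oracle) to $10^{-9}$ relative over hundreds of random scenes and three
voxel sizes. Materializing dense tensors for a whole library
(36 bins × 100 rotamers × 20 amino acids × $25^3$ voxels × 12 classes ×
3 terms in double precision) would cost on the order of 10 GB *per amino
acid*, which no workstation-scale build should require; storing rotamer
geometry and energies and evaluating the identical algebra on the sparse
support keeps the archive small and the numbers bit-equivalent up to
summation order. The unsnapped oracle is also used in a refinement study:
halving the voxel edge (1.6 → 0.8 → 0.4 Å) must not increase the mean
|tensor − continuous| discrepancy.

The environment histogram uses half-open voxels (a boundary atom belongs
to the higher-index voxel) and excludes the target's own backbone window:
N, CA, C, O, CB, the preceding peptide unit's C/O and the following N. CB
is treated as backbone throughout — it is placed with the backbone, kept
on stripping, and excluded from a residue's own environment — so the
"rotamer" that interacts with the environment is exactly the atoms beyond
CB.

## The synthetic conformer factory

The library pipeline (KDE → bin → cluster → tensors) is agnostic to how
the conformer pool was made. The factory draws backbone torsions from a
seeded von Mises mixture (defaults: α at (−63°, −43°), β at (−120°, 130°)
and a PPII-like mode at (−65°, 145°), weighted 0.45/0.35/0.20) and each
χ from wrapped-normal wells at −60°/60°/180° (σ = 12°), then builds
heavy-atom Cartesian coordinates with an NeRF chain over a packaged
ideal-geometry table (ACE and NME caps included). Glycine gets wide
symmetric backbone modes; proline gets a restricted-φ backbone and a fixed
ideal ring — open-chain χ sampling would break ring closure, and ring
rebuilding is orthogonal to the engine. Default pool sizes are 20 000
conformers per amino acid for library builds and 1 000–2 000 in tests.

What this emulates: rotameric well structure, backbone-dependent
populations, and the statistical identities downstream code relies on.
What it does not: the energetic realism of a physical ensemble — well
weights are stylized, solvent and temperature are absent, and pool
energetics never enter the tensors. Passing tests therefore validate the
*machinery* (estimation, clustering, tensorization, sampling) and its
invariants, not the biophysical accuracy of any particular library on real
proteins.

One statistical subtlety: a finite uniform pool gives a flat-but-noisy
density, with fluctuations of roughly $RT/\sqrt{n_{\mathrm{eff}}}$ where
$n_{\mathrm{eff}}$ is the pool size times the kernel's effective area
fraction. The flatness check is run at $n = 100\,000$, where the expected
range sits well below 0.1 kcal/mol at the default bandwidth.

## Sampling protocols

All four protocols score candidates with the same five-term engine and
report breakdowns recomputed from the final structure, so every reported
number is reproducible from the model file alone.

* **repack** — a fixed number of sweeps (default 2) over the repackable
  positions in input order, installing the best admissible rotamer of the
  wild-type amino acid at each visit. Fully deterministic; repacking a
  library-optimal structure is a fixed point.
* **sp** — forces each (position, amino acid) mutation independently:
  repack first, then evaluate every rotamer of the target's bin once. If
  none clears the LJ ceiling the ceiling is raised ×4 (capped at
  1000 kcal/mol) and the *cached* energies re-examined, so the logged
  evaluation count per forced mutation equals the bin size (100 when
  full) regardless of raises, and the mutation always lands in the output
  model together with its energy difference against the repacked wild
  type.
* **cs** — a swarm of `nPaths` greedy paths, each visiting the mutable
  positions in its own seeded order (identity order with
  `scrambleOrder = FALSE`). At a visit, each allowed amino acid is tried
  with its best rotamer; candidates are ranked by their per-position
  score and the best is accepted only if it strictly lowers the aggregate
  energy over the selection, after which repackable positions within 6 Å
  of the new side chain are repacked one sweep. After each iteration the
  path states are pooled, deduplicated by sequence, and the paths
  respawned from the lowest-energy unique states — the
  "loosely-communicating" mechanism chosen here for its testability over
  alternatives like migration or crossover. Acceptance is strict-decrease
  greedy (no Metropolis criterion), which makes the per-path best energy
  provably non-increasing; the run records that trace and the tests
  assert it. Neighborhood repacking happens after acceptance rather than
  inside every candidate evaluation — the cheaper of the two readings and
  the one that keeps candidate ranking deterministic.
* **sd** — identical control flow, but a move is (group, amino acid): the
  amino acid is installed at every position of a symmetry group in the
  provided order, each position keeping its own independently optimized
  rotamer. Symmetry is enforced on the sequence only.

Defaults: `nPaths = 5`, `nIters = 10`, `sweeps = 2`, `maxLj = 5` kcal/mol,
`scrambleOrder` on. The respawn pool size is tied to `nPaths`. An MD
minimization hook before/after the swarm protocols defaults to the
identity — wiring a real minimizer is out of scope for this package.

## Numerical choices and degenerate inputs

* All angles are wrapped to $(-180°, 180°]$; binning maps $+180°$ to the
  $-180°$ edge so the 36-bin tiling is a true partition.
* Dihedral sign convention is IUPAC (clockwise positive looking from the
  second to the third atom); the NeRF builder is phase-matched to it and
  round-trips torsions to $<0.5^\circ$.
* Chain-terminal residues with undefined φ or ψ report
  $\Delta G_{pp} = 0$ with a flag; the missing angle is substituted with
  0° for bin lookup.
* Ties everywhere break to the lowest index (rotamer choice, k-means
  representative), and summations run in fixed residue order, so repeated
  runs are bit-identical.
* Residues with missing backbone atoms are dropped with a warning;
  missing side-chain heavy atoms are rebuilt from ideal internal
  coordinates, measuring χ from whatever defining atoms exist and
  defaulting the rest (χ1 = −60°, others 180°). Terminal OXT atoms are
  removed during preprocessing so canonical atom sets stay uniform.
* Empty (amino acid, bin) cells are recorded in the library metadata at
  build time; sampling into one raises an error naming the amino acid and
  bin.
* The library archive is a single serialized file with a format version
  and a payload checksum; truncation and version mismatches fail loudly.

## Problem sizes

The shipped tests build one full-scale amino acid (leucine: a
20 000-conformer pool, 36 bins, k = 100 with tensors evaluated on demand)
plus a five-amino-acid miniature library (k = 10, 500–2 000 conformers per
pool) that backs the engine and sampler suites; oracle agreement runs on
~200 random scenes at three grid sizes and the statistical identities on
pools of $10^5$. These sizes keep a complete run in well under a minute of
compute per suite while exercising every code path at full-library shape
in the leucine build.

## Known limitations

* Hydrogens are never added or scored; the parameter set is heavy-atom
  (united-style) by construction.
* The interaction closed forms are documented stand-ins with the right
  tensor structure, not a fit to any published force field; absolute
  energies are internally consistent, not transferable.
* Fixed backbone only: no backbone moves, no periodic boundary
  conditions, no polarization, no pairwise coupling between two
  simultaneously movable side chains beyond the samplers' sequential
  placement order.
* Non-proteinogenic residue types, ligands and cofactors are unsupported;
  heteroatoms are removed during preprocessing.
* mmCIF reading is delegated to bio3d and shares its limitations.
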