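Package: rotafield
Title: Tensorized Rotamer-Field Energies for Fixed-Backbone Protein Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds backbone-dependent rotamer libraries from synthetic
    conformer ensembles of capped amino acids (periodic kernel-density
    backbone energies, k-means side-chain clustering into k representative
    rotamers per (phi, psi) bin) and evaluates protein side-chain energies
    by contracting precomputed per-rotamer field tensors (Lennard-Jones,
    electrostatic, solvation) against a voxelized histogram of the
    surrounding atoms. Ships four fixed-backbone design protocols:
    deterministic repacking, single-point mutagenesis with an adaptive
    steric ceiling, a swarm combinatorial sequence sampler, and
    sequence-symmetric design, together with structure preprocessing,
    FASTA/CSV reporting and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, bio3d, Biostrings, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
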