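## Central S4 containers. Payloads are plain data.frames / arrays; accessors
## rather than slot access are the supported interface.

#' @import methods
NULL

#' Voxel grid specification
#'
#' Cubic voxel grid centred on the local-frame origin (the CA atom of the
#' target residue). All rotamer field tensors and environment histograms of
#' one library share a single grid.
#'
#' @slot edge voxel edge length, Angstrom
#' @slot nvox voxels per axis (odd, so one voxel is centred on the origin)
#' @export
setClass("GridSpec", representation(edge = "numeric", nvox = "integer"),
         validity = function(object) {
           if (length(object@edge) != 1 || object@edge <= 0)
             return("edge must be a single positive number")
           if (length(object@nvox) != 1 || object@nvox < 1 ||
               object@nvox %% 2L == 0L)
             return("nvox must be a single odd positive integer")
           TRUE
         })

#' Construct a GridSpec
#' @param edge voxel edge length in Angstrom
#' @param nvox odd number of voxels per axis
#' @return a \linkS4class{GridSpec}
#' @examples gridSpec(0.8, 25L)
#' @export
gridSpec <- function(edge = 0.8, nvox = 25L)
  new("GridSpec", edge = as.numeric(edge), nvox = as.integer(nvox))

#' Grid extent (edge length of the full cube, Angstrom)
#' @param grid a \linkS4class{GridSpec}
#' @return numeric extent in Angstrom
#' @export
gridExtent <- function(grid) grid@edge * grid@nvox

#' Atom-class parameter table
#'
#' Self-contained heavy-atom parameter set: ~12 atom classes with
#' Lennard-Jones well depth/radius and Gaussian solvent-exclusion
#' parameters, plus a per-(residue, atom) map to class id and partial
#' charge. Packaged as plain-text tables under \code{inst/extdata}.
#'
#' @slot classes data.frame: class_id, name, eps (kcal/mol), rmin2 (Rmin/2,
#'   Angstrom), gref (reference solvation free energy, kcal/mol), lambda
#'   (correlation length, Angstrom), vol (atomic volume, Angstrom^3)
#' @slot atoms data.frame: resid, elety, class_id, charge (e)
#' @slot pairEps,pairRmin precomputed Lorentz-Berthelot class-pair matrices
#' @export
setClass("ParameterTable",
         representation(classes = "data.frame", atoms = "data.frame",
                        pairEps = "matrix", pairRmin = "matrix"),
         validity = function(object) {
           cl <- object@classes
           if (any(cl$eps < 0)) return("LJ well depths must be >= 0")
           if (any(cl$rmin2 <= 0)) return("LJ radii must be > 0")
           if (anyNA(match(object@atoms$class_id, cl$class_id)))
             return("atom rows reference unknown atom classes")
           TRUE
         })

#' Protein structure (heavy atoms, typed)
#'
#' @slot atoms data.frame with one row per atom: chain, resno, icode, resid
#'   (3-letter), elety (atom name), x, y, z, element, het (logical flag for
#'   records slated for removal), class_id, charge
#' @slot resTab data.frame with one row per residue: chain, resno, icode,
#'   aa, phi, psi (degrees; NA at chain termini)
#' @slot provenance character log of source and preprocessing steps
#' @export
setClass("ProteinStructure",
         representation(atoms = "data.frame", resTab = "data.frame",
                        provenance = "character"))

#' Ensemble of capped-residue conformations for one amino acid
#'
#' Synthetic stand-in for a molecular-dynamics pool of capped (ACE/NME)
#' amino acids: backbone torsions drawn from a periodic mixture, side-chain
#' torsions from rotameric wells, Cartesian coordinates built from ideal
#' internal coordinates.
#'
#' @slot aa three-letter amino-acid code
#' @slot phi,psi backbone torsions, degrees, length n
#' @slot chi n x n_chi matrix of side-chain torsions (0 columns for Gly/Ala/Pro)
#' @slot coords natoms x 3 x n array, canonical local frame, Angstrom
#' @slot atomNames,parts per-atom name and unit (ACE/RES/NME)
#' @slot seed,spec generator provenance
#' @export
setClass("ConformerPool",
         representation(aa = "character", phi = "numeric", psi = "numeric",
                        chi = "matrix", coords = "array",
                        atomNames = "character", parts = "character",
                        seed = "integer", spec = "list"),
         validity = function(object) {
           n <- length(object@phi)
           if (n < 1) return("pool must contain at least one conformer")
           if (length(object@psi) != n || dim(object@coords)[3] != n)
             return("phi/psi/coords sizes disagree")
           TRUE
         })

#' Backbone-torsion energy map for one amino acid
#'
#' Periodic-KDE density over the (phi, psi) torus converted to an energy
#' surface dG_pp = -RT log p, shifted so the grid minimum is exactly zero.
#'
#' @slot aa amino acid
#' @slot values energy grid (kcal/mol), rows = phi nodes, cols = psi nodes
#' @slot nodes grid node angles, degrees (shared by both axes)
#' @slot bandwidth KDE bandwidth, degrees
#' @slot density the normalized KDE density at the nodes
#' @export
setClass("BackboneEnergyMap",
         representation(aa = "character", values = "matrix",
                        nodes = "numeric", bandwidth = "numeric",
                        density = "matrix"),
         validity = function(object) {
           if (abs(min(object@values)) > 1e-12)
             return("energy grid minimum must be 0 after normalization")
           if (any(!is.finite(object@values)) || any(object@values < 0))
             return("energies must be finite and >= 0")
           TRUE
         })

#' Backbone-dependent rotamer library with precomputable field tensors
#'
#' Per amino acid: a \linkS4class{BackboneEnergyMap} and 36 (phi, psi) bins,
#' each holding up to k representative side-chain conformations with their
#' cluster energies dG_k. Field tensors are defined per rotamer on the
#' shared \linkS4class{GridSpec} and materialized by
#' \link{computeFieldTensor}; runtime contraction evaluates the identical
#' algebra on the occupied voxels of the environment histogram.
#'
#' @slot aas amino acids present
#' @slot maps named list of \linkS4class{BackboneEnergyMap}
#' @slot bins named list; \code{bins[[aa]][[b]]} holds coords (natoms x 3 x k
#'   local-frame side-chain coordinates including CB), dGk, popFrac, n
#'   (conformers in bin), shortfall
#' @slot grid shared \linkS4class{GridSpec}
#' @slot table the embedded \linkS4class{ParameterTable}
#' @slot maxLjField per-voxel LJ clamp used at tensor precompute, kcal/mol
#' @slot metadata build provenance: seeds, pool sizes, bandwidth, k, hashes
#' @slot version archive format version string
#' @export
setClass("RotamerLibrary",
         representation(aas = "character", maps = "list", bins = "list",
                        grid = "GridSpec", table = "ParameterTable",
                        maxLjField = "numeric", metadata = "list",
                        version = "character"))

#' 3D histogram of the atoms surrounding a target position
#'
#' Sparse storage: one row per occupied (voxel, atom class) with its count,
#' plus per-voxel summed partial charges. \link{denseOccupancy} and
#' \link{denseCharge} materialize the dense arrays.
#'
#' @slot grid the \linkS4class{GridSpec}
#' @slot occ integer matrix, columns ix, iy, iz (1-based voxel indices),
#'   class, count
#' @slot charge numeric matrix, columns ix, iy, iz, q (summed charge)
#' @slot nOutside number of environment atoms falling outside the grid
#' @slot nAtoms number of in-grid environment atoms
#' @export
setClass("EnvironmentTensor",
         representation(grid = "GridSpec", occ = "matrix", charge = "matrix",
                        nOutside = "integer", nAtoms = "integer"),
         validity = function(object) {
           if (nrow(object@occ) && any(object@occ[, "count"] < 0))
             return("occupancy counts must be non-negative")
           if (sum(object@occ[, "count"]) != object@nAtoms)
             return("occupancy must sum to the number of in-grid atoms")
           TRUE
         })

#' Per-residue five-term energy breakdown
#'
#' @slot perResidue data.frame: chain, resno, aa, dG_pp, dG_k, E_lj, E_elec,
#'   E_solv, total (kcal/mol), ppUndefined (TRUE when phi or psi was
#'   undefined and dG_pp reported as 0)
#' @slot aggregate sum of per-residue totals
#' @slot average aggregate / number of residues
#' @export
setClass("EnergyBreakdown",
         representation(perResidue = "data.frame", aggregate = "numeric",
                        average = "numeric"),
         validity = function(object) {
           pr <- object@perResidue
           terms <- c("dG_pp", "dG_k", "E_lj", "E_elec", "E_solv")
           if (!all(terms %in% names(pr)))
             return("breakdown must contain the five energy terms")
           if (nrow(pr)) {
             if (abs(object@aggregate - sum(pr$total)) > 1e-9)
               return("aggregate must equal the sum of per-residue totals")
             if (abs(object@average - object@aggregate / nrow(pr)) > 1e-12)
               return("average must be aggregate / residue count")
           }
           TRUE
         })

#' Specification of a design run
#'
#' @slot repackable ordered positions ("chain:resno") whose side chains may
#'   be re-optimized at fixed amino acid
#' @slot mutable named list: position -> allowed amino-acid vector
#' @slot symmetry list of position vectors forced to share one amino acid
#'   (sequence-level symmetry only; rotamers stay independent)
#' @slot nPaths,nIters swarm breadth and depth
#' @slot scrambleOrder randomize per-path visiting order (default TRUE)
#' @slot maxLj runtime clash ceiling, kcal/mol
#' @slot sweeps repack sweeps per pass
#' @slot seed RNG seed
#' @export
setClass("DesignSpec",
         representation(repackable = "character", mutable = "list",
                        symmetry = "list", nPaths = "integer",
                        nIters = "integer", scrambleOrder = "logical",
                        maxLj = "numeric", sweeps = "integer",
                        seed = "integer"),
         validity = function(object) {
           pos <- unlist(object@symmetry)
           if (length(pos) != length(unique(pos)))
             return("symmetry groups must be disjoint")
           if (object@nPaths < 1 || object@nIters < 1)
             return("nPaths and nIters must be >= 1")
           TRUE
         })

#' Result of a design run
#'
#' Models are sorted ascending by average per-residue energy; combinatorial
#' and symmetric design additionally guarantee pairwise distinct sequences.
#'
#' @slot models list; each element has structure
#'   (\linkS4class{ProteinStructure}), breakdown
#'   (\linkS4class{EnergyBreakdown}), mutations (character), pathId,
#'   iteration, and protocol extras (clash flags, raise events, ...)
#' @slot protocol protocol name ("repack", "sp", "cs", "sd")
#' @slot info run metadata (spec echo, seed, log)
#' @export
setClass("DesignResult",
         representation(models = "list", protocol = "character",
                        info = "list"))
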