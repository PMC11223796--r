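## Generics, accessors and show methods.

#' Atom table of a structure
#' @param x a \linkS4class{ProteinStructure}
#' @return data.frame of atoms
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname atomTable
#' @export
setMethod("atomTable", "ProteinStructure", function(x) x@atoms)

#' Residue table (one row per residue, with phi/psi once preprocessed)
#' @param x a \linkS4class{ProteinStructure}
#' @return data.frame of residues
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname residueTable
#' @export
setMethod("residueTable", "ProteinStructure", function(x) x@resTab)

#' Number of residues
#' @param x a \linkS4class{ProteinStructure}
#' @return integer count
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname nResidues
#' @export
setMethod("nResidues", "ProteinStructure", function(x) nrow(x@resTab))

#' One-letter sequence per chain
#' @param x a \linkS4class{ProteinStructure}
#' @return named character vector, one string per chain
#' @export
setGeneric("chainSequences", function(x) standardGeneric("chainSequences"))

#' @rdname chainSequences
#' @export
setMethod("chainSequences", "ProteinStructure", function(x) {
  rt <- x@resTab
  vapply(split(rt, rt$chain), function(d)
    paste(aaOneLetter(d$aa), collapse = ""), character(1))
})

#' Provenance log of a structure
#' @param x a \linkS4class{ProteinStructure}
#' @return character vector of log lines
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
#' @export
setMethod("provenance", "ProteinStructure", function(x) x@provenance)

#' Models of a design result
#' @param x a \linkS4class{DesignResult}
#' @return list of model records
#' @export
setGeneric("models", function(x) standardGeneric("models"))

#' @rdname models
#' @export
setMethod("models", "DesignResult", function(x) x@models)

#' Per-residue energy table of a breakdown
#' @param x an \linkS4class{EnergyBreakdown}
#' @return data.frame with the five terms and totals
#' @export
setGeneric("perResidue", function(x) standardGeneric("perResidue"))

#' @rdname perResidue
#' @export
setMethod("perResidue", "EnergyBreakdown", function(x) x@perResidue)

#' Aggregate energy of a breakdown
#' @param x an \linkS4class{EnergyBreakdown}
#' @return numeric, kcal/mol
#' @export
setGeneric("aggregateEnergy", function(x) standardGeneric("aggregateEnergy"))

#' @rdname aggregateEnergy
#' @export
setMethod("aggregateEnergy", "EnergyBreakdown", function(x) x@aggregate)

#' Average per-residue energy of a breakdown
#' @param x an \linkS4class{EnergyBreakdown}
#' @return numeric, kcal/mol
#' @export
setGeneric("averageEnergy", function(x) standardGeneric("averageEnergy"))

#' @rdname averageEnergy
#' @export
setMethod("averageEnergy", "EnergyBreakdown", function(x) x@average)

#' Grid specification of a library or environment tensor
#' @param x a \linkS4class{RotamerLibrary} or \linkS4class{EnvironmentTensor}
#' @return a \linkS4class{GridSpec}
#' @export
setGeneric("getGrid", function(x) standardGeneric("getGrid"))

#' @rdname getGrid
#' @export
setMethod("getGrid", "RotamerLibrary", function(x) x@grid)

#' @rdname getGrid
#' @export
setMethod("getGrid", "EnvironmentTensor", function(x) x@grid)

setMethod("show", "ProteinStructure", function(object) {
  rt <- object@resTab
  cat("ProteinStructure:", nrow(rt), "residues,",
      nrow(object@atoms), "atoms,",
      length(unique(rt$chain)), "chain(s)\n")
  if (any(object@atoms$het)) cat("  (heteroatoms flagged for removal)\n")
})

setMethod("show", "ConformerPool", function(object) {
  cat("ConformerPool:", object@aa, "-", length(object@phi), "conformers,",
      ncol(object@chi), "chi angle(s), seed", object@seed, "\n")
})

setMethod("show", "RotamerLibrary", function(object) {
  cat("RotamerLibrary:", length(object@aas), "amino acid(s),",
      "36 (phi,psi) bins each; k =", object@metadata$k, "\n")
  cat("  grid:", object@grid@nvox, "^3 voxels,", object@grid@edge,
      "A edge;  max LJ field:", object@maxLjField, "kcal/mol\n")
})

setMethod("show", "EnvironmentTensor", function(object) {
  cat("EnvironmentTensor:", object@nAtoms, "atoms in grid,",
      object@nOutside, "outside;", nrow(object@occ),
      "occupied (voxel, class) cells\n")
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat("EnergyBreakdown over", nrow(object@perResidue), "residue(s):",
      "total", sprintf("%.3f", object@aggregate),
      "kcal/mol; average", sprintf("%.3f", object@average),
      "kcal/mol per residue\n")
})

setMethod("show", "DesignResult", function(object) {
  cat("DesignResult (", object@protocol, "): ", length(object@models),
      " model(s)\n", sep = "")
  for (i in seq_along(object@models)) {
    m <- object@models[[i]]
    cat(sprintf("  %2d. avg %.3f kcal/mol/res  [%s]\n", i,
                m$breakdown@average,
                if (length(m$mutations) && nzchar(m$mutations))
                  m$mutations else "no mutations"))
    if (i >= 10L) { cat("  ...\n"); break }
  }
})
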