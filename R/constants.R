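## Physical constants and amino-acid bookkeeping shared across the package.

## thermal energy at 298.15 K, kcal/mol
RT_KCAL <- 0.593

## Coulomb constant in kcal*Angstrom/(mol*e^2)
COULOMB_K <- 332.0636

## distance floors (Angstrom) guarding the r -> 0 singularities of the
## closed forms; identical in tensors and in the pairwise oracle
R_MIN_LJ <- 1e-3
R_MIN_ELEC <- 0.05
R_MIN_SOLV <- 0.05

## per-voxel clamp on the summed Lennard-Jones field (kcal/mol per occupant)
DEFAULT_MAX_LJ_FIELD <- 10

## runtime clash ceiling per placed residue (kcal/mol)
DEFAULT_MAX_LJ <- 5

## backbone-torsion energy ceiling applied when the KDE underflows (kcal/mol)
DG_PP_CEILING <- 25

AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
names(AA1) <- AA3

CHI_COUNT <- c(ALA = 0L, ARG = 4L, ASN = 2L, ASP = 2L, CYS = 1L, GLN = 3L,
               GLU = 3L, GLY = 0L, HIS = 2L, ILE = 2L, LEU = 2L, LYS = 4L,
               MET = 3L, PHE = 2L, PRO = 0L, SER = 1L, THR = 1L, TRP = 2L,
               TYR = 2L, VAL = 1L)

#' One-letter code for three-letter residue names
#' @param aa3 character vector of three-letter residue names
#' @return character vector of one-letter codes ("X" when unknown)
#' @export
aaOneLetter <- function(aa3) {
  out <- AA1[toupper(aa3)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Standard amino-acid names understood by the engine
#' @return character vector of the 20 three-letter codes
#' @export
standardAminoAcids <- function() AA3

## wrap angles (degrees) into [-180, 180); +180 maps to the -180 edge so
## every torsion has a single representation for binning
wrapAngle <- function(x) x - 360 * floor((x + 180) / 360)
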