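## Ideal internal-coordinate tables for the heavy-atom peptide builder.
## Bond lengths (Angstrom) and angles (degrees) follow standard small-molecule
## amino-acid geometry; torsions are either fixed values or expressions in the
## side-chain torsions chi1..chi4 ("chi2+120" etc.), evaluated at build time.

## backbone ideal values
BB_GEO <- list(
  n_ca = 1.458, ca_c = 1.525, c_o = 1.231, c_n = 1.329, ca_cb = 1.530,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.0, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8, ang_n_ca_cb = 110.5, ang_c_ca_cb = 110.1,
  ## improper torsion N-C-CA-CB fixing L chirality
  improper_cb = 122.6,
  cap_c_ch3 = 1.510, cap_n_ch3 = 1.455
)

## side-chain z-matrix rows: atom, refs A/B/C (C is the bonded parent),
## bond length, bond angle, torsion expression
zrow <- function(atom, a, b, c, d, ang, tor)
  list(atom = atom, a = a, b = b, c = c, d = d, ang = ang, tor = tor)

SIDE_CHAIN_Z <- list(
  ALA = list(),
  GLY = list(),
  SER = list(zrow("OG", "N", "CA", "CB", 1.417, 110.8, "chi1")),
  CYS = list(zrow("SG", "N", "CA", "CB", 1.808, 113.8, "chi1")),
  THR = list(zrow("OG1", "N", "CA", "CB", 1.433, 109.6, "chi1"),
             zrow("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-120")),
  VAL = list(zrow("CG1", "N", "CA", "CB", 1.521, 110.5, "chi1"),
             zrow("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1+122")),
  ILE = list(zrow("CG1", "N", "CA", "CB", 1.530, 110.4, "chi1"),
             zrow("CG2", "N", "CA", "CB", 1.521, 110.5, "chi1-122"),
             zrow("CD1", "CA", "CB", "CG1", 1.513, 113.9, "chi2")),
  LEU = list(zrow("CG", "N", "CA", "CB", 1.530, 113.8, "chi1"),
             zrow("CD1", "CA", "CB", "CG", 1.521, 110.7, "chi2"),
             zrow("CD2", "CA", "CB", "CG", 1.521, 110.7, "chi2+122")),
  MET = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             zrow("SD", "CA", "CB", "CG", 1.803, 112.7, "chi2"),
             zrow("CE", "CB", "CG", "SD", 1.791, 100.9, "chi3")),
  PHE = list(zrow("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
             zrow("CD1", "CA", "CB", "CG", 1.384, 120.8, "chi2"),
             zrow("CD2", "CA", "CB", "CG", 1.384, 120.8, "chi2+180"),
             zrow("CE1", "CB", "CG", "CD1", 1.382, 120.8, "180"),
             zrow("CE2", "CB", "CG", "CD2", 1.382, 120.8, "180"),
             zrow("CZ", "CG", "CD1", "CE1", 1.382, 120.0, "0")),
  TYR = list(zrow("CG", "N", "CA", "CB", 1.502, 113.8, "chi1"),
             zrow("CD1", "CA", "CB", "CG", 1.384, 120.8, "chi2"),
             zrow("CD2", "CA", "CB", "CG", 1.384, 120.8, "chi2+180"),
             zrow("CE1", "CB", "CG", "CD1", 1.382, 120.8, "180"),
             zrow("CE2", "CB", "CG", "CD2", 1.382, 120.8, "180"),
             zrow("CZ", "CG", "CD1", "CE1", 1.382, 120.0, "0"),
             zrow("OH", "CD1", "CE1", "CZ", 1.376, 119.9, "180")),
  TRP = list(zrow("CG", "N", "CA", "CB", 1.498, 113.6, "chi1"),
             zrow("CD1", "CA", "CB", "CG", 1.365, 126.9, "chi2"),
             zrow("CD2", "CA", "CB", "CG", 1.433, 126.7, "chi2+180"),
             zrow("NE1", "CB", "CG", "CD1", 1.374, 110.2, "180"),
             zrow("CE2", "CB", "CG", "CD2", 1.409, 107.2, "180"),
             zrow("CE3", "CB", "CG", "CD2", 1.398, 133.9, "0"),
             zrow("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, "180"),
             zrow("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, "180"),
             zrow("CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, "0")),
  PRO = list(zrow("CG", "N", "CA", "CB", 1.492, 104.5, "28"),
             zrow("CD", "CA", "CB", "CG", 1.503, 106.1, "-34")),
  ASP = list(zrow("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
             zrow("OD1", "CA", "CB", "CG", 1.249, 118.4, "chi2"),
             zrow("OD2", "CA", "CB", "CG", 1.249, 118.4, "chi2+180")),
  ASN = list(zrow("CG", "N", "CA", "CB", 1.516, 112.6, "chi1"),
             zrow("OD1", "CA", "CB", "CG", 1.231, 120.8, "chi2"),
             zrow("ND2", "CA", "CB", "CG", 1.328, 116.4, "chi2+180")),
  GLU = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             zrow("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             zrow("OE1", "CB", "CG", "CD", 1.249, 118.4, "chi3"),
             zrow("OE2", "CB", "CG", "CD", 1.249, 118.4, "chi3+180")),
  GLN = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             zrow("CD", "CA", "CB", "CG", 1.516, 112.6, "chi2"),
             zrow("OE1", "CB", "CG", "CD", 1.231, 120.8, "chi3"),
             zrow("NE2", "CB", "CG", "CD", 1.328, 116.4, "chi3+180")),
  LYS = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             zrow("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
             zrow("CE", "CB", "CG", "CD", 1.520, 111.3, "chi3"),
             zrow("NZ", "CG", "CD", "CE", 1.489, 111.9, "chi4")),
  ARG = list(zrow("CG", "N", "CA", "CB", 1.520, 114.1, "chi1"),
             zrow("CD", "CA", "CB", "CG", 1.520, 111.3, "chi2"),
             zrow("NE", "CB", "CG", "CD", 1.460, 112.0, "chi3"),
             zrow("CZ", "CG", "CD", "NE", 1.329, 124.2, "chi4"),
             zrow("NH1", "CD", "NE", "CZ", 1.326, 120.0, "0"),
             zrow("NH2", "CD", "NE", "CZ", 1.326, 120.0, "180")),
  HIS = list(zrow("CG", "N", "CA", "CB", 1.497, 113.8, "chi1"),
             zrow("ND1", "CA", "CB", "CG", 1.371, 122.7, "chi2"),
             zrow("CD2", "CA", "CB", "CG", 1.356, 131.0, "chi2+180"),
             zrow("CE1", "CB", "CG", "ND1", 1.319, 109.3, "180"),
             zrow("NE2", "CB", "CG", "CD2", 1.374, 107.2, "180"))
)

## the four torsion-defining atoms of each chi, in order chi1..chiN;
## chi k is the torsion over (prev3, atom) along the side chain
CHI_ATOMS <- list(
  SER = list(c("N","CA","CB","OG")),
  CYS = list(c("N","CA","CB","SG")),
  THR = list(c("N","CA","CB","OG1")),
  VAL = list(c("N","CA","CB","CG1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1"))
)

## canonical heavy atoms per residue (backbone + side chain, build order)
canonicalAtoms <- function(aa) {
  bb <- c("N", "CA", "C", "O")
  if (aa == "GLY") return(bb)
  c(bb, "CB", vapply(SIDE_CHAIN_Z[[aa]], function(z) z$atom, character(1)))
}

## side-chain atoms including CB (stored in rotamers); beyond-CB subset is
## what interacts with the environment
sideChainAtoms <- function(aa) {
  if (aa == "GLY") return(character(0))
  c("CB", vapply(SIDE_CHAIN_Z[[aa]], function(z) z$atom, character(1)))
}

## evaluate a torsion expression against a chi vector (degrees)
evalTorsion <- function(expr, chi) {
  if (grepl("^chi", expr)) {
    k <- as.integer(substr(expr, 4, 4))
    off <- 0
    rest <- substr(expr, 5, nchar(expr))
    if (nzchar(rest)) off <- as.numeric(rest)
    wrapAngle(chi[k] + off)
  } else as.numeric(expr)
}
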