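## Closed-form interaction terms and the per-rotamer field tensors.
##
## The three terms share one algebraic structure: for a voxel center at
## distance r from a rotamer atom of class a, the field gives the energy a
## unit occupant of environment class t (or unit charge, for the
## electrostatic term) would contribute. Distances are floored near r = 0;
## the per-(voxel, class) summed LJ field is clamped at maxLjField. The
## identical closed forms drive the dense tensors, the sparse runtime
## contraction and the pairwise verification oracle.

## 12-6 Lennard-Jones with Lorentz-Berthelot combination; eps/rmin are the
## combined pair parameters (rmin = distance at the minimum)
ljPairEnergy <- function(d, eps, rmin) {
  d <- pmax(d, R_MIN_LJ)
  x <- (rmin / d)^6
  eps * (x * x - 2 * x)
}

## Coulomb with distance-dependent dielectric eps(r) = 4r, per unit
## environment charge: k q_a / (4 r^2)
elecPerCharge <- function(d, q) {
  d <- pmax(d, R_MIN_ELEC)
  COULOMB_K * q / (4 * d^2)
}

## Gaussian solvent-exclusion (Lazaridis-Karplus shape), symmetric in the
## two classes: -(f_a(r) V_t + f_t(r) V_a) with
## f_i(r) = Gref_i / (2 pi^1.5 lambda_i r^2) exp(-((r - R_i)/lambda_i)^2)
solvPairEnergy <- function(d, grefA, lamA, rA, volA, grefT, lamT, rT, volT) {
  d <- pmax(d, R_MIN_SOLV)
  fA <- grefA / (2 * pi^1.5 * lamA * d^2) * exp(-((d - rA) / lamA)^2)
  fT <- grefT / (2 * pi^1.5 * lamT * d^2) * exp(-((d - rT) / lamT)^2)
  -(fA * volT + fT * volA)
}

## voxel center coordinate along one axis for 1-based index i
voxelCenters <- function(grid) {
  ext <- gridExtent(grid)
  -ext / 2 + (seq_len(grid@nvox) - 0.5) * grid@edge
}

## all voxel centers as an nvox^3 x 3 matrix (x fastest)
allVoxelCenters <- function(grid) {
  v <- voxelCenters(grid)
  as.matrix(expand.grid(x = v, y = v, z = v, KEEP.OUT.ATTRS = FALSE))
}

#' Assemble a rotamer payload for tensor evaluation
#'
#' A rotamer payload bundles the local-frame coordinates of a side chain's
#' interacting (beyond-CB) atoms with their atom classes and partial
#' charges; it is the unit \link{computeFieldTensor},
#' \link{interactionEnergy} and \link{pairwiseOracle} operate on.
#'
#' @param coords n x 3 matrix of local-frame coordinates, Angstrom
#' @param classIds integer atom-class ids into the parameter table
#' @param charges partial charges, e
#' @return list with coords, classIds, charges
#' @export
rotamerPayload <- function(coords, classIds, charges) {
  coords <- rbind3(coords)
  stopifnot(nrow(coords) == length(classIds),
            length(classIds) == length(charges))
  list(coords = coords, classIds = as.integer(classIds),
       charges = as.numeric(charges))
}

#' Precompute a field tensor for one rotamer
#'
#' For every voxel (taken at its center) and environment atom class, the
#' tensor holds the interaction energy a unit occupant of that class at
#' that voxel would have with the whole rotamer: \code{lj} and \code{solv}
#' give 4-D arrays (x, y, z, class); \code{elec} factorizes over charge and
#' gives a 3-D per-unit-charge array. The summed LJ value is clamped
#' per (voxel, class) at \code{maxLjField}. Rotamer atoms lying outside
#' the grid extent contribute to no voxel and are dropped with a message.
#'
#' @param rot rotamer payload: list with coords (n x 3 local-frame matrix),
#'   classIds, charges (see \link{binRotamers} output plus
#'   \link{rotamerFromBin})
#' @param term one of "lj", "elec", "solv"
#' @param grid a \linkS4class{GridSpec}
#' @param table a \linkS4class{ParameterTable}
#' @param maxLjField per-voxel clamp, kcal/mol
#' @return numeric array (4-D for lj/solv, 3-D for elec)
#' @export
computeFieldTensor <- function(rot, term = c("lj", "elec", "solv"),
                               grid = gridSpec(), table = loadParameterTable(),
                               maxLjField = DEFAULT_MAX_LJ_FIELD) {
  term <- match.arg(term)
  nv <- grid@nvox
  nc <- nrow(table@classes)
  centers <- allVoxelCenters(grid)
  co <- rbind3(rot$coords)
  if (nrow(co)) {
    inside <- apply(abs(co) <= gridExtent(grid) / 2, 1, all)
    if (any(!inside)) {
      message(sum(!inside), " rotamer atom(s) beyond grid extent ignored")
      co <- co[inside, , drop = FALSE]
      rot <- list(coords = co, classIds = rot$classIds[inside],
                  charges = rot$charges[inside])
    }
  }
  if (term == "elec") {
    out <- numeric(nv^3)
    for (a in seq_len(nrow(co))) {
      d <- sqrt(rowSums(sweep(centers, 2, co[a, ])^2))
      out <- out + elecPerCharge(d, rot$charges[a])
    }
    return(array(out, c(nv, nv, nv)))
  }
  out <- matrix(0, nv^3, nc)
  cl <- table@classes
  for (a in seq_len(nrow(co))) {
    d <- sqrt(rowSums(sweep(centers, 2, co[a, ])^2))
    ca <- rot$classIds[a]
    for (t in seq_len(nc)) {
      out[, t] <- out[, t] + if (term == "lj")
        ljPairEnergy(d, table@pairEps[ca, t], table@pairRmin[ca, t])
      else
        solvPairEnergy(d, cl$gref[ca], cl$lambda[ca], cl$rmin2[ca],
                       cl$vol[ca], cl$gref[t], cl$lambda[t], cl$rmin2[t],
                       cl$vol[t])
    }
  }
  if (term == "lj") out <- pmin(out, maxLjField)
  array(out, c(nv, nv, nv, nc))
}

#' Dense occupancy array of an environment tensor
#' @param env an \linkS4class{EnvironmentTensor}
#' @param nclass number of atom-class channels (defaults to the highest
#'   occupied class)
#' @return 4-D array (x, y, z, class) of atom counts
#' @export
denseOccupancy <- function(env, nclass = NULL) {
  nv <- env@grid@nvox
  nc <- if (!is.null(nclass)) as.integer(nclass)
        else max(env@occ[, "class"], 1L)
  out <- array(0, c(nv, nv, nv, nc))
  if (nrow(env@occ))
    out[env@occ[, c("ix", "iy", "iz", "class"), drop = FALSE]] <-
      env@occ[, "count"]
  out
}

#' Dense per-voxel summed-charge array of an environment tensor
#' @param env an \linkS4class{EnvironmentTensor}
#' @return 3-D array of summed partial charges
#' @export
denseCharge <- function(env) {
  nv <- env@grid@nvox
  out <- array(0, c(nv, nv, nv))
  if (nrow(env@charge))
    out[env@charge[, c("ix", "iy", "iz"), drop = FALSE]] <-
      env@charge[, "q"]
  out
}
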