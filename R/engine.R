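## Runtime energy engine: environment histograms in the target's local
## frame, tensor contraction for the three interaction terms, the explicit
## pairwise oracle, and the five-term total-energy breakdown.

## atoms of residue i that lie beyond CB (the interacting side chain)
beyondCBRows <- function(s, i) {
  rows <- resAtomRows(s, i)
  rows[!s@atoms$elety[rows] %in% c("N", "CA", "C", "O", "CB")]
}

## environment exclusion for a target position: own backbone window
## (N, CA, C, O, CB), the preceding peptide unit's C/O and the following N
environmentExclusion <- function(s, i) {
  rows <- resAtomRows(s, i)
  excl <- rows[s@atoms$elety[rows] %in% c("N", "CA", "C", "O", "CB")]
  rt <- s@resTab
  if (i > 1 && rt$chain[i - 1] == rt$chain[i]) {
    prev <- resAtomRows(s, i - 1L)
    excl <- c(excl, prev[s@atoms$elety[prev] %in% c("C", "O")])
  }
  if (i < nrow(rt) && rt$chain[i + 1] == rt$chain[i]) {
    nxt <- resAtomRows(s, i + 1L)
    excl <- c(excl, nxt[s@atoms$elety[nxt] == "N"])
  }
  excl
}

#' Delete the side chain of a target position
#'
#' Removes the heavy atoms beyond CB; backbone and CB remain (CB is treated
#' as backbone for environment purposes). Glycine is a no-op with a warning.
#'
#' @param s a preprocessed \linkS4class{ProteinStructure}
#' @param pos position "chain:resno"
#' @return the structure without that side chain
#' @export
stripSideChain <- function(s, pos) {
  i <- resTabIndex(s, pos)
  if (s@resTab$aa[i] == "GLY") {
    warning("stripSideChain is a no-op for glycine at ", pos)
    return(s)
  }
  drop <- beyondCBRows(s, i)
  if (length(drop)) s@atoms <- s@atoms[-drop, , drop = FALSE]
  s@provenance <- c(s@provenance, paste("stripped side chain at", pos))
  s
}

## histogram a set of local-frame atoms into the sparse environment tensor
envTensorFromLocal <- function(xyz, classIds, charges, grid) {
  nv <- grid@nvox
  ext <- gridExtent(grid)
  if (length(classIds)) {
    idx <- floor((xyz + ext / 2) / grid@edge) + 1
    inGrid <- rowSums(idx >= 1 & idx <= nv) == 3L
  } else {
    idx <- matrix(0L, 0, 3)
    inGrid <- logical(0)
  }
  nOut <- sum(!inGrid)
  idx <- matrix(as.integer(idx[inGrid, , drop = FALSE]), ncol = 3)
  cls <- as.integer(classIds[inGrid])
  q <- as.numeric(charges[inGrid])
  if (nrow(idx)) {
    keyOcc <- paste(idx[, 1], idx[, 2], idx[, 3], cls)
    occAgg <- rowsum(rep(1L, nrow(idx)), keyOcc, reorder = TRUE)
    occIdx <- match(rownames(occAgg), keyOcc)
    occ <- cbind(ix = idx[occIdx, 1], iy = idx[occIdx, 2],
                 iz = idx[occIdx, 3], class = cls[occIdx],
                 count = as.integer(occAgg[, 1]))
    keyVox <- paste(idx[, 1], idx[, 2], idx[, 3])
    qAgg <- rowsum(q, keyVox, reorder = TRUE)
    qIdx <- match(rownames(qAgg), keyVox)
    charge <- cbind(ix = idx[qIdx, 1], iy = idx[qIdx, 2],
                    iz = idx[qIdx, 3], q = qAgg[, 1])
  } else {
    occ <- matrix(integer(0), 0, 5,
                  dimnames = list(NULL, c("ix", "iy", "iz", "class", "count")))
    charge <- matrix(numeric(0), 0, 4,
                     dimnames = list(NULL, c("ix", "iy", "iz", "q")))
  }
  new("EnvironmentTensor", grid = grid, occ = occ, charge = charge,
      nOutside = as.integer(nOut), nAtoms = as.integer(sum(inGrid)))
}

#' Build the environment tensor around a target position
#'
#' Every atom of the structure except the target's own backbone window
#' (N, CA, C, O, CB, the preceding peptide C/O and the following N) and its
#' own side chain is transformed into the residue-local frame and binned
#' into the voxel grid (half-open voxels: a boundary atom goes to the
#' higher-index voxel). Atoms outside the grid are counted but ignored.
#'
#' @param s a preprocessed \linkS4class{ProteinStructure}
#' @param pos position "chain:resno"
#' @param grid a \linkS4class{GridSpec}
#' @return an \linkS4class{EnvironmentTensor}
#' @export
buildEnvironmentTensor <- function(s, pos, grid = gridSpec()) {
  i <- resTabIndex(s, pos)
  excl <- c(environmentExclusion(s, i), beyondCBRows(s, i))
  frame <- residueFrame(s, i)
  keep <- setdiff(which(!s@atoms$het), excl)
  xyz <- toLocal(frame, as.matrix(s@atoms[keep, c("x", "y", "z")]))
  envTensorFromLocal(xyz, s@atoms$class_id[keep], s@atoms$charge[keep], grid)
}

residueFrame <- function(s, i) {
  rows <- resAtomRows(s, i)
  p <- function(n) {
    j <- rows[s@atoms$elety[rows] == n]
    if (!length(j)) stop("missing backbone atom ", n, " at residue ", i)
    as.numeric(s@atoms[j[1], c("x", "y", "z")])
  }
  localFrame(p("N"), p("CA"), p("C"))
}

#' Tensor-contraction interaction energies of a rotamer in an environment
#'
#' Contracts the rotamer's field tensors with the environment histogram:
#' E_lj and E_solv over (voxel, class) occupancy, E_elec over per-voxel
#' summed charge. The contraction is evaluated on the occupied support of
#' the sparse histogram, which is algebraically identical to the dense
#' element-wise product (unoccupied voxels multiply zero).
#'
#' @param rot rotamer payload (coords, classIds, charges), local frame
#' @param env an \linkS4class{EnvironmentTensor} on the same grid
#' @param table a \linkS4class{ParameterTable}
#' @param maxLjField per-voxel LJ clamp, kcal/mol
#' @return named numeric: E_lj, E_elec, E_solv (kcal/mol)
#' @export
interactionEnergy <- function(rot, env, table = loadParameterTable(),
                              maxLjField = DEFAULT_MAX_LJ_FIELD) {
  co <- rbind3(rot$coords)
  zero <- c(E_lj = 0, E_elec = 0, E_solv = 0)
  if (!nrow(co) || (nrow(env@occ) == 0 && nrow(env@charge) == 0)) return(zero)
  ext <- gridExtent(env@grid)
  centerOf <- function(ixyz)
    -ext / 2 + (ixyz - 0.5) * env@grid@edge
  cl <- table@classes
  eLJ <- eSolv <- 0
  if (nrow(env@occ)) {
    centers <- centerOf(env@occ[, c("ix", "iy", "iz"), drop = FALSE])
    tcl <- env@occ[, "class"]
    cnt <- env@occ[, "count"]
    nr <- nrow(centers)
    sumLJ <- numeric(nr); sumSv <- numeric(nr)
    for (a in seq_len(nrow(co))) {
      d <- sqrt((centers[, 1] - co[a, 1])^2 + (centers[, 2] - co[a, 2])^2 +
                (centers[, 3] - co[a, 3])^2)
      ca <- rot$classIds[a]
      sumLJ <- sumLJ + ljPairEnergy(d, table@pairEps[ca, tcl],
                                    table@pairRmin[ca, tcl])
      sumSv <- sumSv + solvPairEnergy(d, cl$gref[ca], cl$lambda[ca],
                                      cl$rmin2[ca], cl$vol[ca],
                                      cl$gref[tcl], cl$lambda[tcl],
                                      cl$rmin2[tcl], cl$vol[tcl])
    }
    eLJ <- sum(pmin(sumLJ, maxLjField) * cnt)
    eSolv <- sum(sumSv * cnt)
  }
  eEl <- 0
  if (nrow(env@charge)) {
    centers <- centerOf(env@charge[, c("ix", "iy", "iz"), drop = FALSE])
    qv <- env@charge[, "q"]
    fld <- numeric(nrow(centers))
    for (a in seq_len(nrow(co))) {
      d <- sqrt((centers[, 1] - co[a, 1])^2 + (centers[, 2] - co[a, 2])^2 +
                (centers[, 3] - co[a, 3])^2)
      fld <- fld + elecPerCharge(d, rot$charges[a])
    }
    eEl <- sum(fld * qv)
  }
  c(E_lj = eLJ, E_elec = eEl, E_solv = eSolv)
}

#' Explicit atom-pair oracle for the interaction terms
#'
#' Double loop over rotamer atoms x environment atoms with the identical
#' closed forms and clamping as the tensor path. With \code{snapped = TRUE}
#' each environment atom is first moved to the center of its voxel (atoms
#' outside the grid are dropped, as in the histogram), which makes the
#' oracle definitionally equal to the tensor contraction.
#'
#' @param rot rotamer payload (local frame)
#' @param envAtoms data.frame with x, y, z (local frame), class_id, charge
#' @param snapped move environment atoms to voxel centers first
#' @param grid a \linkS4class{GridSpec}
#' @param table a \linkS4class{ParameterTable}
#' @param maxLjField per-voxel LJ clamp, kcal/mol
#' @return named numeric: E_lj, E_elec, E_solv
#' @export
pairwiseOracle <- function(rot, envAtoms, snapped = TRUE, grid = gridSpec(),
                           table = loadParameterTable(),
                           maxLjField = DEFAULT_MAX_LJ_FIELD) {
  co <- rbind3(rot$coords)
  if (!nrow(co) || !nrow(envAtoms)) return(c(E_lj = 0, E_elec = 0, E_solv = 0))
  xyz <- as.matrix(envAtoms[, c("x", "y", "z")])
  if (snapped) {
    nv <- grid@nvox; ext <- gridExtent(grid)
    idx <- floor((xyz + ext / 2) / grid@edge) + 1
    inGrid <- rowSums(idx >= 1 & idx <= nv) == 3L
    envAtoms <- envAtoms[inGrid, , drop = FALSE]
    xyz <- -ext / 2 + (idx[inGrid, , drop = FALSE] - 0.5) * grid@edge
  }
  cl <- table@classes
  eLJ <- eEl <- eSolv <- 0
  for (e in seq_len(nrow(xyz))) {
    d <- sqrt(colSums((t(co) - xyz[e, ])^2))
    te <- envAtoms$class_id[e]
    lj <- 0; elv <- 0; sv <- 0
    for (a in seq_len(nrow(co))) {
      ca <- rot$classIds[a]
      lj <- lj + ljPairEnergy(d[a], table@pairEps[ca, te],
                              table@pairRmin[ca, te])
      elv <- elv + elecPerCharge(d[a], rot$charges[a]) * envAtoms$charge[e]
      sv <- sv + solvPairEnergy(d[a], cl$gref[ca], cl$lambda[ca],
                                cl$rmin2[ca], cl$vol[ca], cl$gref[te],
                                cl$lambda[te], cl$rmin2[te], cl$vol[te])
    }
    eLJ <- eLJ + min(lj, maxLjField)
    eEl <- eEl + elv
    eSolv <- eSolv + sv
  }
  c(E_lj = eLJ, E_elec = eEl, E_solv = eSolv)
}

## side-chain coordinates (rows named, CB included) of bin rotamer j;
## keeps the matrix shape and rownames even for single-atom side chains
binCoords <- function(b, j) {
  matrix(b$coords[, , j, drop = FALSE], ncol = 3,
         dimnames = list(dimnames(b$coords)[[1]], NULL))
}

## rotamer payload of library bin rotamer j (beyond-CB atoms only)
rotamerFromBin <- function(lib, aa, bin, j) {
  b <- binRotamers(lib, aa, bin)
  if (is.null(b)) stop("empty rotamer bin ", bin, " for ", aa)
  nm <- dimnames(b$coords)[[1]]
  beyond <- nm != "CB"
  pars <- if (any(beyond))
    lookupAtomParams(lib@table, rep(aa, sum(beyond)), nm[beyond])
  else list(class_id = integer(0), charge = numeric(0))
  co <- binCoords(b, j)
  rotamerPayload(co[nm != "CB", , drop = FALSE], pars$class_id, pars$charge)
}

## current side chain of residue i as a rotamer payload in its local frame
currentSideChainPayload <- function(s, i) {
  rows <- beyondCBRows(s, i)
  frame <- residueFrame(s, i)
  if (!length(rows))
    return(rotamerPayload(matrix(0, 0, 3), integer(0), numeric(0)))
  rotamerPayload(toLocal(frame, as.matrix(s@atoms[rows, c("x", "y", "z")])),
                 s@atoms$class_id[rows], s@atoms$charge[rows])
}

#' Five-term energy breakdown over selected residues
#'
#' For each position: dG_pp from the library's backbone energy map (0 with
#' a flag when phi or psi is undefined at a chain terminus); dG_k of the
#' nearest library rotamer (side-chain RMSD in the local frame, ties to the
#' lower rotamer index) in the position's (phi, psi) bin; and the three
#' interaction terms from the tensor contraction of the current side chain
#' against its environment histogram. Totals are summed in residue order;
#' the average per-residue energy makes runs on proteins of different sizes
#' comparable.
#'
#' @param s a preprocessed \linkS4class{ProteinStructure}
#' @param positions character vector "chain:resno" (default: all residues)
#' @param lib a \linkS4class{RotamerLibrary} containing the residues' amino
#'   acids
#' @return an \linkS4class{EnergyBreakdown}
#' @export
totalEnergy <- function(s, positions = NULL, lib) {
  if (is.null(positions))
    positions <- paste0(s@resTab$chain, ":", s@resTab$resno)
  idx <- resTabIndex(s, positions)
  rows <- vector("list", length(idx))
  for (n in seq_along(idx)) {
    i <- idx[n]
    aa <- s@resTab$aa[i]
    phi <- s@resTab$phi[i]; psi <- s@resTab$psi[i]
    ppUndef <- is.na(phi) || is.na(psi)
    dGpp <- if (ppUndef) 0 else backboneEnergy(lib, aa, phi, psi)
    bphi <- if (is.na(phi)) 0 else phi
    bpsi <- if (is.na(psi)) 0 else psi
    bin <- assignBin(bphi, bpsi)
    rot <- currentSideChainPayload(s, i)
    dGk <- 0
    if (nrow(rot$coords)) {
      b <- binRotamers(lib, aa, bin)
      if (!is.null(b)) {
        nm <- dimnames(b$coords)[[1]]
        beyond <- which(nm != "CB")
        scRows <- beyondCBRows(s, i)
        ord <- match(nm[beyond], s@atoms$elety[scRows])
        cur <- rot$coords[ord, , drop = FALSE]
        rmsd2 <- vapply(seq_along(b$dGk), function(j)
          mean(rowSums((b$coords[beyond, , j, drop = FALSE][, , 1] -
                          cur)^2)), numeric(1))
        dGk <- b$dGk[which.min(rmsd2)]
      }
    }
    env <- buildEnvironmentTensor(s, positions[n], lib@grid)
    ie <- interactionEnergy(rot, env, lib@table, lib@maxLjField)
    rows[[n]] <- data.frame(
      chain = s@resTab$chain[i], resno = s@resTab$resno[i], aa = aa,
      dG_pp = dGpp, dG_k = dGk, E_lj = unname(ie["E_lj"]),
      E_elec = unname(ie["E_elec"]), E_solv = unname(ie["E_solv"]),
      total = dGpp + dGk + sum(ie), ppUndefined = ppUndef,
      stringsAsFactors = FALSE)
  }
  pr <- do.call(rbind, rows)
  new("EnergyBreakdown", perResidue = pr, aggregate = sum(pr$total),
      average = sum(pr$total) / nrow(pr))
}
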