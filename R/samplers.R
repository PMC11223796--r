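## The four design protocols: deterministic repacking, single-point
## mutagenesis with an adaptive LJ ceiling, the swarm combinatorial
## sampler, and sequence-symmetric design.

#' Construct a design specification
#'
#' @param repackable ordered character vector of positions "chain:resno"
#'   re-optimized at fixed amino acid
#' @param mutable named list mapping positions to allowed amino-acid sets;
#'   the shortcuts "all", "polar", "nonpolar" expand to the corresponding
#'   amino-acid classes
#' @param symmetry list of position vectors constrained to one amino acid
#'   per group (sequence-level symmetry; rotamers stay independent)
#' @param nPaths,nIters swarm breadth and depth
#' @param scrambleOrder randomize each path's visiting order (default TRUE)
#' @param maxLj clash ceiling, kcal/mol
#' @param sweeps repack sweeps
#' @param seed RNG seed
#' @return a \linkS4class{DesignSpec}
#' @export
designSpec <- function(repackable = character(0), mutable = list(),
                       symmetry = list(), nPaths = 5L, nIters = 10L,
                       scrambleOrder = TRUE, maxLj = DEFAULT_MAX_LJ,
                       sweeps = 2L, seed = 1L) {
  mutable <- lapply(mutable, expandAAClass)
  new("DesignSpec", repackable = repackable, mutable = mutable,
      symmetry = symmetry, nPaths = as.integer(nPaths),
      nIters = as.integer(nIters), scrambleOrder = scrambleOrder,
      maxLj = as.numeric(maxLj), sweeps = as.integer(sweeps),
      seed = as.integer(seed))
}

POLAR_AA <- c("ARG", "ASN", "ASP", "GLN", "GLU", "HIS", "LYS", "SER",
              "THR", "TYR")
NONPOLAR_AA <- c("ALA", "CYS", "GLY", "ILE", "LEU", "MET", "PHE", "PRO",
                 "TRP", "VAL")

expandAAClass <- function(x) {
  out <- unlist(lapply(x, function(a) switch(tolower(a),
    all = AA3, polar = POLAR_AA, nonpolar = NONPOLAR_AA, toupper(a))))
  bad <- setdiff(out, AA3)
  if (length(bad)) stop("unknown amino acid(s) in design spec: ",
                        paste(bad, collapse = ", "))
  unique(out)
}

## evaluate all library rotamers of (aa, position bin) against the stripped
## environment; scores include dG_pp of the amino acid at the backbone
evalRotamers <- function(s, pos, aa, lib) {
  i <- resTabIndex(s, pos)
  phi <- s@resTab$phi[i]; psi <- s@resTab$psi[i]
  bphi <- if (is.na(phi)) 0 else phi
  bpsi <- if (is.na(psi)) 0 else psi
  bin <- assignBin(bphi, bpsi)
  b <- binRotamers(lib, aa, bin)
  if (is.null(b))
    stop("no rotamers for ", aa, " in (phi,psi) bin ", bin)
  sStr <- if (length(beyondCBRows(s, i))) stripSideChain(s, pos) else s
  env <- buildEnvironmentTensor(sStr, pos, lib@grid)
  nm <- dimnames(b$coords)[[1]]
  beyond <- which(nm != "CB")
  pars <- if (length(beyond))
    lookupAtomParams(lib@table, rep(aa, length(beyond)), nm[beyond])
  else list(class_id = integer(0), charge = numeric(0))
  k <- length(b$dGk)
  sc <- matrix(0, k, 3, dimnames = list(NULL, c("E_lj", "E_elec", "E_solv")))
  for (j in seq_len(k)) {
    rot <- rotamerPayload(
      if (length(beyond)) b$coords[beyond, , j, drop = FALSE][, , 1]
      else matrix(0, 0, 3), pars$class_id, pars$charge)
    sc[j, ] <- interactionEnergy(rot, env, lib@table, lib@maxLjField)
  }
  dGpp <- if (is.na(phi) || is.na(psi)) 0
          else backboneEnergy(lib, aa, phi, psi)
  list(bin = bin, b = b, stripped = sStr, dGpp = dGpp,
       scores = data.frame(rotamer = seq_len(k), dG_k = b$dGk, sc,
                           total = dGpp + b$dGk + rowSums(sc)),
       nEval = k)
}

## replace residue i's side chain (and amino-acid identity) with local-frame
## coordinates coords (rows named, CB included); atoms retyped from table
installSideChain <- function(s, pos, aa, coords, table) {
  i <- resTabIndex(s, pos)
  frame <- residueFrame(s, i)
  rows <- resAtomRows(s, i)
  bbRows <- rows[s@atoms$elety[rows] %in% c("N", "CA", "C", "O")]
  scNames <- rownames(coords)
  glob <- toGlobal(frame, coords)
  bb <- s@atoms[bbRows, , drop = FALSE]
  bb$resid <- aa
  bbPars <- lookupAtomParams(table, bb$resid, bb$elety)
  bb$class_id <- bbPars$class_id; bb$charge <- bbPars$charge
  block <- bb
  if (length(scNames)) {
    pars <- lookupAtomParams(table, rep(aa, length(scNames)), scNames)
    sc <- bb[rep(1L, length(scNames)), , drop = FALSE]
    sc$elety <- scNames
    sc$element <- substr(gsub("[0-9]", "", scNames), 1, 1)
    sc$x <- glob[, 1]; sc$y <- glob[, 2]; sc$z <- glob[, 3]
    sc$class_id <- pars$class_id; sc$charge <- pars$charge
    block <- rbind(bb, sc)
  }
  before <- if (min(rows) > 1) s@atoms[seq_len(min(rows) - 1L), , drop = FALSE]
            else s@atoms[0, , drop = FALSE]
  after <- if (max(rows) < nrow(s@atoms))
    s@atoms[(max(rows) + 1L):nrow(s@atoms), , drop = FALSE]
  else s@atoms[0, , drop = FALSE]
  s@atoms <- rbind(before, block, after)
  rownames(s@atoms) <- NULL
  s@resTab$aa[i] <- aa
  s
}

#' Place the best library rotamer at a position
#'
#' Evaluates dG_k plus the tensor-contraction interaction terms for every
#' rotamer of the amino acid in the position's (phi, psi) bin and installs
#' the total-energy minimizer among rotamers whose E_lj is below the clash
#' ceiling (ties break to the lower rotamer index). When no rotamer clears
#' the ceiling the overall minimizer is installed and the clash flag set.
#'
#' @param s a preprocessed \linkS4class{ProteinStructure}
#' @param pos position "chain:resno"
#' @param aa amino acid to place
#' @param lib a \linkS4class{RotamerLibrary}
#' @param maxLj clash ceiling, kcal/mol
#' @return list: structure, energy (position total incl. dG_pp), terms
#'   (named numeric), clash (logical), nEval, rotamer (index chosen)
#' @export
placeBestRotamer <- function(s, pos, aa, lib, maxLj = DEFAULT_MAX_LJ) {
  ev <- evalRotamers(s, pos, aa, lib)
  adm <- which(ev$scores$E_lj < maxLj)
  clash <- length(adm) == 0
  cand <- if (clash) seq_len(nrow(ev$scores)) else adm
  j <- cand[which.min(ev$scores$total[cand])]
  out <- installSideChain(ev$stripped, pos, aa, binCoords(ev$b, j),
                          lib@table)
  list(structure = out, energy = ev$scores$total[j],
       terms = c(dG_pp = ev$dGpp, dG_k = ev$scores$dG_k[j],
                 E_lj = ev$scores$E_lj[j], E_elec = ev$scores$E_elec[j],
                 E_solv = ev$scores$E_solv[j]),
       clash = clash, nEval = ev$nEval, rotamer = j)
}

## one deterministic repack pass over positions (wild-type amino acids)
repackSweeps <- function(s, positions, lib, maxLj, sweeps) {
  for (sw in seq_len(sweeps))
    for (pos in positions) {
      aa <- s@resTab$aa[resTabIndex(s, pos)]
      if (aa == "GLY") next
      s <- placeBestRotamer(s, pos, aa, lib, maxLj)$structure
    }
  s
}

structureSequence <- function(s) paste(chainSequences(s), collapse = "/")

mutationString <- function(sIn, sOut) {
  a <- sIn@resTab; b <- sOut@resTab
  stopifnot(nrow(a) == nrow(b))
  ch <- which(a$aa != b$aa)
  if (!length(ch)) return("")
  paste(sprintf("%s:%d:%s>%s", a$chain[ch], a$resno[ch], a$aa[ch],
                b$aa[ch]), collapse = ",")
}

newModel <- function(sIn, sOut, selection, lib, pathId = 1L,
                     iteration = 0L, extras = list()) {
  c(list(structure = sOut,
         breakdown = totalEnergy(sOut, selection, lib),
         mutations = mutationString(sIn, sOut),
         pathId = pathId, iteration = iteration), extras)
}

sortModels <- function(models) {
  if (!length(models)) return(models)
  models[order(vapply(models, function(m) m$breakdown@average, numeric(1)))]
}

#' Deterministic side-chain repacking
#'
#' Fixed number of sweeps over the repackable positions in their input
#' order; each visit installs the best wild-type rotamer. Fully
#' deterministic: two runs on the same input are identical.
#'
#' @param s a preprocessed \linkS4class{ProteinStructure}
#' @param spec a \linkS4class{DesignSpec} with repackable positions (no
#'   mutations)
#' @param lib a \linkS4class{RotamerLibrary}
#' @param minimizer optional all-atom minimization hook applied to the
#'   input and to each output model (a function Structure -> Structure);
#'   the default is the identity — no minimization is performed
#' @return a \linkS4class{DesignResult} with one model
#' @export
repack <- function(s, spec, lib, minimizer = identity) {
  s <- minimizer(s)
  positions <- spec@repackable
  if (anyDuplicated(positions)) {
    warning("duplicate repackable positions deduplicated")
    positions <- unique(positions)
  }
  if (!length(positions)) stop("no repackable positions in spec")
  out <- minimizer(repackSweeps(s, positions, lib, spec@maxLj, spec@sweeps))
  new("DesignResult",
      models = list(newModel(s, out, positions, lib)),
      protocol = "repack",
      info = list(spec = spec, positions = positions))
}

#' Single-point mutagenesis scan
#'
#' Forces each specified (position, amino acid) mutation individually:
#' starting from the input, the repackable positions are repacked, then the
#' target amino acid is placed by evaluating every rotamer of its backbone
#' bin. If even the best rotamer exceeds the LJ ceiling, the ceiling is
#' raised (x4 per raise, capped at 1000 kcal/mol) until a rotamer is
#' admitted — the mutation always appears in the output model. Rotamer
#' evaluations are performed once per forced mutation (the raise loop
#' re-examines cached energies), so the logged evaluation count equals the
#' bin's rotamer count. Reports each model's breakdown and its energy
#' difference against the repacked wild-type model.
#'
#' @param s a preprocessed \linkS4class{ProteinStructure}
#' @param spec a \linkS4class{DesignSpec} with >= 1 mutable (position, aa)
#' @param lib a \linkS4class{RotamerLibrary}
#' @return a \linkS4class{DesignResult}, one model per mutation
#' @export
singlePointScan <- function(s, spec, lib) {
  if (!length(spec@mutable)) stop("no mutations in spec")
  base <- if (length(spec@repackable))
    repackSweeps(s, spec@repackable, lib, spec@maxLj, spec@sweeps) else s
  models <- list()
  log <- character(0)
  for (pos in names(spec@mutable)) for (aa in spec@mutable[[pos]]) {
    wt <- s@resTab$aa[resTabIndex(s, pos)]
    note <- if (aa == wt) "target equals wild type: processed as repack" else ""
    ev <- evalRotamers(base, pos, aa, lib)
    maxLj <- spec@maxLj
    raises <- 0L
    repeat {
      adm <- which(ev$scores$E_lj < maxLj)
      if (length(adm) || maxLj >= 1000) break
      maxLj <- min(maxLj * 4, 1000)
      raises <- raises + 1L
      log <- c(log, sprintf("%s>%s: LJ ceiling raised to %g", pos, aa, maxLj))
    }
    cand <- if (length(adm)) adm else seq_len(nrow(ev$scores))
    j <- cand[which.min(ev$scores$total[cand])]
    out <- installSideChain(ev$stripped, pos, aa, binCoords(ev$b, j),
                            lib@table)
    sel <- unique(c(pos, spec@repackable))
    baseE <- totalEnergy(base, sel, lib)
    m <- newModel(s, out, sel, lib,
                  extras = list(nEval = ev$nEval, raises = raises,
                                finalMaxLj = maxLj,
                                clash = !length(which(ev$scores$E_lj <
                                                        spec@maxLj)),
                                dG_vs_wt = NA_real_, note = note))
    m$dG_vs_wt <- m$breakdown@aggregate - baseE@aggregate
    models[[length(models) + 1L]] <- m
  }
  new("DesignResult", models = sortModels(models), protocol = "sp",
      info = list(spec = spec, log = log))
}

## ---- swarm core (shared by combinatorial and symmetric design) ----------

## positions within `radius` Angstrom (any atom) of residue i's side chain
neighborsWithin <- function(s, i, positions, radius = 6) {
  rows <- c(resAtomRows(s, i))
  ref <- as.matrix(s@atoms[rows, c("x", "y", "z")])
  idx <- resTabIndex(s, positions)
  hit <- vapply(idx, function(j) {
    if (j == i) return(FALSE)
    xyz <- as.matrix(s@atoms[resAtomRows(s, j), c("x", "y", "z")])
    min(as.matrix(stats::dist(rbind(ref, xyz)))[seq_len(nrow(ref)),
        nrow(ref) + seq_len(nrow(xyz))]) <= radius
  }, logical(1))
  positions[hit]
}

## attempt one move unit (a group of >= 1 positions sharing an amino acid):
## try each allowed aa, rank candidates by their summed per-position score,
## verify the best strictly lowers the aggregate before accepting
attemptMove <- function(state, unit, allowed, selection, lib, spec) {
  bestTrial <- NULL; bestScore <- Inf; bestAA <- NULL
  for (aa in allowed) {
    trial <- state$structure
    score <- 0
    ok <- TRUE
    for (pos in unit) {
      pl <- tryCatch(placeBestRotamer(trial, pos, aa, lib, spec@maxLj),
                     error = function(e) NULL)
      if (is.null(pl)) { ok <- FALSE; break }
      trial <- pl$structure
      score <- score + pl$energy
    }
    if (!ok) { warning("skipping ", aa, ": empty rotamer bin"); next }
    if (score < bestScore) {
      bestScore <- score; bestTrial <- trial; bestAA <- aa
    }
  }
  if (is.null(bestTrial)) return(state)
  agg <- totalEnergy(bestTrial, selection, lib)@aggregate
  if (agg < state$energy - 1e-12) {
    ## accepted: repack the repackable neighborhood of the changed side chains
    for (pos in unit) {
      nb <- neighborsWithin(bestTrial, resTabIndex(bestTrial, pos),
                            spec@repackable)
      if (length(nb))
        bestTrial <- repackSweeps(bestTrial, nb, lib, spec@maxLj, 1L)
    }
    agg <- totalEnergy(bestTrial, selection, lib)@aggregate
    if (agg < state$energy - 1e-12)
      return(list(structure = bestTrial, energy = agg))
  }
  state
}

swarmDesign <- function(s, spec, lib, units, protocol,
                        minimizer = identity) {
  s <- minimizer(s)
  mutPos <- names(spec@mutable)
  selection <- unique(c(mutPos, spec@repackable))
  e0 <- totalEnergy(s, selection, lib)@aggregate
  init <- list(structure = s, energy = e0)
  paths <- rep(list(init), spec@nPaths)
  best <- rep(list(c(init, list(iteration = 0L))), spec@nPaths)
  bestTrace <- matrix(NA_real_, spec@nPaths, spec@nIters)
  for (it in seq_len(spec@nIters)) {
    for (p in seq_len(spec@nPaths)) {
      ord <- seq_along(units)
      if (spec@scrambleOrder && length(units) > 1) {
        set.seed(spec@seed + 7919L * p + 104729L * it)
        ord <- sample.int(length(units))
      }
      state <- paths[[p]]
      for (u in ord) {
        unit <- units[[u]]
        allowed <- spec@mutable[[unit[1]]]
        state <- attemptMove(state, unit, allowed, selection, lib, spec)
      }
      paths[[p]] <- state
      if (state$energy < best[[p]]$energy)
        best[[p]] <- c(state, list(iteration = it))
      bestTrace[p, it] <- best[[p]]$energy
    }
    ## respawn: pool states, deduplicate by sequence, restart the paths
    ## from the lowest-energy unique states
    seqs <- vapply(paths, function(st) structureSequence(st$structure), "")
    uq <- !duplicated(seqs)
    pool <- paths[uq][order(vapply(paths[uq], `[[`, 0, "energy"))]
    paths <- pool[((seq_len(spec@nPaths) - 1L) %% length(pool)) + 1L]
  }
  models <- lapply(seq_len(spec@nPaths), function(p)
    newModel(s, minimizer(best[[p]]$structure), selection, lib, pathId = p,
             iteration = best[[p]]$iteration))
  seqs <- vapply(models, function(m) structureSequence(m$structure), "")
  models <- sortModels(models[!duplicated(seqs)])
  new("DesignResult", models = models, protocol = protocol,
      info = list(spec = spec, selection = selection, initialEnergy = e0,
                  bestTrace = bestTrace))
}

#' Swarm combinatorial sequence design
#'
#' Tracks nPaths loosely-communicating greedy search paths, each visiting
#' the mutable positions in its own seeded random order (identity order
#' when scrambleOrder is off). At each visit every allowed amino acid is
#' tried with its best rotamer; the best candidate is accepted only if it
#' strictly lowers the aggregate energy over the selection, after which the
#' repackable positions within 6 Angstrom of the new side chain are
#' repacked. After every iteration the path states are pooled, deduplicated
#' by sequence and the paths respawned from the lowest-energy unique
#' states with fresh visiting orders. Returns the best unique-sequence
#' model per path, globally deduplicated and sorted by average per-residue
#' energy.
#'
#' @param s a preprocessed \linkS4class{ProteinStructure}
#' @param spec a \linkS4class{DesignSpec} with >= 1 mutable position
#' @param lib a \linkS4class{RotamerLibrary}
#' @param minimizer optional minimization hook applied to the input and the
#'   final models (default: identity)
#' @return a \linkS4class{DesignResult}
#' @export
combinatorialDesign <- function(s, spec, lib, minimizer = identity) {
  if (!length(spec@mutable)) stop("no mutable positions in spec")
  units <- as.list(names(spec@mutable))
  swarmDesign(s, spec, lib, units, "cs", minimizer)
}

#' Sequence-symmetric design
#'
#' Identical control flow to \link{combinatorialDesign}, except a move is
#' (group, amino acid): the amino acid is installed at every position of a
#' symmetry group in the provided order, each position keeping its own
#' independently optimized rotamer — symmetry is enforced only at the
#' sequence level. Mutable positions outside any group are visited as
#' singleton moves.
#'
#' @param s a preprocessed \linkS4class{ProteinStructure}
#' @param spec a \linkS4class{DesignSpec} with >= 1 symmetry group
#' @param lib a \linkS4class{RotamerLibrary}
#' @param minimizer optional minimization hook applied to the input and the
#'   final models (default: identity)
#' @return a \linkS4class{DesignResult}
#' @export
symmetricDesign <- function(s, spec, lib, minimizer = identity) {
  if (!length(spec@symmetry)) stop("no symmetry groups in spec")
  for (g in spec@symmetry) {
    if (!all(g %in% names(spec@mutable)))
      stop("symmetric positions must be mutable: ",
           paste(setdiff(g, names(spec@mutable)), collapse = ", "))
    sets <- unique(lapply(spec@mutable[g], sort))
    if (length(sets) != 1)
      stop("allowed amino-acid sets must be identical within a symmetry group")
  }
  grouped <- unlist(spec@symmetry)
  units <- c(spec@symmetry,
             as.list(setdiff(names(spec@mutable), grouped)))
  swarmDesign(s, spec, lib, units, "sd", minimizer)
}
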