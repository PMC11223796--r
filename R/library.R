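## Rotamer-library construction: (phi, psi) binning, k-means clustering of
## side-chain conformations within each bin, cluster energies dG_k, and the
## versioned single-file archive.

LIBRARY_VERSION <- "rotafield-lib-1"

#' Assign a (phi, psi) pair to one of the 36 backbone bins
#'
#' The torus is tiled by a uniform 6 x 6 grid of 60 x 60 degree half-open
#' rectangles; +180 maps to the -180 edge, so every angle pair falls in
#' exactly one bin.
#'
#' @param phi,psi torsions in degrees (vectorized)
#' @return integer bin index in 0..35
#' @export
assignBin <- function(phi, psi) {
  p <- wrapAngle(phi); q <- wrapAngle(psi)
  as.integer(6L * floor((p + 180) / 60) + floor((q + 180) / 60))
}

## seeded k-means++ initial centers; ties broken by lowest row index
kppInit <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 <= 0)) { centers <- centers[seq_len(j)]; break }
    centers[j + 1L] <- sample.int(n, 1L, prob = d2 / sum(d2))
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[j + 1L], ])^2))
  }
  x[centers[centers > 0], , drop = FALSE]
}

#' Cluster the side-chain conformations of one backbone bin
#'
#' Features are the flattened local-frame coordinates of the side-chain
#' atoms beyond CB (avoiding chi-periodicity artifacts). Clustering is
#' k-means with seeded k-means++ initialization; each representative is the
#' real pool conformer nearest its centroid, so placed side chains always
#' have physical geometry. Cluster energies are Boltzmann weights of the
#' population fractions, dG_k = -RT log(N_cluster / N_bin).
#'
#' @param pool a \linkS4class{ConformerPool}
#' @param bin bin index 0..35
#' @param k maximum number of representatives (fewer are returned when the
#'   bin holds fewer distinct conformations; the shortfall is recorded)
#' @param seed RNG seed for the initialization
#' @return NULL for an empty bin, else a list with coords (side-chain atoms
#'   including CB, natoms x 3 x k'), dGk, popFrac, n, shortfall, repIdx
#' @export
clusterRotamers <- function(pool, bin, k = 100L, seed = 1L) {
  sel <- which(assignBin(pool@phi, pool@psi) == bin)
  if (!length(sel)) return(NULL)
  aa <- pool@aa
  scAll <- sideChainAtoms(aa)                       # includes CB
  scIdx <- which(pool@parts == "RES" & pool@atomNames %in% scAll)
  beyond <- which(pool@parts == "RES" & pool@atomNames %in% setdiff(scAll, "CB"))
  nb <- length(sel)
  feat <- if (length(beyond))
    matrix(aperm(pool@coords[beyond, , sel, drop = FALSE], c(3, 1, 2)),
           nrow = nb)
  else matrix(0, nb, 0)

  if (ncol(feat) == 0 || nrow(unique(feat)) == 1L) {
    cluster <- rep(1L, nb)
    sizes <- nb
    reps <- 1L
  } else {
    keff <- min(k, nrow(unique(feat)))
    set.seed(as.integer(seed))
    init <- kppInit(feat, keff)
    km <- tryCatch(
      stats::kmeans(feat, centers = init, iter.max = 100L,
                    algorithm = "Lloyd"),
      error = function(e)
        stats::kmeans(feat, centers = init, iter.max = 100L,
                      algorithm = "MacQueen"))
    cluster <- km$cluster
    keep <- which(km$size > 0)
    sizes <- km$size[keep]
    reps <- vapply(keep, function(cl) {
      members <- which(cluster == cl)
      d2 <- rowSums(sweep(feat[members, , drop = FALSE], 2,
                          km$centers[cl, ])^2)
      members[which.min(d2)]          # which.min takes the lowest index tie
    }, integer(1))
  }
  ord <- order(-sizes, reps)          # stable: large clusters first
  sizes <- sizes[ord]; reps <- reps[ord]
  repConf <- sel[reps]
  coords <- pool@coords[scIdx, , repConf, drop = FALSE]
  dimnames(coords) <- list(pool@atomNames[scIdx], NULL, NULL)
  list(coords = coords,
       dGk = -RT_KCAL * log(sizes / nb),
       popFrac = sizes / nb,
       n = nb, shortfall = max(0L, k - length(reps)),
       repIdx = repConf)
}

#' Build a rotamer library from conformer pools
#'
#' Runs the full pipeline per amino acid: periodic-KDE backbone energy map,
#' 36-bin gridding, within-bin k-means clustering into at most k
#' representatives with dG_k cluster energies. Field tensors are defined on
#' the shared grid and materialized per rotamer by
#' \link{computeFieldTensor}; the archive stores the rotamer geometry and
#' energies from which tensors are reproduced deterministically.
#'
#' @param pools named list of \linkS4class{ConformerPool} (one per amino acid)
#' @param grid shared \linkS4class{GridSpec}
#' @param k rotamers per bin (default 100)
#' @param bandwidth KDE bandwidth, degrees
#' @param seed base RNG seed
#' @param table the \linkS4class{ParameterTable} embedded in the library
#' @param maxLjField per-voxel LJ field clamp, kcal/mol
#' @return a \linkS4class{RotamerLibrary}
#' @export
buildRotamerLibrary <- function(pools, grid = gridSpec(), k = 100L,
                                bandwidth = 15, seed = 1L,
                                table = loadParameterTable(),
                                maxLjField = DEFAULT_MAX_LJ_FIELD) {
  if (is.null(names(pools)) || any(!nzchar(names(pools))))
    names(pools) <- vapply(pools, function(p) p@aa, character(1))
  maps <- list(); bins <- list(); empty <- character(0)
  for (aa in names(pools)) {
    pool <- pools[[aa]]
    maps[[aa]] <- estimateBackboneEnergy(pool, bandwidth = bandwidth)
    bb <- vector("list", 36L)
    for (b in 0:35) {
      cell <- clusterRotamers(pool, b, k = k, seed = as.integer(seed) + b)
      bb[b + 1L] <- list(cell)      # keep NULL entries for empty bins
      if (is.null(cell)) empty <- c(empty, paste0(aa, ":", b))
    }
    bins[[aa]] <- bb
  }
  new("RotamerLibrary", aas = names(pools), maps = maps, bins = bins,
      grid = grid, table = table, maxLjField = maxLjField,
      metadata = list(k = as.integer(k), bandwidth = bandwidth,
                      seed = as.integer(seed),
                      poolSizes = vapply(pools, function(p)
                        length(p@phi), integer(1)),
                      poolSeeds = vapply(pools, function(p) p@seed,
                                         integer(1)),
                      emptyBins = empty,
                      tableHash = tableHash(table)),
      version = LIBRARY_VERSION)
}

#' Rotamers of one (amino acid, bin) cell
#' @param lib a \linkS4class{RotamerLibrary}
#' @param aa three-letter code
#' @param bin bin index 0..35
#' @return the bin record (NULL when the bin is empty), see
#'   \link{clusterRotamers}
#' @export
binRotamers <- function(lib, aa, bin) {
  if (!aa %in% lib@aas) stop("amino acid not in library: ", aa)
  lib@bins[[aa]][[bin + 1L]]
}

#' dG_pp lookup against a library
#' @param lib a \linkS4class{RotamerLibrary}
#' @param aa three-letter code
#' @param phi,psi torsions, degrees
#' @return dG_pp, kcal/mol
#' @export
backboneEnergy <- function(lib, aa, phi, psi) {
  if (!aa %in% lib@aas) stop("amino acid not in library: ", aa)
  lookupBackboneEnergy(lib@maps[[aa]], phi, psi)
}

#' Save a rotamer library archive
#'
#' Single-file container (R serialization) holding all arrays plus
#' versioned metadata and a payload checksum verified on load.
#'
#' @param lib a \linkS4class{RotamerLibrary}
#' @param path output file
#' @return invisibly, the path
#' @export
saveLibrary <- function(lib, path) {
  payload <- list(aas = lib@aas, maps = lib@maps, bins = lib@bins,
                  grid = list(edge = lib@grid@edge, nvox = lib@grid@nvox),
                  classes = lib@table@classes, atoms = lib@table@atoms,
                  maxLjField = lib@maxLjField, metadata = lib@metadata)
  f <- tempfile()
  saveRDS(payload, f, version = 2)
  hash <- unname(tools::md5sum(f))
  unlink(f)
  saveRDS(list(version = LIBRARY_VERSION, hash = hash, payload = payload),
          path, version = 2)
  invisible(path)
}

#' Load a rotamer library archive
#' @param path archive written by \link{saveLibrary}
#' @return a \linkS4class{RotamerLibrary}
#' @export
loadLibrary <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("integrity error reading library archive ", path, ": ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj$version) || is.null(obj$payload))
    stop("integrity error: ", path, " is not a library archive")
  if (!identical(obj$version, LIBRARY_VERSION))
    stop("library version mismatch: archive has '", obj$version,
         "', this package reads '", LIBRARY_VERSION, "'")
  f <- tempfile()
  saveRDS(obj$payload, f, version = 2)
  hash <- unname(tools::md5sum(f))
  unlink(f)
  if (!identical(hash, obj$hash))
    stop("integrity error: checksum mismatch in ", path)
  p <- obj$payload
  tab <- new("ParameterTable", classes = p$classes, atoms = p$atoms,
             pairEps = sqrt(outer(p$classes$eps, p$classes$eps)),
             pairRmin = outer(p$classes$rmin2, p$classes$rmin2, "+"))
  new("RotamerLibrary", aas = p$aas, maps = p$maps, bins = p$bins,
      grid = gridSpec(p$grid$edge, p$grid$nvox), table = tab,
      maxLjField = p$maxLjField, metadata = p$metadata,
      version = obj$version)
}
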