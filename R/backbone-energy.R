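## Backbone-torsion energies: periodic kernel density estimation on the
## (phi, psi) torus, converted to dG_pp = -RT log p with the grid minimum
## shifted to zero.

#' Estimate the backbone-torsion energy map of a conformer pool
#'
#' A product of von Mises kernels in phi and psi (concentration
#' kappa = 1/sigma^2 with sigma the bandwidth in radians) is evaluated on a
#' regular grid over the torus. The density is converted to an energy via
#' dG_pp = -RT log p and shifted so the grid minimum is exactly 0. Nodes
#' whose density underflows are capped at a ceiling of
#' \code{25} kcal/mol above the minimum (with a warning).
#'
#' @param pool a \linkS4class{ConformerPool} with >= 100 conformers
#' @param bandwidth kernel bandwidth, degrees (> 0)
#' @param resolution grid node spacing, degrees
#' @return a \linkS4class{BackboneEnergyMap}
#' @export
estimateBackboneEnergy <- function(pool, bandwidth = 15, resolution = 5) {
  stopifnot(bandwidth > 0, resolution > 0)
  if (length(pool@phi) < 100)
    stop("pool too small for density estimation (need >= 100 conformers)")
  nodes <- seq(-180, 180 - resolution, by = resolution)
  kappa <- 1 / (bandwidth * pi / 180)^2
  nr <- nodes * pi / 180
  kernelMat <- function(angles) {
    ar <- angles * pi / 180
    ## nodes x n matrix of von Mises kernel values, in chunks to bound memory
    n <- length(ar)
    out <- matrix(0, length(nr), 0)
    step <- 20000L
    mats <- list()
    for (s in seq(1L, n, by = step)) {
      idx <- s:min(n, s + step - 1L)
      ## exp-scaled kernel exp(kappa (cos d - 1)) avoids overflow at high
      ## concentration; the scaling cancels against the scaled Bessel norm
      mats[[length(mats) + 1L]] <-
        exp(kappa * (cos(outer(nr, ar[idx], "-")) - 1))
    }
    do.call(cbind, mats)
  }
  kphi <- kernelMat(pool@phi)
  kpsi <- kernelMat(pool@psi)
  raw <- kphi %*% t(kpsi)            # sum over conformers of product kernels
  norm <- length(pool@phi) *
    (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))^2
  dens <- raw / norm                  # density per rad^2
  tiny <- .Machine$double.xmin
  under <- dens <= tiny
  e <- -RT_KCAL * log(pmax(dens, tiny))
  e <- e - min(e)
  if (any(e > DG_PP_CEILING)) {
    if (any(under))
      warning("KDE underflow at ", sum(under),
              " grid node(s); energies capped at ", DG_PP_CEILING,
              " kcal/mol")
    e <- pmin(e, DG_PP_CEILING)
  }
  ## node-cell probabilities (sum to 1 over the grid)
  new("BackboneEnergyMap", aa = pool@aa, values = e, nodes = nodes,
      bandwidth = bandwidth, density = dens / sum(dens))
}

#' Look up dG_pp at arbitrary torsions
#'
#' Bilinear interpolation with periodic wrap-around across the +/-180 seam.
#'
#' @param map a \linkS4class{BackboneEnergyMap}
#' @param phi,psi torsions in degrees (vectors recycled to common length)
#' @return dG_pp in kcal/mol
#' @export
lookupBackboneEnergy <- function(map, phi, psi) {
  n <- max(length(phi), length(psi))
  phi <- rep_len(wrapAngle(phi), n)
  psi <- rep_len(wrapAngle(psi), n)
  res <- map@nodes[2] - map@nodes[1]
  m <- length(map@nodes)
  fi <- (phi - map@nodes[1]) / res
  fj <- (psi - map@nodes[1]) / res
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  idx <- function(i) (as.integer(i) %% m) + 1L
  v <- map@values
  v00 <- v[cbind(idx(i0), idx(j0))]
  v10 <- v[cbind(idx(i0 + 1), idx(j0))]
  v01 <- v[cbind(idx(i0), idx(j0 + 1))]
  v11 <- v[cbind(idx(i0 + 1), idx(j0 + 1))]
  v00 * (1 - wi) * (1 - wj) + v10 * wi * (1 - wj) +
    v01 * (1 - wi) * wj + v11 * wi * wj
}
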