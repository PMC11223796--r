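## Synthetic conformer pools: capped-residue coordinate construction from
## internal coordinates, and seeded sampling from periodic mixtures. These
## pools stand in for molecular-dynamics ensembles of capped amino acids;
## the downstream library pipeline is agnostic to how the pool was made.

## conformer atom layout: ACE cap, residue backbone, NME cap, side chain
capAtomParts <- function(aa) {
  sc <- sideChainAtoms(aa)
  list(parts = c(rep("ACE", 3), rep("RES", 4 + length(sc)), rep("NME", 2)),
       names = c("CH3", "C", "O", "N", "CA", "C", "O", sc, "N", "CH3"))
}

## vectorized construction of n capped conformers; phi/psi length n, chi an
## n x n_chi matrix. Returns natoms x 3 x n array in the canonical local
## frame (origin CA, x towards N, z = x cross (C - CA)).
buildConformerCoords <- function(aa, phi, psi, chi) {
  n <- length(phi)
  g <- BB_GEO
  rep3 <- function(v) matrix(v, n, 3, byrow = TRUE)
  CY <- rep3(c(0, 0, 0))
  N <- rep3(c(g$c_n, 0, 0))
  th <- (180 - g$ang_c_n_ca) * pi / 180
  CA <- rep3(c(g$c_n + g$n_ca * cos(th), g$n_ca * sin(th), 0))
  C <- nerfPlace(CY, N, CA, g$ca_c, g$ang_n_ca_c, phi)
  O <- nerfPlace(N, CA, C, g$c_o, g$ang_ca_c_o, wrapAngle(psi + 180))
  NT <- nerfPlace(N, CA, C, g$c_n, g$ang_ca_c_n, psi)
  CAT <- nerfPlace(CA, C, NT, g$cap_n_ch3, g$ang_c_n_ca, 180)
  CAY <- nerfPlace(CA, N, CY, g$cap_c_ch3, g$ang_ca_c_n, 180)
  OY <- nerfPlace(CA, N, CY, g$c_o, 122.5, 0)
  placed <- list(N = N, CA = CA, C = C)
  sc <- sideChainAtoms(aa)
  if (length(sc)) {
    placed$CB <- nerfPlace(N, C, CA, g$ca_cb, g$ang_c_ca_cb, g$improper_cb)
    for (z in SIDE_CHAIN_Z[[aa]]) {
      tor <- if (grepl("^chi", z$tor)) {
        k <- as.integer(substr(z$tor, 4, 4))
        off <- 0
        rest <- substr(z$tor, 5, nchar(z$tor))
        if (nzchar(rest)) off <- as.numeric(rest)
        wrapAngle(chi[, k] + off)
      } else as.numeric(z$tor)
      placed[[z$atom]] <- nerfPlace(placed[[z$a]], placed[[z$b]],
                                    placed[[z$c]], z$d, z$ang, tor)
    }
  }
  mats <- c(list(CAY, CY, OY, placed$N, placed$CA, placed$C, O),
            placed[sc], list(NT, CAT))
  natoms <- length(mats)
  ## canonical frame: rows of rot are the axes
  x <- N - CA; x <- x / sqrt(rowSums(x^2))
  zax <- rowCross(x, C - CA); zax <- zax / sqrt(rowSums(zax^2))
  y <- rowCross(zax, x)
  out <- array(NA_real_, c(natoms, 3, n))
  for (j in seq_along(mats)) {
    d <- mats[[j]] - CA
    out[j, 1, ] <- rowSums(d * x)
    out[j, 2, ] <- rowSums(d * y)
    out[j, 3, ] <- rowSums(d * zax)
  }
  out
}

#' Build one capped conformer from internal coordinates
#'
#' Places the heavy atoms of an ACE-capped, NME-capped residue by
#' sequential NeRF construction with ideal bond lengths and angles, and
#' expresses them in the canonical residue-local frame (origin CA, x axis
#' towards N, z = x cross (C - CA)).
#'
#' @param aa three-letter amino-acid code
#' @param phi,psi backbone torsions, degrees
#' @param chi numeric vector of side-chain torsions (length must equal the
#'   amino acid's chi count; 0 for Gly/Ala/Pro)
#' @return list with aa, phi, psi, chi and an atoms data.frame (part,
#'   elety, x, y, z)
#' @export
buildCoordinates <- function(aa, phi, psi, chi = numeric(0)) {
  if (!aa %in% AA3) stop("unknown amino acid: ", aa)
  if (length(chi) != CHI_COUNT[[aa]])
    stop(aa, " needs ", CHI_COUNT[[aa]], " chi angle(s), got ", length(chi))
  co <- buildConformerCoords(aa, phi, psi,
                             matrix(chi, nrow = 1))
  lay <- capAtomParts(aa)
  list(aa = aa, phi = phi, psi = psi, chi = chi,
       atoms = data.frame(part = lay$parts, elety = lay$names,
                          x = co[, 1, 1], y = co[, 2, 1], z = co[, 3, 1],
                          stringsAsFactors = FALSE))
}

## von Mises sampler (Best-Fisher rejection); mu in degrees, returns degrees
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-6) return(wrapAngle(stats::runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, 2L * (n - length(out)))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
    out <- c(out, theta * 180 / pi)
  }
  wrapAngle(mu + out[seq_len(n)])
}

checkWeights <- function(w, what) {
  if (abs(sum(w) - 1) > 1e-9)
    stop("mixture spec error: ", what, " weights sum to ", sum(w),
         ", expected 1")
}

poolSpecCache <- new.env(parent = emptyenv())

#' Default mixture specification for an amino acid
#'
#' Reads the packaged pool configuration (alpha/beta/PPII backbone modes,
#' gauche-/gauche+/trans chi wells; bespoke entries for Gly and Pro) and
#' returns the per-amino-acid specification.
#'
#' @param aa three-letter code
#' @param file optional overriding YAML config path
#' @return list with \code{backbone} (modes) and \code{chi} (per-chi wells)
#' @export
defaultPoolSpec <- function(aa, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "pool_defaults.yaml",
                        package = "rotafield", mustWork = TRUE)
  key <- paste0(file, "|", aa)
  if (!is.null(poolSpecCache[[key]])) return(poolSpecCache[[key]])
  cfg <- yaml::read_yaml(file)
  base <- cfg$default
  over <- cfg[[aa]]
  backbone <- if (!is.null(over$backbone)) over$backbone else base$backbone
  nchi <- CHI_COUNT[[aa]]
  chi <- if (nchi > 0)
    lapply(seq_len(nchi), function(k) {
      w <- if (k == 1) base$chi1 else base$chiN
      if (!is.null(over[[paste0("chi", k)]])) over[[paste0("chi", k)]] else w
    }) else list()
  spec <- list(backbone = backbone, chi = chi)
  poolSpecCache[[key]] <- spec
  spec
}

#' Sample a synthetic conformer pool
#'
#' Draws n conformers i.i.d.: backbone (phi, psi) from a periodic von Mises
#' mixture, each side-chain torsion from wrapped-normal rotameric wells,
#' then builds Cartesian coordinates with \link{buildCoordinates}'s
#' vectorized core. Fully reproducible from the seed.
#'
#' @param aa three-letter code
#' @param n number of conformers (>= 1)
#' @param spec mixture specification (see \link{defaultPoolSpec})
#' @param seed integer RNG seed
#' @return a \linkS4class{ConformerPool}
#' @export
samplePool <- function(aa, n, spec = defaultPoolSpec(aa), seed = 1L) {
  stopifnot(n >= 1)
  if (!aa %in% AA3) stop("unknown amino acid: ", aa)
  modes <- spec$backbone$modes
  w <- vapply(modes, function(m) m$weight, numeric(1))
  checkWeights(w, "backbone mode")
  for (cw in spec$chi) checkWeights(cw$weights, "chi well")
  set.seed(as.integer(seed))
  mode <- sample.int(length(modes), n, replace = TRUE, prob = w)
  phi <- numeric(n); psi <- numeric(n)
  for (m in seq_along(modes)) {
    idx <- which(mode == m)
    if (!length(idx)) next
    kap <- rep_len(unlist(modes[[m]]$kappa), 2)
    mu <- unlist(modes[[m]]$mu)
    phi[idx] <- rvonmises(length(idx), mu[1], kap[1])
    psi[idx] <- rvonmises(length(idx), mu[2], kap[2])
  }
  nchi <- CHI_COUNT[[aa]]
  chi <- matrix(numeric(0), n, 0)
  if (nchi > 0) {
    chi <- matrix(NA_real_, n, nchi)
    for (k in seq_len(nchi)) {
      wk <- spec$chi[[k]]
      well <- sample.int(length(wk$means), n, replace = TRUE,
                         prob = wk$weights)
      chi[, k] <- wrapAngle(wk$means[well] + stats::rnorm(n, 0, wk$sd))
    }
  }
  co <- buildConformerCoords(aa, phi, psi, chi)
  lay <- capAtomParts(aa)
  new("ConformerPool", aa = aa, phi = phi, psi = psi, chi = chi,
      coords = co, atomNames = lay$names, parts = lay$parts,
      seed = as.integer(seed), spec = spec)
}

## recompute (phi, psi, chi) of pool conformer i from its coordinates
conformerDihedrals <- function(pool, i) {
  co <- pool@coords[, , i]
  nm <- paste(pool@parts, pool@atomNames)
  p <- function(key) co[match(key, nm), ]
  phi <- computeDihedral(p("ACE C"), p("RES N"), p("RES CA"), p("RES C"))
  psi <- computeDihedral(p("RES N"), p("RES CA"), p("RES C"), p("NME N"))
  nchi <- CHI_COUNT[[pool@aa]]
  chi <- if (nchi > 0)
    vapply(seq_len(nchi), function(k) {
      a <- CHI_ATOMS[[pool@aa]][[k]]
      computeDihedral(p(paste("RES", a[1])), p(paste("RES", a[2])),
                      p(paste("RES", a[3])), p(paste("RES", a[4])))
    }, numeric(1)) else numeric(0)
  list(phi = phi, psi = psi, chi = chi)
}
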