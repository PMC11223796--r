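## Structure I/O and preprocessing: PDB/mmCIF reading (via bio3d),
## heteroatom/hydrogen removal, side-chain completion from ideal internal
## coordinates, atom typing, backbone dihedrals, and a fixed-width PDB
## writer.

resKey <- function(chain, resno, icode = "")
  paste(chain, resno, icode, sep = "|")

#' Parse a "chain:resno" position selector
#' @param pos character vector like "A:12"
#' @return data.frame with chain and resno columns
#' @export
parsePosition <- function(pos) {
  parts <- strsplit(pos, ":", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop("malformed position selector: ",
                     paste(pos[bad], collapse = ", "))
  data.frame(chain = vapply(parts, `[`, "", 1L),
             resno = as.integer(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Read a protein structure from PDB or mmCIF
#'
#' All ATOM records are loaded with author chain/residue numbering
#' preserved; HETATM records are retained but flagged for removal by
#' \link{preprocessStructure}. Only MODEL 1 and altloc 'A'/blank are kept.
#'
#' @param path file path
#' @param format "auto" (by extension), "pdb" or "mmcif"
#' @return a \linkS4class{ProteinStructure}
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  parsed <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  icode <- if ("insert" %in% names(at))
    ifelse(is.na(at$insert), "", at$insert) else ""
  atoms <- data.frame(
    chain = chain, resno = at$resno, icode = icode, resid = at$resid,
    elety = at$elety, x = at$x, y = at$y, z = at$z,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy),
    het = at$type == "HETATM", class_id = NA_integer_,
    charge = NA_real_, stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  prot <- atoms[!atoms$het, , drop = FALSE]
  if (nrow(prot) == 0) stop("empty structure: no protein ATOM records in ", path)
  key <- resKey(prot$chain, prot$resno, prot$icode)
  first <- !duplicated(key)
  resTab <- data.frame(chain = prot$chain[first], resno = prot$resno[first],
                       icode = prot$icode[first], aa = prot$resid[first],
                       phi = NA_real_, psi = NA_real_,
                       stringsAsFactors = FALSE)
  new("ProteinStructure", atoms = atoms, resTab = resTab,
      provenance = paste0("read ", format, ": ", path))
}

#' Preprocess a structure for design
#'
#' Removes heteroatoms, hydrogens, terminal OXT atoms and alternate
#' conformations; drops residues with incomplete N/CA/C backbones (with a
#' warning); rebuilds missing side-chain heavy atoms from ideal internal
#' coordinates; assigns an atom class and partial charge to every atom; and
#' computes backbone (phi, psi) torsions.
#'
#' @param s a \linkS4class{ProteinStructure}
#' @param table a \linkS4class{ParameterTable}
#' @return the cleaned, typed \linkS4class{ProteinStructure}
#' @export
preprocessStructure <- function(s, table = loadParameterTable()) {
  at <- s@atoms
  log <- s@provenance
  nhet <- sum(at$het)
  at <- at[!at$het, , drop = FALSE]
  hyd <- toupper(at$element) %in% c("H", "D")
  oxt <- at$elety %in% c("OXT", "OT2")
  if (nhet || any(hyd) || any(oxt))
    log <- c(log, sprintf("removed %d heteroatoms, %d hydrogens, %d OXT",
                          nhet, sum(hyd), sum(oxt)))
  at <- at[!hyd & !oxt, , drop = FALSE]
  unknown <- setdiff(unique(at$resid), AA3)
  if (length(unknown))
    stop("unknown residue name(s): ", paste(unknown, collapse = ", "))

  key <- resKey(at$chain, at$resno, at$icode)
  pieces <- split(at, factor(key, levels = unique(key)))
  rebuilt <- vector("list", length(pieces))
  dropped <- character(0)
  for (i in seq_along(pieces)) {
    res <- pieces[[i]]
    aa <- res$resid[1]
    if (!all(c("N", "CA", "C") %in% res$elety)) {
      dropped <- c(dropped, paste0(res$chain[1], ":", res$resno[1]))
      next
    }
    canon <- canonicalAtoms(aa)
    res <- res[res$elety %in% canon, , drop = FALSE]
    res <- res[!duplicated(res$elety), , drop = FALSE]
    miss <- setdiff(canon, res$elety)
    if (length(miss)) {
      res <- completeResidue(res, aa, miss)
      log <- c(log, sprintf("rebuilt %s in %s:%s", paste(miss, collapse = "+"),
                            res$chain[1], res$resno[1]))
    }
    res <- res[match(canon, res$elety), , drop = FALSE]
    rebuilt[[i]] <- res
  }
  if (length(dropped)) {
    warning("dropped residue(s) with incomplete backbone: ",
            paste(dropped, collapse = ", "))
    log <- c(log, paste("dropped incomplete backbone:",
                        paste(dropped, collapse = ", ")))
  }
  at <- do.call(rbind, rebuilt[!vapply(rebuilt, is.null, TRUE)])
  if (is.null(at) || nrow(at) == 0) stop("empty structure after preprocessing")
  rownames(at) <- NULL
  pars <- lookupAtomParams(table, at$resid, at$elety)
  at$class_id <- pars$class_id
  at$charge <- pars$charge
  out <- new("ProteinStructure", atoms = at,
             resTab = makeResTab(at), provenance = c(log, "preprocessed"))
  out
}

## rebuild missing heavy atoms of one residue from ideal internal coordinates
completeResidue <- function(res, aa, missing) {
  pos <- function(n) {
    i <- match(n, res$elety)
    if (is.na(i)) NULL else as.numeric(res[i, c("x", "y", "z")])
  }
  template <- res[1, , drop = FALSE]
  addAtom <- function(name, xyz) {
    row <- template
    row$elety <- name
    row$x <- xyz[1]; row$y <- xyz[2]; row$z <- xyz[3]
    row$element <- substr(gsub("[0-9]", "", name), 1, 1)
    res <<- rbind(res, row)
  }
  ## O from the backbone plane (trans to a following N is unknown here;
  ## rebuilt anti to N about the CA-C axis)
  if ("O" %in% missing)
    addAtom("O", drop(nerfPlace(matrix(pos("N"), 1), matrix(pos("CA"), 1),
                                matrix(pos("C"), 1), BB_GEO$c_o,
                                BB_GEO$ang_ca_c_o, 180)))
  if ("CB" %in% missing && aa != "GLY")
    addAtom("CB", drop(nerfPlace(matrix(pos("N"), 1), matrix(pos("C"), 1),
                                 matrix(pos("CA"), 1), BB_GEO$ca_cb,
                                 BB_GEO$ang_c_ca_cb, BB_GEO$improper_cb)))
  chiDefault <- c(-60, 180, 180, 180)
  measuredChi <- function(k) {
    atoms <- CHI_ATOMS[[aa]][[k]]
    ps <- lapply(atoms, pos)
    if (any(vapply(ps, is.null, TRUE))) chiDefault[k]
    else computeDihedral(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
  }
  for (z in SIDE_CHAIN_Z[[aa]]) {
    if (!(z$atom %in% res$elety)) {
      chi <- rep(NA_real_, 4)
      if (grepl("^chi", z$tor)) {
        k <- as.integer(substr(z$tor, 4, 4))
        chi[k] <- measuredChi(k)
      }
      tor <- evalTorsion(z$tor, chi)
      addAtom(z$atom, drop(nerfPlace(matrix(pos(z$a), 1), matrix(pos(z$b), 1),
                                     matrix(pos(z$c), 1), z$d, z$ang, tor)))
    }
  }
  res
}

## residue table with phi/psi from coordinates; chain breaks (C-N > 2.0 A)
## treated as termini
makeResTab <- function(at) {
  key <- resKey(at$chain, at$resno, at$icode)
  first <- !duplicated(key)
  rt <- data.frame(chain = at$chain[first], resno = at$resno[first],
                   icode = at$icode[first], aa = at$resid[first],
                   phi = NA_real_, psi = NA_real_, stringsAsFactors = FALSE)
  getPos <- function(k, n) {
    i <- which(key == k & at$elety == n)
    if (length(i)) as.numeric(at[i[1], c("x", "y", "z")]) else NULL
  }
  keys <- key[first]
  for (i in seq_len(nrow(rt))) {
    n <- getPos(keys[i], "N"); ca <- getPos(keys[i], "CA")
    cc <- getPos(keys[i], "C")
    if (i > 1 && rt$chain[i - 1] == rt$chain[i]) {
      cp <- getPos(keys[i - 1], "C")
      if (!is.null(cp) && sqrt(sum((n - cp)^2)) < 2.0)
        rt$phi[i] <- computeDihedral(cp, n, ca, cc)
    }
    if (i < nrow(rt) && rt$chain[i + 1] == rt$chain[i]) {
      nn <- getPos(keys[i + 1], "N")
      if (!is.null(nn) && sqrt(sum((nn - cc)^2)) < 2.0)
        rt$psi[i] <- computeDihedral(n, ca, cc, nn)
    }
  }
  rt
}

#' Build an ideal-geometry peptide
#'
#' Constructs a chain from internal coordinates (sequential NeRF placement
#' with the packaged ideal bond lengths and angles), with the requested
#' backbone and side-chain torsions. Used for fixtures and as a convenient
#' source of geometrically exact test structures.
#'
#' @param seq3 character vector of three-letter residue names
#' @param phi,psi backbone torsions, degrees (recycled); phi of the first and
#'   psi of the last residue only shape terminal atoms
#' @param chi optional list (one numeric vector per residue) of side-chain
#'   torsions; defaults to chi1 = -60 and 180 elsewhere
#' @param chain chain identifier
#' @param table when non-NULL, the built structure is preprocessed/typed
#' @return a \linkS4class{ProteinStructure}
#' @export
buildPeptide <- function(seq3, phi = -60, psi = -45, chi = NULL,
                         chain = "A", table = loadParameterTable()) {
  n <- length(seq3)
  stopifnot(all(seq3 %in% AA3))
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  rows <- list()
  addRow <- function(resno, resid, elety, xyz)
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, icode = "", resid = resid, elety = elety,
      x = xyz[1], y = xyz[2], z = xyz[3],
      element = substr(gsub("[0-9]", "", elety), 1, 1),
      het = FALSE, class_id = NA_integer_, charge = NA_real_,
      stringsAsFactors = FALSE)
  g <- BB_GEO
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  th <- (180 - g$ang_n_ca_c) * pi / 180
  C <- CA + g$ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n)) {
    aa <- seq3[i]
    addRow(i, aa, "N", N); addRow(i, aa, "CA", CA); addRow(i, aa, "C", C)
    addRow(i, aa, "O", drop(nerfPlace(matrix(N, 1), matrix(CA, 1),
                                      matrix(C, 1), g$c_o, g$ang_ca_c_o,
                                      wrapAngle(psi[i] + 180))))
    if (aa != "GLY") {
      CB <- drop(nerfPlace(matrix(N, 1), matrix(C, 1), matrix(CA, 1),
                           g$ca_cb, g$ang_c_ca_cb, g$improper_cb))
      addRow(i, aa, "CB", CB)
      chis <- if (!is.null(chi) && length(chi) >= i && !is.null(chi[[i]]))
        chi[[i]] else defaultChi(aa)
      placed <- list(N = N, CA = CA, C = C, CB = CB)
      for (z in SIDE_CHAIN_Z[[aa]]) {
        xyz <- drop(nerfPlace(matrix(placed[[z$a]], 1),
                              matrix(placed[[z$b]], 1),
                              matrix(placed[[z$c]], 1),
                              z$d, z$ang, evalTorsion(z$tor, chis)))
        placed[[z$atom]] <- xyz
        addRow(i, aa, z$atom, xyz)
      }
    }
    if (i < n) {
      N2 <- drop(nerfPlace(matrix(N, 1), matrix(CA, 1), matrix(C, 1),
                           g$c_n, g$ang_ca_c_n, psi[i]))
      CA2 <- drop(nerfPlace(matrix(CA, 1), matrix(C, 1), matrix(N2, 1),
                            g$n_ca, g$ang_c_n_ca, 180))
      C2 <- drop(nerfPlace(matrix(C, 1), matrix(N2, 1), matrix(CA2, 1),
                           g$ca_c, g$ang_n_ca_c, phi[i + 1]))
      N <- N2; CA <- CA2; C <- C2
    }
  }
  at <- do.call(rbind, rows)
  s <- new("ProteinStructure", atoms = at, resTab = makeResTab(at),
           provenance = "built from ideal internal coordinates")
  if (!is.null(table)) preprocessStructure(s, table) else s
}

defaultChi <- function(aa) {
  nchi <- CHI_COUNT[[aa]]
  if (nchi == 0) return(numeric(0))
  c(-60, rep(180, 3))[seq_len(nchi)]
}

#' Write a structure as fixed-width PDB
#'
#' Emits standard v3.3 ATOM records (columns bit-controlled in-package),
#' one TER per chain and END.
#'
#' @param s a \linkS4class{ProteinStructure}
#' @param path output file
#' @return invisibly, the path
#' @export
writePDB <- function(s, path) {
  at <- s@atoms[!s@atoms$het, , drop = FALSE]
  lines <- character(0)
  serial <- 0L
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      serial <- serial + 1L
      name <- sub$elety[i]
      namef <- if (nchar(name) < 4) sprintf(" %-3s", name)
               else sprintf("%-4s", name)
      lines <- c(lines, sprintf(
        "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, namef, "", sub$resid[i], ch, sub$resno[i],
        sub$icode[i], sub$x[i], sub$y[i], sub$z[i], 1, 0,
        toupper(sub$element[i])))
    }
    serial <- serial + 1L
    lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                              serial %% 100000L,
                              sub$resid[nrow(sub)], ch,
                              sub$resno[nrow(sub)]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## index of a position in the residue table; errors when absent
resTabIndex <- function(s, pos) {
  p <- parsePosition(pos)
  idx <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    j <- which(s@resTab$chain == p$chain[i] & s@resTab$resno == p$resno[i])
    if (!length(j)) stop("position not in structure: ", pos[i])
    idx[i] <- j[1]
  }
  idx
}

## logical selector of one residue's atom rows
resAtomRows <- function(s, i) {
  rt <- s@resTab[i, ]
  which(s@atoms$chain == rt$chain & s@atoms$resno == rt$resno &
        s@atoms$icode == rt$icode & !s@atoms$het)
}
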