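## Parameter-table loading and lookups.

#' Load the packaged heavy-atom parameter table
#'
#' Reads the atom-class table (LJ and solvation parameters) and the
#' per-(residue, atom) typing/charge map shipped under
#' \code{inst/extdata}. Values are a self-contained heavy-atom parameter
#' set in the spirit of protein force fields.
#'
#' @param classFile,atomFile optional overriding paths to the two TSVs
#' @return a \linkS4class{ParameterTable}
#' @export
loadParameterTable <- function(classFile = NULL, atomFile = NULL) {
  if (is.null(classFile))
    classFile <- system.file("extdata", "atom_classes.tsv",
                             package = "rotafield", mustWork = TRUE)
  if (is.null(atomFile))
    atomFile <- system.file("extdata", "atom_params.tsv",
                            package = "rotafield", mustWork = TRUE)
  cl <- utils::read.delim(classFile, stringsAsFactors = FALSE)
  at <- utils::read.delim(atomFile, stringsAsFactors = FALSE)
  nc <- nrow(cl)
  eps <- sqrt(outer(cl$eps, cl$eps))            # Lorentz-Berthelot
  rmin <- outer(cl$rmin2, cl$rmin2, "+")
  dimnames(eps) <- dimnames(rmin) <- list(cl$class_id, cl$class_id)
  new("ParameterTable", classes = cl, atoms = at,
      pairEps = eps, pairRmin = rmin)
}

## class ids / charges for atoms of one residue type; errors on unknowns
lookupAtomParams <- function(table, resid, elety) {
  key <- paste(resid, elety)
  idx <- match(key, paste(table@atoms$resid, table@atoms$elety))
  if (anyNA(idx))
    stop("no parameters for atom(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  list(class_id = table@atoms$class_id[idx], charge = table@atoms$charge[idx])
}

## stable content hash of the table (used in library metadata)
tableHash <- function(table) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(table@classes, table@atoms), f, version = 2)
  unname(tools::md5sum(f))
}
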