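## Result serialization: one PDB per model, a multi-record FASTA and a CSV
## summary table.

#' Write the files of a design result
#'
#' Emits \code{model_NNN.pdb} per model, \code{models.fasta} with one
#' record per model, and \code{summary.csv} with the documented header:
#' model, total_energy, avg_per_residue, dG_pp, dG_k, E_lj, E_elec,
#' E_solv, mutations.
#'
#' @param result a non-empty \linkS4class{DesignResult}
#' @param dir output directory (created if needed)
#' @return invisibly, a character vector of the files written
#' @export
writeOutputs <- function(result, dir) {
  if (!length(result@models)) stop("empty design result")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  files <- character(0)
  seqs <- character(0)
  rows <- list()
  for (i in seq_along(result@models)) {
    m <- result@models[[i]]
    id <- sprintf("model_%03d", i)
    pdb <- file.path(dir, paste0(id, ".pdb"))
    writePDB(m$structure, pdb)
    files <- c(files, pdb)
    seqs[id] <- gsub("/", "", structureSequence(m$structure))
    pr <- m$breakdown@perResidue
    rows[[i]] <- data.frame(
      model = id,
      total_energy = m$breakdown@aggregate,
      avg_per_residue = m$breakdown@average,
      dG_pp = sum(pr$dG_pp), dG_k = sum(pr$dG_k), E_lj = sum(pr$E_lj),
      E_elec = sum(pr$E_elec), E_solv = sum(pr$E_solv),
      mutations = m$mutations, stringsAsFactors = FALSE)
  }
  fasta <- file.path(dir, "models.fasta")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta)
  csv <- file.path(dir, "summary.csv")
  utils::write.csv(do.call(rbind, rows), csv, row.names = FALSE,
                   quote = FALSE)
  invisible(c(files, fasta, csv))
}
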