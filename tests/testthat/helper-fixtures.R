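# Shared fixtures, built in code and memoized for the whole run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

paramTab <- function() memo("paramTab", loadParameterTable)

# small five-amino-acid library: enough bins populated for the samplers
tinyLib <- function() memo("tinyLib", function() {
  pools <- list(LEU = samplePool("LEU", 2000, seed = 11L),
                SER = samplePool("SER", 2000, seed = 12L),
                VAL = samplePool("VAL", 2000, seed = 13L),
                ALA = samplePool("ALA", 500, seed = 14L),
                GLY = samplePool("GLY", 500, seed = 15L))
  buildRotamerLibrary(pools, k = 10L, seed = 5L)
})

# helical host peptide used across engine/sampler tests
hostPeptide <- function() memo("hostPeptide", function()
  buildPeptide(c("LEU", "SER", "LEU", "VAL", "LEU", "ALA", "LEU"),
               phi = -63, psi = -43))

# single LEU residue with (phi, psi) pinned so its bin resolves but with no
# surrounding atoms: interaction terms vanish
isolatedLeu <- function() {
  s <- buildPeptide("LEU", -63, -43)
  s@resTab$phi <- -63
  s@resTab$psi <- -43
  s
}

# append a free-standing obstacle atom (aliphatic carbon, neutral) that the
# environment histogram sees but that belongs to no designable residue
addObstacle <- function(s, xyz, class_id = 4L, charge = 0) {
  row <- s@atoms[1, , drop = FALSE]
  row$chain <- "Z"; row$resno <- 9000L + nrow(s@atoms); row$icode <- ""
  row$resid <- "ALA"; row$elety <- "CB"; row$element <- "C"
  row$x <- xyz[1]; row$y <- xyz[2]; row$z <- xyz[3]
  row$het <- FALSE; row$class_id <- class_id; row$charge <- charge
  s@atoms <- rbind(s@atoms, row)
  rownames(s@atoms) <- NULL
  s
}

randomScene <- function(natoms = NULL, nenv = NULL, span = 6) {
  if (is.null(natoms)) natoms <- sample(1:5, 1)
  if (is.null(nenv)) nenv <- sample(5:40, 1)
  list(rot = rotamerPayload(matrix(stats::runif(natoms * 3, -3, 3), ncol = 3),
                            sample(1:12, natoms, TRUE),
                            stats::runif(natoms, -0.7, 0.7)),
       env = data.frame(x = stats::runif(nenv, -span, span),
                        y = stats::runif(nenv, -span, span),
                        z = stats::runif(nenv, -span, span),
                        class_id = sample(1:12, nenv, TRUE),
                        charge = stats::runif(nenv, -0.7, 0.7)))
}

relErr <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)

structuresIdentical <- function(a, b)
  isTRUE(all.equal(atomTable(a), atomTable(b), tolerance = 0)) &&
  identical(residueTable(a)$aa, residueTable(b)$aa)
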