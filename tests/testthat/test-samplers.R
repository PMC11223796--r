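prepHost <- function() preprocessStructure(hostPeptide(), paramTab())

test_that("without an environment the minimum-dG_k rotamer is chosen", {
  lib <- tinyLib()
  s <- isolatedLeu()
  b <- binRotamers(lib, "LEU", assignBin(-63, -43))
  pl <- placeBestRotamer(s, "A:1", "LEU", lib)
  expect_identical(pl$rotamer, which.min(b$dGk))
  expect_false(pl$clash)
  expect_identical(pl$nEval, length(b$dGk))
})

test_that("a planted obstacle funnels placement to the only open rotamer", {
  # dedicated two-rotamer serine library: two tight chi1 wells 120 deg
  # apart collapse to exactly two well-separated representatives
  spec2 <- list(backbone = list(modes = list(
    list(mu = c(-63, -43), kappa = c(60, 60), weight = 1))),
    chi = list(list(means = c(-65, 175), weights = c(0.7, 0.3), sd = 1)))
  pool <- samplePool("SER", 400, spec = spec2, seed = 91L)
  libS <- buildRotamerLibrary(list(SER = pool), k = 2L, seed = 9L)
  bin <- assignBin(-63, -43)
  b <- binRotamers(libS, "SER", bin)
  expect_length(b$dGk, 2)
  target <- which.max(b$dGk)    # the minority rotamer, never chosen freely
  maj <- which.min(b$dGk)
  s <- buildPeptide("SER", -63, -43)
  s@resTab$phi <- -63; s@resTab$psi <- -43
  free <- placeBestRotamer(s, "A:1", "SER", libS)
  expect_identical(free$rotamer, maj)
  # obstacle 1.2 A beyond the majority rotamer's OG, pointing away from
  # the minority rotamer: clashes the majority branch only
  og <- which(dimnames(b$coords)[[1]] == "OG")
  dirv <- b$coords[og, , maj] - b$coords[og, , target]
  obst <- b$coords[og, , maj] + 1.2 * dirv / sqrt(sum(dirv^2))
  fr <- residueFrame(s, 1L)
  sObs <- addObstacle(s, drop(toGlobal(fr, obst)))
  ev <- evalRotamers(sObs, "A:1", "SER", libS)
  expect_identical(which(ev$scores$E_lj >= 5), maj)  # fixture property
  pl <- placeBestRotamer(sObs, "A:1", "SER", libS, maxLj = 5)
  expect_identical(pl$rotamer, target)
  expect_false(pl$clash)
})

test_that("repacking a library-optimal structure is a fixed point", {
  lib <- tinyLib()
  s <- prepHost()
  spec <- designSpec(repackable = paste0("A:", 2:6))
  r1 <- repack(s, spec, lib)
  m1 <- models(r1)[[1]]$structure
  r2 <- repack(m1, spec, lib)
  m2 <- models(r2)[[1]]$structure
  expect_equal(as.matrix(atomTable(m2)[, c("x", "y", "z")]),
               as.matrix(atomTable(m1)[, c("x", "y", "z")]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(aggregateEnergy(models(r2)[[1]]$breakdown),
               aggregateEnergy(models(r1)[[1]]$breakdown), tolerance = 1e-9)
})

test_that("repacking is deterministic and later sweeps do not raise energy", {
  lib <- tinyLib()
  s <- prepHost()
  spec <- designSpec(repackable = c("A:2", "A:3", "A:4", "A:5"))
  r1 <- repack(s, spec, lib)
  r2 <- repack(s, spec, lib)
  expect_true(structuresIdentical(models(r1)[[1]]$structure,
                                  models(r2)[[1]]$structure))
  expect_identical(models(r1)[[1]]$mutations, "")
  # one sweep vs two sweeps on perturbed fixtures
  set.seed(55)
  for (i in 1:10) {
    chi <- lapply(residueTable(s)$aa, function(aa)
      wrapAngle(defaultChi(aa) + runif(CHI_COUNT[[aa]], -40, 40)))
    sf <- preprocessStructure(
      buildPeptide(residueTable(s)$aa, -60, -45, chi = chi), paramTab())
    e1 <- aggregateEnergy(models(repack(sf, designSpec(
      repackable = spec@repackable, sweeps = 1L), lib))[[1]]$breakdown)
    e2 <- aggregateEnergy(models(repack(sf, designSpec(
      repackable = spec@repackable, sweeps = 2L), lib))[[1]]$breakdown)
    expect_lte(e2, e1 + 1e-9)
  }
})

test_that("duplicate repackable positions are deduplicated with a warning", {
  lib <- tinyLib()
  s <- prepHost()
  expect_warning(r <- repack(s, designSpec(
    repackable = c("A:2", "A:3", "A:2")), lib), "deduplicated")
  expect_length(models(r), 1)
})

test_that("single-point scans force every mutation and report cardinality", {
  lib <- tinyLib()
  s <- prepHost()
  spec <- designSpec(repackable = "A:3",
                     mutable = list("A:4" = c("LEU", "SER", "ALA")))
  r <- singlePointScan(s, spec, lib)
  expect_length(models(r), 3)
  muts <- vapply(models(r), `[[`, "", "mutations")
  expect_setequal(sub(".*>", "", muts), c("LEU", "SER", "ALA"))
  for (m in models(r)) {
    expect_identical(m$nEval,
                     length(binRotamers(lib, sub(".*>", "", m$mutations),
                                        assignBin(-63, -43))$dGk))
    expect_true(is.finite(m$dG_vs_wt))
  }
})

test_that("a buried clash still carries its mutation, with raises logged", {
  lib <- tinyLib()
  s <- buildPeptide("VAL", -63, -43)
  s@resTab$phi <- -63; s@resTab$psi <- -43
  bin <- assignBin(-63, -43)
  b <- binRotamers(lib, "LEU", bin)
  fr <- residueFrame(s, 1L)
  nm <- dimnames(b$coords)[[1]]
  tip <- which(nm == "CD1")
  sObs <- s
  for (j in seq_along(b$dGk))     # block every LEU rotamer
    sObs <- addObstacle(sObs, drop(toGlobal(fr, b$coords[tip, , j])))
  spec <- designSpec(mutable = list("A:1" = "LEU"), maxLj = 5)
  r <- singlePointScan(sObs, spec, lib)
  m <- models(r)[[1]]
  expect_identical(m$mutations, "A:1:VAL>LEU")
  expect_true(m$clash)
  expect_gt(m$raises, 0)
  expect_gt(perResidue(m$breakdown)$E_lj[1], 5)
  expect_true(any(grepl("raised", r@info$log)))
})

test_that("a wild-type target is processed as a repack and noted", {
  lib <- tinyLib()
  s <- prepHost()
  r <- singlePointScan(s, designSpec(mutable = list("A:3" = "LEU")), lib)
  expect_identical(models(r)[[1]]$mutations, "")
  expect_match(models(r)[[1]]$note, "repack")
})

test_that("single-position combinatorial design equals exhaustive search", {
  lib <- tinyLib()
  s <- prepHost()
  allowed <- c("LEU", "SER", "VAL", "ALA")
  spec <- designSpec(mutable = list("A:4" = allowed), nPaths = 1L,
                     nIters = 2L, seed = 3L)
  r <- combinatorialDesign(s, spec, lib)
  got <- aggregateEnergy(models(r)[[1]]$breakdown)
  # brute-force oracle: wild type and every (aa, admissible-best rotamer)
  cands <- aggregateEnergy(totalEnergy(s, "A:4", lib))
  for (aa in allowed) {
    pl <- placeBestRotamer(s, "A:4", aa, lib, maxLj = spec@maxLj)
    cands <- c(cands, aggregateEnergy(totalEnergy(pl$structure, "A:4", lib)))
  }
  expect_equal(got, min(cands), tolerance = 1e-9)
})

test_that("per-path best energies never increase across iterations", {
  lib <- tinyLib()
  s <- prepHost()
  spec <- designSpec(repackable = c("A:3", "A:5"),
                     mutable = list("A:2" = c("SER", "ALA", "VAL"),
                                    "A:4" = c("LEU", "VAL", "SER")),
                     nPaths = 3L, nIters = 3L, seed = 17L)
  r <- combinatorialDesign(s, spec, lib)
  tr <- r@info$bestTrace
  expect_identical(dim(tr), c(3L, 3L))
  expect_true(all(apply(tr, 1, function(x) all(diff(x) <= 1e-12))))
})

test_that("swarm results are unique by sequence and seed-deterministic", {
  lib <- tinyLib()
  s <- prepHost()
  spec <- designSpec(repackable = "A:3",
                     mutable = list("A:2" = c("SER", "ALA", "VAL"),
                                    "A:4" = c("LEU", "VAL", "ALA")),
                     nPaths = 3L, nIters = 2L, seed = 23L)
  r1 <- combinatorialDesign(s, spec, lib)
  r2 <- combinatorialDesign(s, spec, lib)
  expect_identical(lapply(models(r1), function(m) atomTable(m$structure)),
                   lapply(models(r2), function(m) atomTable(m$structure)))
  seqs <- vapply(models(r1), function(m) structureSequence(m$structure), "")
  expect_identical(anyDuplicated(seqs), 0L)
  avg <- vapply(models(r1), function(m) averageEnergy(m$breakdown), 0)
  expect_true(all(diff(avg) >= 0))
  # every reported breakdown is recomputable from its structure
  for (m in models(r1)) {
    re <- totalEnergy(m$structure, r1@info$selection, lib)
    expect_equal(aggregateEnergy(re), aggregateEnergy(m$breakdown),
                 tolerance = 1e-9)
  }
})

test_that("symmetric design keeps groups sequence-identical", {
  lib <- tinyLib()
  s <- prepHost()
  spec <- designSpec(mutable = list("A:3" = c("LEU", "VAL", "SER"),
                                    "A:5" = c("LEU", "VAL", "SER")),
                     symmetry = list(c("A:3", "A:5")),
                     nPaths = 2L, nIters = 2L, seed = 31L)
  r <- symmetricDesign(s, spec, lib)
  for (m in models(r)) {
    rt <- residueTable(m$structure)
    expect_identical(rt$aa[rt$resno == 3], rt$aa[rt$resno == 5])
  }
})

test_that("symmetry holds on sequence only: rotamers stay independent", {
  lib <- tinyLib()
  s <- prepHost()
  spec <- designSpec(mutable = list("A:3" = "LEU", "A:5" = "LEU"),
                     symmetry = list(c("A:3", "A:5")),
                     nPaths = 1L, nIters = 1L, seed = 5L)
  scLocal <- function(model, resno) {
    at <- atomTable(model)
    i <- which(residueTable(model)$resno == resno)
    toLocal(residueFrame(model, i),
            as.matrix(at[at$resno == resno &
                         !at$elety %in% c("N", "CA", "C", "O", "CB"),
                         c("x", "y", "z")]))
  }
  m0 <- models(symmetricDesign(s, spec, lib))[[1]]$structure
  # obstacles in position 3's pocket that clash both symmetric side-chain
  # choices observed without them; position 5 is untouched
  fr3 <- residueFrame(m0, 3L)
  sObs <- s
  for (loc in list(scLocal(m0, 3), scLocal(m0, 5))) {
    tip <- loc[nrow(loc), ]                 # CD2, outermost atom
    cb <- atomTable(m0)
    cbv <- tip / sqrt(sum(tip^2))
    sObs <- addObstacle(sObs, drop(toGlobal(fr3, tip + 1.0 * cbv)))
  }
  m1 <- models(symmetricDesign(sObs, spec, lib))[[1]]$structure
  rt <- residueTable(m1)
  expect_identical(rt$aa[rt$resno == 3], rt$aa[rt$resno == 5])
  expect_identical(rt$aa[rt$resno == 3], "LEU")
  # position 5 keeps its rotamer; position 3 was forced onto a different one
  expect_lt(max(abs(scLocal(m1, 5) - scLocal(m0, 5))), 1e-6)
  expect_gt(max(abs(scLocal(m1, 3) - scLocal(m1, 5))), 0.1)
})

test_that("a singleton symmetry group reduces to combinatorial design", {
  lib <- tinyLib()
  s <- prepHost()
  allowed <- c("LEU", "VAL", "ALA")
  specSd <- designSpec(mutable = list("A:4" = allowed),
                       symmetry = list("A:4"),
                       nPaths = 1L, nIters = 1L, seed = 7L)
  specCs <- designSpec(mutable = list("A:4" = allowed),
                       nPaths = 1L, nIters = 1L, seed = 7L)
  rSd <- symmetricDesign(s, specSd, lib)
  rCs <- combinatorialDesign(s, specCs, lib)
  expect_true(structuresIdentical(models(rSd)[[1]]$structure,
                                  models(rCs)[[1]]$structure))
})

test_that("overlapping symmetry groups are rejected", {
  expect_error(designSpec(mutable = list("A:3" = "LEU", "A:5" = "LEU"),
                          symmetry = list(c("A:3", "A:5"), c("A:5"))),
               "disjoint")
})
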