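test_that("side-chain stripping removes exactly the beyond-CB atoms", {
  s <- preprocessStructure(hostPeptide(), paramTab())
  s2 <- stripSideChain(s, "A:3")     # LEU
  at <- atomTable(s2)
  expect_setequal(at$elety[at$resno == 3], c("N", "CA", "C", "O", "CB"))
  s3 <- stripSideChain(s2, "A:3")
  expect_equal(atomTable(s3), atomTable(s2), ignore_attr = TRUE)
  g <- buildPeptide(c("ALA", "GLY", "ALA"), -60, -45)
  expect_warning(stripSideChain(g, "A:2"), "glycine")
})

test_that("environment histogram counts, placement and boundary convention", {
  s <- isolatedLeu()
  sStr <- stripSideChain(s, "A:1")
  g <- gridSpec(0.8, 15L)
  env <- buildEnvironmentTensor(sStr, "A:1", g)
  expect_identical(env@nAtoms, 0L)         # empty surroundings
  expect_identical(nrow(env@occ), 0L)

  # a single obstacle exactly at a voxel center occupies that voxel only;
  # compute the local-frame position of voxel (10, 8, 8)'s center
  i <- 1L
  fr <- residueFrame(sStr, i)
  ext <- gridExtent(g)
  ctr <- c(-ext / 2 + (10 - 0.5) * g@edge, -ext / 2 + (8 - 0.5) * g@edge,
           -ext / 2 + (8 - 0.5) * g@edge)
  sObs <- addObstacle(sStr, drop(toGlobal(fr, ctr)))
  env2 <- buildEnvironmentTensor(sObs, "A:1", g)
  expect_identical(env2@nAtoms, 1L)
  expect_equal(unname(env2@occ[1, c("ix", "iy", "iz")]), c(10, 8, 8))
  expect_identical(unname(env2@occ[1, "count"]), 1L)

  # boundary atom goes to the higher-index voxel (half-open convention)
  bnd <- c(-ext / 2 + 9 * g@edge, 0.1, 0.1)  # exact x boundary voxel 9|10
  for (shift in c(1e-6, -1e-6)) {
    sB <- addObstacle(sStr, drop(toGlobal(fr, bnd + c(shift, 0, 0))))
    envB <- buildEnvironmentTensor(sB, "A:1", g)
    expect_identical(unname(envB@occ[1, "ix"]),
                     if (shift < 0) 9L else 10L)
  }
})

test_that("tensor contraction equals the snapped pairwise oracle", {
  tab <- paramTab()
  set.seed(101)
  for (g in list(gridSpec(1.6, 9L), gridSpec(0.8, 17L), gridSpec(0.4, 33L))) {
    for (i in 1:25) {
      sc <- randomScene()
      env <- envTensorFromLocal(as.matrix(sc$env[, 1:3]), sc$env$class_id,
                                sc$env$charge, g)
      te <- interactionEnergy(sc$rot, env, tab)
      oe <- pairwiseOracle(sc$rot, sc$env, snapped = TRUE, g, tab)
      expect_lt(max(relErr(te, oe)), 1e-9)
    }
  }
})

test_that("dense tensor contraction equals the sparse evaluation", {
  tab <- paramTab()
  g <- gridSpec(1.0, 9L)
  set.seed(102)
  for (i in 1:5) {
    sc <- randomScene(natoms = 3, nenv = 20, span = 4)
    env <- envTensorFromLocal(as.matrix(sc$env[, 1:3]), sc$env$class_id,
                              sc$env$charge, g)
    occ <- denseOccupancy(env, nclass = nrow(tab@classes))
    qv <- denseCharge(env)
    dense <- c(
      E_lj = sum(computeFieldTensor(sc$rot, "lj", g, tab) * occ),
      E_elec = sum(computeFieldTensor(sc$rot, "elec", g, tab) * qv),
      E_solv = sum(computeFieldTensor(sc$rot, "solv", g, tab) * occ))
    sparse <- interactionEnergy(sc$rot, env, tab)
    expect_lt(max(relErr(dense, sparse)), 1e-9)
  }
})

test_that("discretization error does not grow as voxels are refined", {
  tab <- paramTab()
  set.seed(103)
  grids <- list(gridSpec(1.6, 9L), gridSpec(0.8, 17L), gridSpec(0.4, 33L))
  errs <- matrix(NA_real_, 50, 3)
  for (i in 1:50) {
    sc <- randomScene(span = 5)
    cont <- pairwiseOracle(sc$rot, sc$env, snapped = FALSE,
                           table = tab)
    for (j in 1:3) {
      env <- envTensorFromLocal(as.matrix(sc$env[, 1:3]), sc$env$class_id,
                                sc$env$charge, grids[[j]])
      te <- interactionEnergy(sc$rot, env, tab)
      errs[i, j] <- sum(abs(te - cont))
    }
  }
  m <- colMeans(errs)
  expect_lte(m[2], m[1])
  expect_lte(m[3], m[2])
})

test_that("energies are invariant under rigid motion of the structure", {
  lib <- tinyLib()
  s <- preprocessStructure(hostPeptide(), paramTab())
  e0 <- totalEnergy(s, NULL, lib)
  set.seed(104)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- 0.83
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  xyz <- as.matrix(s@atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, c(-7.3, 12.1, 3.9))
  s2 <- s
  s2@atoms$x <- xyz[, 1]; s2@atoms$y <- xyz[, 2]; s2@atoms$z <- xyz[, 3]
  s2@resTab <- makeResTab(s2@atoms)
  e1 <- totalEnergy(s2, NULL, lib)
  expect_lt(max(abs(perResidue(e1)$total - perResidue(e0)$total)), 1e-6)
})

test_that("zeroing all charges kills the electrostatic term only", {
  lib <- tinyLib()
  s <- preprocessStructure(hostPeptide(), paramTab())
  s2 <- s
  s2@atoms$charge <- 0
  e0 <- perResidue(totalEnergy(s, NULL, lib))
  e1 <- perResidue(totalEnergy(s2, NULL, lib))
  expect_true(all(e1$E_elec == 0))
  expect_true(any(e0$E_elec != 0))
  expect_equal(e1$E_lj, e0$E_lj)
  expect_equal(e1$E_solv, e0$E_solv)
})

test_that("breakdowns carry five terms, exact additivity and the average", {
  lib <- tinyLib()
  s <- preprocessStructure(hostPeptide(), paramTab())
  bd <- totalEnergy(s, NULL, lib)
  pr <- perResidue(bd)
  expect_setequal(intersect(names(pr),
                            c("dG_pp", "dG_k", "E_lj", "E_elec", "E_solv")),
                  c("dG_pp", "dG_k", "E_lj", "E_elec", "E_solv"))
  expect_equal(pr$total,
               pr$dG_pp + pr$dG_k + pr$E_lj + pr$E_elec + pr$E_solv)
  expect_identical(aggregateEnergy(bd), sum(pr$total))
  expect_equal(averageEnergy(bd), aggregateEnergy(bd) / nrow(pr))
  # single-residue evaluation: total equals average
  one <- totalEnergy(s, "A:4", lib)
  expect_identical(aggregateEnergy(one), averageEnergy(one))
  # chain-terminal residues report dG_pp = 0 with the flag set
  expect_true(pr$ppUndefined[1] && pr$dG_pp[1] == 0)
})

test_that("identical far-apart monomers score identical averages", {
  lib <- tinyLib()
  s <- preprocessStructure(hostPeptide(), paramTab())
  atB <- atomTable(s)
  atB$chain <- "B"
  atB$x <- atB$x + 60
  dimer <- new("ProteinStructure", atoms = rbind(atomTable(s), atB),
               resTab = makeResTab(rbind(atomTable(s), atB)),
               provenance = "fixture")
  eA <- totalEnergy(dimer, paste0("A:", 1:7), lib)
  eB <- totalEnergy(dimer, paste0("B:", 1:7), lib)
  expect_equal(averageEnergy(eA), averageEnergy(eB), tolerance = 1e-9)
})
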