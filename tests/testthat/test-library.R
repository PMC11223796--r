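test_that("bin assignment tiles the torus into 36 equal half-open bins", {
  expect_identical(assignBin(-180, -180), 0L)
  expect_identical(assignBin(179.99, 179.99), 35L)
  expect_identical(assignBin(180, 180), 0L)      # +180 maps to the 0-edge
  expect_identical(assignBin(-120, -180), 6L)    # half-open upper edges
  # brute-force 1-degree sweep: surjective and perfectly balanced
  grid <- expand.grid(phi = seq(-180, 179), psi = seq(-180, 179))
  bins <- assignBin(grid$phi, grid$psi)
  expect_identical(sort(unique(bins)), 0:35)
  expect_true(all(table(bins) == 3600L))
})

test_that("two equal point clouds split into clusters of RT ln 2 energy", {
  # hand oracle: -RT log(1/2) = 0.593 * log(2)
  n <- 200L
  chi <- matrix(rep(c(-60, 180), each = n / 2), ncol = 1)
  co <- buildConformerCoords("SER", rep(-60, n), rep(-45, n), chi)
  lay <- capAtomParts("SER")
  pool <- new("ConformerPool", aa = "SER", phi = rep(-60, n),
              psi = rep(-45, n), chi = chi, coords = co,
              atomNames = lay$names, parts = lay$parts, seed = 1L,
              spec = list())
  cl <- clusterRotamers(pool, assignBin(-60, -45), k = 2L, seed = 3L)
  expect_length(cl$dGk, 2)
  expect_equal(cl$dGk, rep(0.593 * log(2), 2), tolerance = 1e-6 / 0.411)
  expect_equal(sum(exp(-cl$dGk / 0.593)), 1, tolerance = 1e-9)
})

test_that("identical conformers collapse to one zero-energy rotamer", {
  n <- 50L
  chi <- matrix(rep(-60, n), ncol = 1)
  co <- buildConformerCoords("SER", rep(-60, n), rep(-45, n), chi)
  lay <- capAtomParts("SER")
  pool <- new("ConformerPool", aa = "SER", phi = rep(-60, n),
              psi = rep(-45, n), chi = chi, coords = co,
              atomNames = lay$names, parts = lay$parts, seed = 1L,
              spec = list())
  cl <- clusterRotamers(pool, assignBin(-60, -45), k = 100L, seed = 3L)
  expect_length(cl$dGk, 1)
  expect_equal(cl$dGk, 0)
})

test_that("a well-populated bin yields exactly k representatives", {
  pool <- samplePool("LEU", 6000, seed = 51L)
  bin <- assignBin(-63, -43)
  expect_gte(sum(assignBin(pool@phi, pool@psi) == bin), 1000)
  cl <- clusterRotamers(pool, bin, k = 100L, seed = 5L)
  expect_length(cl$dGk, 100)
  expect_identical(cl$shortfall, 0L)
  # representatives are real pool conformers
  expect_true(all(cl$repIdx %in% seq_along(pool@phi)))
})

test_that("cluster Boltzmann weights form a distribution in every bin", {
  lib <- tinyLib()
  for (aa in lib@aas) for (b in 0:35) {
    cell <- binRotamers(lib, aa, b)
    if (!is.null(cell))
      expect_equal(sum(exp(-cell$dGk / 0.593)), 1, tolerance = 1e-9)
  }
})

test_that("glycine bins hold one empty-side-chain rotamer at zero energy", {
  lib <- tinyLib()
  populated <- 0L
  for (b in 0:35) {
    cell <- binRotamers(lib, "GLY", b)
    if (is.null(cell)) next
    populated <- populated + 1L
    expect_length(cell$dGk, 1)
    expect_equal(cell$dGk, 0)
    expect_identical(dim(cell$coords)[1], 0L)
  }
  expect_gte(populated, 1L)
})

test_that("library builds are reproducible and archive round-trips", {
  pools <- list(SER = samplePool("SER", 600, seed = 61L))
  lib1 <- buildRotamerLibrary(pools, k = 5L, seed = 7L)
  lib2 <- buildRotamerLibrary(pools, k = 5L, seed = 7L)
  expect_identical(lib1@bins, lib2@bins)
  expect_identical(lib1@maps[["SER"]]@values, lib2@maps[["SER"]]@values)

  f <- withr::local_tempfile(fileext = ".dmt")
  saveLibrary(lib1, f)
  lib3 <- loadLibrary(f)
  expect_identical(lib3@bins, lib1@bins)
  expect_identical(lib3@metadata$k, 5L)
  expect_identical(lib3@metadata$seed, 7L)
  expect_identical(lib3@metadata$bandwidth, 15)
  # identical energies for a fixed evaluation scene
  s <- buildPeptide(c("GLY", "SER", "GLY"), -60, -45)
  e1 <- totalEnergy(s, "A:2", lib1)
  e3 <- totalEnergy(s, "A:2", lib3)
  expect_equal(aggregateEnergy(e1), aggregateEnergy(e3), tolerance = 1e-12)
})

test_that("truncated or alien archives raise integrity errors", {
  pools <- list(SER = samplePool("SER", 600, seed = 61L))
  lib <- buildRotamerLibrary(pools, k = 3L, seed = 7L)
  f <- withr::local_tempfile(fileext = ".dmt")
  saveLibrary(lib, f)
  raw <- readBin(f, "raw", file.info(f)$size)
  writeBin(raw[seq_len(length(raw) %/% 2)], f)
  expect_error(loadLibrary(f), "integrity")
  f2 <- withr::local_tempfile()
  saveRDS(list(not = "a library"), f2)
  expect_error(loadLibrary(f2), "integrity|archive")
})

test_that("empty bins are recorded but do not fail the build", {
  # a tight pool leaves most of the torus unpopulated
  spec <- list(backbone = list(modes = list(
    list(mu = c(-60, -45), kappa = c(80, 80), weight = 1))),
    chi = list(list(means = c(-60, 60, 180),
                    weights = c(0.5, 0.15, 0.35), sd = 10)))
  pools <- list(SER = samplePool("SER", 500, spec = spec, seed = 71L))
  lib <- buildRotamerLibrary(pools, k = 3L, seed = 1L)
  expect_gt(length(lib@metadata$emptyBins), 0)
  expect_length(lib@bins[["SER"]], 36)
})
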