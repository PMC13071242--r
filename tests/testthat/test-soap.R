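# SOAP engine: layout arithmetic, density-coefficient structure, invariances,
# locality and cutoff smoothness.

test_that("descriptor length follows (lMax+1) M(M+1)/2 and matches outputs", {
  cfg <- soapConfig(c("H", "C"), rCut = 6, nMax = 8L, lMax = 6L)
  expect_identical(descriptorLength(cfg), 952L)
  expect_identical(nrow(soapLayout(cfg)), 952L)
  cfg2 <- fastConfig()
  d <- computeSoap(tinyComplex(), cfg2, centers = "hydrogen")
  expect_identical(ncol(descriptorValues(d)), descriptorLength(cfg2))
  expect_identical(nrow(descriptorValues(d)), 2L)
})

test_that("powerSpectrum is zero on zero coefficients and checks shapes", {
  cfg <- fastConfig()
  co <- array(0, dim = c(3L, cfg@nMax, cfg@lMax + 1L, 2L * cfg@lMax + 1L))
  expect_identical(powerSpectrum(co, cfg), numeric(descriptorLength(cfg)))
  bad <- array(0, dim = c(2L, cfg@nMax, cfg@lMax + 1L, 2L * cfg@lMax + 1L))
  expect_error(powerSpectrum(bad, cfg), "shape")
})

test_that("a neighbor beyond the tapered cutoff contributes exactly zero", {
  cfg <- soapConfig(c("H", "Zn"), rCut = 6, nMax = 3L, lMax = 3L,
                    sigmaAtom = 1, cutoffWidth = 0.5)
  near <- MolecularStructure("a", c("Zn", "H"),
                             rbind(c(0, 0, 0), c(0, 0, 2)))
  far <- MolecularStructure("a", c("Zn", "H", "H"),
                            rbind(c(0, 0, 0), c(0, 0, 2), c(7, 0, 0)))
  expect_identical(as.numeric(densityCoefficients(near, 0L, cfg)),
                   as.numeric(densityCoefficients(far, 0L, cfg)))
})

test_that("elements inside the cutoff missing from species error by name", {
  cfg <- soapConfig(c("H", "Zn"), rCut = 4, nMax = 2L, lMax = 2L)
  expect_error(densityCoefficients(tinyComplex(), 0L, cfg), "C")
})

test_that("l = 0 coefficients are rotation-invariant", {
  cfg <- fastConfig()
  s <- tinyComplex()
  R <- randomRotation(5L)
  a <- densityCoefficients(s, 0L, cfg)
  b <- densityCoefficients(applyRotation(s, R), 0L, cfg)
  expect_equal(a[, , 1L, cfg@lMax + 1L], b[, , 1L, cfg@lMax + 1L],
               tolerance = 1e-10)
})

test_that("a single +z neighbor produces only m = 0 coefficients", {
  cfg <- soapConfig(c("H", "Zn"), rCut = 4, nMax = 2L, lMax = 3L,
                    sigmaAtom = 0.5, cutoffWidth = 0)
  s <- MolecularStructure("z", c("Zn", "H"),
                          rbind(c(0, 0, 0), c(0, 0, 1.7)))
  co <- densityCoefficients(s, 0L, cfg)
  hIdx <- 1L  # species sorted by atomic number: H first
  for (l in 0:cfg@lMax) {
    for (m in -l:l) {
      v <- co[hIdx, , l + 1L, m + cfg@lMax + 1L]
      if (m != 0L) expect_lt(max(abs(v)), 1e-10)
    }
  }
  # the m = 0, l-channel coefficients are nonzero (density is there)
  expect_gt(max(abs(co[hIdx, , , cfg@lMax + 1L])), 1e-4)
})

test_that("descriptors are invariant under rotation, translation, permutation", {
  cfg <- fastConfig(c("H", "C", "N", "O", "Zn"))
  structs <- makeToyComplexes(5L, c(8L, 12L), seed = 21L)
  for (i in seq_along(structs)) {
    s <- structs[[i]]
    base <- descriptorValues(computeSoap(s, cfg))
    rot <- descriptorValues(computeSoap(applyRotation(s, randomRotation(i)), cfg))
    tra <- descriptorValues(computeSoap(applyTranslation(s, c(5, -3, 2)), cfg))
    expect_lt(maxRelDev(rot, base), 1e-8)
    expect_lt(maxRelDev(tra, base), 1e-8)
    # swap two atoms of the same species; descriptors of untouched centers
    # must be identical, and the swapped pair's rows exchange
    el <- s@elements
    dupSpecies <- names(which(table(el) >= 2L))[1L]
    pair <- which(el == dupSpecies)[1:2]
    perm <- seq_along(el)
    perm[pair] <- rev(pair)
    swapped <- descriptorValues(computeSoap(permuteAtoms(s, perm), cfg))
    expect_lt(maxRelDev(swapped[perm, , drop = FALSE], base), 1e-8)
  }
})

test_that("atoms beyond rCut + 4 sigma of every center change nothing", {
  cfg <- fastConfig()
  s <- tinyComplex()
  spiked <- MolecularStructure(
    "tiny", c(s@elements, "C"),
    rbind(s@coordinates, c(50, 0, 0)), s@totalCharge)
  a <- descriptorValues(computeSoap(s, cfg))
  b <- descriptorValues(computeSoap(spiked, cfg,
                                    centers = list(seq_along(s@elements) - 1L)))
  expect_lt(max(abs(a - b)), 1e-10)
})

test_that("descriptor entries are continuous as a neighbor crosses rCut", {
  cfg <- soapConfig(c("H", "Zn"), rCut = 4, nMax = 3L, lMax = 3L,
                    sigmaAtom = 0.5, cutoffWidth = 0.5)
  at <- function(x) {
    s <- MolecularStructure("s", c("Zn", "H", "H"),
                            rbind(c(0, 0, 0), c(0, 0, 1.8), c(x, 0, 0)))
    descriptorValues(computeSoap(s, cfg, centers = list(0L)))
  }
  lo <- at(cfg@rCut - 1e-4)
  hi <- at(cfg@rCut + 1e-4)
  # with the cosine taper, the amplitude near rCut is O((pi * dx / 2w)^2),
  # so a 2e-4 Angstrom hop may move entries only by that smooth envelope
  expect_lt(max(abs(hi - lo)), 1e-5)
})

test_that("moleculeDescriptor is the mean of per-atom descriptors", {
  cfg <- fastConfig()
  s <- tinyComplex()
  perAtom <- descriptorValues(computeSoap(s, cfg, centers = "all"))
  expect_equal(moleculeDescriptor(s, cfg), colMeans(perAtom))
  lone <- MolecularStructure("one", "Zn", matrix(1:3, 1L, 3L))
  cfgZn <- soapConfig("Zn", rCut = 4, nMax = 2L, lMax = 2L, sigmaAtom = 0.5)
  expect_equal(moleculeDescriptor(lone, cfgZn),
               as.numeric(descriptorValues(computeSoap(lone, cfgZn))))
  moved <- applyTranslation(s, c(-2, 9, 4))
  expect_equal(moleculeDescriptor(moved, cfg), moleculeDescriptor(s, cfg),
               tolerance = 1e-10)
})

test_that("zinc pooling uses the zinc center alone", {
  cfg <- fastConfig()
  s <- tinyComplex()
  zn <- descriptorValues(computeSoap(s, cfg, centers = "zinc"))
  expect_equal(moleculeDescriptor(s, cfg, pooling = "zinc"),
               as.numeric(zn))
})
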