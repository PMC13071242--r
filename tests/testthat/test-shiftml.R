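# Referencing, feature assembly, splitting, tuning/training and evaluation.

# Small shared fixture: structures, shift table, features at a fast config.
smlFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      structs <- makeToyComplexes(20L, c(6L, 9L), seed = 31L)
      tab <- makeFixtureShiftTable(structs, noiseSeed = 32L)
      species <- sort(unique(unlist(lapply(structs, function(s) s@elements))))
      cfg <- soapConfig(species, rCut = 4, nMax = 3L, lMax = 3L,
                        sigmaAtom = 0.5)
      desc <- computeSoap(structs, cfg, centers = "hydrogen")
      cache <<- list(structs = structs, tab = tab, cfg = cfg, desc = desc,
                     fs = assembleFeatures(desc, tab))
    }
    cache
  }
})

test_that("shieldingToShift implements delta = sigma(TMS) - sigma", {
  expect_equal(shieldingToShift(31.70, 31.70), 0)
  expect_equal(shieldingToShift(24.50, 31.70), 7.20)
  s <- c(10, 20, 30)
  expect_true(all(diff(shieldingToShift(s, 31.7)) < 0))
})

test_that("referenceShifts fills deltas and names missing references", {
  rec <- data.frame(moleculeId = "m", atomIndex = 1L,
                    solvent = c("DMSO", "THF"), epsilon = c(46.7, 7.6),
                    sigmaPpm = c(24.5, 25.0), deltaPpm = NA_real_)
  out <- referenceShifts(rec, c(DMSO = 31.7, THF = 31.9))
  expect_equal(out$deltaPpm, c(7.2, 6.9))
  expect_error(referenceShifts(rec, c(DMSO = 31.7)), "THF")
})

test_that("assembleFeatures appends epsilon and sorts rows deterministically", {
  fx <- smlFixture()
  fs <- fx$fs
  expect_identical(ncol(fs@X), descriptorLength(fx$cfg) + 1L)
  expect_identical(colnames(fs@X)[ncol(fs@X)], "epsilon")
  dmso <- fs@rowInfo$solvent == "DMSO"
  expect_true(all(fs@X[dmso, "epsilon"] == 46.7))
  # same atom in two solvents: identical rows except the epsilon column
  info <- fs@rowInfo
  key <- paste(info$moleculeId, info$atomIndex)
  pair <- which(key == key[1L] & info$solvent %in% c("acetone", "THF"))
  expect_length(pair, 2L)
  d <- ncol(fs@X) - 1L
  expect_identical(fs@X[pair[1L], seq_len(d)], fs@X[pair[2L], seq_len(d)])
  # rows sorted by (molecule, atom, solvent)
  ord <- order(info$moleculeId, info$atomIndex, info$solvent)
  expect_identical(ord, seq_len(nrow(info)))
})

test_that("assembleFeatures errors on records without descriptors", {
  fx <- smlFixture()
  bad <- fx$tab
  bad$atomIndex[1L] <- 999L
  expect_error(assembleFeatures(fx$desc, bad), "999")
})

test_that("45 molecules x 5 solvents split 0.2 gives 180/45 combinations", {
  nH <- 3L
  rows <- expand.grid(moleculeId = sprintf("m%02d", 1:45),
                      atomIndex = seq_len(nH),
                      solvent = c("acetone", "chloroform", "DMSO", "MeOH",
                                  "THF"), stringsAsFactors = FALSE)
  fs <- new("FeatureSet", X = matrix(rnorm(nrow(rows)), ncol = 1L),
            y = rnorm(nrow(rows)), groups = rows$moleculeId,
            rowInfo = data.frame(rows, epsilon = 1))
  plan <- moleculeLevelSplit(fs, 0.2, seed = 41L)
  expect_length(plan@testMolecules, 9L)
  expect_length(plan@trainMolecules, 36L)
  combos <- unique(rows[, c("moleculeId", "solvent")])
  expect_identical(sum(combos$moleculeId %in% plan@trainMolecules), 180L)
  expect_identical(sum(combos$moleculeId %in% plan@testMolecules), 45L)
  # rows follow their molecule; no molecule on both sides
  expect_length(intersect(plan@trainMolecules, plan@testMolecules), 0L)
  expect_identical(sort(c(plan@trainRows, plan@testRows)),
                   seq_len(nrow(rows)))
  expect_identical(plan@testMolecules,
                   moleculeLevelSplit(fs, 0.2, seed = 41L)@testMolecules)
})

test_that("moleculeLevelSplit rejects degenerate inputs", {
  fs <- new("FeatureSet", X = matrix(1:2, 2L, 1L), y = c(1, 2),
            groups = c("a", "a"),
            rowInfo = data.frame(moleculeId = c("a", "a"), atomIndex = 1:2,
                                 solvent = "DMSO", epsilon = 46.7))
  expect_error(moleculeLevelSplit(fs, 0.2), "single molecule")
  fs2 <- smlFixture()$fs
  expect_error(moleculeLevelSplit(fs2, 0), "strictly between")
  expect_error(moleculeLevelSplit(fs2, 1), "strictly between")
})

test_that("grouped CV folds keep molecules intact and cover all of them", {
  fx <- smlFixture()
  groups <- fx$fs@groups
  foldId <- SoapShift:::.groupedFolds(groups, 5L, seed = 42L)
  expect_identical(sort(unique(foldId)), 1:5)
  perMol <- tapply(foldId, groups, function(f) length(unique(f)))
  expect_true(all(perMol == 1L))
})

test_that("a degenerate grid returns its only parameter combination", {
  fx <- smlFixture()
  plan <- moleculeLevelSplit(fx$fs, 0.2, seed = 43L)
  m <- tuneAndTrain("decision-tree", fx$fs, plan, folds = 3L,
                    grid = list(cp = 0.005), seed = 44L, config = fx$cfg)
  expect_equal(m@bestParams$cp, 0.005)
  expect_error(tuneAndTrain("no-such-model", fx$fs, plan), "unknown model")
})

test_that("registered backends all fit and predict on the fixture", {
  fx <- smlFixture()
  plan <- moleculeLevelSplit(fx$fs, 0.2, seed = 45L)
  expect_setequal(registeredModels(),
                  c("gbt", "random-forest", "svr", "gaussian-process",
                    "kernel-ridge", "decision-tree"))
  for (name in c("random-forest", "svr", "kernel-ridge")) {
    m <- tuneAndTrain(name, fx$fs, plan, folds = 3L, seed = 46L,
                      config = fx$cfg)
    p <- predict(m, fx$fs@X[plan@testRows, , drop = FALSE])
    expect_length(p, length(plan@testRows))
    expect_true(all(is.finite(p)))
  }
})

test_that("regressionMetrics matches hand arithmetic and its inequalities", {
  perfect <- regressionMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(perfect), c(mae = 0, rmse = 0, r2 = 1))
  hand <- regressionMetrics(c(0, 2), c(1, 1))
  expect_equal(unlist(hand), c(mae = 1, rmse = 1, r2 = 0))
  set.seed(47)
  y <- rnorm(50); p <- rnorm(50)
  m <- regressionMetrics(y, p)
  expect_gte(m$rmse, m$mae)
  expect_warning(cm <- regressionMetrics(c(1, 1), c(1, 2)), "undefined")
  expect_true(is.nan(cm$r2))
  expect_error(regressionMetrics(1:3, 1:2), "equal")
})

test_that("evaluateBySolvent stratifies, counts and sorts correctly", {
  fx <- smlFixture()
  plan <- moleculeLevelSplit(fx$fs, 0.2, seed = 48L)
  m <- tuneAndTrain("decision-tree", fx$fs, plan, folds = 3L,
                    grid = list(cp = 0.01), seed = 49L, config = fx$cfg)
  rep <- evaluateBySolvent(fx$fs, plan, m)
  per <- rep@perSolvent
  expect_identical(sum(per$n), length(plan@testRows))
  expect_true(!is.unsorted(per$mae))
  expect_true(all(per$solvent %in%
                    unique(fx$fs@rowInfo$solvent[plan@testRows])))
  # permuting feature rows leaves the reported metrics unchanged
  perm <- SoapShift:::.withSeed(50L, sample(nrow(fx$fs@X)))
  fsPerm <- new("FeatureSet", X = fx$fs@X[perm, , drop = FALSE],
                y = fx$fs@y[perm], groups = fx$fs@groups[perm],
                rowInfo = fx$fs@rowInfo[perm, , drop = FALSE])
  planPerm <- new("SplitPlan", trainMolecules = plan@trainMolecules,
                  testMolecules = plan@testMolecules,
                  trainRows = which(fsPerm@groups %in% plan@trainMolecules),
                  testRows = which(fsPerm@groups %in% plan@testMolecules),
                  seed = plan@seed, testFraction = plan@testFraction)
  repPerm <- evaluateBySolvent(fsPerm, planPerm, m)
  expect_equal(repPerm@maePpm, rep@maePpm)
  expect_equal(repPerm@r2, rep@r2)
})

test_that("single-solvent test rows collapse per-solvent onto the overall row", {
  fx <- smlFixture()
  oneSolv <- fx$tab[fx$tab$solvent == "DMSO", ]
  fs <- assembleFeatures(fx$desc, oneSolv)
  plan <- moleculeLevelSplit(fs, 0.2, seed = 51L)
  m <- tuneAndTrain("decision-tree", fs, plan, folds = 3L,
                    grid = list(cp = 0.01), seed = 52L, config = fx$cfg)
  rep <- evaluateBySolvent(fs, plan, m)
  expect_identical(nrow(rep@perSolvent), 1L)
  expect_equal(rep@perSolvent$mae, rep@maePpm)
  expect_equal(rep@perSolvent$r2, rep@r2)
})

test_that("predictShifts is deterministic and transfers to unseen solvents", {
  fx <- smlFixture()
  plan <- moleculeLevelSplit(fx$fs, 0.2, seed = 53L)
  m <- tuneAndTrain("gbt", fx$fs, plan, folds = 3L,
                    grid = list(nrounds = 100L, maxDepth = 4L, eta = 0.1),
                    seed = 54L, config = fx$cfg)
  newMol <- fx$structs[[1L]]
  a <- predictShifts(m, newMol, "acetonitrile")
  b <- predictShifts(m, newMol, "ACN-d3")
  expect_equal(a, b)  # alias resolves to the same canonical solvent
  expect_true(all(a$epsilon == 37.5))
  expect_identical(nrow(a), sum(newMol@elements == "H"))
  noH <- MolecularStructure("noh", c("Zn", "C"),
                            rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_identical(nrow(predictShifts(m, noH, "DMSO")), 0L)
})

test_that("the boosted tree learns the synthetic oracle (held-out R2 >= 0.9)", {
  structs <- makeToyComplexes(30L, c(6L, 10L), seed = 61L)
  tab <- makeFixtureShiftTable(structs, noiseSeed = 62L)
  species <- sort(unique(unlist(lapply(structs, function(s) s@elements))))
  cfg <- soapConfig(species, rCut = 4, nMax = 3L, lMax = 3L, sigmaAtom = 0.5)
  desc <- computeSoap(structs, cfg, centers = "hydrogen")
  fs <- assembleFeatures(desc, tab)
  expect_gte(nrow(fs@X), 400L)
  plan <- moleculeLevelSplit(fs, 0.2, seed = 63L)
  m <- tuneAndTrain("gbt", fs, plan, folds = 5L, seed = 64L, config = cfg)
  rep <- evaluateBySolvent(fs, plan, m)
  expect_gte(rep@r2, 0.9)
})
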