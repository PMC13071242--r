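# Clustering, representative selection, PCA and the validation statistics.

test_that("kmeansFit separates two well-separated blobs exactly", {
  blobs <- makeClusteredDescriptors(2L, 20L, dim = 2L, separation = 10,
                                    seed = 3L)
  km <- kmeansFit(blobs$X, 2L, seed = 4L)
  lab <- clusterLabels(km)
  agree <- max(mean(lab == blobs$trueLabels),
               mean(lab == 1L - blobs$trueLabels))
  expect_identical(agree, 1)
})

test_that("k = 1 returns the column mean as the centroid", {
  X <- matrix(rnorm(40), 10L, 4L)
  km <- kmeansFit(X, 1L, seed = 1L)
  expect_equal(as.numeric(km@centroids), colMeans(X))
  expect_identical(clusterLabels(km), rep(0L, 10L))
})

test_that("kmeansFit inertia matches the exhaustive bipartition minimum", {
  X <- SoapShift:::.withSeed(8L, matrix(rnorm(12), 6L, 2L))
  # brute force over all 31 bipartitions of 6 points into two non-empty sets
  best <- Inf
  for (mask in 1:31) {
    side <- as.logical(bitwAnd(mask, 2L^(0:5)))
    inertia <- sum(apply(X[side, , drop = FALSE], 2L,
                         function(c) sum((c - mean(c))^2))) +
               sum(apply(X[!side, , drop = FALSE], 2L,
                         function(c) sum((c - mean(c))^2)))
    best <- min(best, inertia)
  }
  km <- kmeansFit(X, 2L, seed = 1L, nInit = 20L)
  expect_equal(km@inertia, best, tolerance = 1e-10)
})

test_that("kmeansFit validates k and is deterministic; inertia non-increasing in nInit", {
  X <- matrix(rnorm(30), 10L, 3L)
  expect_error(kmeansFit(X, 11L), "exceeds")
  expect_error(kmeansFit(X, 0L), ">= 1")
  a <- kmeansFit(X, 3L, seed = 9L)
  b <- kmeansFit(X, 3L, seed = 9L)
  expect_identical(clusterLabels(a), clusterLabels(b))
  few <- kmeansFit(X, 3L, seed = 9L, nInit = 1L)
  many <- kmeansFit(X, 3L, seed = 9L, nInit = 10L)
  expect_lte(many@inertia, few@inertia + 1e-12)
})

test_that("selectRepresentatives draws per-cluster counts deterministically", {
  blobs <- makeClusteredDescriptors(3L, 30L, separation = 10, seed = 5L)
  km <- kmeansFit(blobs$X, 3L, seed = 6L)
  ids <- sprintf("mol_%03d", seq_len(nrow(blobs$X)))
  picked <- selectRepresentatives(km, ids, 15L, seed = 7L)
  expect_length(picked, 45L)
  expect_identical(anyDuplicated(picked), 0L)
  perCluster <- table(clusterLabels(km)[match(picked, ids)])
  expect_true(all(perCluster == 15L))
  expect_identical(picked, selectRepresentatives(km, ids, 15L, seed = 7L))
})

test_that("selectRepresentatives errors on an undersized cluster", {
  blobs <- makeClusteredDescriptors(3L, 7L, separation = 10, seed = 5L)
  km <- kmeansFit(blobs$X, 3L, seed = 6L)
  ids <- as.character(seq_len(nrow(blobs$X)))
  expect_error(selectRepresentatives(km, ids, 15L, seed = 1L), "only 7")
})

test_that("pcaProject captures rank-1 data in the first component", {
  t <- seq(-1, 1, length.out = 50L)
  X <- cbind(1 + 2 * t, -t, 0.5 * t) +
    SoapShift:::.withSeed(2L, matrix(rnorm(150, sd = 1e-6), 50L, 3L))
  pca <- pcaProject(X, 3L)
  expect_gt(pca$varianceExplained[1L], 0.9999)
})

test_that("pca scores are orthogonal and the basis reconstructs centered X", {
  X <- SoapShift:::.withSeed(3L, matrix(rnorm(200), 40L, 5L))
  pca <- pcaProject(X, 5L)
  G <- crossprod(pca$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  recon <- pca$scores %*% t(pca$rotation)
  expect_equal(recon, sweep(X, 2L, colMeans(X)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(pcaTransform(pca, X), pca$scores, ignore_attr = TRUE)
  expect_error(pcaProject(matrix(1, 5L, 2L), 1L), "degenerate")
})

test_that("ksValidate reproduces hand-enumerated KS statistics", {
  same <- matrix(c(1, 2, 3, 4), 4L, 1L)
  r <- ksValidate(same, same)
  expect_equal(r$ksStats$D, 0)
  expect_equal(r$ksStats$p, 1)
  disjoint <- ksValidate(matrix(11:14, 4L, 1L), same)
  expect_equal(disjoint$ksStats$D, 1)
  # {1,2,3} vs {1.5,2.5}: ECDF gaps are 1/3 - 0, 1/3, 1/3 -> D = 1/3
  hand <- ksValidate(matrix(c(1, 2, 3), 3L, 1L), matrix(c(1.5, 2.5), 2L, 1L))
  expect_equal(hand$ksStats$D, 1 / 3)
  # D is symmetric under swapping the samples
  swap <- ksValidate(matrix(c(1.5, 2.5), 2L, 1L), matrix(c(1, 2, 3), 3L, 1L))
  expect_equal(swap$ksStats$D, hand$ksStats$D)
  expect_error(ksValidate(matrix(1, 1L, 1L), same), "2 rows")
})

test_that("ksValidate counts significant components", {
  set.seed(10)
  a <- matrix(rnorm(200), 100L, 2L)
  b <- cbind(a[1:30, 1L], a[1:30, 2L] + 50)  # second column displaced
  r <- ksValidate(b, a)
  expect_identical(r$nSignificant, 1L)
})

test_that("diversityRatio of a random subset is ~1 within Monte-Carlo error", {
  X <- SoapShift:::.withSeed(11L, matrix(rnorm(400), 100L, 4L))
  sub <- SoapShift:::.withSeed(12L, X[sample.int(100L, 20L), ])
  # the subset statistic is itself one draw from the null distribution, so
  # the ratio scatters with the draw standard deviation (not the SE of the
  # 200-draw reference mean)
  draws <- SoapShift:::.withSeed(13L, vapply(1:200, function(i)
    mean(dist(X[sample.int(100L, 20L), ])), 0))
  ratio <- diversityRatio(sub, X, nRandom = 200L, seed = 14L)
  expect_lt(abs(ratio - 1), 3 * sd(draws) / mean(draws))
})

test_that("convex-hull extremes have diversity ratio above 1", {
  X <- SoapShift:::.withSeed(15L, matrix(rnorm(100), 50L, 2L))
  hull <- X[chull(X), ]
  expect_gt(diversityRatio(hull, X, seed = 1L), 1)
})

test_that("diversityRatio equals the exhaustive 5-of-20 enumeration", {
  X <- SoapShift:::.withSeed(16L, matrix(rnorm(40), 20L, 2L))
  sub <- X[c(1L, 5L, 9L, 13L, 17L), ]
  combos <- utils::combn(20L, 5L)
  refStat <- mean(apply(combos, 2L, function(idx) mean(dist(X[idx, ]))))
  expected <- mean(dist(sub)) / refStat
  # Monte-Carlo estimate converges to the exhaustive value
  mc <- diversityRatio(sub, X, nRandom = 4000L, seed = 17L)
  expect_equal(mc, expected, tolerance = 0.02)
  expect_error(diversityRatio(X[1L, , drop = FALSE], X), "at least 2")
})

test_that("seeded helpers leave the caller's RNG stream untouched", {
  X <- matrix(rnorm(20), 10L, 2L)
  set.seed(123)
  before <- .Random.seed
  invisible(kmeansFit(X, 2L, seed = 1L))
  invisible(makeToyComplexes(2L, c(5L, 6L), seed = 2L))
  expect_identical(.Random.seed, before)
})
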