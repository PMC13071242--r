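# Representative-subset machinery: cluster the molecule-level descriptor
# cloud, draw a fixed number of molecules per cluster, and check that the
# draw is statistically representative of the full database.

# Evaluate an expression with a temporary RNG state so package functions are
# deterministic given their seed argument without disturbing the caller's
# random stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 32-bit string hash (djb2), for deriving record-keyed seeds.
.stringSeed <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

.kmeansPlusPlusInit <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1L], ])^2)
  for (j in seq_len(k - 1L)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = probs)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[j + 1L], ])^2))
  }
  X[centers, , drop = FALSE]
}

.lloyd <- function(X, centroids, maxIter) {
  k <- nrow(centroids)
  labels <- integer(nrow(X))
  for (it in seq_len(maxIter)) {
    # squared distances to each centroid
    d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centroids) +
      outer(rep(1, nrow(X)), rowSums(centroids^2))
    newLabels <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      members <- newLabels == j
      if (!any(members)) {
        # re-seed an emptied centroid at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(nrow(X)), newLabels)])
        newLabels[far] <- j
        members <- newLabels == j
      }
      centroids[j, ] <- colMeans(X[members, , drop = FALSE])
    }
    if (identical(newLabels, labels)) break
    labels <- newLabels
  }
  d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centroids) +
    outer(rep(1, nrow(X)), rowSums(centroids^2))
  labels <- max.col(-d2, ties.method = "first")
  inertia <- sum(pmax(d2[cbind(seq_len(nrow(X)), labels)], 0))
  list(labels = labels, centroids = centroids, inertia = inertia)
}

#' Fit k-means to a descriptor matrix
#'
#' Lloyd iterations from k-means++ seeding, best of \code{nInit} restarts by
#' within-cluster inertia; deterministic given \code{seed}.  Emptied clusters
#' are re-seeded at the point farthest from its current centroid, so every
#' cluster in the returned model is non-empty.
#'
#' @param X Numeric matrix, one row per molecule.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param nInit Number of restarts (default 10).
#' @param maxIter Maximum Lloyd iterations per restart (default 300).
#' @return A \linkS4class{ClusterModel} with 0-based labels.
#' @export
kmeansFit <- function(X, k, seed = 1L, nInit = 10L, maxIter = 300L) {
  X <- as.matrix(X)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(X))
    stop("k = ", k, " exceeds the number of rows (", nrow(X), ")")
  best <- NULL
  .withSeed(seed, {
    for (i in seq_len(nInit)) {
      init <- .kmeansPlusPlusInit(X, k)
      fit <- .lloyd(X, init, maxIter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  new("ClusterModel", k = as.integer(k), centroids = best$centroids,
      labels = as.integer(best$labels - 1L), inertia = best$inertia,
      seed = as.integer(seed))
}

#' Draw the representative subset: fixed count per cluster
#'
#' Uniform draw without replacement of \code{perCluster} molecule ids from
#' each cluster of a fitted \linkS4class{ClusterModel}; the selection
#' protocol behind the 45-complex training database (3 clusters x 15).
#'
#' @param model A \linkS4class{ClusterModel}.
#' @param moleculeIds Character vector aligned with the clustered rows.
#' @param perCluster Number of molecules to draw from each cluster.
#' @param seed Integer seed.
#' @return Character vector of selected ids, sorted by (cluster, id).
#' @export
selectRepresentatives <- function(model, moleculeIds, perCluster, seed = 1L) {
  if (length(moleculeIds) != length(model@labels))
    stop("moleculeIds must align with the clustered rows")
  picks <- .withSeed(seed, {
    lapply(seq_len(model@k) - 1L, function(cl) {
      members <- moleculeIds[model@labels == cl]
      if (length(members) < perCluster)
        stop("cluster ", cl, " holds only ", length(members),
             " molecules; cannot draw ", perCluster)
      sort(sample(members, perCluster))
    })
  })
  unlist(picks)
}

#' Project data onto principal components
#'
#' Centered (not scaled) PCA; component signs are fixed by making each
#' component's largest-magnitude loading positive, so scores are
#' reproducible across platforms.
#'
#' @param X Numeric matrix.
#' @param nComponents Number of leading components.
#' @return A list with \code{scores} (rows of X projected), \code{rotation},
#'   \code{center} and \code{varianceExplained} (per retained component);
#'   class \code{soapPca}.  Use \code{\link{pcaTransform}} to project new
#'   data into the same basis.
#' @export
pcaProject <- function(X, nComponents) {
  X <- as.matrix(X)
  if (nComponents > min(nrow(X) - 1L, ncol(X)))
    stop("nComponents exceeds min(rows - 1, cols)")
  keep <- apply(X, 2L, function(col) diff(range(col)) > 0)
  if (!any(keep)) stop("degenerate input: all columns are constant")
  pr <- stats::prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
                      rank. = nComponents)
  rot <- pr$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, 0)
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- sweep(pr$x, 2L, flip, `*`)
  vexp <- pr$sdev[seq_len(ncol(rot))]^2 / sum(pr$sdev^2)
  structure(list(scores = scores, rotation = rot, center = pr$center,
                 keep = keep, varianceExplained = vexp),
            class = "soapPca")
}

#' Project new rows into an existing PCA basis
#'
#' @param pca A \code{soapPca} from \code{\link{pcaProject}}.
#' @param X New data with the same columns as the fitted matrix.
#' @return Score matrix in the fitted basis.
#' @export
pcaTransform <- function(pca, X) {
  X <- as.matrix(X)[, pca$keep, drop = FALSE]
  sweep(X, 2L, pca$center) %*% pca$rotation
}

#' Kolmogorov-Smirnov validation of a representative subset
#'
#' Per-component two-sample KS test (asymptotic p-values) comparing the
#' subset's principal-component scores against the full database's, in the
#' PCA basis fitted on the full database.  A representative draw shows no
#' significant difference (p > 0.05) on most components.
#'
#' @param subsetScores,fullScores Score matrices with identical column count
#'   (conventionally the top 10 components).
#' @return A list of class \code{validationReport}: \code{ksStats}
#'   (data.frame with \code{component}, \code{D}, \code{p}),
#'   \code{nSignificant} (count of p <= 0.05) and \code{diversityRatio}
#'   (NA here; filled by \code{\link{diversityRatio}} callers).
#' @export
ksValidate <- function(subsetScores, fullScores) {
  subsetScores <- as.matrix(subsetScores)
  fullScores <- as.matrix(fullScores)
  if (ncol(subsetScores) != ncol(fullScores))
    stop("score matrices must share column count")
  if (nrow(subsetScores) < 2L || nrow(fullScores) < 2L)
    stop("need at least 2 rows on each side")
  ks <- lapply(seq_len(ncol(fullScores)), function(j) {
    t <- suppressWarnings(
      stats::ks.test(subsetScores[, j], fullScores[, j], exact = FALSE))
    data.frame(component = j, D = unname(t$statistic), p = t$p.value)
  })
  ks <- do.call(rbind, ks)
  structure(list(ksStats = ks, nSignificant = sum(ks$p <= 0.05),
                 diversityRatio = NA_real_,
                 diversityDefinition = "artifact default"),
            class = "validationReport")
}

#' Diversity ratio of a subset relative to its parent cloud
#'
#' Mean pairwise Euclidean distance within the subset divided by the average
#' of the same statistic over \code{nRandom} uniform random subsets of equal
#' size drawn from the full matrix.  A value above 1 means the subset spreads
#' wider than random sampling; the selection protocol targets such
#' broader-than-random coverage.  The normalization by random subsets is this
#' package's explicit definition (reported as "artifact default" in
#' validation output).
#'
#' @param subsetX Numeric matrix of the selected rows (>= 2 rows).
#' @param fullX Numeric matrix of the full cloud.
#' @param nRandom Number of random reference subsets (default 200).
#' @param seed Integer seed.
#' @return The dimensionless ratio.
#' @export
diversityRatio <- function(subsetX, fullX, nRandom = 200L, seed = 1L) {
  subsetX <- as.matrix(subsetX); fullX <- as.matrix(fullX)
  m <- nrow(subsetX)
  if (m < 2L) stop("subset must contain at least 2 rows")
  if (nRandom < 1L) stop("nRandom must be >= 1")
  meanPairDist <- function(M) mean(stats::dist(M))
  subStat <- meanPairDist(subsetX)
  refStat <- .withSeed(seed, {
    mean(vapply(seq_len(nRandom), function(i) {
      meanPairDist(fullX[sample.int(nrow(fullX), m), , drop = FALSE])
    }, 0))
  })
  subStat / refStat
}
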