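# Synthetic fixtures: toy zinc-centered structures, a known shift-generating
# function, and clustered descriptor clouds, so every stage of the pipeline
# can be exercised against a ground truth without any external data.

#' Default parameters of the synthetic shift-generating function
#'
#' The synthetic target is
#' \deqn{\delta = \beta_0 + \beta_d \, d(H, Zn) + \beta_c \, C_H +
#'       \beta_\epsilon \, \epsilon + N(0, \sigma_{noise})}
#' where \eqn{d(H, Zn)} is the hydrogen's distance to the zinc center in
#' Angstrom and \eqn{C_H} the number of heavy (non-H) atoms within 3 Angstrom
#' of the hydrogen.  Distance and coordination count are functions of the
#' local environment, hence learnable from SOAP features, and the
#' dielectric term is linear in epsilon, mirroring the modeling assumption
#' that the dielectric constant alone encodes the solvent.  Defaults are
#' chosen so generated shifts span roughly 0-12 ppm, the scale of 1H shifts
#' in zinc-complex spectra.
#'
#' @param beta0 Offset, ppm (default -3).
#' @param betaDist Slope on the H-Zn distance, ppm per Angstrom
#'   (default 1.8).
#' @param betaCoord Increment per heavy neighbor within 3 Angstrom of the H,
#'   ppm (default 0.35).
#' @param betaEps Slope on the dielectric constant, ppm per epsilon unit
#'   (default 0.03).
#' @param noiseSigma Gaussian noise standard deviation, ppm (default 0.05:
#'   small against the 0-12 ppm spread, large enough to exercise
#'   regularization).
#' @return Named list of parameters.
#' @export
fixtureParams <- function(beta0 = -3, betaDist = 1.8, betaCoord = 0.35,
                          betaEps = 0.03, noiseSigma = 0.05) {
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  list(beta0 = beta0, betaDist = betaDist, betaCoord = betaCoord,
       betaEps = betaEps, noiseSigma = noiseSigma)
}

#' Generate toy zinc complexes
#'
#' Each molecule has exactly one Zn at the origin, at least two H, and the
#' remaining atoms drawn from C, N, O.  Ligand atoms are placed at random
#' directions in a shell 1.8-5 Angstrom from the zinc, with rejection until
#' every pairwise distance is at least 0.8 Angstrom.  Purely a statistical
#' stand-in for coordination geometry: no valence or bonding rules.
#' Deterministic given \code{seed}.
#'
#' @param nMolecules Number of molecules.
#' @param atomsRange Length-2 integer range of total atoms per molecule,
#'   within [5, 40] (default c(8, 14)).
#' @param seed Integer seed.
#' @return List of \linkS4class{MolecularStructure} with ids
#'   \code{synth_000}, ... and total charge 0.
#' @export
makeToyComplexes <- function(nMolecules, atomsRange = c(8L, 14L), seed = 1L) {
  if (nMolecules < 1L) stop("nMolecules must be >= 1")
  if (atomsRange[1] < 5L || atomsRange[2] > 40L || atomsRange[1] > atomsRange[2])
    stop("atomsRange must lie within [5, 40]")
  .withSeed(seed, {
    lapply(seq_len(nMolecules) - 1L, function(i) {
      natoms <- sample(seq(atomsRange[1], atomsRange[2]), 1L)
      # one Zn + guaranteed 2 H + the rest drawn H/C/N/O
      others <- c("H", "H",
                  sample(c("H", "C", "N", "O"), natoms - 3L, replace = TRUE,
                         prob = c(0.35, 0.35, 0.15, 0.15)))
      elements <- c("Zn", sample(others))
      coords <- matrix(0, natoms, 3L)
      for (a in 2:natoms) {
        placed <- FALSE
        for (try in seq_len(500L)) {
          u <- stats::rnorm(3L)
          u <- u / sqrt(sum(u^2))
          pos <- u * stats::runif(1L, 1.8, 5.0)
          d <- sqrt(rowSums(sweep(coords[seq_len(a - 1L), , drop = FALSE],
                                  2L, pos)^2))
          if (all(d >= 0.8)) {
            coords[a, ] <- pos
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stop("could not place atom ", a, " after 500 attempts; ",
               "try fewer atoms per molecule")
      }
      MolecularStructure(sprintf("synth_%03d", i), elements, coords, 0L)
    })
  })
}

#' Ground-truth synthetic shift for one hydrogen in one solvent
#'
#' Evaluates the shift-generating function of \code{\link{fixtureParams}}.
#' The noise draw is keyed deterministically by (molecule, atom, solvent,
#' \code{noiseSeed}), so the same record always receives the same noise and
#' different records receive independent draws.
#'
#' @param structure A \linkS4class{MolecularStructure} containing one Zn.
#' @param atomIndex 0-based index of a hydrogen atom.
#' @param epsilon Solvent dielectric constant.
#' @param params Parameters from \code{\link{fixtureParams}}.
#' @param noiseSeed Integer seed of the noise stream.
#' @return Shift delta in ppm.
#' @export
syntheticShiftOracle <- function(structure, atomIndex, epsilon,
                                 params = fixtureParams(), noiseSeed = 1L) {
  el <- structure@elements
  if (atomIndex < 0L || atomIndex >= length(el))
    stop("atomIndex out of range")
  if (el[atomIndex + 1L] != "H")
    stop("atom ", atomIndex, " is ", el[atomIndex + 1L], ", not H")
  zn <- which(el == "Zn")
  if (length(zn) != 1L) stop("structure must contain exactly one Zn")
  h <- structure@coordinates[atomIndex + 1L, ]
  dZn <- sqrt(sum((h - structure@coordinates[zn, ])^2))
  heavy <- which(el != "H")
  dHeavy <- sqrt(rowSums(sweep(structure@coordinates[heavy, , drop = FALSE],
                               2L, h)^2))
  coord <- sum(dHeavy <= 3.0)
  delta <- params$beta0 + params$betaDist * dZn +
    params$betaCoord * coord + params$betaEps * epsilon
  if (params$noiseSigma > 0) {
    key <- .stringSeed(paste(structure@moleculeId, atomIndex,
                             format(epsilon), noiseSeed, sep = "|"))
    delta <- delta + .withSeed(key, stats::rnorm(1L, 0, params$noiseSigma))
  }
  delta
}

#' Build the full synthetic shift table for a set of structures
#'
#' One record per hydrogen per solvent, with \code{deltaPpm} from
#' \code{\link{syntheticShiftOracle}}.
#'
#' @param structures List of \linkS4class{MolecularStructure}.
#' @param solvents Character vector of registered solvent names (default:
#'   the five training solvents).
#' @param params Parameters from \code{\link{fixtureParams}}.
#' @param noiseSeed Integer seed of the noise stream.
#' @param registry Solvent registry.
#' @return A shift-record \code{data.frame} in the
#'   \code{\link{loadShiftTable}} layout.
#' @export
makeFixtureShiftTable <- function(structures,
                                  solvents = c("acetone", "chloroform",
                                               "DMSO", "MeOH", "THF"),
                                  params = fixtureParams(), noiseSeed = 1L,
                                  registry = solventRegistry()) {
  rows <- list()
  for (s in structures) {
    hIdx <- which(s@elements == "H") - 1L
    for (solv in solvents) {
      sol <- lookupSolvent(solv, registry)
      for (ai in hIdx) {
        rows[[length(rows) + 1L]] <- data.frame(
          moleculeId = s@moleculeId, atomIndex = ai, solvent = sol$name,
          epsilon = sol$epsilon, sigmaPpm = NA_real_,
          deltaPpm = syntheticShiftOracle(s, ai, sol$epsilon, params,
                                          noiseSeed),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate clustered Gaussian descriptor clouds
#'
#' Isotropic unit-variance Gaussian blobs whose centroids are drawn with
#' pairwise spacing \code{separation} times the within-blob spread; a test
#' bed with known labels for the clustering and selection machinery.
#'
#' @param k Number of blobs.
#' @param nPerCluster Points per blob.
#' @param dim Dimensionality (default 8).
#' @param separation Centroid spacing in units of within-blob spread
#'   (default 10; 0 collapses all blobs onto one).
#' @param seed Integer seed.
#' @return List with \code{X} (matrix, \code{k * nPerCluster} rows) and
#'   \code{trueLabels} (0-based integer vector).
#' @export
makeClusteredDescriptors <- function(k, nPerCluster, dim = 8L,
                                     separation = 10, seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  if (separation < 0) stop("separation must be >= 0")
  .withSeed(seed, {
    centroids <- matrix(0, k, dim)
    if (k > 1L && separation > 0) {
      for (j in 2:k) {
        repeat {
          cand <- stats::rnorm(dim)
          cand <- cand / sqrt(sum(cand^2)) * separation *
            stats::runif(1L, 1, 1.5)
          d <- sqrt(rowSums(sweep(centroids[seq_len(j - 1L), , drop = FALSE],
                                  2L, cand)^2))
          if (all(d >= separation)) break
        }
        centroids[j, ] <- cand
      }
    }
    X <- do.call(rbind, lapply(seq_len(k), function(j) {
      sweep(matrix(stats::rnorm(nPerCluster * dim), nPerCluster, dim),
            2L, centroids[j, ], `+`)
    }))
    list(X = X, trueLabels = rep(seq_len(k) - 1L, each = nPerCluster))
  })
}
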