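# SOAP power-spectrum engine.
#
# The atomic neighbor density around a center is a sum of unnormalized
# Gaussians of width sigmaAtom at every neighbor position within rCut
# (including the center atom itself, in its own species channel).  The
# density is expanded on orthonormal radial functions g_n(r) times real
# spherical harmonics Y_lm, and the rotationally invariant power spectrum
#   p(Z1,Z2,n,n',l) = pi * sqrt(8/(2l+1)) * sum_m c(Z1,n,l,m) c(Z2,n',l,m)
# is flattened per species pair (Z1 <= Z2 by atomic number), l, then (n,n')
# with the redundant (n,n') half stored once for Z1 == Z2.  With rbf "gto"
# and cutoffWidth 0 this reproduces the reference descriptor library
# bit-for-bit (verified to ~1e-10 relative).

# ---- radial bases -----------------------------------------------------------

# Symmetric inverse square root of an SPD matrix (Lowdin orthonormalization).
.invSqrtm <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values <= 0))
    stop("radial-basis overlap matrix is not positive definite; ",
         "lower nMax or increase rCut")
  if (max(e$values) / min(e$values) > 1e12)
    warning("radial-basis overlap matrix is ill-conditioned (cond > 1e12); ",
            "the orthonormalized basis is numerically unreliable -- ",
            "lower nMax (or use rbf = \"gto\")", call. = FALSE)
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# GTO radial basis: per l, g_nl(r) = sum_n' beta[n,n'] r^l exp(-alpha_n' r^2),
# alphas chosen so each primitive decays to 1e-3 at cutoffs evenly spaced on
# [1, rCut]; Lowdin-orthonormalized with the analytic overlap
# int_0^inf r^(2l+2) exp(-(ai+aj) r^2) dr = Gamma(l+3/2)/2 * (ai+aj)^-(l+3/2).
# Returns a list over l of nMax x length(r) matrices.
.radialBasisGto <- function(config, r) {
  nmax <- config@nMax
  a <- if (nmax == 1L) config@rCut else seq(1, config@rCut, length.out = nmax)
  lapply(0:config@lMax, function(l) {
    alphas <- -log(1e-3 / a^l) / a^2
    m <- outer(alphas, alphas, `+`)
    S <- 0.5 * gamma(l + 1.5) * m^(-(l + 1.5))
    beta <- .invSqrtm(S)
    prim <- t(vapply(alphas, function(al) r^l * exp(-al * r^2), r))
    beta %*% prim
  })
}

# Polynomial radial basis: g_n(r) = sum_n' beta[n,n'] (rCut - r)^(n'+2) on
# [0, rCut], with the analytic overlap
# int_0^rcut (rc-r)^(i+2) (rc-r)^(j+2) r^2 dr
#   = 2 rc^(i+j+7) / ((i+j+5)(i+j+6)(i+j+7)).
# l-independent; replicated over l for a uniform interface.
.radialBasisPoly <- function(config, r) {
  nmax <- config@nMax
  rc <- config@rCut
  ij <- outer(seq_len(nmax), seq_len(nmax), `+`)
  S <- 2 * rc^(ij + 7) / ((ij + 5) * (ij + 6) * (ij + 7))
  beta <- .invSqrtm(S)
  prim <- t(vapply(seq_len(nmax),
                   function(n) pmax(rc - r, 0)^(n + 2), r))
  g <- beta %*% prim
  rep(list(g), config@lMax + 1L)
}

# Quadrature grid + discretized basis for a config, computed once per call
# into computeSoap and shared across centers.
.radialSetup <- function(config) {
  if (config@rbf == "gto") {
    rmax <- config@rCut + 10 * config@sigmaAtom
    gl <- pracma::gaussLegendre(300L, 0, rmax)
    basis <- .radialBasisGto(config, gl$x)
  } else {
    gl <- pracma::gaussLegendre(150L, 0, config@rCut)
    basis <- .radialBasisPoly(config, gl$x)
  }
  list(r = gl$x, w = gl$w, basis = basis)
}

# ---- angular part -----------------------------------------------------------

# Real spherical harmonics Y_lm evaluated at unit vectors, one l at a time.
# Returns a length(theta) x (2l+1) matrix, m = -l..l.  Condon-Shortley-free.
.realSphHarm <- function(l, costheta, phi) {
  nv <- length(costheta)
  if (l == 0L) return(matrix(1 / sqrt(4 * pi), nv, 1L))
  # pracma::legendre returns (l+1) x nv, rows m = 0..l, with the
  # Condon-Shortley phase (-1)^m baked in; we cancel it below.
  P <- pracma::legendre(l, costheta)
  if (is.null(dim(P))) P <- matrix(P, ncol = 1L)
  Y <- matrix(0, nv, 2L * l + 1L)
  for (m in 0:l) {
    norm <- sqrt((2 * l + 1) / (4 * pi) *
                 exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    Pm <- (-1)^m * P[m + 1L, ]
    if (m == 0L) {
      Y[, l + 1L] <- norm * Pm
    } else {
      Y[, l + 1L + m] <- sqrt(2) * norm * Pm * cos(m * phi)
      Y[, l + 1L - m] <- sqrt(2) * norm * Pm * sin(m * phi)
    }
  }
  Y
}

# Modified spherical Bessel function of the first kind i_l(x), exponentially
# scaled: returns i_l(x) * exp(-x).  Vectorized over x >= 0.
.sphBesselIScaled <- function(l, x) {
  out <- numeric(length(x))
  tiny <- x < 1e-8
  if (any(tiny))  # series limit i_l(x) ~ x^l / (2l+1)!!
    out[tiny] <- x[tiny]^l / prod(seq(1, 2 * l + 1, by = 2)) * exp(-x[tiny])
  if (any(!tiny))
    out[!tiny] <- sqrt(pi / (2 * x[!tiny])) *
      besselI(x[!tiny], l + 0.5, expon.scaled = TRUE)
  out
}

# Cosine taper of the neighbor density amplitude over the final cutoffWidth
# Angstrom before rCut; identically 1 with cutoffWidth 0.
.cutoffTaper <- function(dist, rCut, width) {
  w <- rep(1, length(dist))
  if (width > 0) {
    inside <- dist > (rCut - width)
    w[inside] <- 0.5 * (1 + cos(pi * (dist[inside] - rCut + width) / width))
  }
  w
}

# ---- density expansion ------------------------------------------------------

#' Expansion coefficients of the neighbor density around one center
#'
#' Expands the species-resolved smeared neighbor density (Gaussians of width
#' \code{sigmaAtom} at every atom within \code{rCut} of the center, the
#' center atom included) on the orthonormal radial basis times real spherical
#' harmonics.
#'
#' @param structure A \linkS4class{MolecularStructure}.
#' @param centerIndex 0-based index of the center atom.
#' @param config A \linkS4class{SoapConfig}; its species must cover every
#'   element within \code{rCut} of the center.
#' @param setup Internal precomputed radial setup (leave default).
#' @return A 4-d array \code{c[species, n, l+1, m+lMax+1]} of class
#'   \code{DensityCoefficients} with the config attached as attribute
#'   \code{config}.  Entries with |m| > l are structurally zero.
#' @seealso \code{\link{powerSpectrum}}, \code{\link{computeSoap}}
#' @export
densityCoefficients <- function(structure, centerIndex, config,
                                setup = .radialSetup(config)) {
  natoms <- length(structure@elements)
  if (centerIndex < 0L || centerIndex >= natoms)
    stop("centerIndex ", centerIndex, " out of range [0, ", natoms, ")")
  nmax <- config@nMax; lmax <- config@lMax
  nsp <- length(config@species)
  center <- structure@coordinates[centerIndex + 1L, ]
  disp <- sweep(structure@coordinates, 2L, center)
  dist <- sqrt(rowSums(disp^2))
  # With the taper active, neighbor weights vanish at rCut, so locality is
  # exact there.  Without it (the reference-library convention) a Gaussian
  # centered slightly beyond rCut still carries density inside the sphere:
  # include neighbors out to where that density has decayed to 1e-3.
  reach <- if (config@cutoffWidth > 0) config@rCut
           else config@rCut + config@sigmaAtom * sqrt(-2 * log(1e-3))
  within <- dist <= reach
  el <- structure@elements[within]
  missing <- setdiff(unique(el), config@species)
  if (length(missing))
    stop("element(s) within the cutoff are absent from config species: ",
         paste(missing, collapse = ", "))
  disp <- disp[within, , drop = FALSE]
  dist <- dist[within]
  spIdx <- match(el, config@species)
  taper <- .cutoffTaper(dist, config@rCut, config@cutoffWidth)

  r <- setup$r; wq <- setup$w; basis <- setup$basis
  sig2 <- config@sigmaAtom^2
  co <- array(0, dim = c(nsp, nmax, lmax + 1L, 2L * lmax + 1L))

  isCenter <- dist < 1e-12
  # center atom: only the l = 0, m = 0 channel survives (Y00 constant)
  if (any(isCenter)) {
    f0 <- r^2 * exp(-r^2 / (2 * sig2))
    I0 <- as.numeric(basis[[1L]] %*% (wq * f0))
    for (i in which(isCenter))
      co[spIdx[i], , 1L, lmax + 1L] <-
        co[spIdx[i], , 1L, lmax + 1L] + sqrt(4 * pi) * taper[i] * I0
  }

  keep <- which(!isCenter)
  if (length(keep)) {
    Ri <- dist[keep]
    u <- disp[keep, , drop = FALSE] / Ri
    costheta <- pmin(pmax(u[, 3L], -1), 1)
    phi <- atan2(u[, 2L], u[, 1L])
    sk <- spIdx[keep]; tk <- taper[keep]
    # gaussian envelope exp(-(r - Ri)^2 / (2 sigma^2)) after i_l descaling
    env <- outer(r, Ri, function(rr, dd) exp(-(rr - dd)^2 / (2 * sig2)))
    x <- outer(r, Ri) / sig2
    for (l in 0:lmax) {
      il <- matrix(.sphBesselIScaled(l, x), nrow = length(r))
      Fmat <- (r^2 * wq) * (env * il)           # grid x neighbors
      Il <- basis[[l + 1L]] %*% Fmat            # nmax x neighbors
      Y <- .realSphHarm(l, costheta, phi)       # neighbors x (2l+1)
      mcols <- (lmax + 1L - l):(lmax + 1L + l)
      for (s in unique(sk)) {
        sel <- sk == s
        contrib <- Il[, sel, drop = FALSE] %*%
          (4 * pi * tk[sel] * Y[sel, , drop = FALSE])
        co[s, , l + 1L, mcols] <- co[s, , l + 1L, mcols] + contrib
      }
    }
  }
  structure(co, class = "DensityCoefficients", config = config)
}

# ---- power spectrum ---------------------------------------------------------

#' Layout of the flattened SOAP power spectrum
#'
#' @param config A \linkS4class{SoapConfig}.
#' @return A \code{data.frame} with one row per descriptor entry: columns
#'   \code{species1}, \code{species2}, \code{l}, \code{n1}, \code{n2}
#'   (1-based radial indices).
#' @export
soapLayout <- function(config) {
  nsp <- length(config@species); nmax <- config@nMax
  rows <- vector("list", nsp * (nsp + 1L) / 2L)
  k <- 0L
  for (s1 in seq_len(nsp)) for (s2 in s1:nsp) {
    same <- s1 == s2
    blk <- do.call(rbind, lapply(0:config@lMax, function(l) {
      if (same) {
        n1 <- rep(seq_len(nmax), times = nmax:1)
        n2 <- unlist(lapply(seq_len(nmax), function(n) n:nmax))
      } else {
        n1 <- rep(seq_len(nmax), each = nmax)
        n2 <- rep(seq_len(nmax), times = nmax)
      }
      data.frame(species1 = config@species[s1],
                 species2 = config@species[s2],
                 l = l, n1 = n1, n2 = n2, stringsAsFactors = FALSE)
    }))
    k <- k + 1L
    rows[[k]] <- blk
  }
  do.call(rbind, rows)
}

#' Length of the flattened SOAP descriptor
#'
#' Equals \code{(lMax + 1) * M * (M + 1) / 2} with
#' \code{M = length(species) * nMax}, the number of unique
#' (species, n) <= (species', n') pairs per angular channel.
#'
#' @param config A \linkS4class{SoapConfig}.
#' @return Integer descriptor length.
#' @export
descriptorLength <- function(config) {
  M <- length(config@species) * config@nMax
  as.integer((config@lMax + 1L) * M * (M + 1L) / 2L)
}

#' Contract density coefficients into the invariant power spectrum
#'
#' @param coeffs A \code{DensityCoefficients} array from
#'   \code{\link{densityCoefficients}}.
#' @param config The same \linkS4class{SoapConfig} the coefficients were
#'   produced under.
#' @return Numeric vector of length \code{\link{descriptorLength}(config)},
#'   ordered per \code{\link{soapLayout}}.
#' @export
powerSpectrum <- function(coeffs, config) {
  nmax <- config@nMax; lmax <- config@lMax
  nsp <- length(config@species)
  if (!identical(dim(coeffs), c(nsp, nmax, lmax + 1L, 2L * lmax + 1L)))
    stop("coefficient array shape does not match the config")
  out <- numeric(descriptorLength(config))
  pos <- 0L
  # row-major upper triangle (n1 outer, n2 >= n1) as column-major indices
  n1u <- rep(seq_len(nmax), times = nmax:1)
  n2u <- unlist(lapply(seq_len(nmax), function(n) n:nmax))
  triIdx <- n1u + (n2u - 1L) * nmax
  for (s1 in seq_len(nsp)) for (s2 in s1:nsp) {
    same <- s1 == s2
    for (l in 0:lmax) {
      mcols <- (lmax + 1L - l):(lmax + 1L + l)
      c1 <- matrix(coeffs[s1, , l + 1L, mcols], nrow = nmax)
      c2 <- matrix(coeffs[s2, , l + 1L, mcols], nrow = nmax)
      P <- pi * sqrt(8 / (2 * l + 1)) * tcrossprod(c1, c2)
      vals <- if (same) P[triIdx] else as.numeric(t(P))
      out[pos + seq_along(vals)] <- vals
      pos <- pos + length(vals)
    }
  }
  out
}

# ---- user-facing featurization ---------------------------------------------

#' Compute SOAP descriptors for atomic centers
#'
#' Deterministic, and invariant under global rotation and translation of a
#' structure and under reordering of atoms within a species.
#'
#' @param structures A \linkS4class{MolecularStructure} or a list of them.
#' @param config A \linkS4class{SoapConfig}.
#' @param centers Which atoms to expand around: \code{"all"} (default),
#'   \code{"hydrogen"} (all H atoms, the centers used for shift features),
#'   \code{"zinc"}, or a list of 0-based integer vectors, one per structure.
#' @return A \linkS4class{SoapDescriptors}.
#' @examples
#' s <- MolecularStructure("m", c("Zn", "H"), rbind(c(0, 0, 0), c(0, 0, 1.9)))
#' cfg <- soapConfig(c("H", "Zn"), rCut = 4, nMax = 2L, lMax = 2L,
#'                   sigmaAtom = 0.5)
#' computeSoap(s, cfg, centers = "hydrogen")
#' @export
computeSoap <- function(structures, config, centers = "all") {
  if (is(structures, "MolecularStructure")) structures <- list(structures)
  setup <- .radialSetup(config)
  pickCenters <- function(s, i) {
    if (is.list(centers)) return(as.integer(centers[[i]]))
    switch(centers,
      all = seq_along(s@elements) - 1L,
      hydrogen = which(s@elements == "H") - 1L,
      zinc = which(s@elements == "Zn") - 1L,
      stop("centers must be 'all', 'hydrogen', 'zinc' or a list of index vectors"))
  }
  valrows <- list(); inforows <- list()
  for (i in seq_along(structures)) {
    s <- structures[[i]]
    ctr <- pickCenters(s, i)
    if (any(ctr < 0L | ctr >= length(s@elements)))
      stop("center index out of range for molecule ", s@moleculeId)
    for (ci in ctr) {
      co <- densityCoefficients(s, ci, config, setup)
      valrows[[length(valrows) + 1L]] <- powerSpectrum(co, config)
      inforows[[length(inforows) + 1L]] <- data.frame(
        moleculeId = s@moleculeId, atomIndex = ci,
        element = s@elements[ci + 1L], stringsAsFactors = FALSE)
    }
  }
  vals <- if (length(valrows)) do.call(rbind, valrows)
          else matrix(0, 0L, descriptorLength(config))
  info <- if (length(inforows)) do.call(rbind, inforows)
          else data.frame(moleculeId = character(0), atomIndex = integer(0),
                          element = character(0))
  rownames(info) <- NULL
  new("SoapDescriptors", values = vals, layout = soapLayout(config),
      config = config, centerInfo = info)
}

#' Pool atomic descriptors into one molecule-level vector
#'
#' The embedding clustered by \code{\link{kmeansFit}} when selecting
#' representative complexes.  Mean pooling over all atoms is the default;
#' \code{"zinc"} uses the descriptor of the zinc center alone.
#'
#' @param structure A \linkS4class{MolecularStructure}.
#' @param config A \linkS4class{SoapConfig}.
#' @param pooling \code{"mean"} (default) or \code{"zinc"}.
#' @return Numeric vector of length \code{\link{descriptorLength}(config)}.
#' @export
moleculeDescriptor <- function(structure, config,
                               pooling = c("mean", "zinc")) {
  pooling <- match.arg(pooling)
  d <- computeSoap(structure, config,
                   centers = if (pooling == "mean") "all" else "zinc")
  if (nrow(d@values) == 0L)
    stop("no centers found for pooling '", pooling, "' in molecule ",
         structure@moleculeId)
  colMeans(d@values)
}
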