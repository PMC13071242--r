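# Shared test helpers: tiny structures, rotations, and a fast SOAP config.

# A small Zn complex with known geometry: Zn at origin, two H, one C.
tinyComplex <- function(id = "tiny") {
  MolecularStructure(
    id, c("Zn", "H", "H", "C"),
    rbind(c(0, 0, 0), c(0, 0, 1.9), c(1.8, 0.3, -0.5), c(-1.2, 2.0, 0.4)),
    totalCharge = 0L)
}

# Deterministic random rotation matrix (QR of a Gaussian matrix, det +1).
randomRotation <- function(seed) {
  m <- SoapShift:::.withSeed(seed, matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

applyRotation <- function(structure, R) {
  MolecularStructure(structure@moleculeId, structure@elements,
                     structure@coordinates %*% t(R), structure@totalCharge)
}

applyTranslation <- function(structure, shift) {
  MolecularStructure(structure@moleculeId, structure@elements,
                     sweep(structure@coordinates, 2L, shift, `+`),
                     structure@totalCharge)
}

permuteAtoms <- function(structure, perm) {
  MolecularStructure(structure@moleculeId, structure@elements[perm],
                     structure@coordinates[perm, , drop = FALSE],
                     structure@totalCharge)
}

# Small, fast config used throughout the module tests.
fastConfig <- function(species = c("H", "C", "Zn")) {
  soapConfig(species, rCut = 4, nMax = 3L, lMax = 3L, sigmaAtom = 0.5,
             cutoffWidth = 0.5)
}

# Max elementwise relative deviation with an absolute floor on the
# denominator, so zero-entries compare on an absolute scale.
maxRelDev <- function(a, b, floor = 1e-10) {
  max(abs(a - b) / pmax(abs(b), floor))
}
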