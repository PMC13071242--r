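#' @import methods
NULL

# Element symbols in atomic-number order; index == Z.  Covers H..Rn, which is
# far more than any zinc-complex dataset needs but keeps XYZ validation strict.
.PERIODIC_TABLE <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

#' Atomic numbers for element symbols
#'
#' @param symbols Character vector of element symbols (case-sensitive,
#'   e.g. \code{"Zn"}).
#' @return Integer vector of atomic numbers.
#' @examples
#' atomicNumber(c("H", "C", "Zn"))
#' @export
atomicNumber <- function(symbols) {
  z <- match(symbols, .PERIODIC_TABLE)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(z)]), collapse = ", "))
  }
  z
}

#' MolecularStructure: one molecule's elements and Cartesian coordinates
#'
#' The geometric substrate for SOAP descriptors: an ordered list of element
#' symbols with matching Cartesian coordinates in Angstrom.  Atom indexing is
#' 0-based everywhere in this package (the convention of the upstream XYZ and
#' shift-table formats) and stable across all operations.
#'
#' @slot moleculeId Character scalar identifying the molecule.
#' @slot elements Character vector of element symbols, one per atom.
#' @slot coordinates Numeric matrix with one row per atom and columns x, y, z
#'   in Angstrom.
#' @slot totalCharge Integer scalar, the total charge of the complex
#'   (default 0; used by \code{\link{filterNeutralZinc}}).
#' @seealso \code{\link{readXYZ}}, \code{\link{makeToyComplexes}}
#' @export
setClass("MolecularStructure",
  representation(
    moleculeId = "character",
    elements = "character",
    coordinates = "matrix",
    totalCharge = "integer"
  ),
  prototype(totalCharge = 0L)
)

setValidity("MolecularStructure", function(object) {
  msg <- character(0)
  n <- length(object@elements)
  if (n < 1L) msg <- c(msg, "structure must contain at least one atom")
  if (!is.numeric(object@coordinates) || ncol(object@coordinates) != 3L)
    msg <- c(msg, "coordinates must be a numeric matrix with 3 columns")
  else if (nrow(object@coordinates) != n)
    msg <- c(msg, "elements and coordinates disagree in atom count")
  else if (!all(is.finite(object@coordinates)))
    msg <- c(msg, "coordinates must all be finite")
  bad <- !(object@elements %in% .PERIODIC_TABLE)
  if (any(bad))
    msg <- c(msg, paste0("unknown element symbol(s): ",
                         paste(unique(object@elements[bad]), collapse = ", ")))
  if (length(object@moleculeId) != 1L || is.na(object@moleculeId))
    msg <- c(msg, "moleculeId must be a single non-NA string")
  if (length(object@totalCharge) != 1L || is.na(object@totalCharge))
    msg <- c(msg, "totalCharge must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a MolecularStructure
#'
#' @param moleculeId Character scalar id.
#' @param elements Character vector of element symbols.
#' @param coordinates Numeric matrix (n x 3) of Cartesian coordinates in
#'   Angstrom.
#' @param totalCharge Integer total charge (default 0).
#' @return A \linkS4class{MolecularStructure}.
#' @examples
#' MolecularStructure("zn0", c("Zn", "H"), rbind(c(0, 0, 0), c(0, 0, 1.9)))
#' @export
MolecularStructure <- function(moleculeId, elements, coordinates,
                               totalCharge = 0L) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  dimnames(coordinates) <- NULL
  new("MolecularStructure", moleculeId = as.character(moleculeId),
      elements = as.character(elements), coordinates = coordinates,
      totalCharge = as.integer(totalCharge))
}

#' @describeIn MolecularStructure-class Number of atoms.
#' @param x,object A \code{MolecularStructure}.
#' @export
setMethod("length", "MolecularStructure", function(x) length(x@elements))

#' @noRd
#' @export
setMethod("show", "MolecularStructure", function(object) {
  comp <- table(object@elements)
  cat("MolecularStructure ", object@moleculeId, ": ", length(object@elements),
      " atoms (", paste0(names(comp), comp, collapse = " "), "), charge ",
      object@totalCharge, "\n", sep = "")
})

#' SoapConfig: hyperparameters of the SOAP power-spectrum descriptor
#'
#' @slot rCut Radial cutoff in Angstrom.
#' @slot nMax Number of radial basis functions.
#' @slot lMax Maximum angular momentum of the spherical-harmonic expansion.
#' @slot sigmaAtom Gaussian smearing width of the atomic density, Angstrom.
#' @slot species Ordered (by atomic number) element symbols spanned by the
#'   descriptor; every molecule featurized under one config shares this list
#'   so all descriptors live in one feature space.
#' @slot rbf Radial basis family: \code{"gto"} (spherical primitive Gaussians,
#'   Lowdin-orthonormalized; the convention of the reference descriptor
#'   library) or \code{"polynomial"}.
#' @slot cutoffWidth Width in Angstrom of the cosine taper applied to each
#'   neighbor's density amplitude over the final \code{cutoffWidth} Angstrom
#'   before \code{rCut}; 0 reproduces the reference library's hard neighbor
#'   truncation.
#' @seealso \code{\link{soapConfig}}, \code{\link{computeSoap}}
#' @export
setClass("SoapConfig",
  representation(
    rCut = "numeric", nMax = "integer", lMax = "integer",
    sigmaAtom = "numeric", species = "character", rbf = "character",
    cutoffWidth = "numeric"
  )
)

setValidity("SoapConfig", function(object) {
  msg <- character(0)
  if (object@rCut <= 0) msg <- c(msg, "rCut must be > 0")
  if (object@nMax < 1L) msg <- c(msg, "nMax must be >= 1")
  if (object@lMax < 0L) msg <- c(msg, "lMax must be >= 0")
  if (object@sigmaAtom <= 0) msg <- c(msg, "sigmaAtom must be > 0")
  if (length(object@species) < 1L) msg <- c(msg, "species must be non-empty")
  if (anyDuplicated(object@species)) msg <- c(msg, "species must be unique")
  z <- match(object@species, .PERIODIC_TABLE)
  if (anyNA(z)) msg <- c(msg, "species contains unknown element symbols")
  else if (is.unsorted(z)) msg <- c(msg, "species must be sorted by atomic number")
  if (!object@rbf %in% c("gto", "polynomial"))
    msg <- c(msg, "rbf must be 'gto' or 'polynomial'")
  if (object@cutoffWidth < 0 || object@cutoffWidth >= object@rCut)
    msg <- c(msg, "cutoffWidth must be in [0, rCut)")
  if (length(msg)) msg else TRUE
})

#' Construct a SoapConfig
#'
#' Defaults follow the descriptor settings used throughout the package for
#' zinc complexes: 6 Angstrom cutoff, 8 radial basis functions, angular
#' expansion to order 6, 1.0 Angstrom smearing.  \code{species} is sorted by
#' atomic number automatically so the feature layout is reproducible.
#'
#' @param species Character vector of element symbols the descriptor spans.
#' @param rCut Radial cutoff, Angstrom (default 6).
#' @param nMax Radial basis size (default 8).
#' @param lMax Angular momentum cutoff (default 6).
#' @param sigmaAtom Density smearing width, Angstrom (default 1.0).
#' @param rbf \code{"gto"} (default) or \code{"polynomial"}.
#' @param cutoffWidth Cosine-taper width at the cutoff, Angstrom
#'   (default 0.5; 0 = hard truncation, the reference-library convention).
#' @return A \linkS4class{SoapConfig}.
#' @examples
#' cfg <- soapConfig(c("H", "C", "N", "O", "Zn"))
#' descriptorLength(cfg)
#' @export
soapConfig <- function(species, rCut = 6, nMax = 8L, lMax = 6L,
                       sigmaAtom = 1.0, rbf = c("gto", "polynomial"),
                       cutoffWidth = 0.5) {
  rbf <- match.arg(rbf)
  species <- unique(as.character(species))
  species <- species[order(match(species, .PERIODIC_TABLE))]
  new("SoapConfig", rCut = rCut, nMax = as.integer(nMax),
      lMax = as.integer(lMax), sigmaAtom = sigmaAtom, species = species,
      rbf = rbf, cutoffWidth = cutoffWidth)
}

#' @noRd
#' @export
setMethod("show", "SoapConfig", function(object) {
  cat("SoapConfig: rCut ", object@rCut, " A, nMax ", object@nMax, ", lMax ",
      object@lMax, ", sigma ", object@sigmaAtom, " A, rbf ", object@rbf,
      ", taper ", object@cutoffWidth, " A\n  species: ",
      paste(object@species, collapse = " "), " -> ",
      descriptorLength(object), " features\n", sep = "")
})

#' SoapDescriptors: a matrix of per-center SOAP power spectra
#'
#' @slot values Numeric matrix, one row per center, one column per
#'   power-spectrum entry.
#' @slot layout \code{data.frame} describing each column: species pair
#'   (\code{z1}, \code{z2}), radial indices (\code{n1}, \code{n2}, 1-based)
#'   and angular momentum \code{l}.
#' @slot config The \linkS4class{SoapConfig} used.
#' @slot centerInfo \code{data.frame} with \code{moleculeId},
#'   \code{atomIndex} (0-based) and \code{element} per row of \code{values}.
#' @export
setClass("SoapDescriptors",
  representation(
    values = "matrix", layout = "data.frame", config = "SoapConfig",
    centerInfo = "data.frame"
  )
)

setValidity("SoapDescriptors", function(object) {
  msg <- character(0)
  if (ncol(object@values) != nrow(object@layout))
    msg <- c(msg, "values columns and layout rows disagree")
  if (nrow(object@values) != nrow(object@centerInfo))
    msg <- c(msg, "values rows and centerInfo rows disagree")
  if (length(msg)) msg else TRUE
})

#' @noRd
#' @export
setMethod("show", "SoapDescriptors", function(object) {
  cat("SoapDescriptors: ", nrow(object@values), " centers x ",
      ncol(object@values), " features (",
      length(unique(object@centerInfo$moleculeId)), " molecules)\n", sep = "")
})

#' @describeIn SoapDescriptors-class The descriptor matrix.
#' @param object A \code{SoapDescriptors}.
#' @export
setGeneric("descriptorValues", function(object) standardGeneric("descriptorValues"))

#' @rdname SoapDescriptors-class
#' @export
setMethod("descriptorValues", "SoapDescriptors", function(object) object@values)

#' @describeIn SoapDescriptors-class Per-center metadata.
#' @export
setGeneric("centerInfo", function(object) standardGeneric("centerInfo"))

#' @rdname SoapDescriptors-class
#' @export
setMethod("centerInfo", "SoapDescriptors", function(object) object@centerInfo)

#' FeatureSet: assembled design matrix for shift regression
#'
#' Rows are hydrogen-in-solvent records; columns are the SOAP descriptor
#' entries followed by a single dielectric-constant column \code{epsilon}.
#'
#' @slot X Numeric design matrix.
#' @slot y Numeric vector of chemical shifts, ppm (NA where unknown).
#' @slot groups Character vector, \code{moleculeId} per row; the unit of the
#'   leakage-free split.
#' @slot rowInfo \code{data.frame} with \code{moleculeId}, \code{atomIndex},
#'   \code{solvent}, \code{epsilon} per row.
#' @export
setClass("FeatureSet",
  representation(X = "matrix", y = "numeric", groups = "character",
                 rowInfo = "data.frame")
)

setValidity("FeatureSet", function(object) {
  msg <- character(0)
  n <- nrow(object@X)
  if (length(object@y) != n) msg <- c(msg, "y length must equal rows of X")
  if (length(object@groups) != n) msg <- c(msg, "groups length must equal rows of X")
  if (nrow(object@rowInfo) != n) msg <- c(msg, "rowInfo rows must equal rows of X")
  if (length(msg)) msg else TRUE
})

#' @noRd
#' @export
setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet: ", nrow(object@X), " records x ", ncol(object@X),
      " features (", length(unique(object@groups)), " molecules, ",
      length(unique(object@rowInfo$solvent)), " solvents)\n", sep = "")
})

#' @describeIn FeatureSet-class Number of records (rows).
#' @param x,object A \code{FeatureSet}.
#' @export
setMethod("nrow", "FeatureSet", function(x) base::nrow(x@X))

#' SplitPlan: molecule-level train/test partition
#'
#' Every record of a molecule (all H atoms, all solvents) falls on exactly one
#' side, which is the leakage guarantee of the molecule-level split.
#'
#' @slot trainMolecules,testMolecules Disjoint, exhaustive molecule-id sets.
#' @slot trainRows,testRows 1-based row indices into the originating
#'   \linkS4class{FeatureSet}.
#' @slot seed Integer seed the shuffle was derived from.
#' @slot testFraction Target test proportion of molecules.
#' @export
setClass("SplitPlan",
  representation(
    trainMolecules = "character", testMolecules = "character",
    trainRows = "integer", testRows = "integer",
    seed = "integer", testFraction = "numeric"
  )
)

setValidity("SplitPlan", function(object) {
  msg <- character(0)
  if (length(intersect(object@trainMolecules, object@testMolecules)))
    msg <- c(msg, "train and test molecule sets overlap")
  if (length(intersect(object@trainRows, object@testRows)))
    msg <- c(msg, "train and test rows overlap")
  if (length(msg)) msg else TRUE
})

#' @noRd
#' @export
setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan: ", length(object@trainMolecules), " train / ",
      length(object@testMolecules), " test molecules (",
      length(object@trainRows), " / ", length(object@testRows),
      " records), seed ", object@seed, "\n", sep = "")
})

#' ClusterModel: a fitted k-means partition of descriptor space
#'
#' @slot k Number of clusters.
#' @slot centroids Numeric matrix, k rows.
#' @slot labels Integer cluster id per row of the clustered matrix,
#'   in \code{[0, k)}.
#' @slot inertia Total within-cluster sum of squared distances.
#' @slot seed Integer seed.
#' @export
setClass("ClusterModel",
  representation(k = "integer", centroids = "matrix", labels = "integer",
                 inertia = "numeric", seed = "integer")
)

setValidity("ClusterModel", function(object) {
  msg <- character(0)
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroids must have k rows")
  if (any(object@labels < 0L | object@labels >= object@k))
    msg <- c(msg, "labels must lie in [0, k)")
  if (length(unique(object@labels)) != object@k)
    msg <- c(msg, "every cluster must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @noRd
#' @export
setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel: k = ", object@k, ", sizes ",
      paste(tabulate(object@labels + 1L, object@k), collapse = "/"),
      ", inertia ", signif(object@inertia, 6), "\n", sep = "")
})

#' @describeIn ClusterModel-class Cluster labels (0-based).
#' @param object A \code{ClusterModel}.
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname ClusterModel-class
#' @export
setMethod("clusterLabels", "ClusterModel", function(object) object@labels)

#' ShiftModel: a tuned, fitted shift-regression backend
#'
#' @slot modelName Registry name of the backend.
#' @slot fit The fitted backend object.
#' @slot bestParams Chosen hyperparameters (named list).
#' @slot cvMae Mean cross-validation MAE of the chosen parameters, ppm.
#' @slot standardize Logical: were columns standardized (kernel-family
#'   backends)?
#' @slot center,scale Column standardization parameters (empty when
#'   \code{standardize} is FALSE).
#' @slot config \linkS4class{SoapConfig} the training features were built
#'   with (used by \code{\link{predictShifts}}).
#' @slot seed Integer seed.
#' @export
setClass("ShiftModel",
  representation(
    modelName = "character", fit = "ANY", bestParams = "list",
    cvMae = "numeric", standardize = "logical",
    center = "numeric", scale = "numeric", config = "SoapConfig",
    seed = "integer"
  )
)

#' @noRd
#' @export
setMethod("show", "ShiftModel", function(object) {
  cat("ShiftModel <", object@modelName, ">: CV MAE ",
      signif(object@cvMae, 4), " ppm; params: ",
      paste(names(object@bestParams),
            vapply(object@bestParams, format, ""), sep = "=", collapse = ", "),
      "\n", sep = "")
})
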