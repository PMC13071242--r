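#' Read a (multi-frame) XYZ file
#'
#' Parses standard XYZ: an atom-count line, a comment line, then one
#' \code{element x y z} line per atom; frames may be concatenated.  Element
#' symbols are required (atomic numbers are not accepted); columns after
#' x, y, z are ignored.  The molecule id is taken from an \code{id=<token>}
#' entry on the comment line when present, otherwise \code{frame_<k>}
#' (0-based).  A \code{charge=<int>} token on the comment line sets
#' \code{totalCharge}.
#'
#' @param path Path to the XYZ file.
#' @return A list of \linkS4class{MolecularStructure}, in file order.
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("1", "id=zn0", "Zn 0 0 0"), f)
#' readXYZ(f)
#' @seealso \code{\link{writeXYZ}}
#' @export
readXYZ <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  out <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L)
      stop("line ", i, ": expected a positive atom count, got '", lines[i], "'")
    if (i + 1L + nat > length(lines))
      stop("line ", i, ": frame declares ", nat,
           " atoms but the file ends after ",
           length(lines) - i - 1L, " atom line(s)")
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + nat)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    elements <- character(nat)
    coords <- matrix(NA_real_, nat, 3L)
    for (a in seq_len(nat)) {
      tk <- toks[[a]]
      if (length(tk) < 4L)
        stop("line ", i + 1L + a, ": expected 'element x y z', got '",
             body[a], "'")
      if (!tk[1] %in% .PERIODIC_TABLE)
        stop("line ", i + 1L + a, ": '", tk[1],
             "' is not an element symbol")
      xyz <- suppressWarnings(as.numeric(tk[2:4]))
      if (anyNA(xyz))
        stop("line ", i + 1L + a, ": non-numeric coordinate in '",
             body[a], "'")
      elements[a] <- tk[1]
      coords[a, ] <- xyz
    }
    id <- .commentToken(comment, "id")
    if (is.na(id)) id <- paste0("frame_", k)
    charge <- .commentToken(comment, "charge")
    charge <- if (is.na(charge)) 0L else as.integer(charge)
    out[[length(out) + 1L]] <-
      MolecularStructure(id, elements, coords, charge)
    i <- i + 2L + nat
    k <- k + 1L
  }
  out
}

.commentToken <- function(comment, key) {
  m <- regmatches(comment,
                  regexpr(paste0(key, "=[^[:space:]]+"), comment))
  if (length(m)) sub(paste0(key, "="), "", m) else NA_character_
}

#' Write structures to a (multi-frame) XYZ file
#'
#' The comment line carries \code{id=} and \code{charge=} tokens so
#' \code{\link{readXYZ}} round-trips ids and charges.  Coordinates are
#' printed with 10 decimal places.
#'
#' @param structures A \linkS4class{MolecularStructure} or list of them.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeXYZ <- function(structures, path) {
  if (is(structures, "MolecularStructure")) structures <- list(structures)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in structures) {
    writeLines(as.character(length(s@elements)), con)
    writeLines(sprintf("id=%s charge=%d", s@moleculeId, s@totalCharge), con)
    writeLines(sprintf("%s %.10f %.10f %.10f", s@elements,
                       s@coordinates[, 1], s@coordinates[, 2],
                       s@coordinates[, 3]), con)
  }
  invisible(path)
}

# ---- solvent registry -------------------------------------------------------

.registryEnv <- new.env(parent = emptyenv())

.defaultRegistry <- function() {
  if (is.null(.registryEnv$registry)) {
    path <- system.file("extdata", "solvents.json", package = "SoapShift")
    .registryEnv$registry <- .parseRegistry(jsonlite::fromJSON(path,
                                            simplifyDataFrame = FALSE))
  }
  .registryEnv$registry
}

.parseRegistry <- function(entries) {
  names <- vapply(entries, `[[`, "", "name")
  eps <- vapply(entries, `[[`, 0, "epsilon")
  if (any(eps <= 1)) stop("solvent registry: epsilon must be > 1")
  aliases <- lapply(entries, function(e) as.character(e$aliases))
  alias_tab <- data.frame(
    alias = tolower(c(names, unlist(aliases))),
    canonical = c(names, rep(names, lengths(aliases))),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(alias_tab$alias))
    stop("solvent registry: duplicate (case-insensitive) name or alias")
  list(names = names, epsilon = stats::setNames(eps, names),
       aliases = alias_tab)
}

#' The solvent registry
#'
#' Returns the packaged registry of solvents and their static dielectric
#' constants (the sole solvent feature of the shift model), optionally
#' extended with user entries.  Deuterated aliases (DMSO-d6, CDCl3,
#' MeOH-d4, ACN-d3, D2O, ...) resolve to the same epsilon as the protiated
#' solvent.
#'
#' @param extra Optional list of entries, each a list with \code{name},
#'   \code{epsilon} and optional \code{aliases}, appended to the packaged
#'   registry.
#' @return A registry object (list with \code{names}, \code{epsilon},
#'   \code{aliases}) accepted by \code{\link{lookupSolvent}}.
#' @examples
#' reg <- solventRegistry()
#' reg$epsilon["DMSO"]
#' @export
solventRegistry <- function(extra = NULL) {
  reg <- .defaultRegistry()
  if (is.null(extra)) return(reg)
  path <- system.file("extdata", "solvents.json", package = "SoapShift")
  .parseRegistry(c(jsonlite::fromJSON(path, simplifyDataFrame = FALSE), extra))
}

#' Look up a solvent's dielectric constant
#'
#' Case-insensitive lookup by canonical name or registered alias.
#'
#' @param name Solvent name, e.g. \code{"DMSO"} or \code{"dmso-d6"}.
#' @param registry A registry from \code{\link{solventRegistry}}.
#' @return A list with \code{name} (canonical) and \code{epsilon}.
#' @examples
#' lookupSolvent("THF")$epsilon     # 7.6
#' lookupSolvent("acetonitrile")$epsilon  # 37.5
#' @export
lookupSolvent <- function(name, registry = solventRegistry()) {
  stopifnot(length(name) == 1L)
  hit <- match(tolower(name), registry$aliases$alias)
  if (is.na(hit)) {
    stop("unknown solvent '", name, "'; registered solvents: ",
         paste(registry$names, collapse = ", "))
  }
  canonical <- registry$aliases$canonical[hit]
  list(name = canonical, epsilon = unname(registry$epsilon[canonical]))
}

# ---- shift tables -----------------------------------------------------------

#' Load a table of shielding/shift records
#'
#' Reads a delimited text table (comma by default, tab auto-detected) with
#' header columns \code{molecule_id}, \code{atom_index} (0-based),
#' \code{solvent} and at least one of \code{sigma_ppm} (isotropic shielding)
#' or \code{delta_ppm} (chemical shift).  Every row is validated against the
#' supplied structures: the atom index must address a hydrogen atom, and the
#' solvent must resolve in the registry.
#'
#' @param path Path to the CSV/TSV file.
#' @param structures List of \linkS4class{MolecularStructure} the records
#'   refer to.
#' @param registry Solvent registry (see \code{\link{solventRegistry}}).
#' @return A \code{data.frame} with columns \code{moleculeId},
#'   \code{atomIndex}, \code{solvent} (canonical), \code{epsilon},
#'   \code{sigmaPpm}, \code{deltaPpm}.
#' @seealso \code{\link{writeShiftTable}}, \code{\link{shieldingToShift}}
#' @export
loadShiftTable <- function(path, structures, registry = solventRegistry()) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("molecule_id", "atom_index", "solvent")
  if (!all(need %in% names(tab)))
    stop("shift table must have header columns: ",
         paste(need, collapse = ", "))
  has_sigma <- "sigma_ppm" %in% names(tab)
  has_delta <- "delta_ppm" %in% names(tab)
  if (!has_sigma && !has_delta)
    stop("shift table needs a sigma_ppm and/or delta_ppm column")
  ids <- vapply(structures, function(s) s@moleculeId, "")
  out <- data.frame(
    moleculeId = as.character(tab$molecule_id),
    atomIndex = as.integer(tab$atom_index),
    solvent = rep(NA_character_, nrow(tab)),
    epsilon = rep(NA_real_, nrow(tab)),
    sigmaPpm = if (has_sigma) as.numeric(tab$sigma_ppm)
               else rep(NA_real_, nrow(tab)),
    deltaPpm = if (has_delta) as.numeric(tab$delta_ppm)
               else rep(NA_real_, nrow(tab)),
    stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(out))) {
    rowlab <- paste0("shift table row ", r, ": ")
    si <- match(out$moleculeId[r], ids)
    if (is.na(si))
      stop(rowlab, "unknown molecule_id '", out$moleculeId[r], "'")
    s <- structures[[si]]
    ai <- out$atomIndex[r]
    if (is.na(ai) || ai < 0L || ai >= length(s@elements))
      stop(rowlab, "atom_index ", ai, " out of range for molecule '",
           out$moleculeId[r], "' (", length(s@elements), " atoms)")
    if (s@elements[ai + 1L] != "H")
      stop(rowlab, "atom_index ", ai, " of '", out$moleculeId[r],
           "' is ", s@elements[ai + 1L], ", not H")
    sol <- tryCatch(lookupSolvent(tab$solvent[r], registry),
                    error = function(e) stop(rowlab, conditionMessage(e),
                                             call. = FALSE))
    out$solvent[r] <- sol$name
    out$epsilon[r] <- sol$epsilon
    if (is.na(out$sigmaPpm[r]) && is.na(out$deltaPpm[r]))
      stop(rowlab, "both sigma_ppm and delta_ppm are missing")
  }
  out
}

#' Write a shift table in the package CSV dialect
#'
#' @param records A \code{data.frame} as returned by
#'   \code{\link{loadShiftTable}} (columns \code{moleculeId},
#'   \code{atomIndex}, \code{solvent} and \code{sigmaPpm}/\code{deltaPpm}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeShiftTable <- function(records, path) {
  tab <- data.frame(
    molecule_id = records$moleculeId,
    atom_index = records$atomIndex,
    solvent = records$solvent,
    sigma_ppm = if ("sigmaPpm" %in% names(records)) records$sigmaPpm else NA,
    delta_ppm = if ("deltaPpm" %in% names(records)) records$deltaPpm else NA
  )
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter for neutral zinc complexes
#'
#' The training-set criterion applied to the upstream database: a complex is
#' kept when its declared total charge is zero and it contains at least one
#' zinc atom.  Charge is metadata supplied with the structures; it is never
#' inferred from geometry.
#'
#' @param structures List of \linkS4class{MolecularStructure}.
#' @return The sublist of neutral Zn-containing structures.
#' @export
filterNeutralZinc <- function(structures) {
  keep <- vapply(structures, function(s) {
    s@totalCharge == 0L && "Zn" %in% s@elements
  }, NA)
  structures[keep]
}
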