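## PDB fixed-column reading/writing, atom selections and radius assignment.
##
## The reader resolves alternate locations to the highest-occupancy record
## (ties -> first encountered), drops HETATM and waters by default, and
## verifies identical topology across MODEL blocks when an ensemble is
## requested.  The writer emits standard fixed-width ATOM records and
## guarantees 0.001 A round-trip fidelity.

WATER_RESIDUES <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "DOD")

#' Construct a Structure
#'
#' Low-level constructor from an identity table and coordinate matrix.
#' Missing optional columns (`insert`, `alt`, `element`, `radius`) are
#' filled with defaults.
#'
#' @param atoms data.frame with at least `serial`, `name`, `resid`,
#'   `chain`, `resno`.
#' @param xyz numeric n x 3 matrix, Angstrom.
#' @param modelId integer model number.
#' @return a [Structure].
#' @export
Structure <- function(atoms, xyz, modelId = 1L) {
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$element))
    atoms$element <- .inferElement(atoms$name)
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  atoms <- atoms[REQUIRED_ATOM_COLS]
  rownames(atoms) <- NULL
  xyz <- as.matrix(xyz)
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  new("Structure", atoms = atoms, xyz = xyz, modelId = as.integer(modelId))
}

## Element from atom name when the element column is blank: strip digits
## and primes, take the first character (sufficient for the standard
## C/N/O/S/H organic set this pipeline handles).
.inferElement <- function(name) {
  e <- gsub("[0-9']", "", trimws(name))
  toupper(substr(e, 1L, 1L))
}

#' Read a PDB file
#'
#' Parses ATOM records from fixed-column PDB text.  With
#' `modelPolicy = "first"` the first MODEL (or the sole implicit model)
#' is returned as a [Structure]; with `"all"`, MODEL/ENDMDL blocks become
#' the frames of an [Ensemble] and topology identity across models is
#' verified.  Alternate locations are resolved to the highest-occupancy
#' record (ties broken by file order); HETATM records and waters are
#' excluded unless requested.
#'
#' @param source file path, connection, or character vector of PDB lines.
#' @param modelPolicy `"first"` or `"all"`.
#' @param includeHet keep HETATM records (waters still filtered unless
#'   `keepWaters`).
#' @param keepWaters keep water residues.
#' @param trajectoryId trajectory label for the returned [Ensemble].
#' @return a [Structure] or an [Ensemble].
#' @examples
#' lines <- c(
#'   "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
#'   "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C")
#' s <- readPdb(lines)
#' nAtoms(s)
#' @export
readPdb <- function(source, modelPolicy = c("first", "all"),
                    includeHet = FALSE, keepWaters = FALSE,
                    trajectoryId = "ensemble") {
  modelPolicy <- match.arg(modelPolicy)
  lines <- if (is.character(source) && length(source) == 1L &&
               !grepl("\n", source) && file.exists(source))
    readLines(source, warn = FALSE)
  else if (inherits(source, "connection"))
    readLines(source, warn = FALSE)
  else as.character(source)

  rec <- substr(lines, 1L, 6L)
  isAtom <- startsWith(rec, "ATOM")
  isHet <- startsWith(rec, "HETATM")
  isModel <- startsWith(rec, "MODEL")
  isEnd <- startsWith(rec, "ENDMDL")
  take <- isAtom | (includeHet & isHet)
  if (!any(isAtom)) stop("PDB parse error: no ATOM records found")

  ## assign a model index to every line
  modelIdx <- cumsum(isModel)
  modelIdx[modelIdx == 0L] <- 1L
  ## lines after ENDMDL but before next MODEL belong to no model; drop them
  inBlock <- rep(TRUE, length(lines))
  if (any(isModel)) {
    closed <- cumsum(isEnd)
    opened <- cumsum(isModel)
    inBlock <- opened > closed | isModel
  }
  take <- take & inBlock

  idx <- which(take)
  if (length(idx) == 0L) stop("PDB parse error: no coordinate records retained")
  ln <- lines[idx]

  fx <- function(from, to) substr(ln, from, to)
  xs <- suppressWarnings(as.numeric(fx(31L, 38L)))
  ys <- suppressWarnings(as.numeric(fx(39L, 46L)))
  zs <- suppressWarnings(as.numeric(fx(47L, 54L)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs))
  if (length(bad) > 0L)
    stop(sprintf("PDB parse error: malformed coordinate field at line %d",
                 idx[bad[1L]]))
  occ <- suppressWarnings(as.numeric(fx(55L, 60L)))
  occ[is.na(occ)] <- 1.0

  atoms <- data.frame(
    serial = suppressWarnings(as.integer(fx(7L, 11L))),
    name = trimws(fx(13L, 16L)),
    resid = trimws(fx(18L, 20L)),
    chain = trimws(fx(22L, 22L)),
    resno = suppressWarnings(as.integer(fx(23L, 26L))),
    insert = trimws(fx(27L, 27L)),
    alt = trimws(fx(17L, 17L)),
    element = trimws(fx(77L, 78L)),
    radius = NA_real_,
    stringsAsFactors = FALSE)
  badNo <- which(is.na(atoms$resno))
  if (length(badNo) > 0L)
    stop(sprintf("PDB parse error: malformed residue number at line %d",
                 idx[badNo[1L]]))
  if (anyNA(atoms$serial)) atoms$serial[is.na(atoms$serial)] <- 0L
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- .inferElement(atoms$name[blank])

  if (!keepWaters) {
    w <- atoms$resid %in% WATER_RESIDUES
    atoms <- atoms[!w, , drop = FALSE]
    xs <- xs[!w]; ys <- ys[!w]; zs <- zs[!w]; occ <- occ[!w]
    idx <- idx[!w]
    if (nrow(atoms) == 0L) stop("PDB parse error: only water records present")
  }
  mod <- modelIdx[idx]

  buildStructure <- function(rows, modelId) {
    a <- atoms[rows, , drop = FALSE]
    xyz <- cbind(xs[rows], ys[rows], zs[rows])
    o <- occ[rows]
    ## alt-loc resolution: highest occupancy, ties -> first encountered
    key <- paste(a$chain, a$resno, a$insert, a$name, sep = "\r")
    ord <- order(match(key, unique(key)), -o, seq_along(o))
    keep <- ord[!duplicated(key[ord])]
    keep <- sort(keep)
    a <- a[keep, , drop = FALSE]
    xyz <- xyz[keep, , drop = FALSE]
    a$alt[nzchar(a$alt)] <- a$alt[nzchar(a$alt)]  # preserved as read
    Structure(a, xyz, modelId = modelId)
  }

  models <- unique(mod)
  if (modelPolicy == "first") {
    return(buildStructure(which(mod == models[1L]), modelId = 1L))
  }
  frames <- lapply(seq_along(models), function(k)
    buildStructure(which(mod == models[k]), modelId = k))
  key0 <- .identityKey(frames[[1L]]@atoms)
  for (k in seq_along(frames)[-1L]) {
    if (length(.identityKey(frames[[k]]@atoms)) != length(key0) ||
        !identical(.identityKey(frames[[k]]@atoms), key0))
      stop(sprintf("PDB topology error: model %d atom identities differ from model 1", k))
  }
  new("Ensemble", frames = frames, trajectoryId = trajectoryId,
      frameTimes = rep(NA_real_, length(frames)))
}

## PDB atom-name column convention: names of 1-3 characters start in
## column 14; 4-character names start in column 13.
.formatAtomName <- function(name) {
  ifelse(nchar(name) >= 4L, substr(name, 1L, 4L),
         sprintf(" %-3s", name))
}

.structureLines <- function(s) {
  a <- s@atoms
  if (any(nchar(a$chain) > 1L))
    stop("PDB format error: chain identifiers longer than one character")
  if (any(abs(s@xyz) >= 10000) || any(s@xyz <= -1000))
    stop("PDB format error: coordinate out of fixed-width range (-999.999, 9999.999)")
  body <- sprintf("ATOM  %5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  a$serial %% 100000L, .formatAtomName(a$name),
                  substr(paste0(a$alt, " "), 1L, 1L), a$resid,
                  ifelse(nzchar(a$chain), a$chain, " "), a$resno,
                  substr(paste0(a$insert, " "), 1L, 1L),
                  s@xyz[, 1L], s@xyz[, 2L], s@xyz[, 3L],
                  1.0, 0.0, a$element)
  ## TER record after each chain block
  ends <- cumsum(rle(a$chain)$lengths)
  out <- character(0)
  prev <- 0L
  for (e in ends) {
    out <- c(out, body[(prev + 1L):e], "TER")
    prev <- e
  }
  out
}

#' Write a structure or ensemble as PDB text
#'
#' Round-trips through [readPdb()] reproduce coordinates to the PDB fixed
#' format precision (0.001 Angstrom) and all identity fields exactly.
#' Ensembles are written as MODEL/ENDMDL blocks.
#'
#' @param x a [Structure] or [Ensemble].
#' @param sink file path or connection.
#' @return invisibly, the character vector of lines written.
#' @rdname writePdb
#' @export
setMethod("writePdb", "Structure", function(x, sink) {
  out <- c(.structureLines(x), "END")
  writeLines(out, sink)
  invisible(out)
})

#' @rdname writePdb
#' @export
setMethod("writePdb", "Ensemble", function(x, sink) {
  out <- character(0)
  for (k in seq_along(x@frames)) {
    out <- c(out, sprintf("MODEL %8d", k), .structureLines(x@frames[[k]]),
             "ENDMDL")
  }
  out <- c(out, "END")
  writeLines(out, sink)
  invisible(out)
})

#' Create an atom selection
#'
#' @param chains character vector of chain ids, or NULL for any.
#' @param residues residue specification: `"1-100,120"` style string,
#'   numeric vector, or 2-column from/to matrix; NULL for any.
#' @param atomNames character vector of atom names, or NULL for any.
#' @return an [AtomSelection].
#' @examples
#' atomSelection(chains = "A", residues = "1-100", atomNames = "CA")
#' @export
atomSelection <- function(chains = NULL, residues = NULL, atomNames = NULL) {
  new("AtomSelection",
      chains = if (is.null(chains)) character(0) else as.character(chains),
      resnoRanges = .parseRanges(residues),
      atomNames = if (is.null(atomNames)) character(0) else as.character(atomNames))
}

#' Resolve a selection against a structure
#'
#' Returns the strictly increasing indices of atoms matching all supplied
#' criteria (intersection semantics; empty criteria match everything).
#' Matching zero atoms is an error, because silently empty selections
#' corrupt downstream RMSD and surface-area calculations.
#'
#' @param structure a [Structure].
#' @param selection an [AtomSelection].
#' @return integer vector of atom indices, strictly increasing.
#' @export
resolveSelection <- function(structure, selection) {
  a <- structure@atoms
  keep <- rep(TRUE, nrow(a))
  if (length(selection@chains) > 0L)
    keep <- keep & a$chain %in% selection@chains
  rr <- selection@resnoRanges
  if (nrow(rr) > 0L) {
    inRange <- rep(FALSE, nrow(a))
    for (i in seq_len(nrow(rr)))
      inRange <- inRange | (a$resno >= rr[i, 1L] & a$resno <= rr[i, 2L])
    keep <- keep & inRange
  }
  if (length(selection@atomNames) > 0L)
    keep <- keep & a$name %in% selection@atomNames
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("empty selection: no atoms match the requested chains/residues/atom names")
  idx
}

#' Subset a structure by atom indices
#'
#' @param structure a [Structure].
#' @param idx integer atom indices.
#' @return a [Structure] containing the selected atoms, order preserved.
#' @export
subsetStructure <- function(structure, idx) {
  Structure(structure@atoms[idx, , drop = FALSE],
            structure@xyz[idx, , drop = FALSE],
            modelId = structure@modelId)
}

#' Standard van der Waals radii
#'
#' The default element radius table (Angstrom): C 1.70, N 1.55, O 1.52,
#' S 1.80, H 1.20.
#'
#' @return named numeric vector.
#' @export
defaultVdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)
}

#' Read a radius table file
#'
#' Two whitespace-separated columns: element symbol, radius in Angstrom.
#' `#` comments and blank lines are ignored.
#'
#' @param path file path.
#' @return named numeric vector.
#' @export
readRadiusTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  el <- vapply(parts, `[[`, character(1), 1L)
  r <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (anyNA(r) || any(r <= 0)) stop("radius table: radii must be positive numbers")
  names(r) <- toupper(el)
  r
}

#' Assign van der Waals radii to a structure
#'
#' Populates the `radius` column from an element -> Angstrom table.
#' Unknown elements are an error unless `defaultRadius` is supplied, in
#' which case they receive the default with a warning.
#'
#' @param structure a [Structure].
#' @param radiusTable named numeric vector (element -> radius, Angstrom).
#' @param defaultRadius optional fallback radius for unknown elements.
#' @return the structure with `radius` populated; coordinates untouched.
#' @export
assignRadii <- function(structure, radiusTable = defaultVdwRadii(),
                        defaultRadius = NULL) {
  el <- toupper(structure@atoms$element)
  r <- unname(radiusTable[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    bad <- unique(el[unknown])
    if (is.null(defaultRadius))
      stop(sprintf("radius assignment error: no radius for element(s) %s",
                   paste(bad, collapse = ", ")))
    warning(sprintf("element(s) %s not in radius table; using default %.2f A",
                    paste(bad, collapse = ", "), defaultRadius))
    r[unknown] <- defaultRadius
  }
  structure@atoms$radius <- r
  validObject(structure)
  structure
}
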