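## Central S4 containers.  Coordinates are always Angstrom; residue
## numbering follows 1-based PDB author numbering with inclusive ranges.

REQUIRED_ATOM_COLS <- c("serial", "name", "resid", "chain", "resno",
                        "insert", "alt", "element", "radius")

#' Atom selection
#'
#' A declarative selection of atoms by chain, residue range and/or atom
#' name.  An empty criterion (length-zero slot) matches everything for that
#' field; criteria combine by intersection.  Resolving a selection against a
#' [Structure] yields a deterministic, strictly increasing index vector.
#'
#' @slot chains character vector of single-character chain identifiers
#'   (length 0 = any chain).
#' @slot resnoRanges integer matrix with columns `from`, `to`; inclusive
#'   1-based residue-number intervals (0 rows = any residue).
#' @slot atomNames character vector of atom names (length 0 = any name).
#' @seealso [atomSelection()], [resolveSelection()]
#' @export
setClass("AtomSelection",
  slots = c(chains = "character", resnoRanges = "matrix",
            atomNames = "character"),
  prototype = prototype(chains = character(0),
                        resnoRanges = matrix(integer(0), ncol = 2,
                          dimnames = list(NULL, c("from", "to"))),
                        atomNames = character(0)))

setValidity("AtomSelection", function(object) {
  m <- object@resnoRanges
  if (ncol(m) != 2L) return("resnoRanges must have two columns")
  if (nrow(m) > 0L && any(m[, 2L] < m[, 1L]))
    return("resnoRanges must satisfy from <= to")
  if (any(nchar(object@chains) > 1L))
    return("chain identifiers must be single characters")
  TRUE
})

#' Molecular structure
#'
#' An ordered set of atom records with 3D coordinates.  `atoms` holds the
#' identity fields (serial, name, resid, chain, resno, insert, alt, element,
#' radius); `xyz` is the matching n x 3 coordinate matrix in Angstrom.
#'
#' @slot atoms data.frame of atom identity fields, one row per atom.
#' @slot xyz numeric matrix, n x 3, Angstrom.
#' @slot modelId integer model number (PDB MODEL record; 1 for single-model
#'   structures).
#' @seealso [Structure()], [readPdb()], [writePdb()]
#' @export
setClass("Structure",
  slots = c(atoms = "data.frame", xyz = "matrix", modelId = "integer"))

setValidity("Structure", function(object) {
  a <- object@atoms
  missing <- setdiff(REQUIRED_ATOM_COLS, names(a))
  if (length(missing) > 0L)
    return(paste("atoms table lacks columns:", paste(missing, collapse = ", ")))
  if (nrow(a) != nrow(object@xyz))
    return("atoms table and xyz must have the same number of rows")
  if (ncol(object@xyz) != 3L) return("xyz must have 3 columns")
  if (nrow(object@xyz) > 0L && !all(is.finite(object@xyz)))
    return("coordinates must be finite")
  rad <- a$radius
  if (any(!is.na(rad) & rad <= 0)) return("assigned vdw radii must be > 0")
  if (any(nchar(a$chain) > 1L)) return("chain identifiers must be single characters")
  key <- paste(a$chain, a$resno, a$insert, a$name, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (chain, resno, insert, name) atom identity after alt-loc resolution")
  ## chains must form contiguous blocks in atom order
  r <- rle(a$chain)$values
  if (anyDuplicated(r)) return("chains must be contiguous blocks in atom order")
  TRUE
})

#' Conformational ensemble
#'
#' An ordered sequence of [Structure] frames sharing identical topology
#' (the same atom identities in the same order), e.g. the models of a
#' multi-model PDB file standing in for trajectory snapshots.
#'
#' @slot frames list of [Structure] objects.
#' @slot trajectoryId character scalar naming the trajectory.
#' @slot frameTimes numeric vector of frame times (ns), same length as
#'   `frames` (may be NA).
#' @export
setClass("Ensemble",
  slots = c(frames = "list", trajectoryId = "character",
            frameTimes = "numeric"))

setValidity("Ensemble", function(object) {
  if (length(object@frames) == 0L) return("ensemble must contain at least one frame")
  if (!all(vapply(object@frames, is, logical(1), class2 = "Structure")))
    return("all frames must be Structure objects")
  if (length(object@frameTimes) != length(object@frames))
    return("frameTimes length must equal frame count")
  key0 <- .identityKey(object@frames[[1L]]@atoms)
  for (k in seq_along(object@frames)[-1L]) {
    if (!identical(.identityKey(object@frames[[k]]@atoms), key0))
      return(sprintf("frame %d topology differs from frame 1", k))
  }
  TRUE
})

.identityKey <- function(atoms, withChain = TRUE) {
  if (withChain)
    paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid, atoms$name,
          sep = "\r")
  else
    paste(atoms$resno, atoms$insert, atoms$resid, atoms$name, sep = "\r")
}

#' Rigid-body transform
#'
#' A proper rotation plus translation, `x -> R x + t`.  Output of
#' [kabschFit()]; input to [applyTransform()] and the conformer builders.
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation numeric 3-vector, Angstrom.
#' @export
setClass("RigidTransform",
  slots = c(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must be length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8)
    return("rotation must be orthonormal within 1e-8")
  if (abs(det(R) - 1) > 1e-8)
    return("rotation must be proper (det +1 within 1e-8)")
  TRUE
})

#' Binding-mode template
#'
#' A receptor-monomer + ligand complex together with the selections that
#' drive template docking: the receptor atoms used for superposition, the
#' ligand atoms carried along by the fitted transform, and the ligand's
#' membrane-proximal (carboxy-terminal) domain used for clash scoring.
#'
#' @slot complex [Structure] holding one receptor chain and one ligand chain.
#' @slot receptorFit [AtomSelection] of receptor atoms used for the fit.
#' @slot ligandSel [AtomSelection] covering the ligand.
#' @slot ligandCterm [AtomSelection], subset of `ligandSel`, the
#'   membrane-proximal ligand domain.
#' @export
setClass("BindingTemplate",
  slots = c(complex = "Structure", receptorFit = "AtomSelection",
            ligandSel = "AtomSelection", ligandCterm = "AtomSelection"))

setValidity("BindingTemplate", function(object) {
  iFit <- tryCatch(resolveSelection(object@complex, object@receptorFit),
                   error = function(e) e)
  iLig <- tryCatch(resolveSelection(object@complex, object@ligandSel),
                   error = function(e) e)
  iCt  <- tryCatch(resolveSelection(object@complex, object@ligandCterm),
                   error = function(e) e)
  for (x in list(iFit, iLig, iCt))
    if (inherits(x, "error")) return(conditionMessage(x))
  if (length(intersect(iFit, iLig)) > 0L)
    return("receptor fit selection and ligand selection must be disjoint")
  if (!all(iCt %in% iLig))
    return("ligand C-terminal selection must be a subset of the ligand selection")
  TRUE
})

#' Docked dimer--ligand complex
#'
#' Result of docking one ligand onto each monomer of a dimer conformer.
#' The receptor frame is untouched; the two ligand blocks are rigid copies
#' of the template ligand placed by the per-monomer fits.
#'
#' @slot dimer the input dimer [Structure] (read-only copy).
#' @slot ligand1,ligand2 docked ligand [Structure]s (chains relabelled to
#'   avoid collision with the receptor chains).
#' @slot fitRmsd1,fitRmsd2 superposition RMSD of each monomer fit, Angstrom.
#' @slot qualityFlag1,qualityFlag2 TRUE when the fit RMSD exceeded the
#'   configured ceiling (dock-quality warning, not fatal).
#' @export
setClass("DockedComplex",
  slots = c(dimer = "Structure", ligand1 = "Structure", ligand2 = "Structure",
            fitRmsd1 = "numeric", fitRmsd2 = "numeric",
            qualityFlag1 = "logical", qualityFlag2 = "logical"))

setValidity("DockedComplex", function(object) {
  if (object@fitRmsd1 < 0 || object@fitRmsd2 < 0)
    return("fit RMSD values must be nonnegative")
  if (!identical(.identityKey(object@ligand1@atoms, withChain = FALSE),
                 .identityKey(object@ligand2@atoms, withChain = FALSE)))
    return("the two docked ligands must share the template ligand topology")
  TRUE
})

#' Solvent-accessible surface area result
#'
#' @slot perAtomArea numeric vector of per-atom SASA, Angstrom^2.
#' @slot totalArea numeric scalar, sum of per-atom areas.
#' @slot probeRadius probe radius used, Angstrom.
#' @slot nSpherePoints number of test points per atom.
#' @export
setClass("SasaResult",
  slots = c(perAtomArea = "numeric", totalArea = "numeric",
            probeRadius = "numeric", nSpherePoints = "integer"))

setValidity("SasaResult", function(object) {
  if (any(object@perAtomArea < 0)) return("per-atom areas must be nonnegative")
  tot <- sum(object@perAtomArea)
  if (abs(object@totalArea - tot) > 1e-6 * max(1, abs(tot)))
    return("totalArea must equal the sum of per-atom areas")
  TRUE
})

#' Buried surface area between two atom groups
#'
#' `value = (areaA + areaB - areaComplex) / 2`, clamped to zero against
#' round-off.  Zero if and only if neither group occludes the other's
#' solvent-accessible surface.
#'
#' @slot value buried area per side, Angstrom^2.
#' @slot groupAArea,groupBArea,complexArea component SASA totals.
#' @export
setClass("BuriedSurface",
  slots = c(value = "numeric", groupAArea = "numeric",
            groupBArea = "numeric", complexArea = "numeric"))

setValidity("BuriedSurface", function(object) {
  if (object@value < 0) return("buried surface must be nonnegative")
  TRUE
})

#' RMSD time series for an ensemble
#'
#' @slot values RMSD versus the first frame, Angstrom, one per frame.
#' @slot frameTimes matching frame times (ns).
#' @slot selectionUsed the [AtomSelection] the series was computed on.
#' @export
setClass("RmsdSeries",
  slots = c(values = "numeric", frameTimes = "numeric",
            selectionUsed = "AtomSelection"))

setValidity("RmsdSeries", function(object) {
  if (any(object@values < 0)) return("RMSD values must be nonnegative")
  if (length(object@values) != length(object@frameTimes))
    return("values and frameTimes must have equal length")
  TRUE
})

#' Dimer geometry descriptor
#'
#' Scalar geometry of a two-subunit conformer: distance between the two
#' binding-site centroids, distance between the two interface-anchor
#' centroids, angle between the monomer principal axes (each axis oriented
#' from its interface-anchor centroid toward its binding-site centroid) and
#' the twist (dihedral of the two binding-site centroids about the
#' inter-anchor axis).
#'
#' @slot bindingSiteSeparation Angstrom. @slot interfaceGap Angstrom.
#' @slot openingAngle degrees in \[0, 180\]. @slot twistAngle degrees in
#'   \[0, 180\].
#' @export
setClass("DimerDescriptor",
  slots = c(bindingSiteSeparation = "numeric", interfaceGap = "numeric",
            openingAngle = "numeric", twistAngle = "numeric"))

setValidity("DimerDescriptor", function(object) {
  if (object@bindingSiteSeparation < 0 || object@interfaceGap < 0)
    return("distances must be nonnegative")
  if (object@openingAngle < -1e-9 || object@openingAngle > 180 + 1e-9)
    return("openingAngle must lie in [0, 180] degrees")
  if (object@twistAngle < -1e-9 || object@twistAngle > 180 + 1e-9)
    return("twistAngle must lie in [0, 180] degrees")
  TRUE
})

#' Dimer reorientation specification
#'
#' Parameters for rotating one subunit of a dimer about an axis while
#' requiring that a declared set of interface residues remains in contact
#' with the partner subunit (heavy-atom distance at or below
#' `contactCutoff`), mirroring the constraint that the hydrophobic interface
#' residues of the starting conformation stay part of the interface.
#'
#' @slot axisDefinition `"interface_axis"` (line through the two
#'   interface-anchor centroids) or `"custom"`.
#' @slot axisVector,axisPoint custom axis direction and a point on it
#'   (ignored for `"interface_axis"`).
#' @slot angle rotation angle, degrees.
#' @slot preserveInterface [AtomSelection] of residues that must stay in
#'   contact.
#' @slot anchor1,anchor2 [AtomSelection]s of the two interface-anchor
#'   groups defining the interface axis.
#' @slot contactCutoff heavy-atom contact distance, Angstrom (default 5).
#' @export
setClass("ReorientationSpec",
  slots = c(axisDefinition = "character", axisVector = "numeric",
            axisPoint = "numeric", angle = "numeric",
            preserveInterface = "AtomSelection",
            anchor1 = "AtomSelection", anchor2 = "AtomSelection",
            contactCutoff = "numeric"))

setValidity("ReorientationSpec", function(object) {
  if (!object@axisDefinition %in% c("interface_axis", "custom"))
    return("axisDefinition must be 'interface_axis' or 'custom'")
  if (object@axisDefinition == "custom" &&
      (length(object@axisVector) != 3L || length(object@axisPoint) != 3L))
    return("custom axis requires a 3-vector direction and point")
  if (object@contactCutoff <= 0) return("contactCutoff must be positive")
  TRUE
})

#' Ensemble valency summary
#'
#' Per-trajectory bivalent-competent fractions, their unweighted mean
#' across trajectories (the headline statistic), the frame-weighted mean
#' for comparison, frame counts, the zero tolerance used, and the full
#' per-frame record table.
#'
#' @slot perTrajectoryFraction named numeric in \[0, 1\].
#' @slot meanFraction unweighted arithmetic mean of per-trajectory fractions.
#' @slot weightedMeanFraction frame-weighted pooled fraction.
#' @slot nFramesPerTrajectory named integer.
#' @slot nQualityFlagged named integer: frames whose dock fit exceeded the
#'   RMSD ceiling.
#' @slot zeroTolerance Angstrom^2.
#' @slot records data.frame of per-frame valency records.
#' @export
setClass("EnsembleSummary",
  slots = c(perTrajectoryFraction = "numeric", meanFraction = "numeric",
            weightedMeanFraction = "numeric",
            nFramesPerTrajectory = "integer", nQualityFlagged = "integer",
            zeroTolerance = "numeric", records = "data.frame"))

setValidity("EnsembleSummary", function(object) {
  f <- object@perTrajectoryFraction
  if (any(f < 0 | f > 1)) return("fractions must lie in [0, 1]")
  if (abs(object@meanFraction - mean(f)) > 1e-12)
    return("meanFraction must equal the unweighted mean of per-trajectory fractions")
  TRUE
})

#' Toy dimer system specification
#'
#' Dimensions of the synthetic rigid-body system: an elongated pseudo-Ig
#' monomer rod and a tandem two-domain ligand (distal binding domain plus
#' proximal carboxy-terminal domain).  All lengths in Angstrom.
#'
#' @slot monomerAtoms,ligandDomainAtoms atom counts (>= 4).
#' @slot monomerLength rod length. @slot monomerRadius rod lattice radius.
#' @slot ligandDomainRadius radius of each quasi-spherical ligand domain.
#' @slot ligandDomainSeparation centre-to-centre distance between the two
#'   ligand domains.
#' @slot ligandStandoff gap between the monomer tip and the binding-domain
#'   centre.
#' @slot interfaceOffset lateral half-spacing of the two subunits at the
#'   dimer base (times two).
#' @slot seed RNG seed recorded with the system.
#' @export
setClass("ToySystemSpec",
  slots = c(monomerAtoms = "integer", monomerLength = "numeric",
            monomerRadius = "numeric", ligandDomainAtoms = "integer",
            ligandDomainRadius = "numeric", ligandDomainSeparation = "numeric",
            ligandStandoff = "numeric", interfaceOffset = "numeric",
            seed = "integer"))

setValidity("ToySystemSpec", function(object) {
  if (object@monomerAtoms < 4L || object@ligandDomainAtoms < 4L)
    return("each body needs at least 4 atoms")
  if (object@monomerLength <= 0 || object@ligandDomainSeparation <= 0 ||
      object@monomerRadius <= 0 || object@ligandDomainRadius <= 0)
    return("body dimensions must be positive")
  TRUE
})

#' Synthetic ensemble specification
#'
#' Sampling parameters for toy dimer ensembles.  When
#' `bivalentFractionTarget` is set, frames are drawn from two well-separated
#' opening-angle regimes (`compactAngle`, `openAngle`) in exactly that
#' proportion (rounded to the nearest frame count, shuffled by seed);
#' otherwise opening angles follow a truncated normal continuum.
#'
#' @slot nFrames frame count.
#' @slot openingAngleMean,openingAngleSd degrees (continuum mode mean;
#'   within-regime sd in two-regime mode).
#' @slot twistMean,twistSd degrees.
#' @slot atomJitterSd per-atom isotropic Gaussian jitter, Angstrom.
#' @slot bivalentFractionTarget target fraction in \[0, 1\] or NA.
#' @slot compactAngle,openAngle the two regime means, degrees.
#' @slot seed integer RNG seed.
#' @slot trajectoryId character label.
#' @export
setClass("EnsembleSpec",
  slots = c(nFrames = "integer", openingAngleMean = "numeric",
            openingAngleSd = "numeric", twistMean = "numeric",
            twistSd = "numeric", atomJitterSd = "numeric",
            bivalentFractionTarget = "numeric", compactAngle = "numeric",
            openAngle = "numeric", seed = "integer",
            trajectoryId = "character"))

setValidity("EnsembleSpec", function(object) {
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  t <- object@bivalentFractionTarget
  if (!is.na(t) && (t < 0 || t > 1))
    return("bivalentFractionTarget must lie in [0, 1]")
  if (object@atomJitterSd < 0) return("atomJitterSd must be nonnegative")
  TRUE
})
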