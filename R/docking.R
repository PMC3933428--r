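## Template-based rigid docking: superpose a binding-mode template's
## receptor onto a dimer monomer and carry the template ligand along.

#' Construct a binding-mode template
#'
#' @param complex [Structure] with one receptor chain and one ligand chain.
#' @param receptorFit [AtomSelection] of receptor atoms used for the
#'   superposition (conventionally the C-alpha atoms of the receptor Ig
#'   domain).
#' @param ligand [AtomSelection] covering the ligand.
#' @param ligandCterm [AtomSelection] of the ligand's membrane-proximal
#'   (carboxy-terminal) domain, subset of `ligand`.
#' @return a [BindingTemplate].
#' @export
bindingTemplate <- function(complex, receptorFit, ligand, ligandCterm) {
  new("BindingTemplate", complex = complex, receptorFit = receptorFit,
      ligandSel = ligand, ligandCterm = ligandCterm)
}

#' Read a template bundle (PDB + selection config)
#'
#' The config is plain `key = value` text with keys `receptor_chain`,
#' `ligand_chain`, `ligand_cterm_residues` (range string) and optional
#' `receptor_fit_residues`, `receptor_fit_atoms` (default `CA`).
#'
#' @param pdbPath template complex PDB file.
#' @param configPath selection config file.
#' @return a [BindingTemplate].
#' @export
readTemplateBundle <- function(pdbPath, configPath) {
  cfg <- readKeyValueConfig(configPath)
  need <- c("receptor_chain", "ligand_chain", "ligand_cterm_residues")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L)
    stop(sprintf("template config lacks key(s): %s", paste(miss, collapse = ", ")))
  complex <- readPdb(pdbPath, modelPolicy = "first")
  fitAtoms <- if (!is.null(cfg$receptor_fit_atoms))
    trimws(strsplit(cfg$receptor_fit_atoms, ",")[[1L]]) else "CA"
  bindingTemplate(
    complex,
    receptorFit = atomSelection(chains = cfg$receptor_chain,
                                residues = cfg$receptor_fit_residues,
                                atomNames = fitAtoms),
    ligand = atomSelection(chains = cfg$ligand_chain),
    ligandCterm = atomSelection(chains = cfg$ligand_chain,
                                residues = cfg$ligand_cterm_residues))
}

## Template-receptor atoms are paired to frame-monomer atoms on
## (resno, insert, resid, name); chains are excluded by design since the
## template receptor chain differs from the dimer's chain ids.
.dockPairing <- function(frame, monomerSelection, template) {
  iF <- resolveSelection(frame, monomerSelection)
  iT <- resolveSelection(template@complex, template@receptorFit)
  kF <- .identityKey(frame@atoms[iF, , drop = FALSE], withChain = FALSE)
  kT <- .identityKey(template@complex@atoms[iT, , drop = FALSE],
                     withChain = FALSE)
  if (length(kF) != length(kT) || !identical(kF, kT))
    stop("pairing error: monomer selection and template receptor fit selection resolve to different atom identities")
  list(frame = iF, template = iT)
}

#' Dock the template ligand onto one monomer
#'
#' Superposes the template receptor onto the selected monomer atoms
#' (Kabsch fit) and returns the template ligand carried by that transform.
#' The fit RMSD is reported for quality control; exceeding `rmsdCeiling`
#' raises a dock-quality warning (not an error) and flags the result.
#'
#' @param frame dimer conformer [Structure].
#' @param monomerSelection [AtomSelection] of the monomer atoms matching
#'   the template's receptor fit selection.
#' @param template a [BindingTemplate].
#' @param rmsdCeiling fit-RMSD warning threshold, Angstrom (default 3.0).
#' @return list with `ligand` ([Structure]), `fitRmsd` (Angstrom),
#'   `qualityFlag` (logical) and `transform` (the fitted [RigidTransform]).
#' @export
dockOne <- function(frame, monomerSelection, template, rmsdCeiling = 3.0) {
  p <- .dockPairing(frame, monomerSelection, template)
  fit <- kabschFit(template@complex@xyz[p$template, , drop = FALSE],
                   frame@xyz[p$frame, , drop = FALSE])
  flag <- fit$rmsd > rmsdCeiling
  if (flag)
    warning(sprintf("dock-quality warning: fit RMSD %.2f A exceeds ceiling %.2f A",
                    fit$rmsd, rmsdCeiling))
  lig <- subsetStructure(template@complex,
                         resolveSelection(template@complex, template@ligandSel))
  lig <- applyTransform(lig, fit$transform)
  list(ligand = lig, fitRmsd = fit$rmsd, qualityFlag = flag,
       transform = fit$transform)
}

## first chain letters not already in use, deterministic
.freeChainIds <- function(used, n) {
  pool <- c(LETTERS, letters, as.character(0:9))
  setdiff(pool, used)[seq_len(n)]
}

.relabelChain <- function(structure, chainId) {
  structure@atoms$chain <- rep(chainId, nrow(structure@atoms))
  structure
}

#' Dock one ligand onto each monomer of a dimer
#'
#' Runs [dockOne()] independently on the two monomer selections and
#' relabels the docked ligand chains to the first two identifiers not used
#' by the receptor, so the result can be written as a single PDB complex.
#'
#' @param frame dimer conformer [Structure] (two receptor chains).
#' @param monomer1,monomer2 disjoint [AtomSelection]s, one per monomer.
#' @param template a [BindingTemplate].
#' @param rmsdCeiling fit-RMSD warning threshold, Angstrom.
#' @return a [DockedComplex].
#' @export
dockDimer <- function(frame, monomer1, monomer2, template, rmsdCeiling = 3.0) {
  i1 <- resolveSelection(frame, monomer1)
  i2 <- resolveSelection(frame, monomer2)
  if (length(intersect(i1, i2)) > 0L)
    stop("the two monomer selections must be disjoint")
  d1 <- dockOne(frame, monomer1, template, rmsdCeiling)
  d2 <- dockOne(frame, monomer2, template, rmsdCeiling)
  ids <- .freeChainIds(unique(frame@atoms$chain), 2L)
  new("DockedComplex",
      dimer = frame,
      ligand1 = .relabelChain(d1$ligand, ids[1L]),
      ligand2 = .relabelChain(d2$ligand, ids[2L]),
      fitRmsd1 = d1$fitRmsd, fitRmsd2 = d2$fitRmsd,
      qualityFlag1 = d1$qualityFlag, qualityFlag2 = d2$qualityFlag)
}

#' Merge a docked complex into a single structure
#'
#' Concatenates the receptor dimer and the two docked ligands (serials
#' renumbered) for inspection or PDB export.
#'
#' @param docked a [DockedComplex].
#' @return a [Structure].
#' @export
asStructure <- function(docked) {
  a <- rbind(docked@dimer@atoms, docked@ligand1@atoms, docked@ligand2@atoms)
  a$serial <- seq_len(nrow(a))
  xyz <- rbind(docked@dimer@xyz, docked@ligand1@xyz, docked@ligand2@xyz)
  Structure(a, xyz, modelId = docked@dimer@modelId)
}
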