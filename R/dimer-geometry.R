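## Dimer openness descriptors and reoriented/grafted conformer builds.

.heavyIdx <- function(structure, idx) {
  idx[toupper(structure@atoms$element[idx]) != "H"]
}

.centroid <- function(structure, selection) {
  idx <- .heavyIdx(structure, resolveSelection(structure, selection))
  if (length(idx) == 0L) stop("empty selection: no heavy atoms")
  colMeans(structure@xyz[idx, , drop = FALSE])
}

## first principal axis of a monomer's C-alpha cloud (all heavy atoms when
## no CA present), sign-oriented from `from` toward `to`
.principalAxis <- function(structure, monomerSel, from, to) {
  idx <- resolveSelection(structure, monomerSel)
  ca <- idx[structure@atoms$name[idx] == "CA"]
  if (length(ca) < 3L) ca <- .heavyIdx(structure, idx)
  x <- structure@xyz[ca, , drop = FALSE]
  x <- sweep(x, 2L, colMeans(x))
  ax <- svd(x, nu = 0, nv = 1)$v[, 1L]
  if (sum(ax * (to - from)) < 0) ax <- -ax
  ax
}

#' Geometric descriptor of a dimer conformer
#'
#' Computes the openness of a two-subunit conformer: the distance between
#' the two binding-site centroids, the gap between the two interface-anchor
#' centroids (e.g. the residues at the base of the dimer interface), the
#' opening angle between the monomer principal axes (each oriented from its
#' interface-anchor centroid toward its binding-site centroid), and the
#' twist (dihedral of the binding-site centroids about the inter-anchor
#' axis).  Centroids are over heavy atoms; axes over C-alpha atoms.
#'
#' @param frame dimer [Structure].
#' @param monomer1,monomer2 [AtomSelection]s of the two subunits.
#' @param bindingSite1,bindingSite2 [AtomSelection]s of the two ligand
#'   binding sites.
#' @param interfaceAnchor1,interfaceAnchor2 [AtomSelection]s of the two
#'   interface-anchor residue groups.
#' @return a [DimerDescriptor].
#' @export
describeDimer <- function(frame, monomer1, monomer2,
                          bindingSite1, bindingSite2,
                          interfaceAnchor1, interfaceAnchor2) {
  b1 <- .centroid(frame, bindingSite1)
  b2 <- .centroid(frame, bindingSite2)
  a1 <- .centroid(frame, interfaceAnchor1)
  a2 <- .centroid(frame, interfaceAnchor2)
  u1 <- .principalAxis(frame, monomer1, a1, b1)
  u2 <- .principalAxis(frame, monomer2, a2, b2)
  new("DimerDescriptor",
      bindingSiteSeparation = .vnorm(b1 - b2),
      interfaceGap = .vnorm(a1 - a2),
      openingAngle = .angleDeg(u1, u2),
      twistAngle = .dihedralDeg(b1, a1, a2, b2))
}

#' Create a reorientation specification
#'
#' @param angle rotation angle, degrees.
#' @param preserveInterface [AtomSelection] of residues that must remain in
#'   heavy-atom contact with the partner subunit after the rotation.
#' @param anchor1,anchor2 [AtomSelection]s of the two interface-anchor
#'   groups; the interface axis is the line through their centroids.
#' @param axisDefinition `"interface_axis"` (default) or `"custom"`.
#' @param axisVector,axisPoint direction and point for a custom axis.
#' @param contactCutoff heavy-atom contact distance, Angstrom (default 5.0).
#' @return a [ReorientationSpec].
#' @export
reorientationSpec <- function(angle, preserveInterface, anchor1, anchor2,
                              axisDefinition = "interface_axis",
                              axisVector = numeric(0), axisPoint = numeric(0),
                              contactCutoff = 5.0) {
  new("ReorientationSpec", axisDefinition = axisDefinition,
      axisVector = as.numeric(axisVector), axisPoint = as.numeric(axisPoint),
      angle = angle, preserveInterface = preserveInterface,
      anchor1 = anchor1, anchor2 = anchor2, contactCutoff = contactCutoff)
}

## minimum heavy-atom distance from each residue of `idx` to `partnerXyz`
.residueMinDist <- function(structure, idx, partnerXyz) {
  a <- structure@atoms[idx, , drop = FALSE]
  res <- paste(a$chain, a$resno, a$insert, sep = "\r")
  groups <- split(idx, factor(res, levels = unique(res)))
  vapply(groups, function(g) {
    x <- structure@xyz[g, , drop = FALSE]
    d2 <- outer(rowSums(x^2), rowSums(partnerXyz^2), "+") -
      2 * x %*% t(partnerXyz)
    sqrt(max(0, min(d2)))
  }, numeric(1))
}

#' Rotate one subunit of a dimer about an interface axis
#'
#' Applies an exactly rigid rotation to the selected chain about the
#' interface axis (the line through the two interface-anchor centroids) or
#' a custom axis, then verifies that every residue in the spec's
#' preserve-interface selection still has a heavy-atom contact at or below
#' the cutoff with the partner subunit.  Builds that lose the interface are
#' rejected with an error naming the lost contacts.
#'
#' @param frame dimer [Structure].
#' @param monomerToMove [AtomSelection] that must cover one entire chain.
#' @param spec a [ReorientationSpec].
#' @return the reoriented [Structure].
#' @export
reorientDimer <- function(frame, monomerToMove, spec) {
  idxMove <- resolveSelection(frame, monomerToMove)
  movedChains <- unique(frame@atoms$chain[idxMove])
  if (length(movedChains) != 1L ||
      !all(which(frame@atoms$chain == movedChains) %in% idxMove))
    stop("monomerToMove must select exactly one entire chain")
  if (spec@axisDefinition == "interface_axis") {
    p1 <- .centroid(frame, spec@anchor1)
    p2 <- .centroid(frame, spec@anchor2)
    axis <- p2 - p1
    point <- p1
  } else {
    axis <- spec@axisVector
    point <- spec@axisPoint
  }
  R <- rotationAboutAxis(axis, spec@angle)
  out <- frame
  x <- out@xyz[idxMove, , drop = FALSE]
  x <- sweep(sweep(x, 2L, point) %*% t(R), 2L, point, "+")
  out@xyz[idxMove, ] <- x
  ## interface-preservation check
  idxKeep <- resolveSelection(out, spec@preserveInterface)
  keepChains <- unique(out@atoms$chain[idxKeep])
  for (ch in keepChains) {
    sel <- idxKeep[out@atoms$chain[idxKeep] == ch]
    sel <- .heavyIdx(out, sel)
    partner <- .heavyIdx(out, which(out@atoms$chain != ch))
    d <- .residueMinDist(out, sel, out@xyz[partner, , drop = FALSE])
    lost <- d > spec@contactCutoff
    if (any(lost)) {
      a <- out@atoms[sel, , drop = FALSE]
      res <- unique(paste0(a$chain, ":", a$resno, a$insert))[lost]
      stop(sprintf("rejected build: interface lost for residue(s) %s (min contact > %.1f A)",
                   paste(res, collapse = ", "), spec@contactCutoff))
    }
  }
  out
}

#' Graft a monomer onto a dimer template
#'
#' Places two rigid copies of a monomer by superposing it onto each subunit
#' of a dimer template (Kabsch fit over `fitSelection`, atoms paired on
#' residue number, insertion code, residue name and atom name).  The copies
#' inherit the template's chain identifiers, so the build adopts the
#' template's subunit orientation — e.g. rebuilding a compact dimer in an
#' open dimer's orientation.
#'
#' @param monomer single-chain [Structure].
#' @param dimerTemplate two-chain [Structure] providing the target
#'   orientation.
#' @param templateMonomer1,templateMonomer2 [AtomSelection]s of the
#'   template's two subunits.
#' @param fitSelection [AtomSelection] of atoms used for each fit
#'   (default: C-alpha atoms).
#' @return the grafted dimer [Structure].
#' @export
graftOntoDimerTemplate <- function(monomer, dimerTemplate,
                                   templateMonomer1, templateMonomer2,
                                   fitSelection = atomSelection(atomNames = "CA")) {
  placeCopy <- function(templateSel) {
    iT <- resolveSelection(dimerTemplate, templateSel)
    subFit <- resolveSelection(dimerTemplate, fitSelection)
    iT <- intersect(iT, subFit)
    iM <- resolveSelection(monomer, fitSelection)
    kT <- .identityKey(dimerTemplate@atoms[iT, , drop = FALSE], withChain = FALSE)
    kM <- .identityKey(monomer@atoms[iM, , drop = FALSE], withChain = FALSE)
    if (length(kT) == 0L || length(kT) != length(kM) || !identical(kT, kM))
      stop("pairing error: monomer and template subunit fit selections do not match")
    fit <- kabschFit(monomer@xyz[iM, , drop = FALSE],
                     dimerTemplate@xyz[iT, , drop = FALSE])
    copy <- applyTransform(monomer, fit$transform)
    .relabelChain(copy, unique(dimerTemplate@atoms$chain[iT])[1L])
  }
  c1 <- placeCopy(templateMonomer1)
  c2 <- placeCopy(templateMonomer2)
  a <- rbind(c1@atoms, c2@atoms)
  a$serial <- seq_len(nrow(a))
  Structure(a, rbind(c1@xyz, c2@xyz), modelId = dimerTemplate@modelId)
}
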