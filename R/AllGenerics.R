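#' @rdname Structure-accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Structure-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname Structure-accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname Structure-accessors
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname Ensemble-accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname applyTransform
#' @export
setGeneric("applyTransform", function(x, transform) standardGeneric("applyTransform"))

#' @rdname writePdb
#' @export
setGeneric("writePdb", function(x, sink) standardGeneric("writePdb"))

#' Accessors for Structure objects
#'
#' `nAtoms()` returns the atom count, `atomTable()` the identity table,
#' `coords()` the n x 3 coordinate matrix (Angstrom); `coords<-` replaces
#' coordinates without touching identities.
#'
#' @param x a [Structure] (or [Ensemble] for `nAtoms`).
#' @param value replacement n x 3 coordinate matrix.
#' @return See individual descriptions.
#' @name Structure-accessors
#' @aliases nAtoms atomTable coords coords<-
NULL

#' Accessors for Ensemble objects
#'
#' `nFrames()` counts frames, `getFrame(x, i)` extracts frame `i` as a
#' [Structure], `frameTimes()` returns the frame times (ns).
#'
#' @param x an [Ensemble].
#' @param i frame index (1-based).
#' @name Ensemble-accessors
#' @aliases nFrames getFrame frameTimes
NULL

setMethod("nAtoms", "Structure", function(x) nrow(x@atoms))
setMethod("nAtoms", "Ensemble", function(x) nrow(x@frames[[1L]]@atoms))
setMethod("atomTable", "Structure", function(x) x@atoms)
setMethod("coords", "Structure", function(x) x@xyz)
setMethod("coords<-", "Structure", function(x, value) {
  stopifnot(is.matrix(value), ncol(value) == 3L, nrow(value) == nrow(x@atoms))
  x@xyz <- value
  validObject(x)
  x
})
setMethod("nFrames", "Ensemble", function(x) length(x@frames))
setMethod("getFrame", "Ensemble", function(x, i) x@frames[[i]])
setMethod("frameTimes", "Ensemble", function(x) x@frameTimes)

setMethod("show", "Structure", function(object) {
  ch <- unique(object@atoms$chain)
  cat(sprintf("Structure: %d atoms, %d chain(s) [%s], model %d\n",
              nrow(object@atoms), length(ch), paste(ch, collapse = ","),
              object@modelId))
})

setMethod("show", "Ensemble", function(object) {
  cat(sprintf("Ensemble '%s': %d frames x %d atoms\n",
              object@trajectoryId, length(object@frames),
              nrow(object@frames[[1L]]@atoms)))
})

setMethod("show", "AtomSelection", function(object) {
  fmt <- function(v, what) if (length(v) == 0L) paste0("any ", what)
         else paste0(what, " {", paste(v, collapse = ","), "}")
  rr <- if (nrow(object@resnoRanges) == 0L) "any residue"
        else paste0("residues ", paste(apply(object@resnoRanges, 1L,
             function(r) if (r[1] == r[2]) r[1] else paste0(r[1], "-", r[2])),
             collapse = ","))
  cat("AtomSelection:", fmt(object@chains, "chain"), "|", rr, "|",
      fmt(object@atomNames, "atom"), "\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (x -> R x + t)\n")
  cat("  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(round(object@translation, 4), collapse = " "), "\n")
})

setMethod("show", "BindingTemplate", function(object) {
  cat("BindingTemplate:\n  complex: ")
  show(object@complex)
  nf <- length(resolveSelection(object@complex, object@receptorFit))
  nl <- length(resolveSelection(object@complex, object@ligandSel))
  nc <- length(resolveSelection(object@complex, object@ligandCterm))
  cat(sprintf("  receptor fit atoms: %d | ligand atoms: %d | ligand C-term atoms: %d\n",
              nf, nl, nc))
})

setMethod("show", "DockedComplex", function(object) {
  cat(sprintf("DockedComplex: dimer %d atoms + 2 x %d ligand atoms; fit RMSD %.3f / %.3f A%s\n",
              nrow(object@dimer@atoms), nrow(object@ligand1@atoms),
              object@fitRmsd1, object@fitRmsd2,
              if (object@qualityFlag1 || object@qualityFlag2)
                " [dock-quality flag]" else ""))
})

setMethod("show", "SasaResult", function(object) {
  cat(sprintf("SASA: %.2f A^2 over %d atoms (probe %.2f A, %d points/atom)\n",
              object@totalArea, length(object@perAtomArea),
              object@probeRadius, object@nSpherePoints))
})

setMethod("show", "BuriedSurface", function(object) {
  cat(sprintf("Buried surface: %.2f A^2 (A %.2f + B %.2f - AB %.2f)/2\n",
              object@value, object@groupAArea, object@groupBArea,
              object@complexArea))
})

setMethod("show", "RmsdSeries", function(object) {
  cat(sprintf("RmsdSeries: %d frames, max %.3f A, final %.3f A\n",
              length(object@values),
              if (length(object@values)) max(object@values) else NA_real_,
              if (length(object@values)) object@values[length(object@values)] else NA_real_))
})

setMethod("show", "DimerDescriptor", function(object) {
  cat(sprintf(paste0("DimerDescriptor: binding-site separation %.2f A | ",
                     "interface gap %.2f A | opening %.2f deg | twist %.2f deg\n"),
              object@bindingSiteSeparation, object@interfaceGap,
              object@openingAngle, object@twistAngle))
})

setMethod("show", "EnsembleSummary", function(object) {
  cat("Ensemble valency summary\n")
  for (id in names(object@perTrajectoryFraction))
    cat(sprintf("  %s: %.3f bivalent-competent (%d frames, %d dock-quality flagged)\n",
                id, object@perTrajectoryFraction[[id]],
                object@nFramesPerTrajectory[[id]],
                object@nQualityFlagged[[id]]))
  cat(sprintf("  mean over trajectories (unweighted): %.3f\n", object@meanFraction))
  cat(sprintf("  pooled (frame-weighted): %.3f\n", object@weightedMeanFraction))
  cat(sprintf("  zero tolerance: %.2f A^2\n", object@zeroTolerance))
})
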