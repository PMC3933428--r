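## Least-squares rigid superposition (Kabsch, via SVD with reflection
## correction) and RMSD over declared atom selections.

#' Identity transform
#' @return a [RigidTransform] with identity rotation and zero translation.
#' @export
identityTransform <- function() {
  new("RigidTransform", rotation = diag(3), translation = c(0, 0, 0))
}

#' Build a rigid transform
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation numeric 3-vector.
#' @return a [RigidTransform].
#' @export
rigidTransform <- function(rotation, translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Compose two rigid transforms
#'
#' `composeTransforms(a, b)` applies `b` first, then `a`:
#' `x -> Ra (Rb x + tb) + ta`.
#'
#' @param a,b [RigidTransform] objects.
#' @return the composite [RigidTransform].
#' @export
composeTransforms <- function(a, b) {
  new("RigidTransform",
      rotation = a@rotation %*% b@rotation,
      translation = as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param x a [RigidTransform].
#' @return the inverse [RigidTransform].
#' @export
invertTransform <- function(x) {
  Rt <- t(x@rotation)
  new("RigidTransform", rotation = Rt,
      translation = as.numeric(-Rt %*% x@translation))
}

#' Apply a rigid transform
#'
#' For a coordinate matrix, returns the transformed n x 3 matrix; for a
#' [Structure] or [Ensemble], returns a copy with transformed coordinates
#' and untouched identities.
#'
#' @param x n x 3 matrix, [Structure] or [Ensemble].
#' @param transform a [RigidTransform].
#' @name applyTransform
#' @export
setMethod("applyTransform", "matrix", function(x, transform) {
  out <- x %*% t(transform@rotation)
  out <- sweep(out, 2L, transform@translation, "+")
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "Structure", function(x, transform) {
  x@xyz <- applyTransform(x@xyz, transform)
  x
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "Ensemble", function(x, transform) {
  x@frames <- lapply(x@frames, applyTransform, transform = transform)
  x
})

#' Kabsch least-squares superposition
#'
#' Finds the proper rigid transform minimising the RMSD between paired
#' point sets, mapping `mobile` onto `reference`.  The reflection branch of
#' the SVD is corrected by flipping the smallest singular vector, so the
#' returned rotation always has determinant +1.
#'
#' @param mobile,reference N x 3 coordinate matrices, paired index to index
#'   (N >= 3, not all points collinear).
#' @return list with elements `transform` (a [RigidTransform]) and `rmsd`
#'   (Angstrom, after applying the transform).
#' @examples
#' ref <- matrix(rnorm(30), 10, 3)
#' tr <- rigidTransform(rotationZ(35), c(1, -2, 0.5))
#' fit <- kabschFit(applyTransform(ref, tr), ref)
#' fit$rmsd  # ~0
#' @export
kabschFit <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("mobile and reference must be N x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3L) stop("degenerate superposition: need at least 3 paired points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  M <- sweep(mobile, 2L, cm); Rf <- sweep(reference, 2L, cr)
  H <- crossprod(M, Rf)  # 3x3 covariance
  sv <- svd(H)
  ## degeneracy: collinear point sets leave the rotation underdetermined
  spread <- svd(M, nu = 0, nv = 0)$d
  if (spread[2L] < 1e-9 * max(spread[1L], 1e-12))
    stop("degenerate superposition: points are collinear (rank < 2)")
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tr <- as.numeric(cr - R %*% cm)
  transform <- new("RigidTransform", rotation = R, translation = tr)
  diff <- applyTransform(mobile, transform) - reference
  rmsd <- sqrt(max(0, mean(rowSums(diff * diff))))
  list(transform = transform, rmsd = rmsd)
}

## Resolve a selection on two structures and insist the atom identity
## lists match exactly (chain included).
.pairedIndices <- function(a, b, selection) {
  ia <- resolveSelection(a, selection)
  ib <- resolveSelection(b, selection)
  if (length(ia) != length(ib) ||
      !identical(.identityKey(a@atoms[ia, , drop = FALSE]),
                 .identityKey(b@atoms[ib, , drop = FALSE])))
    stop("pairing error: selection resolves to different atom identities in the two structures")
  list(a = ia, b = ib)
}

#' RMSD after optimal superposition
#'
#' Superposes `b` onto `a` on the selected atoms and reports the RMSD over
#' that same selection.  The default selection is C-alpha atoms; pass an
#' explicit selection for all-heavy-atom fits or to exclude flexible
#' segments (e.g. a membrane-proximal stalk) by residue range.
#'
#' @param a,b [Structure]s with identical atom identities over the selection.
#' @param selection an [AtomSelection] (default: atoms named CA).
#' @return RMSD in Angstrom.
#' @export
rmsdAfterFit <- function(a, b, selection = atomSelection(atomNames = "CA")) {
  p <- .pairedIndices(a, b, selection)
  kabschFit(b@xyz[p$b, , drop = FALSE], a@xyz[p$a, , drop = FALSE])$rmsd
}

#' RMSD of every frame versus the initial conformation
#'
#' For each frame of the ensemble, the RMSD (after superposition on the
#' selection) with respect to frame 1 — the standard
#' stability trace for a trajectory.  The first value is zero by
#' construction.
#'
#' @param ensemble an [Ensemble].
#' @param selection an [AtomSelection] (default: C-alpha atoms).
#' @return an [RmsdSeries].
#' @export
rmsdVsInitial <- function(ensemble, selection = atomSelection(atomNames = "CA")) {
  ref <- ensemble@frames[[1L]]
  vals <- vapply(ensemble@frames, function(f) rmsdAfterFit(ref, f, selection),
                 numeric(1))
  vals[1L] <- 0
  new("RmsdSeries", values = vals, frameTimes = ensemble@frameTimes,
      selectionUsed = selection)
}

#' Export an RMSD series as CSV
#'
#' Columns `frame`, `time_ns`, `rmsd_A`.
#'
#' @param series an [RmsdSeries].
#' @param path output file path.
#' @return invisibly, the data.frame written.
#' @export
exportRmsdSeries <- function(series, path) {
  df <- data.frame(frame = seq_along(series@values) - 1L,
                   time_ns = series@frameTimes,
                   rmsd_A = series@values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
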