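## Solvent-accessible surface area (Shrake-Rupley) and the buried surface
## between two atom groups -- the quantitative core of the valency readout.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-section spiral: point k (k = 0..n-1) has
#' `z = 1 - 2(k + 0.5)/n` and azimuth `k * pi * (3 - sqrt(5))`.
#' Deterministic, so SASA values are reproducible bit for bit.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
goldenSpiralPoints <- function(n) {
  k <- seq_len(n) - 1
  z <- 1 - 2 * (k + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

.sasaPerAtom <- function(xyz, radii, probeRadius, nSpherePoints) {
  if (any(radii <= 0) || anyNA(radii))
    stop("SASA requires positive radii for every atom (run assignRadii first)")
  if (nSpherePoints < 32L) stop("nSpherePoints must be >= 32")
  if (anyDuplicated(xyz) > 0L)
    warning("degenerate geometry: two atoms share identical coordinates")
  pts <- goldenSpiralPoints(nSpherePoints)
  exposed <- .sasaExposedCounts(xyz, radii, probeRadius, pts)
  (exposed / nSpherePoints) * 4 * pi * (radii + probeRadius)^2
}

.coordsAndRadii <- function(x, radii = NULL) {
  if (is(x, "Structure")) {
    list(xyz = x@xyz, radii = x@atoms$radius)
  } else {
    list(xyz = as.matrix(x), radii = radii)
  }
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by the Shrake-Rupley test-point method: each atom carries
#' a deterministic golden-spiral point set on its probe-inflated sphere and
#' its area is the unoccluded fraction times `4 pi (r + probe)^2`.
#'
#' @param x a [Structure] with radii assigned (see [assignRadii()]), or an
#'   n x 3 coordinate matrix (then supply `radii`).
#' @param probeRadius probe radius in Angstrom (default 1.4, water).
#' @param nSpherePoints test points per atom (default 960).
#' @param radii numeric radii when `x` is a bare matrix.
#' @return a [SasaResult].
#' @examples
#' ## isolated atom: exactly the analytic sphere area
#' r <- sasa(matrix(0, 1, 3), radii = 1.6)
#' r@totalArea - 4 * pi * 3.0^2
#' @export
sasa <- function(x, probeRadius = 1.4, nSpherePoints = 960L, radii = NULL) {
  cr <- .coordsAndRadii(x, radii)
  per <- .sasaPerAtom(cr$xyz, cr$radii, probeRadius, as.integer(nSpherePoints))
  new("SasaResult", perAtomArea = per, totalArea = sum(per),
      probeRadius = probeRadius, nSpherePoints = as.integer(nSpherePoints))
}

#' Buried surface area between two atom groups
#'
#' `(SASA(A alone) + SASA(B alone) - SASA(A union B)) / 2` — the per-side
#' area convention.  Symmetric in the two groups; tiny negative round-off
#' is clamped to zero.  When every cross-group atom pair is separated by
#' more than `r_i + r_j + 2 probe`, the per-atom areas in the complex are
#' bitwise identical to the isolated ones and the result is exactly zero.
#'
#' @param groupA,groupB [Structure]s with radii assigned, or n x 3
#'   matrices (then supply `radiiA`/`radiiB`).
#' @param probeRadius probe radius, Angstrom.
#' @param nSpherePoints test points per atom.
#' @param radiiA,radiiB radii when matrices are passed.
#' @return a [BuriedSurface].
#' @export
buriedSurface <- function(groupA, groupB, probeRadius = 1.4,
                          nSpherePoints = 960L,
                          radiiA = NULL, radiiB = NULL) {
  a <- .coordsAndRadii(groupA, radiiA)
  b <- .coordsAndRadii(groupB, radiiB)
  if (nrow(a$xyz) == 0L || nrow(b$xyz) == 0L)
    stop("empty selection: buried surface needs two non-empty groups")
  nSpherePoints <- as.integer(nSpherePoints)
  perA <- .sasaPerAtom(a$xyz, a$radii, probeRadius, nSpherePoints)
  perB <- .sasaPerAtom(b$xyz, b$radii, probeRadius, nSpherePoints)
  perU <- .sasaPerAtom(rbind(a$xyz, b$xyz), c(a$radii, b$radii),
                       probeRadius, nSpherePoints)
  nA <- length(perA)
  areaA <- sum(perA)
  areaB <- sum(perB)
  ## sum the union per-atom areas group-wise so that, for fully separated
  ## groups, the cancellation (A + B - AB) is exact in floating point
  areaU <- sum(perU[seq_len(nA)]) + sum(perU[-seq_len(nA)])
  value <- (areaA + areaB - areaU) / 2
  if (abs(value) < 1e-9) value <- 0
  value <- max(0, value)
  new("BuriedSurface", value = value, groupAArea = areaA,
      groupBArea = areaB, complexArea = areaU)
}
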