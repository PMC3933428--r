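## Small geometry and parsing helpers shared across modules.

.deg2rad <- function(d) d * pi / 180

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, angle in degrees.
#'
#' @param deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotationX <- function(deg) {
  a <- .deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L, 3L)
}

#' @rdname rotationX
#' @export
rotationY <- function(deg) {
  a <- .deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
}

#' @rdname rotationX
#' @export
rotationZ <- function(deg) {
  a <- .deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation matrix about a (not necessarily unit) axis direction.
#'
#' @param axis numeric 3-vector, axis direction.
#' @param deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotationAboutAxis <- function(axis, deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be a nonzero vector")
  u <- axis / n
  a <- .deg2rad(deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L, 3L)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

## Angle between two vectors, degrees in [0, 180].
.angleDeg <- function(u, v) {
  c <- sum(.unit(u) * .unit(v))
  acos(max(-1, min(1, c))) * 180 / pi
}

## Absolute dihedral angle b1-a1-a2-b2 about the a1->a2 axis, degrees [0, 180].
.dihedralDeg <- function(b1, a1, a2, b2) {
  ax <- .unit(a2 - a1)
  v1 <- (b1 - a1) - sum((b1 - a1) * ax) * ax
  v2 <- (b2 - a2) - sum((b2 - a2) * ax) * ax
  if (.vnorm(v1) < 1e-9 || .vnorm(v2) < 1e-9) return(0)
  .angleDeg(v1, v2)
}

#' Parse a plain-text key-value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are returned as strings; callers coerce as needed.
#'
#' @param path file path.
#' @return named list of character values.
#' @export
readKeyValueConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed config line (no '='): '%s'", ln))
    key <- trimws(substr(ln, 1L, eq - 1L))
    val <- trimws(substr(ln, eq + 1L, nchar(ln)))
    if (!nzchar(key)) stop(sprintf("malformed config line (empty key): '%s'", ln))
    out[[key]] <- val
  }
  out
}

## Parse "1-60,70,80-90" into an inclusive-range integer matrix.
.parseRanges <- function(x) {
  if (is.null(x) || (is.character(x) && !nzchar(x)))
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("from", "to"))))
  if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    colnames(x) <- c("from", "to")
    return(x)
  }
  if (is.numeric(x)) {
    x <- as.integer(x)
    return(cbind(from = x, to = x))
  }
  parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1L]])
  parts <- parts[nzchar(parts)]
  rng <- t(vapply(parts, function(p) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      if (length(ab) != 2L || anyNA(ab)) stop(sprintf("bad residue range '%s'", p))
      ab
    } else {
      v <- as.integer(p)
      if (is.na(v)) stop(sprintf("bad residue number '%s'", p))
      c(v, v)
    }
  }, integer(2L)))
  dimnames(rng) <- list(NULL, c("from", "to"))
  rng
}
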