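## Independent oracles and shared fixtures for the test suite.
## The oracles deliberately use different algorithms/discretisations than
## the package implementation they check.

## shared toy system, built once
toySys <- makeToySystem()
toySel <- toySys$selections

## ---- dense-grid SASA oracle -------------------------------------------
## Equal-area latitude/longitude lattice on the unit sphere (uniform in z
## and in azimuth), a different discretisation than the golden spiral.
denseGridSphere <- function(n) {
  nz <- max(2L, round(sqrt(n / 2)))
  nphi <- ceiling(n / nz)
  z <- (seq_len(nz) - 0.5) / nz * 2 - 1
  phi <- (seq_len(nphi) - 0.5) / nphi * 2 * pi
  g <- expand.grid(z = z, phi = phi)
  r <- sqrt(pmax(0, 1 - g$z^2))
  cbind(r * cos(g$phi), r * sin(g$phi), g$z)
}

## brute-force total SASA: for each atom, integrate exposure over a dense
## equal-area grid with plain vectorised R distance tests
denseGridSasaTotal <- function(xyz, radii, probe = 1.4, nPerAtom = 1e5) {
  pts <- denseGridSphere(nPerAtom)
  total <- 0
  n <- nrow(xyz)
  for (i in seq_len(n)) {
    Ri <- radii[i] + probe
    p <- sweep(pts * Ri, 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, nrow(p))
    for (j in seq_len(n)) {
      if (j == i) next
      Rj <- radii[j] + probe
      if (sum((xyz[j, ] - xyz[i, ])^2) >= (Ri + Rj)^2) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & (d2 >= Rj^2)
    }
    total <- total + mean(exposed) * 4 * pi * Ri^2
  }
  total
}

denseGridBuried <- function(xyzA, radiiA, xyzB, radiiB, probe = 1.4,
                            nPerAtom = 1e5) {
  a <- denseGridSasaTotal(xyzA, radiiA, probe, nPerAtom)
  b <- denseGridSasaTotal(xyzB, radiiB, probe, nPerAtom)
  u <- denseGridSasaTotal(rbind(xyzA, xyzB), c(radiiA, radiiB), probe, nPerAtom)
  (a + b - u) / 2
}

## ---- numerical-optimisation superposition oracle ----------------------
quatToRot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L)
}

## minimise RMSD over unit-quaternion rotations (translation eliminated by
## centring), multi-start Nelder-Mead
oracleMinRmsd <- function(mobile, reference, nStart = 12) {
  M <- sweep(mobile, 2L, colMeans(mobile))
  Rf <- sweep(reference, 2L, colMeans(reference))
  f <- function(par) {
    R <- quatToRot(par)
    sqrt(mean(rowSums((M %*% t(R) - Rf)^2)))
  }
  best <- Inf
  for (s in seq_len(nStart)) {
    par0 <- rnorm(4)
    r <- optim(par0, f, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
    r <- optim(r$par, f, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
    best <- min(best, r$value)
  }
  best
}

## ---- random generators -------------------------------------------------
randomRotation <- function() {
  quatToRot(rnorm(4))
}

randomTransform <- function(shift = 10) {
  rigidTransform(randomRotation(), rnorm(3, sd = shift))
}

randomCluster <- function(n, spread = 3) {
  matrix(rnorm(3 * n, sd = spread), ncol = 3L)
}

## a random multi-chain structure with valid identities for round-trip tests
randomStructure <- function(nChains = 2, resPerChain = 5, atomsPerRes = 3) {
  chains <- LETTERS[seq_len(nChains)]
  names <- c("N", "CA", "C", "O", "CB")[seq_len(atomsPerRes)]
  rows <- expand.grid(name = names, resno = seq_len(resPerChain),
                      chain = chains, stringsAsFactors = FALSE)
  rows <- rows[order(match(rows$chain, chains), rows$resno), ]
  n <- nrow(rows)
  atoms <- data.frame(serial = seq_len(n), name = rows$name, resid = "ALA",
                      chain = rows$chain, resno = rows$resno,
                      insert = "", alt = "",
                      element = substr(rows$name, 1L, 1L),
                      radius = NA_real_, stringsAsFactors = FALSE)
  xyz <- matrix(round(runif(3 * n, -99, 999), 3), ncol = 3L)
  Structure(atoms, xyz)
}

describeToy <- function(frame) {
  describeDimer(frame, toySel$monomer1, toySel$monomer2,
                toySel$bindingSite1, toySel$bindingSite2,
                toySel$interfaceAnchor1, toySel$interfaceAnchor2)
}

classifyToy <- function(frame, ...) {
  classifyFrame(frame, toySel$monomer1, toySel$monomer2, toySys$template, ...)
}
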