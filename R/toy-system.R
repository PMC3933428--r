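## Synthetic rigid-body dimer/ligand systems with closed-form ground truth.
##
## The toy monomer is an elongated deterministic lattice rod (a stand-in
## for an Ig-domain subunit); the toy ligand is a tandem pair of
## quasi-spherical shell domains (distal binding domain + proximal
## carboxy-terminal domain), mirroring the elongated two-domain ligand
## geometry that makes bivalent binding sterically conditional on the
## dimer opening angle.  Every body is deterministic; only the jitter and
## the frame-order shuffle consume random numbers, from a fixed, recorded
## generator ("Mersenne-Twister/Inversion").

RNG_ALGORITHM_ID <- "Mersenne-Twister/Inversion"

.setSeed <- function(seed) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

#' Toy system specification
#'
#' @param monomerAtoms,monomerLength,monomerRadius rod atom count, length
#'   and lattice radius (Angstrom).
#' @param ligandDomainAtoms,ligandDomainRadius atoms and shell radius of
#'   each ligand domain.
#' @param ligandDomainSeparation centre distance between the ligand's two
#'   domains.
#' @param ligandStandoff gap between monomer tip and binding-domain centre.
#' @param interfaceOffset lateral spacing of the two subunits at the base.
#' @param seed integer seed recorded with the system.
#' @return a [ToySystemSpec].
#' @export
toySystemSpec <- function(monomerAtoms = 60L, monomerLength = 30,
                          monomerRadius = 3, ligandDomainAtoms = 24L,
                          ligandDomainRadius = 3,
                          ligandDomainSeparation = 12, ligandStandoff = 6,
                          interfaceOffset = 2, seed = 1L) {
  new("ToySystemSpec", monomerAtoms = as.integer(monomerAtoms),
      monomerLength = monomerLength, monomerRadius = monomerRadius,
      ligandDomainAtoms = as.integer(ligandDomainAtoms),
      ligandDomainRadius = ligandDomainRadius,
      ligandDomainSeparation = ligandDomainSeparation,
      ligandStandoff = ligandStandoff, interfaceOffset = interfaceOffset,
      seed = as.integer(seed))
}

#' Synthetic ensemble specification
#'
#' @param nFrames frame count.
#' @param openingAngleMean,openingAngleSd continuum-mode opening angle
#'   distribution (degrees); in two-regime mode `openingAngleSd` is the
#'   within-regime spread.
#' @param twistMean,twistSd subunit twist distribution (degrees).
#' @param atomJitterSd per-atom Gaussian jitter (Angstrom).
#' @param bivalentFractionTarget two-regime target fraction, or NA for the
#'   continuum mode.
#' @param compactAngle,openAngle the two regime means (degrees).
#' @param seed integer RNG seed.
#' @param trajectoryId trajectory label.
#' @return an [EnsembleSpec].
#' @export
ensembleSpec <- function(nFrames = 200L, openingAngleMean = 45,
                         openingAngleSd = 0, twistMean = 0, twistSd = 0,
                         atomJitterSd = 0.05,
                         bivalentFractionTarget = NA_real_,
                         compactAngle = 5, openAngle = 80, seed = 1L,
                         trajectoryId = "synthetic-1") {
  new("EnsembleSpec", nFrames = as.integer(nFrames),
      openingAngleMean = openingAngleMean, openingAngleSd = openingAngleSd,
      twistMean = twistMean, twistSd = twistSd, atomJitterSd = atomJitterSd,
      bivalentFractionTarget = as.numeric(bivalentFractionTarget),
      compactAngle = compactAngle, openAngle = openAngle,
      seed = as.integer(seed), trajectoryId = trajectoryId)
}

## Deterministic lattice rod along +z built from antipodal atom pairs
## (+x,+y,z) / (-x,-y,z) on a golden-angle spiral.  The pairing zeroes the
## xz and yz covariances, so the rod's first principal axis is exactly the
## z axis -- which makes opening-angle identities of the dimer descriptors
## hold to numerical precision rather than approximately.
.rodCoords <- function(n, length, radius) {
  np <- n %/% 2L
  i <- seq_len(np) - 1
  phi <- i * pi * (3 - sqrt(5))
  z <- if (np > 1L) i / (np - 1) * length else rep(length / 2, np)
  base <- cbind(radius * cos(phi), radius * sin(phi), z)
  out <- rbind(base, cbind(-base[, 1L], -base[, 2L], base[, 3L]))
  if (n %% 2L == 1L) out <- rbind(out, c(0, 0, length / 2))
  colnames(out) <- c("x", "y", "z")
  out
}

.bodyStructure <- function(xyz, chain, resid, resnoStart = 1L,
                           serialStart = 1L) {
  n <- nrow(xyz)
  Structure(data.frame(
    serial = serialStart + seq_len(n) - 1L,
    name = "CA", resid = resid, chain = chain,
    resno = resnoStart + seq_len(n) - 1L,
    insert = "", alt = "", element = "C", radius = NA_real_,
    stringsAsFactors = FALSE), xyz)
}

#' Build the toy receptor/ligand system and its binding-mode template
#'
#' Constructs the toy monomer (chain `R`, elongated rod based at the
#' origin, tip at `monomerLength` on +z), the tandem two-domain ligand
#' (chain `L`, binding domain centred `ligandStandoff` above the tip,
#' carboxy-terminal domain a further `ligandDomainSeparation` out), the
#' [BindingTemplate] encoding their bound pose, and the named selections
#' used throughout the pipeline.
#'
#' @param spec a [ToySystemSpec].
#' @return list with elements `monomer`, `ligand`, `template` (a
#'   [BindingTemplate]), `selections` (monomer1/monomer2 chains,
#'   interface anchors, binding sites, ligand C-term) and `geometry`
#'   (closed-form constants: `cTermCentroidDistance`, domain radius,
#'   interface offset).
#' @examples
#' sys <- makeToySystem()
#' sys$template
#' @export
makeToySystem <- function(spec = toySystemSpec()) {
  n <- spec@monomerAtoms
  m <- spec@ligandDomainAtoms
  monomer <- .bodyStructure(.rodCoords(n, spec@monomerLength, spec@monomerRadius),
                            chain = "R", resid = "GLY")
  shell <- goldenSpiralPoints(m) * spec@ligandDomainRadius
  zBind <- spec@monomerLength + spec@ligandStandoff
  zCterm <- zBind + spec@ligandDomainSeparation
  ligXyz <- rbind(sweep(shell, 2L, c(0, 0, zBind), "+"),
                  sweep(shell, 2L, c(0, 0, zCterm), "+"))
  ligand <- .bodyStructure(ligXyz, chain = "L", resid = "LIG",
                           serialStart = n + 1L)
  complexAtoms <- rbind(monomer@atoms, ligand@atoms)
  complexAtoms$serial <- seq_len(nrow(complexAtoms))
  complex <- Structure(complexAtoms, rbind(monomer@xyz, ligand@xyz))
  template <- bindingTemplate(
    complex,
    receptorFit = atomSelection(chains = "R", atomNames = "CA"),
    ligand = atomSelection(chains = "L"),
    ligandCterm = atomSelection(chains = "L",
                                residues = cbind(m + 1L, 2L * m)))
  anchorRes <- cbind(1L, min(5L, n))
  siteRes <- cbind(max(1L, n - 4L), n)
  list(
    monomer = monomer,
    ligand = ligand,
    template = template,
    selections = list(
      monomer1 = atomSelection(chains = "A"),
      monomer2 = atomSelection(chains = "B"),
      monomerFit = atomSelection(atomNames = "CA"),
      interfaceAnchor1 = atomSelection(chains = "A", residues = anchorRes),
      interfaceAnchor2 = atomSelection(chains = "B", residues = anchorRes),
      bindingSite1 = atomSelection(chains = "A", residues = siteRes),
      bindingSite2 = atomSelection(chains = "B", residues = siteRes),
      ligandCterm = atomSelection(residues = cbind(m + 1L, 2L * m))),
    geometry = list(
      cTermCentroidDistance = zCterm,
      ligandDomainRadius = spec@ligandDomainRadius,
      interfaceOffset = spec@interfaceOffset,
      spec = spec))
}

#' Rigid transforms placing the two subunits of a toy dimer frame
#'
#' Subunit 1 is the monomer tilted by half the opening angle about y
#' (after an own-axis twist about z) and shifted by half the interface
#' offset along +x; subunit 2 is subunit 1 rotated 180 degrees about z,
#' so every frame has exact C2 symmetry about the z axis.
#'
#' @param openingAngle,twist degrees.
#' @param interfaceOffset Angstrom.
#' @return list of two [RigidTransform]s `T1`, `T2`.
#' @export
dimerFrameTransforms <- function(openingAngle, twist = 0,
                                 interfaceOffset = 2) {
  R1 <- rotationY(openingAngle / 2) %*% rotationZ(twist)
  T1 <- rigidTransform(R1, c(interfaceOffset / 2, 0, 0))
  C2 <- rigidTransform(rotationZ(180), c(0, 0, 0))
  list(T1 = T1, T2 = composeTransforms(C2, T1))
}

#' Build one toy dimer frame
#'
#' Two rigid copies of the monomer about a C2 axis with the given opening
#' angle and twist (see [dimerFrameTransforms()]), chains `A` and `B`,
#' plus optional i.i.d. Gaussian coordinate jitter.  Deterministic for a
#' fixed seed.
#'
#' @param monomer single-chain monomer [Structure] (rod along +z, base at
#'   the origin).
#' @param openingAngle degrees, in \[0, 120\].
#' @param twist own-axis twist, degrees.
#' @param jitterSd per-atom Gaussian jitter sd, Angstrom.
#' @param seed RNG seed for the jitter.
#' @param interfaceOffset lateral base spacing, Angstrom.
#' @return dimer [Structure] with chains `A` and `B`.
#' @export
makeDimerFrame <- function(monomer, openingAngle, twist = 0, jitterSd = 0,
                           seed = 1L, interfaceOffset = 2) {
  if (openingAngle < 0 || openingAngle > 120)
    stop("openingAngle must lie in [0, 120] degrees")
  tr <- dimerFrameTransforms(openingAngle, twist, interfaceOffset)
  s1 <- .relabelChain(applyTransform(monomer, tr$T1), "A")
  s2 <- .relabelChain(applyTransform(monomer, tr$T2), "B")
  a <- rbind(s1@atoms, s2@atoms)
  a$serial <- seq_len(nrow(a))
  xyz <- rbind(s1@xyz, s2@xyz)
  if (jitterSd > 0) {
    .setSeed(seed)
    xyz <- xyz + matrix(rnorm(length(xyz), sd = jitterSd), ncol = 3L)
  }
  Structure(a, xyz)
}

## minimum cross distance between two coordinate sets
.minCrossDist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Generate a synthetic dimer ensemble with ground-truth valency
#'
#' Draws per-frame opening angles and twists according to the
#' [EnsembleSpec], builds each frame with [makeDimerFrame()] (plus jitter),
#' and computes the closed-form ground truth: a frame is bivalent iff the
#' minimum distance between the two would-be docked ligand carboxy-terminal
#' domains (the template ligand under the exact construction transforms)
#' exceeds the occlusion bound `2 * (maxRadius + probeRadius)`, beyond
#' which buried surface is exactly zero.  In two-regime mode the regimes
#' are chosen so every frame clears the bound by a wide margin on its own
#' side, making classifier agreement exact.
#'
#' @param system a toy system from [makeToySystem()].
#' @param spec an [EnsembleSpec].
#' @param probeRadius,maxRadius parameters of the occlusion bound used for
#'   ground truth (defaults: water probe 1.4 A, carbon radius 1.7 A).
#' @return list with `ensemble` (an [Ensemble]), `groundTruth`
#'   (data.frame: `frame_index`, `opening_angle_deg`, `twist_deg`,
#'   `min_cterm_distance_A`, `margin_A`, `bivalent_true`),
#'   `realisedFraction`, and `rngAlgorithm`.
#' @examples
#' sys <- makeToySystem()
#' gen <- generateToyEnsemble(sys, ensembleSpec(nFrames = 10,
#'   bivalentFractionTarget = 0.5, seed = 7))
#' gen$realisedFraction
#' @export
generateToyEnsemble <- function(system, spec = ensembleSpec(),
                                probeRadius = 1.4, maxRadius = 1.7) {
  n <- spec@nFrames
  .setSeed(spec@seed)
  target <- spec@bivalentFractionTarget
  if (!is.na(target)) {
    nOpen <- as.integer(round(target * n))
    planned <- c(rep(TRUE, nOpen), rep(FALSE, n - nOpen))
    planned <- planned[sample.int(n)]
    angles <- ifelse(planned, spec@openAngle, spec@compactAngle)
    if (spec@openingAngleSd > 0)
      angles <- angles + rnorm(n, 0, spec@openingAngleSd)
  } else {
    angles <- rnorm(n, spec@openingAngleMean, spec@openingAngleSd)
  }
  angles <- pmin(120, pmax(0, angles))
  twists <- if (spec@twistSd > 0 || spec@twistMean != 0)
    rnorm(n, spec@twistMean, spec@twistSd) else rep(0, n)

  off <- system$geometry$interfaceOffset
  bound <- 2 * (maxRadius + probeRadius)
  ligCt <- subsetStructure(
    system$template@complex,
    resolveSelection(system$template@complex,
                     system$template@ligandCterm))@xyz

  frames <- vector("list", n)
  minDist <- numeric(n)
  nAtomsFrame <- 2L * nrow(system$monomer@atoms)
  for (i in seq_len(n)) {
    f <- makeDimerFrame(system$monomer, angles[i], twists[i], jitterSd = 0,
                        interfaceOffset = off)
    if (spec@atomJitterSd > 0)
      f@xyz <- f@xyz + matrix(rnorm(3L * nAtomsFrame, sd = spec@atomJitterSd),
                              ncol = 3L)
    frames[[i]] <- f
    tr <- dimerFrameTransforms(angles[i], twists[i], off)
    minDist[i] <- .minCrossDist(applyTransform(ligCt, tr$T1),
                                applyTransform(ligCt, tr$T2))
  }
  flags <- minDist > bound
  gt <- data.frame(frame_index = seq_len(n) - 1L,
                   opening_angle_deg = angles,
                   twist_deg = twists,
                   min_cterm_distance_A = minDist,
                   margin_A = abs(minDist - bound),
                   bivalent_true = flags)
  list(ensemble = new("Ensemble", frames = frames,
                      trajectoryId = spec@trajectoryId,
                      frameTimes = as.numeric(seq_len(n) - 1L)),
       groundTruth = gt,
       realisedFraction = mean(flags),
       rngAlgorithm = RNG_ALGORITHM_ID)
}

#' Write a complete toy bundle to disk
#'
#' Emits everything the command-line pipeline consumes: the multi-model
#' ensemble PDB, the template PDB, the template selection config, a
#' pipeline config, and `ground_truth.csv`.
#'
#' @param dir output directory (created if needed).
#' @param system toy system from [makeToySystem()].
#' @param generated result of [generateToyEnsemble()].
#' @return invisibly, the named vector of file paths written.
#' @export
writeToyBundle <- function(dir, system, generated) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- system$geometry$spec@ligandDomainAtoms
  paths <- c(ensemble = file.path(dir, "ensemble.pdb"),
             template = file.path(dir, "template.pdb"),
             templateConfig = file.path(dir, "template_config.txt"),
             pipelineConfig = file.path(dir, "pipeline_config.txt"),
             groundTruth = file.path(dir, "ground_truth.csv"))
  writePdb(generated$ensemble, paths[["ensemble"]])
  writePdb(system$template@complex, paths[["template"]])
  writeLines(c("receptor_chain = R",
               "ligand_chain = L",
               sprintf("ligand_cterm_residues = %d-%d", m + 1L, 2L * m),
               "receptor_fit_atoms = CA"),
             paths[["templateConfig"]])
  writeLines(c("monomer1_chains = A", "monomer2_chains = B",
               "probe_radius = 1.4", "n_sphere_points = 960",
               "zero_tolerance = 1.0", "stride = 1",
               "scoring_mode = cterm_domain", "rmsd_ceiling = 3.0"),
             paths[["pipelineConfig"]])
  gt <- generated$groundTruth
  num <- vapply(gt, is.double, logical(1))
  gt[num] <- lapply(gt[num], function(v) format(v, digits = 15, trim = TRUE))
  write.csv(gt, paths[["groundTruth"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
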