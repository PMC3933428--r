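## a dimer frame whose chain-A monomer is an exact copy of the template
## receptor is the reference case for self-docking
selfFrame <- function() {
  makeDimerFrame(toySys$monomer, 0, interfaceOffset = 0)
}

test_that("self-docking reproduces the template ligand exactly", {
  tpl <- toySys$template
  frame <- selfFrame()
  ## chain A at opening 0 with zero offset coincides with the template receptor
  d <- dockOne(frame, toySel$monomer1, tpl)
  ligT <- subsetStructure(tpl@complex,
                          resolveSelection(tpl@complex, tpl@ligandSel))
  expect_lt(d$fitRmsd, 1e-9)
  expect_lt(max(abs(coords(d$ligand) - coords(ligT))), 1e-6)
})

test_that("docking is equivariant under rigid motions of the frame", {
  set.seed(30)
  frame <- makeDimerFrame(toySys$monomer, 25,
                          interfaceOffset = toySys$geometry$interfaceOffset)
  base <- dockOne(frame, toySel$monomer1, toySys$template)
  for (k in 1:10) {
    tr <- randomTransform()
    moved <- dockOne(applyTransform(frame, tr), toySel$monomer1, toySys$template)
    expect_lt(max(abs(coords(moved$ligand) -
                      applyTransform(coords(base$ligand), tr))), 1e-6)
  }
})

test_that("fit RMSD on a jittered monomer matches the independent superposition module", {
  set.seed(31)
  frame <- makeDimerFrame(toySys$monomer, 10, jitterSd = 0.2, seed = 99,
                          interfaceOffset = toySys$geometry$interfaceOffset)
  d <- dockOne(frame, toySel$monomer1, toySys$template)
  ## cross-check: relabel the frame monomer to the template's receptor chain
  ## and recompute with rmsdAfterFit
  mono <- subsetStructure(frame, resolveSelection(frame, toySel$monomer1))
  mono@atoms$chain <- rep("R", nAtoms(mono))
  recep <- subsetStructure(
    toySys$template@complex,
    resolveSelection(toySys$template@complex, atomSelection(chains = "R")))
  expect_equal(d$fitRmsd,
               rmsdAfterFit(mono, recep, atomSelection(atomNames = "CA")),
               tolerance = 1e-9)
  expect_gt(d$fitRmsd, 0)
})

test_that("docking never moves receptor atoms", {
  frame <- makeDimerFrame(toySys$monomer, 30,
                          interfaceOffset = toySys$geometry$interfaceOffset)
  docked <- dockDimer(frame, toySel$monomer1, toySel$monomer2, toySys$template)
  expect_identical(coords(docked@dimer), coords(frame))
})

test_that("dockDimer respects the dimer's C2 symmetry and relabels ligand chains", {
  frame <- makeDimerFrame(toySys$monomer, 40,
                          interfaceOffset = toySys$geometry$interfaceOffset)
  docked <- dockDimer(frame, toySel$monomer1, toySel$monomer2, toySys$template)
  ## the toy dimer is exactly C2 about z: ligand2 = Rz(180) ligand1
  c2 <- rigidTransform(rotationZ(180))
  expect_lt(max(abs(coords(docked@ligand2) -
                    applyTransform(coords(docked@ligand1), c2))), 1e-6)
  chains <- c(unique(atomTable(docked@ligand1)$chain),
              unique(atomTable(docked@ligand2)$chain))
  expect_length(unique(chains), 2L)
  expect_false(any(chains %in% atomTable(frame)$chain))
})

test_that("swapping the monomer selections swaps the ligands", {
  frame <- makeDimerFrame(toySys$monomer, 35,
                          interfaceOffset = toySys$geometry$interfaceOffset)
  d12 <- dockDimer(frame, toySel$monomer1, toySel$monomer2, toySys$template)
  d21 <- dockDimer(frame, toySel$monomer2, toySel$monomer1, toySys$template)
  expect_equal(coords(d12@ligand1), coords(d21@ligand2), tolerance = 1e-12)
  expect_equal(coords(d12@ligand2), coords(d21@ligand1), tolerance = 1e-12)
})

test_that("compact geometry overlaps the docked ligands; open geometry separates them", {
  m <- toySys$geometry$spec@ligandDomainAtoms
  ctPos <- (m + 1L):(2L * m) + m * 0L  # positions of C-term atoms in ligand block
  getCt <- function(docked, which) {
    lig <- if (which == 1L) docked@ligand1 else docked@ligand2
    coords(lig)[atomTable(lig)$resno > m, , drop = FALSE]
  }
  compact <- dockDimer(makeDimerFrame(toySys$monomer, 0,
                                      interfaceOffset = toySys$geometry$interfaceOffset),
                       toySel$monomer1, toySel$monomer2, toySys$template)
  dCompact <- min(as.matrix(dist(rbind(getCt(compact, 1), getCt(compact, 2))))[
    seq_len(m), m + seq_len(m)])
  expect_lt(dCompact, 2 * (1.7 + 1.4))
  open <- dockDimer(makeDimerFrame(toySys$monomer, 80,
                                   interfaceOffset = toySys$geometry$interfaceOffset),
                    toySel$monomer1, toySel$monomer2, toySys$template)
  dOpen <- min(as.matrix(dist(rbind(getCt(open, 1), getCt(open, 2))))[
    seq_len(m), m + seq_len(m)])
  expect_gt(dOpen, 2 * (1.7 + 1.4))
})

test_that("distorted monomers trigger a dock-quality warning, not an error", {
  frame <- makeDimerFrame(toySys$monomer, 20, jitterSd = 1.0, seed = 5,
                          interfaceOffset = toySys$geometry$interfaceOffset)
  expect_warning(d <- dockOne(frame, toySel$monomer1, toySys$template,
                              rmsdCeiling = 0.1), "dock-quality")
  expect_true(d$qualityFlag)
})

test_that("atom-pairing mismatches raise a pairing error", {
  frame <- makeDimerFrame(toySys$monomer, 20,
                          interfaceOffset = toySys$geometry$interfaceOffset)
  badSel <- atomSelection(chains = "A", residues = "1-10")
  expect_error(dockOne(frame, badSel, toySys$template), "pairing error")
})

test_that("template bundles round-trip through PDB + config files", {
  dir <- withr::local_tempdir()
  writePdb(toySys$template@complex, file.path(dir, "template.pdb"))
  m <- toySys$geometry$spec@ligandDomainAtoms
  writeLines(c("receptor_chain = R", "ligand_chain = L",
               sprintf("ligand_cterm_residues = %d-%d", m + 1L, 2L * m),
               "receptor_fit_atoms = CA"),
             file.path(dir, "cfg.txt"))
  tpl <- readTemplateBundle(file.path(dir, "template.pdb"),
                            file.path(dir, "cfg.txt"))
  expect_s4_class(tpl, "BindingTemplate")
  frame <- makeDimerFrame(toySys$monomer, 60,
                          interfaceOffset = toySys$geometry$interfaceOffset)
  a <- dockOne(frame, toySel$monomer1, toySys$template)
  b <- dockOne(frame, toySel$monomer1, tpl)
  expect_lt(max(abs(coords(a$ligand) - coords(b$ligand))), 1e-3)
})
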