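pdbLine <- function(serial, name, resid, chain, resno, x, y, z,
                    occ = 1.0, alt = " ", element = "C") {
  sprintf("ATOM  %5d  %-3s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resid, chain, resno, x, y, z, occ, 0.0, element)
}

test_that("a handcrafted ATOM block is parsed with exact identities and coordinates", {
  lines <- c(pdbLine(1, "N", "GLY", "A", 1, 1.234, -2.5, 3.75),
             pdbLine(2, "CA", "GLY", "A", 1, 4.0, 5.125, -6.25),
             pdbLine(3, "C", "GLY", "A", 2, 7.5, 8.0, 9.001))
  s <- readPdb(lines)
  expect_s4_class(s, "Structure")
  expect_equal(nAtoms(s), 3L)
  expect_equal(atomTable(s)$name, c("N", "CA", "C"))
  expect_equal(atomTable(s)$resno, c(1L, 1L, 2L))
  expect_equal(coords(s)[2, ], c(x = 4.0, y = 5.125, z = -6.25),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("MODEL blocks become ensemble frames and topology is verified", {
  block <- c(pdbLine(1, "CA", "GLY", "A", 1, 0, 0, 0),
             pdbLine(2, "CA", "GLY", "A", 2, 1, 1, 1),
             pdbLine(3, "CB", "ALA", "B", 1, 2, 2, 2))
  twoModels <- c("MODEL        1", block, "ENDMDL",
                 "MODEL        2", block, "ENDMDL", "END")
  e <- readPdb(twoModels, modelPolicy = "all")
  expect_s4_class(e, "Ensemble")
  expect_equal(nFrames(e), 2L)
  expect_identical(coords(getFrame(e, 1)), coords(getFrame(e, 2)))
  ## "first" policy returns just the first model
  expect_equal(nAtoms(readPdb(twoModels, modelPolicy = "first")), 3L)
  ## atom order permuted between models -> topology error
  permuted <- c("MODEL        1", block, "ENDMDL",
                "MODEL        2", block[c(2, 1, 3)], "ENDMDL", "END")
  expect_error(readPdb(permuted, modelPolicy = "all"), "topology")
})

test_that("malformed coordinate fields are reported with their line number", {
  lines <- c(pdbLine(1, "CA", "GLY", "A", 1, 0, 0, 0),
             "ATOM      2  CA  GLY A   2      xx.xxx   0.000   0.000  1.00  0.00           C")
  expect_error(readPdb(lines), "line 2")
})

test_that("alt-locs resolve to highest occupancy with ties to first encountered", {
  lines <- c(pdbLine(1, "CA", "GLY", "A", 1, 1, 0, 0, occ = 0.4, alt = "A"),
             pdbLine(2, "CA", "GLY", "A", 1, 2, 0, 0, occ = 0.6, alt = "B"),
             pdbLine(3, "CB", "GLY", "A", 1, 3, 0, 0, occ = 0.5, alt = "A"),
             pdbLine(4, "CB", "GLY", "A", 1, 4, 0, 0, occ = 0.5, alt = "B"))
  s <- readPdb(lines)
  expect_equal(nAtoms(s), 2L)
  expect_equal(coords(s)[, "x"], c(2, 3), ignore_attr = TRUE)
})

test_that("HETATM and waters are excluded by default", {
  lines <- c(pdbLine(1, "CA", "GLY", "A", 1, 0, 0, 0),
             sub("^ATOM  ", "HETATM", pdbLine(2, "ZN", "ZN", "A", 90, 1, 1, 1)),
             pdbLine(3, "O", "HOH", "W", 1, 2, 2, 2))
  expect_equal(nAtoms(readPdb(lines)), 1L)
  expect_equal(nAtoms(readPdb(lines, includeHet = TRUE)), 2L)
  expect_equal(nAtoms(readPdb(lines, includeHet = TRUE, keepWaters = TRUE)), 3L)
})

test_that("write -> read round-trip is the identity on identities and coordinates", {
  set.seed(42)
  for (k in 1:15) {
    s <- randomStructure(nChains = sample(1:3, 1), resPerChain = sample(2:6, 1))
    tmp <- withr::local_tempfile(fileext = ".pdb")
    writePdb(s, tmp)
    r <- readPdb(tmp)
    expect_identical(atomTable(r)[c("name", "resid", "chain", "resno", "insert")],
                     atomTable(s)[c("name", "resid", "chain", "resno", "insert")])
    expect_lt(max(abs(coords(r) - coords(s))), 5e-4 + 1e-12)
  }
})

test_that("the written PDB is readable by an independent parser (bio3d)", {
  skip_if_not_installed("bio3d")
  set.seed(7)
  s <- randomStructure(nChains = 2)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writePdb(s, tmp)
  b <- bio3d::read.pdb(tmp)
  expect_equal(nrow(b$atom), nAtoms(s))
  expect_equal(matrix(b$xyz, ncol = 3, byrow = TRUE), unname(coords(s)),
               tolerance = 1e-3)
  expect_equal(b$atom$resno, atomTable(s)$resno)
  expect_equal(b$atom$elety, atomTable(s)$name)
})

test_that("ensembles write as one MODEL block per frame and round-trip", {
  set.seed(11)
  s <- randomStructure()
  frames <- lapply(1:3, function(i) {
    f <- s
    coords(f) <- round(coords(s) + i, 3)
    f
  })
  e <- new("Ensemble", frames = frames, trajectoryId = "t",
           frameTimes = c(0, 1, 2))
  tmp <- withr::local_tempfile(fileext = ".pdb")
  lines <- writePdb(e, tmp)
  expect_equal(sum(startsWith(lines, "MODEL")), 3L)
  r <- readPdb(tmp, modelPolicy = "all")
  expect_equal(nFrames(r), 3L)
  expect_lt(max(abs(coords(getFrame(r, 3)) - coords(frames[[3]]))), 5e-4)
})

test_that("coordinates outside the fixed-width field are a format error", {
  s <- randomStructure()
  xyz <- coords(s)
  xyz[1, 1] <- 10000
  coords(s) <- xyz
  expect_error(writePdb(s, withr::local_tempfile()), "format error")
})

test_that("selections intersect criteria and resolve deterministically", {
  s <- randomStructure(nChains = 2, resPerChain = 6, atomsPerRes = 3)
  iA <- resolveSelection(s, atomSelection(chains = "A"))
  expect_identical(iA, which(atomTable(s)$chain == "A"))
  i13 <- resolveSelection(s, atomSelection(chains = "A", residues = "1-3"))
  expect_true(all(atomTable(s)$resno[i13] <= 3))
  iCA <- resolveSelection(s, atomSelection(atomNames = "CA"))
  expect_equal(length(iCA), 12L)  # one CA per residue
  ## idempotence / order stability
  expect_identical(resolveSelection(s, atomSelection(chains = "A")), iA)
  expect_true(all(diff(iA) > 0))
  ## union of a residue-range partition equals the full-chain selection
  parts <- c(resolveSelection(s, atomSelection(chains = "A", residues = "1-3")),
             resolveSelection(s, atomSelection(chains = "A", residues = "4-6")))
  expect_identical(sort(parts), iA)
  expect_error(resolveSelection(s, atomSelection(chains = "Z")), "empty selection")
})

test_that("radius assignment uses the table, defaults, and errors on unknowns", {
  s <- randomStructure()
  s2 <- assignRadii(s, c(C = 1.70, N = 1.55, O = 1.52))
  expect_equal(atomTable(s2)$radius[atomTable(s2)$name == "CA"][1], 1.70)
  expect_identical(coords(s2), coords(s))
  sx <- randomStructure()
  sx@atoms$element[1] <- "X"
  expect_error(assignRadii(sx), "radius assignment error")
  expect_warning(sy <- assignRadii(sx, defaultRadius = 1.5), "default")
  expect_equal(atomTable(sy)$radius[1], 1.5)
})

test_that("radius tables read from two-column text", {
  tmp <- withr::local_tempfile(lines = c("# element radius", "C 1.70", "N  1.55"))
  tab <- readRadiusTable(tmp)
  expect_equal(tab[["C"]], 1.70)
  expect_equal(tab[["N"]], 1.55)
})
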