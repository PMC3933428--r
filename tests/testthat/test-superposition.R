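test_that("kabschFit recovers exact rigid motions and the identity", {
  set.seed(1)
  ref <- randomCluster(12)
  id <- kabschFit(ref, ref)
  expect_equal(id$transform@rotation, diag(3), tolerance = 1e-10)
  expect_equal(id$transform@translation, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(id$rmsd, 1e-10)
  ## 90 degrees about z plus a shift is inverted exactly
  tr <- rigidTransform(rotationZ(90), c(5, 0, 0))
  mob <- applyTransform(ref, tr)
  fit <- kabschFit(mob, ref)
  expect_lt(fit$rmsd, 1e-6)
  back <- composeTransforms(fit$transform, tr)
  expect_equal(back@rotation, diag(3), tolerance = 1e-8)
  expect_equal(back@translation, c(0, 0, 0), tolerance = 1e-8)
})

test_that("kabschFit rmsd matches a numerical-optimisation oracle under noise", {
  set.seed(2)
  for (k in 1:5) {
    ref <- randomCluster(10)
    mob <- applyTransform(ref, randomTransform()) +
      matrix(rnorm(30, sd = 0.1), ncol = 3)
    fit <- kabschFit(mob, ref)
    expect_equal(fit$rmsd, oracleMinRmsd(mob, ref), tolerance = 1e-6)
  }
})

test_that("kabschFit rmsd agrees with bio3d's least-squares fit", {
  skip_if_not_installed("bio3d")
  set.seed(3)
  ref <- randomCluster(20)
  mob <- applyTransform(ref, randomTransform()) +
    matrix(rnorm(60, sd = 0.2), ncol = 3)
  fit <- kabschFit(mob, ref)
  xyzRef <- as.numeric(t(ref))
  xyzMob <- as.numeric(t(mob))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyzRef, mobile = xyzMob))
  oracle <- sqrt(mean(colSums(matrix((fitted - xyzRef)^2, nrow = 3))))
  expect_equal(fit$rmsd, oracle, tolerance = 1e-6)
})

test_that("fitted rotations are always proper, even for near-planar inputs", {
  set.seed(4)
  for (k in 1:25) {
    ref <- randomCluster(8)
    ref[, 3] <- ref[, 3] * 1e-6  # nearly planar
    mob <- applyTransform(ref, randomTransform())
    fit <- kabschFit(mob, ref)
    expect_equal(det(fit$transform@rotation), 1, tolerance = 1e-8)
  }
})

test_that("degenerate inputs raise degeneracy errors", {
  expect_error(kabschFit(matrix(0, 2, 3), matrix(0, 2, 3)), "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))  # collinear
  expect_error(kabschFit(line, line), "collinear")
})

test_that("the fitted rmsd is a minimum under rotation perturbations", {
  set.seed(5)
  ref <- randomCluster(15)
  mob <- applyTransform(ref, randomTransform()) +
    matrix(rnorm(45, sd = 0.3), ncol = 3)
  fit <- kabschFit(mob, ref)
  for (k in 1:20) {
    pert <- composeTransforms(
      rigidTransform(rotationAboutAxis(rnorm(3), runif(1, 0.5, 5))),
      fit$transform)
    moved <- applyTransform(mob, pert)
    ## re-centre the perturbed pose optimally before comparing
    moved <- sweep(moved, 2L, colMeans(moved) - colMeans(ref))
    rmsdPert <- sqrt(mean(rowSums((moved - ref)^2)))
    expect_gte(rmsdPert, fit$rmsd - 1e-9)
  }
})

test_that("rmsdAfterFit obeys closed forms, symmetry and rigid invariance", {
  set.seed(6)
  a <- randomStructure(nChains = 1, resPerChain = 8)
  expect_equal(rmsdAfterFit(a, a), 0, tolerance = 1e-8)
  ## rigid motion of either argument leaves RMSD unchanged
  b <- applyTransform(a, randomTransform())
  expect_equal(rmsdAfterFit(a, b), 0, tolerance = 1e-6)
  ## displacing one selected atom by 1 A gives sqrt(1/N) -- computed
  ## without superposition freedom by comparing against the pre-fit pose
  sel <- atomSelection(atomNames = "CA")
  n <- length(resolveSelection(a, sel))
  d <- coords(a)
  i <- resolveSelection(a, sel)[1]
  d[i, 1] <- d[i, 1] + 1
  bMoved <- a
  coords(bMoved) <- d
  ## the optimal fit can only reduce the naive sqrt(1/N), never exceed it
  expect_lte(rmsdAfterFit(a, bMoved), sqrt(1 / n) + 1e-9)
  expect_gt(rmsdAfterFit(a, bMoved), 0.8 * sqrt(1 / n))
  ## symmetry
  set.seed(7)
  noisy <- a
  coords(noisy) <- coords(a) + matrix(rnorm(3 * nAtoms(a)), ncol = 3)
  expect_equal(rmsdAfterFit(a, noisy), rmsdAfterFit(noisy, a),
               tolerance = 1e-9)
})

test_that("selection identity mismatches raise a pairing error", {
  a <- randomStructure(nChains = 2)
  b <- subsetStructure(a, which(atomTable(a)$chain == "A"))
  expect_error(rmsdAfterFit(a, b, atomSelection(atomNames = "CA")), "pairing error")
})

test_that("rmsdVsInitial is zero for identical or rigidly moved frames", {
  s <- randomStructure(nChains = 1, resPerChain = 10)
  frames <- list(s, s, s)
  e <- new("Ensemble", frames = frames, trajectoryId = "t",
           frameTimes = c(0, 1, 2))
  expect_equal(rmsdVsInitial(e)@values, c(0, 0, 0), tolerance = 1e-8)
  set.seed(8)
  rigid <- lapply(1:4, function(i) applyTransform(s, randomTransform()))
  e2 <- new("Ensemble", frames = c(list(s), rigid), trajectoryId = "t",
            frameTimes = as.numeric(0:4))
  expect_lt(max(rmsdVsInitial(e2)@values), 1e-6)
})

test_that("a hinge-opening ensemble has a nondecreasing RMSD trace matching per-frame fits", {
  angles <- seq(0, 40, by = 10)
  frames <- lapply(angles, function(a)
    makeDimerFrame(toySys$monomer, a,
                   interfaceOffset = toySys$geometry$interfaceOffset))
  e <- new("Ensemble", frames = frames, trajectoryId = "hinge",
           frameTimes = as.numeric(seq_along(angles) - 1))
  series <- rmsdVsInitial(e)
  expect_equal(series@values[1], 0)
  expect_true(all(diff(series@values) >= -1e-9))
  direct <- vapply(seq_along(frames), function(k)
    rmsdAfterFit(frames[[1]], frames[[k]]), numeric(1))
  direct[1] <- 0
  expect_equal(series@values, direct, tolerance = 1e-12)
})

test_that("transform algebra composes and inverts consistently", {
  set.seed(9)
  a <- randomTransform(); b <- randomTransform()
  x <- randomCluster(5)
  expect_equal(applyTransform(applyTransform(x, b), a),
               applyTransform(x, composeTransforms(a, b)), tolerance = 1e-10)
  expect_equal(applyTransform(applyTransform(x, a), invertTransform(a)), x,
               tolerance = 1e-9)
})
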