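test_that("diameterPair returns the extreme pair deterministically", {
  p <- rbind(c(0, 0, 0), c(0, 0, 10), c(0, 1, 5))
  dp <- diameterPair(p)
  expect_equal(dp$distance, 10)
  expect_equal(dp$a, c(0, 0, 0))
  expect_equal(dp$b, c(0, 0, 10))

  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  dpc <- diameterPair(cube)
  expect_equal(dpc$distance, sqrt(3))
  # lexicographic tie-break: smallest corner pair, repeatably
  expect_equal(dpc$a, c(0, 0, 0))
  expect_equal(dpc$b, c(1, 1, 1))

  expect_error(diameterPair(matrix(1, 5, 3)), "degenerate")
})

test_that("diameter matches the all-pairs brute force on random clouds", {
  for (s in 1:3) {
    set.seed(s)
    p <- matrix(rnorm(1500), 500, 3)
    dp <- diameterPair(p)
    brute <- max(stats::dist(p))
    expect_equal(dp$distance, brute, tolerance = 1e-12)
  }
})

test_that("end-centroid registration is idempotent and restores rotated clouds", {
  ph <- standardPhantom()
  p <- coords(ph$aligned)
  st <- endCentroidRegistration(p, 0.10)
  expect_lt(max(abs(st$transform@rotation - diag(3))), 1e-6)
  expect_lt(max(abs(st$transform@translation)), 1e-6 * ph$aligned@zLength)

  # a 90-degree rotation is recovered once the provisional diameter axis
  # is re-derived (full alignment); the distal centroid returns to +z
  rot <- new("PointCloud",
             coords = applyTransform(p, new("RigidTransform",
               rotation = bacumorph:::rotXMat(pi / 2),
               translation = c(0, 0, 0))),
             specimenId = "rot90")
  back <- coords(alignBaculum(rot))
  z <- back[, 3]
  distal <- back[(z - min(z)) / diff(range(z)) >= 0.9, , drop = FALSE]
  cd <- bacumorph:::hullVolumeCentroid(distal, convexHull3d(distal))
  expect_lt(max(abs(cd[1:2])), 1e-9 * diff(range(z)))
  expect_gt(cd[3], 0)
  expect_lt(max(abs(back - p)), 1e-6)
})

test_that("end-slab hull centroid equals the vertex mean in hull_vertex mode", {
  ph <- standardPhantom()
  p <- coords(ph$aligned)
  z <- p[, 3]
  slab <- p[(z - min(z)) / diff(range(z)) < 0.10, , drop = FALSE]
  hull <- convexHull3d(slab)
  expect_equal(bacumorph:::endSlabCentroid(slab, "hull_vertex")$centroid,
               colMeans(slab[hull$vertices, , drop = FALSE]))
})

test_that("mbrOrient rotates a band's long side onto x", {
  ph <- standardPhantom()
  p <- coords(ph$aligned)
  mo <- mbrOrient(p)
  expect_lt(abs(mo$angle), 1e-6)      # already oriented: identity

  for (th in c(0.4, -1.1)) {
    rot <- applyTransform(p, new("RigidTransform",
                                 rotation = bacumorph:::rotZMat(th),
                                 translation = c(0, 0, 0)))
    mo2 <- mbrOrient(rot)
    resid_ <- (mo2$angle + th) %% pi
    expect_lt(min(resid_, pi - resid_), 1e-9)
    back <- applyTransform(rot, mo2$transform)
    z <- back[, 3]; L <- diff(range(z))
    u <- (z - min(z)) / L
    band <- back[u >= 0.15 & u < 0.1525, 1:2, drop = FALSE]
    expect_lt(min(mbr2d(band)$angle %% pi, pi - mbr2d(band)$angle %% pi),
              1e-6)
  }
})

test_that("dorsoventral resolution flips mirrored bones and flags straight ones", {
  ph <- standardPhantom()
  p <- coords(ph$aligned)
  dv <- resolveDorsoventral(p)
  expect_false(dv$flipped)

  mir <- p
  mir[, 1] <- -mir[, 1]; mir[, 2] <- -mir[, 2]   # proper half-turn about z
  dv2 <- resolveDorsoventral(mir)
  expect_true(dv2$flipped)
  expect_equal(applyTransform(mir, dv2$transform), p)

  straight <- generateBone(bonePhantomParams(nPoints = 5000, curvature = 0,
                                             seed = 77, randomPose = FALSE))
  dv3 <- resolveDorsoventral(coords(straight))
  expect_match(dv3$warnings, "ambiguous")
})

test_that("alignBaculum is idempotent and invariant to rigid motions", {
  ph <- standardPhantom()
  al <- ph$aligned
  al2 <- alignBaculum(al)
  expect_lt(max(abs(coords(al2) - coords(al))), 1e-6)
  expect_lt(max(abs(al2@transform@rotation - diag(3))), 1e-6)

  lm0 <- coords(ph$lms)
  for (s in 1:10) {
    rig <- randomRigid(1000 + s)
    moved <- new("PointCloud",
                 coords = sweep(coords(ph$cloud) %*% t(rig$R), 2, -rig$t),
                 specimenId = "moved")
    lm1 <- coords(extractSemilandmarks(alignBaculum(moved)))
    rmsd <- sqrt(mean(rowSums((lm1 - lm0)^2)))
    expect_lt(rmsd, 1e-3 * al@zLength)
  }
})

test_that("the broad (base) end lands at the origin", {
  ph <- standardPhantom()
  p <- coords(ph$aligned)
  z <- p[, 3]; L <- diff(range(z))
  u <- (z - min(z)) / L
  baseArea <- mbr2d(p[u < 0.1, 1:2, drop = FALSE])$area
  tipArea <- mbr2d(p[u >= 0.9, 1:2, drop = FALSE])$area
  expect_gt(baseArea, tipArea)   # the phantom tapers base -> tip
  # base cross-section sits at low z, i.e. at the origin end
  expect_lt(abs(min(z)), 0.1 * L)
})

test_that("all alignment transforms are proper rotations", {
  ph <- standardPhantom()
  R <- ph$aligned@transform@rotation
  expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  expect_equal(det(R), 1, tolerance = 1e-9)
})
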