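test_that("slice bands are well-placed, disjoint and bounds-checked", {
  ph <- standardPhantom()
  cfg <- pipelineConfig()
  al <- ph$aligned
  expect_error(sliceBand(al, 0, cfg), "outside")
  expect_error(sliceBand(al, cfg@nSlices + 1L, cfg), "outside")

  z <- coords(al)[, 3]
  b1 <- sliceBand(al, 1, cfg)
  expect_true(all(abs(z[b1$idx] - b1$center) <=
                  cfg@sliceThicknessFrac * diff(range(z)) / 2 + 1e-12))

  # adjacent bands cannot overlap: thickness 0.25% versus 2% spacing
  b2 <- sliceBand(al, 2, cfg)
  expect_length(intersect(b1$idx, b2$idx), 0)

  # uniform-density filter oracle: band membership equals a direct filter
  L <- diff(range(z))
  t <- cfg@sliceThicknessFrac * L
  manual <- which(z >= b1$center - t / 2 & z < b1$center + t / 2)
  expect_identical(sort(b1$idx), sort(manual))
})

test_that("slice semilandmarks follow the closed form on a circular ring", {
  r <- 2
  band <- ringBand(r = r, n = 20000)
  cfg <- pipelineConfig()
  sl <- sliceSemilandmarks(band, cfg)
  expect_equal(nrow(sl$coords), 16)
  expect_setequal(sl$roles, c(sprintf("dorsal_%d", 1:7),
                              sprintf("ventral_%d", 1:7),
                              "leftmost", "rightmost"))
  lm <- sl$coords[match(c("leftmost", "rightmost"), sl$roles), ]
  expect_equal(lm[1, 1], -r, tolerance = 1e-4)
  expect_equal(lm[2, 1], r, tolerance = 1e-4)
  expect_lt(max(abs(lm[, 2])), 0.05)

  W <- 2 * r
  tolw <- cfg@projectionTolFrac * W
  for (l in 1:7) {
    xl <- -r + l / 8 * W
    dors <- sl$coords[match(sprintf("dorsal_%d", l), sl$roles), ]
    vent <- sl$coords[match(sprintf("ventral_%d", l), sl$roles), ]
    expect_equal(dors[1], xl)                      # projected onto the line
    # closed form: within the projection window the extreme y sits at the
    # window edge nearest x = 0
    xEff <- max(abs(xl) - tolw, 0)
    yExp <- sqrt(r^2 - xEff^2)
    expect_equal(dors[2], yExp, tolerance = 2e-3)
    expect_equal(vent[2], -yExp, tolerance = 2e-3)
    expect_gte(dors[2], vent[2])
  }
})

test_that("degenerate bands are rejected", {
  expect_error(sliceSemilandmarks(rbind(c(1, 0, 0), c(1, 2, 0)),
                                  pipelineConfig()),
               "distinct x")
})

test_that("extraction yields the full labeled configuration deterministically", {
  ph <- standardPhantom()
  cfg <- pipelineConfig()
  lms <- ph$lms
  expect_equal(nrow(coords(lms)), cfg@nSlices * 16 + 2)
  expect_equal(sum(lms@labels$role %in% c("proximal_tip", "distal_tip")), 2)
  expect_false(anyDuplicated(paste(lms@labels$slice, lms@labels$role)) > 0)

  again <- extractSemilandmarks(ph$aligned, cfg)
  expect_identical(coords(again), coords(lms))

  # leftmost/rightmost bound their band in x; dorsal above ventral per line
  for (i in c(1, 25, 50)) {
    rows <- which(lms@labels$slice == i)
    xs <- coords(lms)[rows, 1]
    roles <- lms@labels$role[rows]
    expect_equal(which.min(xs), match("leftmost", roles))
    expect_equal(which.max(xs), match("rightmost", roles))
    for (l in 1:7) {
      d <- coords(lms)[rows[match(sprintf("dorsal_%d", l), roles)], 2]
      v <- coords(lms)[rows[match(sprintf("ventral_%d", l), roles)], 2]
      expect_gte(d, v)
    }
  }
})

test_that("landmark CSV round-trips the configuration", {
  ph <- standardPhantom()
  f <- withr::local_tempfile(fileext = ".csv")
  writeLandmarksCSV(ph$lms, f)
  back <- readLandmarksCSV(f)
  expect_equal(coords(back), coords(ph$lms), tolerance = 1e-12)
  expect_equal(back@labels$role, ph$lms@labels$role)
})

test_that("centroid size follows its closed forms and invariances", {
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(centroidSize(sq), 2 * sqrt(2))
  expect_equal(centroidSize(matrix(c(3, 4, 5), 1)), 0)

  set.seed(12)
  X <- matrix(rnorm(60), 20, 3)
  for (s in c(0.5, 2, 10))
    expect_equal(centroidSize(s * X), s * centroidSize(X))

  for (s in 1:5) {
    rig <- randomRigid(300 + s)
    Y <- sweep(X %*% t(rig$R), 2, -rig$t)
    expect_lt(abs(centroidSize(Y) - centroidSize(X)),
              1e-9 * centroidSize(X))
  }
})
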