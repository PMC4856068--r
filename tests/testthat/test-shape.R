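test_that("opa is zero on identical and similarity-transformed configurations", {
  A <- randomConfig(10, 1)
  expect_equal(opa(A, A)$distance, 0, tolerance = 1e-12)
  rig <- randomRigid(2)
  B <- sweep(2.7 * A %*% t(rig$R), 2, -rig$t)
  expect_lt(opa(B, A)$distance, 1e-9)
  expect_error(opa(matrix(1, 4, 3), A[1:4, ]), "degenerate")
})

test_that("opa matches a brute-force rotation-grid search", {
  # independent oracle: d^2 = |A|^2 + |B|^2 - 2 max_R tr(R'M), M = A'B,
  # maximized over a coarse-to-fine grid of proper Euler rotations
  gridSearch <- function(M) {
    euler <- function(a, b, c) {
      bacumorph:::rotZMat(a) %*% bacumorph:::rotYMat(b) %*%
        bacumorph:::rotZMat(c)
    }
    best <- -Inf; arg <- c(0, 0, 0)
    sweepGrid <- function(as, bs, cs) {
      for (a in as) for (b in bs) for (c in cs) {
        v <- sum(euler(a, b, c) * M)
        if (v > best) { best <<- v; arg <<- c(a, b, c) }
      }
    }
    step <- 6 * pi / 180
    sweepGrid(seq(0, 2 * pi, by = step), seq(0, pi, by = step),
              seq(0, 2 * pi, by = step))
    fine <- 0.15 * pi / 180
    sweepGrid(arg[1] + seq(-step, step, by = fine),
              arg[2] + seq(-step, step, by = fine),
              arg[3] + seq(-step, step, by = fine))
    best
  }
  for (s in 1:2) {
    A <- bacumorph:::centerScale(randomConfig(5, 10 + s))
    B <- bacumorph:::centerScale(randomConfig(5, 20 + s))
    d <- opa(A, B)$distance
    tr <- gridSearch(crossprod(A, B))
    dGrid <- sqrt(max(sum(A^2) + sum(B^2) - 2 * tr, 0))
    expect_equal(d, dGrid, tolerance = 1e-4)
    expect_lte(d, dGrid + 1e-12)   # the SVD solution can only be better
  }
})

test_that("gpa collapses similarity-equivalent copies and reduces to opa for pairs", {
  A <- randomConfig(12, 30)
  copies <- lapply(1:5, function(s) {
    rig <- randomRigid(40 + s)
    sweep(runif(1, 0.5, 2) * A %*% t(rig$R), 2, -rig$t)
  })
  sp <- gpa(copies)
  expect_lt(max(sp@dist), 1e-6)

  B <- randomConfig(12, 31)
  sp2 <- gpa(list(a = A, b = B))
  expect_equal(sp2@dist[1, 2], opa(A, B)$distance, tolerance = 1e-6)

  expect_true(all(sp2@dist == t(sp2@dist)))
  expect_true(all(diag(sp2@dist) == 0))
  expect_equal(centroidSize(sp2@consensus), 1, tolerance = 1e-9)
})

test_that("gpa distances are invariant to input ordering", {
  configs <- lapply(1:4, function(s) randomConfig(10, 50 + s))
  names(configs) <- paste0("c", 1:4)
  d1 <- distMatrix(gpa(configs))
  perm <- c(3, 1, 4, 2)
  d2 <- distMatrix(gpa(configs[perm]))
  expect_equal(d2[names(configs), names(configs)], d1, tolerance = 1e-8)
})

test_that("sliding lowers thin-plate-spline bending energy every pass", {
  pp <- parentParams(n = 8000)
  lms <- lapply(1:3, function(i) phantomLandmarks(pp$p1, 500 + i,
                                                 sprintf("s%d", i)))
  sp <- gpa(lms, slide = TRUE, slideIter = 2L)
  expect_true(sp@slid)
  expect_true(all(sp@slideDiagnostics$beAfter <=
                  sp@slideDiagnostics$beBefore + 1e-9))
  expect_error(gpa(lapply(lms, coords), slide = TRUE), "labels")
})

test_that("LD1 separates separable clusters with the sign convention", {
  set.seed(60)
  base <- randomConfig(20, 61)
  mkCluster <- function(shift, n, tag) {
    lapply(seq_len(n), function(i) {
      X <- base + matrix(rnorm(60, 0, 0.01), 20, 3)
      X[1:5, 1] <- X[1:5, 1] + shift
      rig <- randomRigid(700 + shift * 100 + i)
      cfg <- sweep(X %*% t(rig$R), 2, -rig$t)
      rownames(cfg) <- NULL
      cfg
    })
  }
  g1 <- mkCluster(0, 4, "a"); g2 <- mkCluster(0.6, 4, "b")
  configs <- c(g1, g2)
  names(configs) <- c(paste0("a", 1:4), paste0("b", 1:4))
  sp <- gpa(configs)
  lab <- setNames(rep(c("A", "B"), each = 4), names(configs))
  model <- fitLD1(sp, lab)
  sc <- projectLD1(model, sp)
  expect_true(max(sc[1:4]) < min(sc[5:8]))           # 100% separation
  expect_lt(model@parentMeans["A"], model@parentMeans["B"])

  expect_error(fitLD1(sp, lab[c(1, 5:8)]), "at least 2")
  expect_error(fitLD1(sp, lab[1:4]), "exactly 2")
})

test_that("LD1 projection is consistent for training and duplicate specimens", {
  configs <- lapply(1:6, function(s) randomConfig(15, 80 + s))
  configs[[7]] <- configs[[1]]                      # duplicate of a trainer
  names(configs) <- c(paste0("p", 1:6), "dup")
  sp <- gpa(configs)
  lab <- setNames(rep(c("P1", "P2"), each = 3), paste0("p", 1:6))
  model <- fitLD1(sp, lab)
  sc <- projectLD1(model, sp)

  # training parental means reproduce fit-time means
  expect_equal(mean(sc[1:3]), unname(model@parentMeans["P1"]),
               tolerance = 1e-9)
  expect_equal(mean(sc[4:6]), unname(model@parentMeans["P2"]),
               tolerance = 1e-9)
  # a specimen identical to a training specimen scores identically
  expect_equal(unname(sc["dup"]), unname(sc["p1"]), tolerance = 1e-7)
  expect_error(projectLD1(model, sp, ids = "absent"), "absent")
})
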