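test_that("size repeatability matches hand arithmetic and its bounds", {
  expect_equal(repeatabilitySize(c(5, 5, 5, 7, 7), c("a", "a", "a", "b", "b")),
               1)
  expect_equal(repeatabilitySize(c(100, 102), c("g", "g")),
               1 - sqrt(2) / 101)
  expect_error(repeatabilitySize(c(1, 2, 3), c("a", "a", "b")), ">= 2")
  expect_error(repeatabilitySize(c(-1, 1), c("a", "a")), "zero mean")
})

test_that("size repeatability decreases with replicate noise", {
  reps <- sapply(c(0.01, 0.05, 0.2), function(sd_) {
    median(sapply(1:10, function(s) {
      set.seed(s)
      vals <- rep(100, 40) + rnorm(40, 0, 100 * sd_)
      repeatabilitySize(vals, rep(1:20, each = 2))
    }))
  })
  expect_true(all(diff(reps) < 0))
})

test_that("shape repeatability matches hand arithmetic", {
  D <- matrix(0, 3, 3, dimnames = list(c("r1", "r2", "o"),
                                       c("r1", "r2", "o")))
  D["r1", "o"] <- D["o", "r1"] <- 1.0
  D["r2", "o"] <- D["o", "r2"] <- 1.2
  D["r1", "r2"] <- D["r2", "r1"] <- 0.1
  expect_equal(repeatabilityShape(D, list(c("r1", "r2"))),
               1 - sqrt(0.02) / 1.1)

  # identical replicates: perfect repeatability
  D2 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D2) <- 0
  expect_equal(repeatabilityShape(D2, list(c("a", "b")), others = c("c", "d")),
               1)
})

test_that("heritability recovers closed forms and planted variance ratios", {
  tab <- data.frame(strain = rep(c("A", "B", "C"), each = 3),
                    CS = rep(c(1, 2, 3), each = 3))
  h <- suppressWarnings(heritability(tab, "CS"))  # exact fit warns in anova
  expect_equal(h$h2, 1)

  # null: strain means equal, noise only -> R^2 concentrates at its
  # degrees-of-freedom ratio (k-1)/(N-1) = 59/179
  nullh <- sapply(1:10, function(s) {
    tabn <- generateStrainPhenotypes(60, 3, 0, seed = s)
    heritability(tabn, "CS")$h2
  })
  expect_lt(abs(mean(nullh) - 59 / 179), 0.05)

  # planted intraclass correlation 0.6: the ANOVA R^2 estimates the
  # expected SS fraction E[SSB]/E[SST], upward of the planted ratio by the
  # noise entering strain means (k=60, n=5: 0.676)
  h2s <- sapply(1:50, function(s) {
    heritability(generateStrainPhenotypes(60, 5, 0.6, seed = s), "CS")$h2
  })
  expected <- (59 * (0.4 + 5 * 0.6)) / (59 * (0.4 + 5 * 0.6) + 240 * 0.4)
  expect_lt(abs(mean(h2s) - expected), 0.05)
  expect_true(all(h2s >= 0 & h2s <= 1))

  # invariance to adding a constant
  tab$CS <- tab$CS + 100
  expect_equal(suppressWarnings(heritability(tab, "CS"))$h2, 1)

  # strains below the minimum are excluded
  tab2 <- rbind(tab, data.frame(strain = "tiny", CS = 1))
  expect_equal(suppressWarnings(heritability(tab2, "CS"))$nStrains, 3)
})

test_that("nested lab ANOVA decomposes sums of squares as hand-computed", {
  tab <- data.frame(strain = rep(c("A", "B"), each = 4),
                    lab = rep(c("L1", "L1", "L2", "L2"), 2),
                    CS = c(10, 11, 14, 15, 20, 21, 26, 27))
  r <- nestedAnovaEnv(tab, "CS")
  # brute-force mean decomposition
  grand <- mean(tab$CS)
  sm <- tapply(tab$CS, tab$strain, mean)
  lm_ <- tapply(tab$CS, paste(tab$strain, tab$lab), mean)
  ssStrain <- 4 * sum((sm - grand)^2)
  ssLab <- 2 * sum((lm_ - rep(sm, each = 2))^2)
  ssRes <- sum((tab$CS - rep(lm_, each = 2))^2)
  expect_equal(r$anova[["Sum Sq"]], c(ssStrain, ssLab, ssRes))
  expect_equal(r$varianceFraction, ssLab / (ssStrain + ssLab + ssRes))
  expect_equal(r$F, (ssLab / 2) / (ssRes / 4))

  # labs identical in distribution: tiny lab fraction
  set.seed(3)
  tab0 <- data.frame(strain = rep(c("A", "B"), each = 40),
                     lab = rep(rep(c("L1", "L2"), each = 20), 2),
                     CS = rnorm(80) + rep(c(0, 3), each = 40))
  expect_lt(nestedAnovaEnv(tab0, "CS")$varianceFraction, 0.05)

  expect_error(nestedAnovaEnv(data.frame(strain = c("A", "A"),
                                         lab = c("L1", "L1"),
                                         CS = 1:2), "CS"),
               "multiple labs")
})

test_that("a planted lab offset is detected against a permutation null", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    tab <- data.frame(strain = rep(c("A", "B"), each = 20),
                      lab = rep(rep(c("L1", "L2"), each = 10), 2),
                      CS = rnorm(40))
    tab$CS[tab$strain == "A" & tab$lab == "L2"] <-
      tab$CS[tab$strain == "A" & tab$lab == "L2"] + 2
    obs <- nestedAnovaEnv(tab, "CS")$F
    perm <- replicate(49, {
      t2 <- tab
      for (st in c("A", "B")) {
        i <- which(t2$strain == st)
        t2$lab[i] <- sample(t2$lab[i])       # permute labs within strain
      }
      nestedAnovaEnv(t2, "CS")$F
    })
    if (obs > quantile(perm, 0.95)) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("strain-mean correlation behaves under exact and null structure", {
  tab <- data.frame(strain = rep(letters[1:5], each = 2),
                    CS = rep(1:5, each = 2), LD1 = rep(-(1:5) * 2 + 3, each = 2))
  r <- strainMeanCorrelation(tab)
  expect_equal(r$r, -1)

  # affine rescaling leaves r unchanged
  tab2 <- tab; tab2$CS <- 100 * tab2$CS - 7
  expect_equal(strainMeanCorrelation(tab2)$r, r$r)

  rs <- sapply(1:10, function(s) {
    set.seed(s)
    tabn <- data.frame(strain = letters[1:20], CS = rnorm(20),
                       LD1 = rnorm(20))
    strainMeanCorrelation(tabn)$r
  })
  expect_lt(abs(mean(rs)), 0.25)

  expect_error(strainMeanCorrelation(data.frame(strain = c("a", "b", "c"),
                                                CS = 1, LD1 = 1:3)),
               "zero variance")
})
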