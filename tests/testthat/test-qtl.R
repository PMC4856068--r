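makePanel <- function(geno, pos = NULL, y = NULL, chr = NULL,
                      parents = character()) {
  ns <- nrow(geno); nm <- ncol(geno)
  if (is.null(pos)) pos <- seq(0, 10 * (nm - 1), length.out = nm)
  if (is.null(chr)) chr <- rep(1, nm)
  strains <- sprintf("s%02d", seq_len(ns))
  rownames(geno) <- strains
  markers <- data.frame(marker = sprintf("m%d_%d", chr, seq_len(nm)),
                        chr = chr, pos = pos)
  colnames(geno) <- markers$marker
  pheno <- data.frame(row.names = strains)
  pheno$CS <- if (is.null(y)) rnorm(ns) else y
  new("RILPanel", strains = strains, markers = markers, geno = geno,
      phenotypes = pheno, parents = parents)
}

test_that("genotype probabilities are exact for observed and symmetric cases", {
  g <- matrix(c("B", "D", "B", "D", "D", "B"), 2, 3)
  pan <- makePanel(g, y = c(1, 2))
  P <- imputeGenotypeProbs(pan)
  expect_true(all(P %in% c(0, 1)))

  # midway missing marker between opposite homozygotes: 0.5 by symmetry
  g2 <- rbind(c("B", NA, "D"), c("B", "B", "B"))
  pan2 <- makePanel(g2, pos = c(0, 10, 20), y = c(1, 2))
  P2 <- imputeGenotypeProbs(pan2)
  expect_equal(P2[1, 2], 0.5)
  expect_equal(P2[2, ], c(m1_1 = 0, m1_2 = 0, m1_3 = 0))

  # fully missing chromosome
  g3 <- rbind(c(NA, NA, NA), c("B", "D", "B"))
  expect_warning(P3 <- imputeGenotypeProbs(makePanel(g3, y = c(1, 2))),
                 "fully missing")
  expect_equal(unname(P3[1, ]), rep(0.5, 3))
})

test_that("imputed probabilities match brute-force chain enumeration", {
  pos <- c(0, 7, 19, 33, 52)
  rstar <- rilExpandedR(haldaneR(diff(pos)))
  enum <- function(obs) {
    states <- as.matrix(expand.grid(rep(list(0:1), 5)))
    pr <- apply(states, 1, function(s) {
      p <- 0.5
      for (j in 2:5)
        p <- p * ifelse(s[j] == s[j - 1], 1 - rstar[j - 1], rstar[j - 1])
      if (all(is.na(obs) | obs == s)) p else 0
    })
    unname(colSums(states * pr) / sum(pr))
  }
  set.seed(8)
  for (trial in 1:40) {
    obs <- sample(c(0, 1, NA), 5, replace = TRUE, prob = c(0.35, 0.35, 0.3))
    if (all(is.na(obs))) next
    g <- rbind(ifelse(is.na(obs), NA, ifelse(obs == 1, "D", "B")),
               rep("B", 5))
    pan <- makePanel(g, pos = pos, y = c(1, 2))
    expect_equal(unname(imputeGenotypeProbs(pan)[1, ]), enum(obs),
                 tolerance = 1e-12)
  }
})

test_that("hkLod reproduces the worked example and the least-squares oracle", {
  r <- hkLod(c(0, 0, 1, 1), c(1, 1.1, 2, 2.1))
  expect_equal(r$lod, 2 * log10(101), tolerance = 1e-12)
  expect_equal(r$effect, 1, tolerance = 1e-12)
  expect_equal(r$r2, 1 - 0.01 / 1.01, tolerance = 1e-12)

  expect_equal(hkLod(c(0, 1, 0, 1), c(3, 3, 3, 3))$lod, 0)

  set.seed(14)
  for (i in 1:50) {
    n <- sample(5:30, 1)
    x <- runif(n); y <- rnorm(n)
    fit0 <- lm(y ~ 1); fit1 <- lm(y ~ x)
    lodRef <- (n / 2) * log10(sum(resid(fit0)^2) / sum(resid(fit1)^2))
    r <- hkLod(x, y)
    expect_equal(r$lod, lodRef, tolerance = 1e-9)
    expect_equal(r$effect, unname(coef(fit1)["x"]), tolerance = 1e-9)
  }

  # the LOD / R^2 identity
  expect_equal(r$r2, 1 - 10^(-2 * r$lod / n), tolerance = 1e-9)
})

test_that("scan reduces to hkLod, excludes parents, and is order-invariant", {
  set.seed(15)
  g <- matrix(sample(c("B", "D"), 30, replace = TRUE), 10, 3)
  y <- rnorm(10)
  pan <- makePanel(g, y = y)
  sc <- scanQTL(pan, "CS")
  P <- imputeGenotypeProbs(pan)
  for (j in 1:3)
    expect_equal(sc@table$lod[j], hkLod(P[, j], y)$lod)
  expect_true(all(sc@table$lod >= 0))

  # single-marker genome
  pan1 <- makePanel(g[, 1, drop = FALSE], y = y)
  expect_equal(scanQTL(pan1, "CS")@table$lod, hkLod(P[, 1], y)$lod)

  # strain order must not matter
  perm <- sample(10)
  pan2 <- new("RILPanel", strains = pan@strains[perm],
              markers = pan@markers, geno = pan@geno[perm, ],
              phenotypes = pan@phenotypes[perm, , drop = FALSE],
              parents = character())
  expect_equal(scanQTL(pan2, "CS")@table$lod, sc@table$lod,
               tolerance = 1e-12)

  # parental strains are dropped from the scan
  panP <- makePanel(g, y = y, parents = c("s01", "s02"))
  scP <- scanQTL(panP, "CS")
  expect_equal(scP@table$lod,
               hkLod(P[3:10, , drop = FALSE], y[3:10])$lod)
})

test_that("permutation thresholds are seeded, monotone and yield p-value labels", {
  sim <- generatePanel(panelSimParams(nStrains = 40, nChromosomes = 2,
    markersPerChromosome = 15, seed = 30))
  p1 <- permutationThreshold(sim$panel, "CS", nPerm = 100, seed = 7)
  p2 <- permutationThreshold(sim$panel, "CS", nPerm = 100, seed = 7)
  expect_identical(p1$threshold, p2$threshold)

  p90 <- permutationThreshold(sim$panel, "CS", nPerm = 100, seed = 7,
                              quantile = 0.90)
  expect_lte(p90$threshold, p1$threshold)
  expect_equal(p1$threshold,
               quantile(p1$maxima, 0.95, type = 7, names = FALSE))

  big <- max(p1$maxima) + 1
  ep <- empiricalP(p1, big)
  expect_equal(ep$p, 0)
  expect_match(ep$label, "P < 0.01")

  expect_warning(permutationThreshold(sim$panel, "CS", nPerm = 10, seed = 1),
                 "unstable")
})

test_that("LOD support intervals read the curve as specified", {
  tab <- data.frame(marker = paste0("m", 1:5), chr = 1,
                    pos = c(0, 10, 20, 30, 40),
                    lod = c(1, 3.5, 5, 3.5, 1), effect = 0, r2 = 0)
  sc <- new("ScanResult", table = tab, trait = "CS")
  iv <- lodSupportInterval(sc, 1, drop = 1.5)
  expect_equal(c(iv$lo, iv$hi), c(10, 30))
  expect_equal(iv$markers, c("m2", "m4"))

  tab$lod <- 1:5
  iv2 <- lodSupportInterval(new("ScanResult", table = tab, trait = "CS"), 1)
  expect_equal(iv2$hi, 40)   # monotone curve runs to the chromosome end

  tab$lod <- rep(2, 5)
  expect_warning(
    iv3 <- lodSupportInterval(new("ScanResult", table = tab, trait = "CS"), 1),
    "flat")
  expect_equal(c(iv3$lo, iv3$hi), c(0, 40))

  expect_error(lodSupportInterval(sc, 99), "not present")
})

test_that("the QTL LD chi-square matches hand counts", {
  g <- cbind(rep(c("B", "D"), each = 20), rep(c("B", "D"), each = 20))
  pan <- makePanel(g, chr = c(1, 2), pos = c(0, 0), y = rnorm(40))
  r <- qtlLdTest(pan, "m1_1", "m2_2")
  expect_equal(r$chisq, 40)
  expect_equal(r$df, 1)
  expect_lt(r$p, 1e-9)

  g2 <- cbind(rep(c("B", "D"), 20), rep(c("B", "B", "D", "D"), 10))
  pan2 <- makePanel(g2, chr = c(1, 2), pos = c(0, 0), y = rnorm(40))
  r2 <- qtlLdTest(pan2, "m1_1", "m2_2")
  expect_equal(r2$chisq, 0)
  expect_equal(r2$p, 1)

  g3 <- cbind(rep("B", 40), rep(c("B", "D"), 20))
  expect_error(qtlLdTest(makePanel(g3, chr = c(1, 2), pos = c(0, 0),
                                   y = rnorm(40)), "m1_1", "m2_2"),
               "monomorphic")

  # independent markers: chi-square small on average over seeds
  chis <- sapply(1:10, function(s) {
    set.seed(s)
    gg <- cbind(sample(rep(c("B", "D"), 25)), sample(rep(c("B", "D"), 25)))
    qtlLdTest(makePanel(gg, chr = c(1, 2), pos = c(0, 0),
                        y = rnorm(50)), "m1_1", "m2_2")$chisq
  })
  expect_lt(mean(chis), 3)
})

test_that("additive-effect estimates at the true marker are unbiased", {
  eff <- sapply(1:100, function(s) {
    sim <- generatePanel(panelSimParams(nStrains = 60, nChromosomes = 1,
      markersPerChromosome = 11, qtl = data.frame(chr = 1, index = 6,
                                                  effect = 1.5),
      residSd = 1, missingRate = 0, seed = 4000 + s))
    P <- imputeGenotypeProbs(sim$panel)
    hkLod(P[, 6], sim$panel@phenotypes$CS)$effect
  })
  expect_lt(abs(mean(eff) - 1.5), 0.05 * 1.5)
})
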