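# Synthetic data: bone phantoms with strain-dependent geometry, replicate
# scans, morph continua, strain phenotype tables and simulated RIL panels
# with planted additive QTL. Every generator is a pure function of
# (params, seed).

#' Bone phantom parameters
#'
#' Geometry of a synthetic elongate bone: superellipse cross-sections swept
#' along a bowed centerline, interior filled except for a hollow medullary
#' core. Defaults emulate an adult mouse baculum in millimetres: ~6.5 mm
#' long, broad proximal base tapering distally, a dorsal bow, and point
#' jitter of about half a 15.5-micrometre voxel. The default point count
#' (20000) keeps phantoms fast; raise `nPoints` toward the ~175000 points
#' of a real micro-CT segmentation when realism matters more than speed.
#'
#' @param length bone length (mm).
#' @param baseWidth,baseHeight full width (x) and height (y) of the proximal
#'   base cross-section (mm).
#' @param taperTip width/height multiplier at the distal tip (linear taper
#'   from 1 at the base).
#' @param curvature dorsal bow amplitude of the centerline (mm): maximum y
#'   offset at midlength. B6-like bones bow (~0.35); D2-like bones are
#'   nearly straight (~0.05).
#' @param cavityFrac hollow-core fraction of the cross-section radius,
#'   in `[0, 1)`.
#' @param exponent superellipse exponent (2 = ellipse).
#' @param nPoints number of points to sample.
#' @param noiseSd isotropic Gaussian jitter SD (mm).
#' @param randomPose return the phantom under a random rigid pose so
#'   alignment is always exercised (default TRUE).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param specimenId specimen identifier.
#' @return a list of class `BonePhantomParams`.
#' @export
bonePhantomParams <- function(length = 6.5, baseWidth = 1.3,
                              baseHeight = 0.9, taperTip = 0.5,
                              curvature = 0.35, cavityFrac = 0.35,
                              exponent = 2, nPoints = 20000,
                              noiseSd = 0.008, randomPose = TRUE,
                              seed = 1L, specimenId = "phantom") {
  stopifnot(length > 0, baseWidth > 0, baseHeight > 0, taperTip > 0,
            cavityFrac >= 0, cavityFrac < 1, nPoints >= 100,
            noiseSd >= 0, !is.null(seed))
  structure(list(length = length, baseWidth = baseWidth,
                 baseHeight = baseHeight, taperTip = taperTip,
                 curvature = curvature, cavityFrac = cavityFrac,
                 exponent = exponent, nPoints = nPoints, noiseSd = noiseSd,
                 randomPose = randomPose, seed = seed,
                 specimenId = specimenId),
            class = "BonePhantomParams")
}

#' Generate a synthetic bone point cloud
#'
#' Samples points uniformly along the bone axis and area-uniformly over the
#' annular superellipse cross-section (hollow core excluded), sweeps them
#' along the bowed centerline, adds Gaussian jitter, and (by default)
#' returns the cloud under a random rigid pose. Bit-reproducible from the
#' seed.
#'
#' @param params a [bonePhantomParams()] list.
#' @return a [PointCloud-class]; the true (unposed) frame has the proximal
#'   base at z = 0 and the bone along +z, dorsal bow toward +y.
#' @examples
#' ph <- generateBone(bonePhantomParams(nPoints = 2000, seed = 7))
#' nrow(coords(ph))
#' @export
generateBone <- function(params) {
  stopifnot(inherits(params, "BonePhantomParams"))
  withSeed(params$seed, {
    n <- params$nPoints
    s <- runif(n)
    mult <- 1 + (params$taperTip - 1) * s
    a <- params$baseWidth / 2 * mult
    b <- params$baseHeight / 2 * mult
    th <- runif(n, 0, 2 * pi)
    e <- params$exponent
    ux <- sign(cos(th)) * abs(cos(th))^(2 / e)
    uy <- sign(sin(th)) * abs(sin(th))^(2 / e)
    rho <- sqrt(params$cavityFrac^2 + runif(n) * (1 - params$cavityFrac^2))
    bow <- params$curvature * 4 * s * (1 - s)
    pts <- cbind(rho * a * ux,
                 rho * b * uy + bow,
                 s * params$length)
    if (params$noiseSd > 0)
      pts <- pts + matrix(rnorm(3 * n, 0, params$noiseSd), n, 3)
    if (params$randomPose) {
      R <- randomRotation()
      tr <- runif(3, -params$length, params$length)
      pts <- sweep(pts %*% t(R), 2, -tr)
    }
    new("PointCloud", coords = pts, specimenId = params$specimenId,
        meta = list(generator = "bone_phantom", seed = params$seed,
                    curvature = params$curvature, length = params$length))
  })
}

#' Interpolated phantoms along a morph continuum
#'
#' Linear parameter-wise interpolation between two phantom parameter sets:
#' `t = 0` reproduces the first parent's distribution and `t = 1` the
#' second's. Used to check that the discriminant shape score orders
#' intermediate morphologies by their mixing parameter.
#'
#' @param p1,p2 [bonePhantomParams()] lists (the two parents).
#' @param tValues mixing parameters in `[0, 1]`.
#' @param seed base seed; phantom `k` uses `seed + k`.
#' @return list of [PointCloud-class] objects named `morph_t<t>`.
#' @export
generateMorphContinuum <- function(p1, p2, tValues, seed = 1L) {
  stopifnot(all(tValues >= 0 & tValues <= 1))
  numf <- c("length", "baseWidth", "baseHeight", "taperTip", "curvature",
            "cavityFrac", "exponent", "noiseSd")
  out <- vector("list", length(tValues))
  for (k in seq_along(tValues)) {
    t <- tValues[k]
    pk <- p1
    for (f in numf) pk[[f]] <- (1 - t) * p1[[f]] + t * p2[[f]]
    pk$seed <- seed + k
    pk$specimenId <- sprintf("morph_t%g_%d", t, k)
    out[[k]] <- generateBone(pk)
  }
  names(out) <- vapply(out, specimenId, character(1))
  out
}

#' Simulated replicate scans of one bone
#'
#' Emulates removing and reloading a specimen between scans: each replicate
#' is the same cloud under an independent small random rigid motion plus
#' per-point resampling noise.
#'
#' @param cloud a [PointCloud-class].
#' @param n number of replicates (>= 2).
#' @param rotSd SD of the random rotation angle (radians).
#' @param transSd SD of each translation component.
#' @param noiseSd per-point Gaussian jitter SD.
#' @param seed RNG seed.
#' @return list of [PointCloud-class] replicates, ids suffixed `_repK`.
#' @export
generateReplicates <- function(cloud, n, rotSd = 0.2, transSd = 1,
                               noiseSd = 0.008, seed = 1L) {
  stopifnot(n >= 2)
  p <- coords(cloud)
  ctr <- colMeans(p)
  withSeed(seed, {
    lapply(seq_len(n), function(k) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- rnorm(1, 0, rotSd)
      K <- skewMat(ax)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      q <- sweep(sweep(p, 2, ctr) %*% t(R), 2, -ctr - rnorm(3, 0, transSd))
      if (noiseSd > 0)
        q <- q + matrix(rnorm(length(q), 0, noiseSd), nrow(q), 3)
      new("PointCloud", coords = q, voxelSize = cloud@voxelSize,
          specimenId = sprintf("%s_rep%d", specimenId(cloud), k),
          meta = c(cloud@meta, list(replicate = k)))
    })
  })
}

#' Strain phenotype table with planted heritability
#'
#' Draws strain effects and residuals so that the intraclass correlation
#' (strain variance over total variance) equals `h2`.
#'
#' @param nStrains number of strains.
#' @param nPerStrain individuals per strain (scalar or per-strain vector).
#' @param h2 intraclass correlation in `[0, 1)`.
#' @param totalSd total phenotypic SD.
#' @param mean grand mean.
#' @param trait name of the value column (default "CS").
#' @param seed RNG seed.
#' @return data.frame with columns `specimen_id`, `strain` and the trait.
#' @export
generateStrainPhenotypes <- function(nStrains, nPerStrain, h2,
                                     totalSd = 1, mean = 0, trait = "CS",
                                     seed = 1L) {
  stopifnot(h2 >= 0, h2 < 1)
  nper <- rep_len(nPerStrain, nStrains)
  withSeed(seed, {
    sb <- totalSd * sqrt(h2)
    sw <- totalSd * sqrt(1 - h2)
    eff <- rnorm(nStrains, 0, sb)
    strain <- rep(sprintf("S%03d", seq_len(nStrains)), nper)
    val <- mean + rep(eff, nper) + rnorm(sum(nper), 0, sw)
    df <- data.frame(specimen_id = sprintf("%s_i%d", strain,
                       unlist(lapply(nper, seq_len))),
                     strain = strain, stringsAsFactors = FALSE)
    df[[trait]] <- val
    df
  })
}

#' RIL panel simulation parameters
#'
#' Defaults emulate a BXD-scale panel: 73 strains genotyped at a dense
#' marker map with ~2% missing data; genotypes follow a two-state Markov
#' chain along each chromosome with recombination fractions expanded for
#' sib-mated RILs.
#'
#' @param nStrains number of RIL strains.
#' @param nChromosomes number of chromosomes.
#' @param markersPerChromosome markers per chromosome (evenly spaced).
#' @param chrLengthCM chromosome length in cM.
#' @param qtl data.frame of planted QTL with columns `chr`, `index` (marker
#'   index within the chromosome) and `effect` (additive D-minus-B effect on
#'   the trait), or NULL for a null panel.
#' @param residSd residual SD of the strain-mean phenotype.
#' @param missingRate genotype missingness rate in `[0, 0.5]`.
#' @param trait phenotype column name.
#' @param addParents add the two parental strains (all-B and all-D),
#'   flagged so scans exclude them.
#' @param seed RNG seed (mandatory).
#' @return a list of class `PanelSimParams`.
#' @export
panelSimParams <- function(nStrains = 73, nChromosomes = 19,
                           markersPerChromosome = 200, chrLengthCM = 80,
                           qtl = NULL, residSd = 1, missingRate = 0.022,
                           trait = "CS", addParents = FALSE, seed = 1L) {
  stopifnot(missingRate >= 0, missingRate <= 0.5, !is.null(seed),
            nStrains >= 2, markersPerChromosome >= 2)
  if (!is.null(qtl))
    stopifnot(all(c("chr", "index", "effect") %in% names(qtl)),
              all(is.finite(qtl$effect)))
  structure(list(nStrains = nStrains, nChromosomes = nChromosomes,
                 markersPerChromosome = markersPerChromosome,
                 chrLengthCM = chrLengthCM, qtl = qtl, residSd = residSd,
                 missingRate = missingRate, trait = trait,
                 addParents = addParents, seed = seed),
            class = "PanelSimParams")
}

#' Simulate a RIL panel with planted genetic architecture
#'
#' Per strain and chromosome, genotypes are a two-state Markov chain over
#' the marker map with per-interval recombination fractions
#' `r* = 4r/(1 + 6r)` (sib-mating RIL map expansion of the Haldane
#' fraction). The strain-mean phenotype is the sum of planted additive
#' effects (B = 0, D = 1 coding) plus Gaussian residual; genotypes are then
#' masked at `missingRate`.
#'
#' @param params a [panelSimParams()] list.
#' @return list with `panel` (a [RILPanel-class]) and `truth` (planted QTL
#'   table with absolute marker names, plus the seed).
#' @examples
#' sim <- generatePanel(panelSimParams(nStrains = 30, nChromosomes = 2,
#'   markersPerChromosome = 10, seed = 3))
#' sim$panel
#' @export
generatePanel <- function(params) {
  stopifnot(inherits(params, "PanelSimParams"))
  withSeed(params$seed, {
    nc <- params$nChromosomes
    m <- params$markersPerChromosome
    ns <- params$nStrains
    pos <- seq(0, params$chrLengthCM, length.out = m)
    markers <- data.frame(
      marker = sprintf("m%d_%d", rep(seq_len(nc), each = m),
                       rep(seq_len(m), nc)),
      chr = rep(seq_len(nc), each = m),
      pos = rep(pos, nc), stringsAsFactors = FALSE)
    rstar <- rilExpandedR(haldaneR(diff(pos)))
    G <- matrix(0L, ns, nc * m)
    for (ch in seq_len(nc)) {
      g <- matrix(0L, ns, m)
      g[, 1] <- rbinom(ns, 1, 0.5)
      for (j in 2:m) {
        flip <- runif(ns) < rstar[j - 1]
        g[, j] <- ifelse(flip, 1L - g[, j - 1], g[, j - 1])
      }
      G[, (ch - 1) * m + seq_len(m)] <- g
    }
    strains <- sprintf("RIL%03d", seq_len(ns))
    y <- rnorm(ns, 0, params$residSd)
    truth <- NULL
    if (!is.null(params$qtl)) {
      truth <- params$qtl
      truth$marker <- sprintf("m%d_%d", truth$chr, truth$index)
      truth$pos <- pos[truth$index]
      for (r in seq_len(nrow(truth))) {
        col <- (truth$chr[r] - 1) * m + truth$index[r]
        y <- y + truth$effect[r] * G[, col]
      }
    }
    geno <- matrix(ifelse(G == 1L, "D", "B"), ns, nc * m)
    if (params$missingRate > 0) {
      mask <- matrix(runif(length(geno)) < params$missingRate, ns)
      geno[mask] <- NA_character_
    }
    parents <- character()
    if (params$addParents) {
      strains <- c(strains, "P_B", "P_D")
      geno <- rbind(geno, matrix("B", 1, nc * m), matrix("D", 1, nc * m))
      y <- c(y, 0, sum(params$qtl$effect %||% 0))
      parents <- c("P_B", "P_D")
    }
    rownames(geno) <- strains
    colnames(geno) <- markers$marker
    pheno <- data.frame(row.names = strains)
    pheno[[params$trait]] <- y
    panel <- new("RILPanel", strains = strains, markers = markers,
                 geno = geno, phenotypes = pheno, parents = parents)
    list(panel = panel, truth = list(qtl = truth, seed = params$seed))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
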