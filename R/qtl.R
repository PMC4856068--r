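# Single-QTL genome scan for RIL strain means: Haley-Knott regression on
# genotype probabilities, permutation significance thresholds, 1.5-LOD
# support intervals, and the inter-QTL linkage-disequilibrium chi-square.

#' Haldane map function
#'
#' Recombination fraction for a genetic distance `d` in centimorgans:
#' `r = (1 - exp(-2 d / 100)) / 2` (no interference).
#'
#' @param dCM distance in cM.
#' @return recombination fraction in `[0, 0.5)`.
#' @export
haldaneR <- function(dCM) (1 - exp(-2 * dCM / 100)) / 2

#' RIL map expansion for sib-mated lines
#'
#' The effective recombination fraction between the fixed genomes of
#' sib-mated autosomal RILs: `r* = 4r / (1 + 6r)`.
#'
#' @param r single-generation recombination fraction.
#' @return expanded recombination fraction.
#' @export
rilExpandedR <- function(r) 4 * r / (1 + 6 * r)

## 2-state transition probability across an interval with (expanded)
## recombination fraction r: P(change) = r.
chainProduct <- function(rvec) {
  # product of [[1-r, r], [r, 1-r]] over intervals; returns P(change)
  p <- 0
  for (r in rvec) p <- p * (1 - r) + (1 - p) * r
  p
}

#' Genotype probabilities for a RIL panel
#'
#' Converts observed genotypes to P(D allele): observed B -> 0, D -> 1.
#' Missing genotypes between observed flanking markers get their
#' conditional expectation under the two-state homozygote Markov chain
#' along the marker map, with per-interval Haldane recombination fractions
#' expanded for sib-mated RILs (`r* = 4r/(1+6r)`). Missing genotypes beyond
#' the outermost observed marker get the conditional expectation given that
#' single nearest flank (the chain transition probability across the gap);
#' a strain with a fully missing chromosome gets probability 0.5 there,
#' with a warning.
#'
#' @param panel a [RILPanel-class].
#' @return strains x markers numeric matrix of P(D).
#' @export
imputeGenotypeProbs <- function(panel) {
  mk <- panel@markers
  ns <- length(panel@strains)
  P <- matrix(NA_real_, ns, nrow(mk),
              dimnames = list(panel@strains, mk$marker))
  fullyMissing <- 0L
  for (ch in unique(mk$chr)) {
    cols <- which(mk$chr == ch)
    rstar <- rilExpandedR(haldaneR(diff(mk$pos[cols])))
    g <- panel@geno[, cols, drop = FALSE]
    x <- matrix(NA_real_, ns, length(cols))
    x[g == "B"] <- 0; x[g == "D"] <- 1
    for (s in seq_len(ns)) {
      obs <- which(!is.na(x[s, ]))
      if (!length(obs)) {
        x[s, ] <- 0.5
        fullyMissing <- fullyMissing + 1L
        next
      }
      xs <- x[s, ]
      # ends: conditional expectation given the single nearest observed
      # flank (the chain transition probability across the gap)
      if (obs[1] > 1) {
        for (m in seq_len(obs[1] - 1)) {
          r <- chainProduct(rstar[m:(obs[1] - 1)])
          xs[m] <- if (xs[obs[1]] == 1) 1 - r else r
        }
      }
      last <- obs[length(obs)]
      if (last < length(cols)) {
        for (m in (last + 1):length(cols)) {
          r <- chainProduct(rstar[last:(m - 1)])
          xs[m] <- if (xs[last] == 1) 1 - r else r
        }
      }
      # interior gaps: condition on both flanks
      if (length(obs) > 1) {
        for (k in seq_len(length(obs) - 1)) {
          L <- obs[k]; R <- obs[k + 1]
          if (R - L <= 1) next
          gL <- xs[L]; gR <- xs[R]
          rLR <- chainProduct(rstar[L:(R - 1)])
          for (m in (L + 1):(R - 1)) {
            rLm <- chainProduct(rstar[L:(m - 1)])
            rmR <- chainProduct(rstar[m:(R - 1)])
            # P(g_m = D | g_L, g_R)
            pLtoD <- if (gL == 1) 1 - rLm else rLm
            pDtoR <- if (gR == 1) 1 - rmR else rmR
            pLtoR <- if (gL == gR) 1 - rLR else rLR
            xs[m] <- pLtoD * pDtoR / pLtoR
          }
        }
      }
      x[s, ] <- xs
    }
    P[, cols] <- x
  }
  if (fullyMissing > 0)
    warning(fullyMissing, " strain-chromosome(s) fully missing; probability 0.5 used")
  P
}

#' Haley-Knott LOD score at one position
#'
#' Regresses the phenotype on the genotype probability:
#' `LOD = (n/2) log10(RSS0 / RSS1)` with `RSS0` from the intercept-only
#' model and `RSS1` from the one-covariate regression (RILs have two
#' homozygous classes, so no dominance term). A perfect fit is capped at
#' LOD 300 with a flag.
#'
#' @param probs P(D) at one position (vector over strains) or a
#'   strains x markers matrix (vectorized over columns).
#' @param y phenotype vector (same strain order).
#' @return for a vector input, a list with `lod`, `effect` (additive
#'   D-minus-B estimate), `r2` and `capped`; for a matrix, a data.frame
#'   with one row per column.
#' @examples
#' hkLod(c(0, 0, 1, 1), c(1, 1.1, 2, 2.1))$lod   # 2*log10(101)
#' @export
hkLod <- function(probs, y) {
  vec <- is.null(dim(probs))
  X <- if (vec) matrix(probs, ncol = 1) else as.matrix(probs)
  ok <- stats::complete.cases(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  n <- length(y)
  if (n < 3) stop("need >= 3 strains with phenotype and probability",
                  call. = FALSE)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  Sxx <- colSums(Xc^2)
  Sxy <- as.numeric(crossprod(Xc, yc))
  Syy <- sum(yc^2)
  rss1 <- Syy - ifelse(Sxx > 0, Sxy^2 / Sxx, 0)
  effect <- ifelse(Sxx > 0, Sxy / Sxx, 0)
  if (Syy == 0) {                      # constant phenotype: no signal
    z <- numeric(ncol(X))
    lod <- z; r2 <- z; capped <- z > 0; effect <- z
  } else {
    capped <- rss1 <= Syy * 1e-300
    lod <- ifelse(capped, 300, pmin((n / 2) * log10(Syy / rss1), 300))
    r2 <- 1 - rss1 / Syy
  }
  if (vec) list(lod = lod[1], effect = effect[1], r2 = r2[1],
                capped = capped[1])
  else data.frame(lod = lod, effect = effect, r2 = r2, capped = capped)
}

scanStrains <- function(panel, trait, excludeParents) {
  y <- panel@phenotypes[[trait]]
  if (is.null(y)) stop("trait '", trait, "' not in panel phenotypes",
                       call. = FALSE)
  names(y) <- rownames(panel@phenotypes)
  keep <- panel@strains
  if (excludeParents) keep <- setdiff(keep, panel@parents)
  keep <- keep[!is.na(y[keep])]
  list(strains = keep, y = y[keep])
}

#' Single-QTL genome scan by Haley-Knott regression
#'
#' Computes the Haley-Knott LOD score at every marker (parental strains,
#' which carry no recombinant chromosomes, are excluded by default) and
#' records per-chromosome maxima.
#'
#' @param panel a [RILPanel-class].
#' @param trait phenotype column to scan.
#' @param excludeParents drop parental strains (default TRUE).
#' @param probs optional precomputed [imputeGenotypeProbs()] matrix.
#' @return a [ScanResult-class].
#' @export
scanQTL <- function(panel, trait, excludeParents = TRUE, probs = NULL) {
  ss <- scanStrains(panel, trait, excludeParents)
  if (is.null(probs)) probs <- imputeGenotypeProbs(panel)
  res <- hkLod(probs[ss$strains, , drop = FALSE], ss$y)
  tab <- cbind(panel@markers, res[, c("lod", "effect", "r2")])
  peaks <- do.call(rbind, lapply(split(tab, tab$chr), function(d)
    d[which.max(d$lod), ]))
  rownames(peaks) <- NULL
  new("ScanResult", table = tab, peaks = peaks, trait = trait)
}

#' Permutation significance threshold for a genome scan
#'
#' Shuffles the phenotype vector against the strains `nPerm` times,
#' rescans, and returns the requested quantile (type-7 linear
#' interpolation) of the permutation genome-wide maximum LOD scores.
#' Deterministic given `seed`.
#'
#' @param panel a [RILPanel-class].
#' @param trait phenotype column.
#' @param nPerm number of permutations (default 1000; fewer than 20 warns).
#' @param quantile quantile of the permutation maxima (default 0.95).
#' @param seed RNG seed.
#' @param excludeParents drop parental strains (default TRUE).
#' @param probs optional precomputed probability matrix.
#' @return list with `threshold`, `maxima` (the `nPerm` genome-wide
#'   maxima), `nPerm` and `quantile`.
#' @export
permutationThreshold <- function(panel, trait, nPerm = 1000,
                                 quantile = 0.95, seed = 1L,
                                 excludeParents = TRUE, probs = NULL) {
  if (nPerm < 20) warning("fewer than 20 permutations: quantile unstable")
  ss <- scanStrains(panel, trait, excludeParents)
  if (is.null(probs)) probs <- imputeGenotypeProbs(panel)
  X <- probs[ss$strains, , drop = FALSE]
  n <- length(ss$y)
  Xc <- sweep(X, 2, colMeans(X))
  Sxx <- colSums(Xc^2)
  use <- Sxx > 0
  maxima <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      yp <- sample(ss$y)
      yc <- yp - mean(yp)
      Syy <- sum(yc^2)
      Sxy <- as.numeric(crossprod(Xc[, use, drop = FALSE], yc))
      rss1 <- Syy - Sxy^2 / Sxx[use]
      rss1 <- pmax(rss1, Syy * 1e-300)
      max((n / 2) * log10(Syy / rss1))
    }, numeric(1))
  })
  list(threshold = stats::quantile(maxima, quantile, type = 7,
                                   names = FALSE),
       maxima = maxima, nPerm = nPerm, quantile = quantile)
}

#' Empirical permutation p-value of an observed LOD
#'
#' The fraction of permutation genome-wide maxima at or above the observed
#' LOD. An observed LOD exceeding every permutation is reported as below
#' one over the number of permutations.
#'
#' @param perm result of [permutationThreshold()].
#' @param lod observed LOD score.
#' @return list with `p` (count / nPerm), `count`, and `label` (e.g.
#'   `"P < 0.001"` when no permutation reaches the observed LOD).
#' @export
empiricalP <- function(perm, lod) {
  count <- sum(perm$maxima >= lod)
  p <- count / perm$nPerm
  label <- if (count == 0) sprintf("P < %g", 1 / perm$nPerm)
           else sprintf("P = %g", p)
  list(p = p, count = count, label = label)
}

#' 1.5-LOD support interval on a chromosome
#'
#' The contiguous marker interval around the chromosome's LOD peak whose
#' endpoints are the outermost markers still within `drop` LOD units of
#' the peak, clipped at the chromosome ends. A flat LOD curve returns the
#' whole chromosome with a warning.
#'
#' @param scan a [ScanResult-class].
#' @param chromosome chromosome identifier.
#' @param drop LOD units dropped from the peak (default 1.5).
#' @return list with `lo`, `hi` (positions), `markers` (flanking marker
#'   names) and `peak` (the peak row of the scan table).
#' @export
lodSupportInterval <- function(scan, chromosome, drop = 1.5) {
  tab <- scan@table[scan@table$chr == chromosome, , drop = FALSE]
  if (!nrow(tab)) stop("chromosome not present in scan", call. = FALSE)
  tab <- tab[order(tab$pos), , drop = FALSE]
  lod <- tab$lod
  pk <- which.max(lod)
  if (max(lod) - min(lod) < 1e-12) {
    warning("flat LOD curve; returning the whole chromosome")
    lo <- 1L; hi <- nrow(tab)
  } else {
    cut <- lod[pk] - drop
    lo <- pk
    while (lo > 1 && lod[lo - 1] >= cut) lo <- lo - 1
    hi <- pk
    while (hi < nrow(tab) && lod[hi + 1] >= cut) hi <- hi + 1
  }
  list(lo = tab$pos[lo], hi = tab$pos[hi],
       markers = c(tab$marker[lo], tab$marker[hi]),
       peak = tab[pk, ])
}

#' Linkage-disequilibrium test between two QTL markers
#'
#' Pearson chi-square (no continuity correction) on the 2x2 contingency of
#' strain alleles (B/D) at the two markers, over strains genotyped at both.
#'
#' @param panel a [RILPanel-class].
#' @param markerA,markerB marker names.
#' @param excludeParents drop parental strains (default TRUE).
#' @return list with `chisq`, `df`, `p` and the contingency `table`.
#' @export
qtlLdTest <- function(panel, markerA, markerB, excludeParents = TRUE) {
  ia <- match(markerA, panel@markers$marker)
  ib <- match(markerB, panel@markers$marker)
  if (is.na(ia) || is.na(ib)) stop("marker not found in panel",
                                   call. = FALSE)
  keep <- panel@strains
  if (excludeParents) keep <- setdiff(keep, panel@parents)
  ga <- panel@geno[keep, ia]; gb <- panel@geno[keep, ib]
  ok <- !is.na(ga) & !is.na(gb)
  ga <- factor(ga[ok], levels = c("B", "D"))
  gb <- factor(gb[ok], levels = c("B", "D"))
  if (length(unique(ga)) < 2 || length(unique(gb)) < 2)
    stop("monomorphic marker among the genotyped strains", call. = FALSE)
  tab <- table(ga, gb)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}
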