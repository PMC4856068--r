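# Repeatability, environmental and heritability statistics on specimen
# tables (columns: specimen_id, strain, lab, replicate_group, CS, LD1 --
# plain data.frames; only the columns an analysis needs must be present).

#' Size repeatability from replicate scans
#'
#' One minus the median coefficient of variation of centroid size across
#' replicate groups; the CV of a group is its unbiased ((n-1)-denominator)
#' standard deviation divided by its mean.
#'
#' @param values numeric centroid sizes.
#' @param group replicate-group labels (same length as `values`); every
#'   group must have >= 2 measurements.
#' @return scalar repeatability (<= 1).
#' @examples
#' repeatabilitySize(c(100, 102), c("a", "a"))   # 1 - sqrt(2)/101
#' @export
repeatabilitySize <- function(values, group) {
  g <- split(values, group)
  if (any(lengths(g) < 2))
    stop("every replicate group needs >= 2 measurements", call. = FALSE)
  cv <- vapply(g, function(v) {
    m <- mean(v)
    if (m == 0) stop("replicate group with zero mean", call. = FALSE)
    sd(v) / m
  }, numeric(1))
  1 - median(cv)
}

#' Shape repeatability from the full distance matrix
#'
#' For each replicate group and each non-replicate specimen, the
#' coefficient of variation of the replicate-to-specimen Procrustes
#' distances is computed across the group's replicate scans; the
#' repeatability is one minus the mean CV over all (group, specimen)
#' pairwise comparisons.
#'
#' @param dist full symmetric distance matrix with specimen ids as
#'   dimnames (e.g. `distMatrix(space)`).
#' @param replicateGroups list of character vectors of replicate scan ids
#'   (each of length >= 2).
#' @param others ids of the non-replicate specimens compared against
#'   (default: all ids not in any replicate group).
#' @return scalar repeatability (<= 1).
#' @export
repeatabilityShape <- function(dist, replicateGroups, others = NULL) {
  ids <- rownames(dist)
  if (is.null(others)) others <- setdiff(ids, unlist(replicateGroups))
  if (!length(others)) stop("need at least 1 non-replicate specimen",
                            call. = FALSE)
  cvs <- numeric(0)
  for (grp in replicateGroups) {
    if (length(grp) < 2) stop("replicate groups need >= 2 scans",
                              call. = FALSE)
    sub <- dist[grp, others, drop = FALSE]
    m <- colMeans(sub)
    zero <- m == 0
    if (any(zero)) {
      warning("skipping ", sum(zero), " comparison(s) with zero mean distance")
      sub <- sub[, !zero, drop = FALSE]
      m <- m[!zero]
    }
    if (!length(m)) next
    cvs <- c(cvs, apply(sub, 2, sd) / m)
  }
  1 - mean(cvs)
}

#' ANOVA heritability of a trait
#'
#' One-way ANOVA of the trait on strain identity; the proportion of the
#' total sum of squares explained by strain (the ANOVA R-squared) is taken
#' as the broad-sense heritability. Strains with fewer than `minN`
#' individuals are excluded first.
#'
#' @param table data.frame with columns `strain` and the trait.
#' @param trait trait column name ("CS" or "LD1").
#' @param minN minimum individuals per strain (default 3).
#' @return list with `h2`, `F`, `df` (length 2), `p`, `nStrains`, `n`.
#' @export
heritability <- function(table, trait, minN = 3L) {
  stopifnot(trait %in% names(table), "strain" %in% names(table))
  tab <- table[!is.na(table[[trait]]), , drop = FALSE]
  counts <- table(tab$strain)
  keep <- names(counts)[counts >= minN]
  if (length(keep) < 2)
    stop("need >= 2 strains with at least minN individuals", call. = FALSE)
  tab <- tab[tab$strain %in% keep, , drop = FALSE]
  fit <- stats::lm(tab[[trait]] ~ factor(tab$strain))
  an <- stats::anova(fit)
  ss <- an[["Sum Sq"]]
  list(h2 = ss[1] / sum(ss), F = an[["F value"]][1],
       df = an[["Df"]], p = an[["Pr(>F)"]][1],
       nStrains = length(keep), n = nrow(tab))
}

#' Nested ANOVA for laboratory origin within strain
#'
#' Fixed-effects ANOVA with lab origin nested within strain: sums of
#' squares for strain, lab-within-strain and residual; the F statistic for
#' the nested lab term; and the fraction of the total sum of squares
#' attributable to lab.
#'
#' @param table data.frame with columns `strain`, `lab` and the trait.
#' @param trait trait column name.
#' @return list with `F`, `df`, `p`, `varianceFraction` and the `anova`
#'   table.
#' @export
nestedAnovaEnv <- function(table, trait) {
  stopifnot(all(c("strain", "lab", trait) %in% names(table)))
  tab <- table[!is.na(table[[trait]]), , drop = FALSE]
  nlabs <- vapply(split(tab$lab, tab$strain),
                  function(l) length(unique(l)), integer(1))
  if (!any(nlabs >= 2))
    stop("no strain has individuals from multiple labs", call. = FALSE)
  strain <- factor(tab$strain); lab <- factor(tab$lab)
  fit <- stats::lm(tab[[trait]] ~ strain / lab)
  an <- stats::anova(fit)
  labRow <- grep(":lab", rownames(an))
  ss <- an[["Sum Sq"]]
  list(F = an[["F value"]][labRow], df = an[["Df"]],
       p = an[["Pr(>F)"]][labRow],
       varianceFraction = ss[labRow] / sum(ss), anova = an)
}

#' Correlation of strain-mean size and shape
#'
#' Pearson correlation between per-strain mean centroid size and mean LD1,
#' with the two-sided t-test p-value.
#'
#' @param table data.frame with columns `strain`, `CS` and `LD1`.
#' @param sizeTrait,shapeTrait column names (defaults "CS", "LD1").
#' @return list with `r`, `p`, `n` (number of strains) and the strain-mean
#'   data.frame.
#' @export
strainMeanCorrelation <- function(table, sizeTrait = "CS",
                                  shapeTrait = "LD1") {
  stopifnot(all(c("strain", sizeTrait, shapeTrait) %in% names(table)))
  ok <- !is.na(table[[sizeTrait]]) & !is.na(table[[shapeTrait]])
  tab <- table[ok, , drop = FALSE]
  ms <- tapply(tab[[sizeTrait]], tab$strain, mean)
  ml <- tapply(tab[[shapeTrait]], tab$strain, mean)
  if (length(ms) < 3) stop("need >= 3 strains with both traits",
                           call. = FALSE)
  if (sd(ms) == 0 || sd(ml) == 0)
    stop("zero variance in a strain-mean trait", call. = FALSE)
  ct <- stats::cor.test(ms, ml, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(ms),
       strainMeans = data.frame(strain = names(ms), size = as.numeric(ms),
                                shape = as.numeric(ml)))
}
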