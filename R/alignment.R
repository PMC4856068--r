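# Canonical alignment of bone point clouds: the composed rigid transform
# that puts the proximal end-slab centroid at the origin, the distal
# end-slab centroid on +z, the cross-section MBR long side on x, and the
# dorsal bow on +y.

## Half-open fractional band [lo, hi) of the z range, with symmetric
## thickness-doubling expansion (at most `maxDoublings`) while the band
## fails `need` (by default: nonempty).
bandIndices <- function(z, lo, hi, maxDoublings = 5L, what = "band",
                        need = length) {
  zmin <- min(z); L <- max(z) - zmin
  if (L <= 0) stop(what, ": zero z extent", call. = FALSE)
  u <- (z - zmin) / L
  widened <- 0L
  repeat {
    idx <- which(u >= lo & u < hi)
    if (need(idx)) return(list(idx = idx, widened = widened))
    if (widened >= maxDoublings)
      stop(what, " still deficient after ", maxDoublings, " doublings",
           call. = FALSE)
    c0 <- (lo + hi) / 2
    h <- (hi - lo) * 2
    lo <- max(0, c0 - h / 2)
    hi <- min(1 + 1e-12, c0 + h / 2)
    widened <- widened + 1L
  }
}

#' Furthest-apart pair of points in a cloud
#'
#' Finds a pair of points attaining the maximum pairwise Euclidean distance.
#' The search runs over the convex hull vertices (the diameter endpoints are
#' always hull vertices); ties are broken by lexicographic coordinate order
#' for determinism.
#'
#' @param cloud a [PointCloud-class], or an n x 3 matrix.
#' @return list with `a`, `b` (the two points, `a` lexicographically before
#'   `b`) and `distance`.
#' @examples
#' p <- rbind(c(0, 0, 0), c(0, 0, 10), c(0, 1, 5))
#' diameterPair(p)$distance
#' @export
diameterPair <- function(cloud) {
  p <- if (is(cloud, "PointCloud")) coords(cloud) else as.matrix(cloud)
  if (nrow(p) < 2) stop("diameterPair needs at least 2 points", call. = FALSE)
  scale <- max(abs(p)) + 1
  if (max(apply(p, 2, function(v) diff(range(v)))) < 1e-12 * scale)
    stop("degenerate geometry: all points identical", call. = FALSE)
  cand <- p
  if (nrow(p) >= 4) {
    hull <- tryCatch(convexHull3d(p), error = function(e) NULL)
    if (!is.null(hull)) cand <- p[hull$vertices, , drop = FALSE]
  }
  m <- nrow(cand)
  n2 <- rowNorms2(cand)
  best <- -1; pairs <- NULL
  chunk <- max(1L, min(m, floor(2e6 / m)))
  for (s in seq(1L, m, by = chunk)) {
    rows <- s:min(m, s + chunk - 1L)
    d2 <- outer(n2[rows], n2, `+`) -
      2 * cand[rows, , drop = FALSE] %*% t(cand)
    mx <- max(d2)
    if (mx > best + 1e-300) {
      best <- mx
      pairs <- which(d2 == mx, arr.ind = TRUE)
      pairs[, 1] <- rows[pairs[, 1]]
    } else if (mx == best) {
      extra <- which(d2 == mx, arr.ind = TRUE)
      extra[, 1] <- rows[extra[, 1]]
      pairs <- rbind(pairs, extra)
    }
  }
  # canonicalize each pair (a lexicographically <= b), then pick the
  # lexicographically smallest pair
  ptsA <- cand[pairs[, 1], , drop = FALSE]
  ptsB <- cand[pairs[, 2], , drop = FALSE]
  swap <- apply(ptsA - ptsB, 1, function(d) {
    nz <- which(d != 0)[1]
    !is.na(nz) && d[nz] > 0
  })
  tmp <- ptsA[swap, , drop = FALSE]
  ptsA[swap, ] <- ptsB[swap, , drop = FALSE]
  ptsB[swap, ] <- tmp
  o <- lexOrder(cbind(ptsA, ptsB))[1]
  list(a = unname(ptsA[o, ]), b = unname(ptsB[o, ]),
       distance = sqrt(max(best, 0)))
}

## Centroid of one end slab under the configured mode, with a fallback to
## the plain slab centroid (plus warning string) for degenerate slabs.
endSlabCentroid <- function(slab, mode) {
  warn <- character()
  cent <- NULL
  if (mode != "plain" && nrow(slab) >= 4) {
    hull <- tryCatch(convexHull3d(slab), error = function(e) NULL)
    if (!is.null(hull)) {
      cent <- if (mode == "hull_volume") hullVolumeCentroid(slab, hull)
              else colMeans(slab[hull$vertices, , drop = FALSE])
    }
  }
  if (is.null(cent)) {
    if (mode != "plain")
      warn <- "degenerate end slab: fell back to plain slab centroid"
    cent <- colMeans(slab)
  }
  list(centroid = cent, warn = warn)
}

#' One step of end-centroid registration
#'
#' With a provisional z axis already applied, slices out the proximal and
#' distal `endFrac` slabs of the z extent, computes the centroid of each
#' slab's convex hull, and returns the rigid transform mapping the proximal
#' centroid to the origin and the distal centroid onto +z.
#'
#' @param points n x 3 matrix in the provisional frame.
#' @param endFrac end-slab fraction of the z extent (default 0.10).
#' @param mode end-slab centroid mode: `"hull_volume"` (volume-weighted
#'   centroid of the slab hull polyhedron; robust to point density),
#'   `"hull_vertex"` (mean of hull vertices) or `"plain"`.
#' @return list with `transform` (a [RigidTransform-class]) and `warnings`.
#' @export
endCentroidRegistration <- function(points, endFrac = 0.10,
                                    mode = "hull_volume") {
  p <- as.matrix(points)
  z <- p[, 3]
  prox <- bandIndices(z, 0, endFrac, what = "proximal end slab")
  dist_ <- bandIndices(z, 1 - endFrac, 1 + 1e-12, what = "distal end slab")
  cp <- endSlabCentroid(p[prox$idx, , drop = FALSE], mode)
  cd <- endSlabCentroid(p[dist_$idx, , drop = FALSE], mode)
  axis <- cd$centroid - cp$centroid
  if (sqrt(sum(axis^2)) < 1e-12 * (max(abs(p)) + 1))
    stop("degenerate geometry: coincident end centroids", call. = FALSE)
  R <- rotationBetween(axis, c(0, 0, 1))
  tr <- new("RigidTransform", rotation = R,
            translation = as.numeric(-R %*% cp$centroid))
  list(transform = tr, warnings = c(cp$warn, cd$warn))
}

#' Orient the cross-section MBR long side along x
#'
#' Slices out the points whose z lies in the `band` fraction interval of
#' the z extent, computes the minimum bounding rectangle of their x-y
#' projection, and returns the rotation about z (the smaller of the two
#' half-turn-equivalent angles) that makes the MBR long side parallel to x.
#'
#' @param points n x 3 matrix in the end-registered frame.
#' @param band length-2 fraction interval (default `c(0.1500, 0.1525)`).
#' @return list with `transform`, `angle` (applied rotation angle, radians)
#'   and `warnings` (band expansion notices).
#' @export
mbrOrient <- function(points, band = c(0.1500, 0.1525)) {
  p <- as.matrix(points)
  bi <- bandIndices(p[, 3], band[1], band[2], what = "MBR band")
  warns <- if (bi$widened > 0)
    sprintf("MBR band widened %d time(s)", bi$widened) else character()
  m <- mbr2d(p[bi$idx, 1:2, drop = FALSE])
  a <- m$angle                      # long-side direction, [0, pi)
  delta <- if (a <= pi / 2) -a else pi - a
  tr <- new("RigidTransform", rotation = rotZMat(delta),
            translation = c(0, 0, 0))
  list(transform = tr, angle = delta, warnings = warns)
}

#' Resolve the dorsoventral orientation
#'
#' Uses the bone's distal curvature: if the mean y of the most-distal
#' `distalFrac` of the points is negative, a 180-degree rotation about z
#' (a proper rotation; chirality is preserved) flips dorsal onto +y. When
#' the distal mean y is statistically indistinguishable from zero (within
#' 3 standard errors), no flip is applied and an ambiguity warning is
#' recorded.
#'
#' @param points n x 3 matrix in the MBR-oriented frame.
#' @param distalFrac distal fraction examined (default 0.25).
#' @return list with `transform`, `flipped` (logical) and `warnings`.
#' @export
resolveDorsoventral <- function(points, distalFrac = 0.25) {
  p <- as.matrix(points)
  bi <- bandIndices(p[, 3], 1 - distalFrac, 1 + 1e-12,
                    what = "distal quarter")
  y <- p[bi$idx, 2]
  my <- mean(y)
  se <- if (length(y) > 1) sd(y) / sqrt(length(y)) else 0
  ambig <- abs(my) <= max(3 * se, 1e-12)
  warns <- character(); flipped <- FALSE
  R <- diag(3)
  if (ambig) {
    warns <- "dorsoventral orientation ambiguous (distal curvature ~ 0); no flip applied"
  } else if (my < 0) {
    R <- rotZMat(pi)
    flipped <- TRUE
  }
  list(transform = new("RigidTransform", rotation = R,
                       translation = c(0, 0, 0)),
       flipped = flipped, warnings = warns)
}

## Compose t2 after t1: y = R2 (R1 x + t1) + t2.
composeTransforms <- function(t2, t1) {
  new("RigidTransform", rotation = t2@rotation %*% t1@rotation,
      translation = as.numeric(t2@rotation %*% t1@translation) +
        t2@translation)
}

#' Apply a rigid transform to points
#'
#' @param points n x 3 matrix.
#' @param transform a [RigidTransform-class].
#' @return transformed n x 3 matrix.
#' @export
applyTransform <- function(points, transform) {
  sweep(as.matrix(points) %*% t(transform@rotation), 2,
        -transform@translation)
}

#' Align a bone point cloud to the canonical frame
#'
#' Composes the full alignment: (1) the furthest-apart point pair defines a
#' provisional proximal-distal z axis; the broader end (larger end-slab MBR
#' area, the baculum base) is taken as proximal; (2) end-slab hull-centroid
#' registration places the proximal centroid at the origin and the distal
#' centroid on +z (iterated to its fixed point, which makes the alignment
#' idempotent); (3) the 15.00-15.25% cross-section band's MBR long side is
#' rotated onto x; (4) distal curvature resolves the dorsoventral sign.
#'
#' @param cloud a [PointCloud-class].
#' @param config a [PipelineConfig-class] (defaults from `pipelineConfig()`).
#' @param proximalEnd `"auto"` (larger end-slab MBR area), `"low"` or
#'   `"high"`: which end of the provisional diameter axis is proximal.
#' @param maxIter maximum end-registration fixed-point iterations.
#' @return an [AlignedCloud-class] with the composed transform recorded.
#' @examples
#' ph <- generateBone(bonePhantomParams(nPoints = 2000, seed = 1))
#' al <- alignBaculum(ph)
#' al@zLength
#' @export
alignBaculum <- function(cloud, config = pipelineConfig(),
                         proximalEnd = c("auto", "low", "high"),
                         maxIter = 60L) {
  proximalEnd <- match.arg(proximalEnd)
  p0 <- coords(cloud)
  if (nrow(p0) < 4)
    stop("alignment stage diameter: need at least 4 points", call. = FALSE)
  warns <- character()

  # step 1: provisional axis from the diameter pair
  dp <- tryCatch(diameterPair(p0), error = function(e)
    stop("alignment stage diameter (", specimenId(cloud), "): ",
         conditionMessage(e), call. = FALSE))
  axis <- dp$b - dp$a
  tot <- new("RigidTransform", rotation = rotationBetween(axis, c(0, 0, 1)),
             translation = c(0, 0, 0))
  p <- applyTransform(p0, tot)

  # proximal-end identification: the broader end (larger end-slab MBR area)
  lowIdx <- bandIndices(p[, 3], 0, config@endFrac)$idx
  highIdx <- bandIndices(p[, 3], 1 - config@endFrac, 1 + 1e-12)$idx
  slabArea <- function(idx) {
    tryCatch(mbr2d(p[idx, 1:2, drop = FALSE])$area,
             error = function(e) prod(apply(p[idx, 1:2, drop = FALSE], 2,
                                            function(v) diff(range(v)))))
  }
  proxLow <- switch(proximalEnd,
    low = TRUE, high = FALSE,
    auto = slabArea(lowIdx) >= slabArea(highIdx))
  if (!proxLow) {
    flip <- new("RigidTransform", rotation = rotXMat(pi),
                translation = c(0, 0, 0))
    tot <- composeTransforms(flip, tot)
    p <- applyTransform(p0, tot)
  }

  # step 2: end-centroid registration, iterated to a fixed point
  for (it in seq_len(maxIter)) {
    st <- tryCatch(
      endCentroidRegistration(p, config@endFrac, config@endCentroidMode),
      error = function(e) stop("alignment stage end-registration (",
        specimenId(cloud), "): ", conditionMessage(e), call. = FALSE))
    warns <- c(warns, st$warnings)
    tot <- composeTransforms(st$transform, tot)
    p <- applyTransform(p0, tot)
    drift <- max(abs(st$transform@rotation - diag(3)),
                 abs(st$transform@translation) / (diff(range(p[, 3])) + 1e-300))
    if (drift < 1e-12) break
  }

  # step 3: MBR orientation about z
  mo <- tryCatch(mbrOrient(p, config@mbrBand), error = function(e)
    stop("alignment stage mbr-orient (", specimenId(cloud), "): ",
         conditionMessage(e), call. = FALSE))
  warns <- c(warns, mo$warnings)
  tot <- composeTransforms(mo$transform, tot)
  p <- applyTransform(p0, tot)

  # step 4: dorsoventral sign from distal curvature
  dv <- resolveDorsoventral(p, config@distalFrac)
  warns <- c(warns, dv$warnings)
  tot <- composeTransforms(dv$transform, tot)
  p <- applyTransform(p0, tot)

  new("AlignedCloud", coords = p, voxelSize = cloud@voxelSize,
      specimenId = specimenId(cloud), meta = cloud@meta, transform = tot,
      zLength = diff(range(p[, 3])), dvFlipped = dv$flipped,
      stageWarnings = unique(warns))
}
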