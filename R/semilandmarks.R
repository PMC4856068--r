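# Rule-based semilandmark extraction: 50 cross-sectional slices x 16
# labeled points plus the two tips, and centroid size.

sliceCenters <- function(zmin, zLength, nSlices) {
  zmin + (seq_len(nSlices) - 0.5) / nSlices * zLength
}

#' Points of one cross-sectional slice band
#'
#' Slice `i` (1-based) is the half-open z band
#' `[c_i - t/2, c_i + t/2)` with center
#' `c_i = z_min + (i - 0.5)/n_slices * z_length` and thickness
#' `t = slice_thickness_frac * z_length`. An empty band is widened by
#' symmetric thickness doubling, at most 5 times.
#'
#' @param cloud an [AlignedCloud-class] (or n x 3 matrix in the aligned
#'   frame).
#' @param i slice index, `1 <= i <= nSlices`.
#' @param config a [PipelineConfig-class].
#' @return list with `idx` (row indices of the band points), `center`
#'   (band center z) and `widened` (number of doublings applied).
#' @export
sliceBand <- function(cloud, i, config = pipelineConfig()) {
  p <- if (is(cloud, "PointCloud")) coords(cloud) else as.matrix(cloud)
  n <- config@nSlices
  if (i < 1 || i > n)
    stop(sprintf("slice index %d outside 1..%d", i, n), call. = FALSE)
  z <- p[, 3]
  zmin <- min(z); L <- max(z) - zmin
  ci <- zmin + (i - 0.5) / n * L
  t <- config@sliceThicknessFrac * L
  lo <- (ci - t / 2 - zmin) / L
  hi <- (ci + t / 2 - zmin) / L
  # a band is usable once it has two distinct x values (the slice rules
  # need a nonzero width); sparse tip bands widen like empty ones
  usable <- function(idx) length(idx) >= 2 &&
    diff(range(p[idx, 1])) > 0
  bi <- tryCatch(bandIndices(z, lo, hi, what = sprintf("slice %d", i),
                             need = usable),
                 error = function(e) stop(conditionMessage(e), call. = FALSE))
  list(idx = bi$idx, center = ci, widened = bi$widened)
}

## Deterministic extremal pick: first row under the given column priority
## (each column optionally negated for "largest").
pickExtremal <- function(m, prior) {
  cols <- lapply(seq_along(prior), function(j) {
    v <- m[, abs(prior[j])]
    if (prior[j] < 0) -v else v
  })
  do.call(order, cols)[1]
}

#' Semilandmarks of one slice band
#'
#' With slice width `W = x_max - x_min`, places `nLines` interior lines at
#' `x_l = x_min + l/(nLines+1) * W`. For each line, points within
#' `projectionTolFrac * W` of the line are projected onto it (x set to
#' `x_l`, y and z kept) and the dorsalmost (max y) and ventralmost (min y)
#' become semilandmarks; the band's leftmost and rightmost points complete
#' the slice, 16 points at defaults. An empty projection window is doubled
#' up to 5 times. Ties are broken by smallest z, then the smallest remaining
#' coordinate.
#'
#' @param band m x 3 matrix of band points (at least 2 distinct x values).
#' @param config a [PipelineConfig-class].
#' @return list with `coords` (`2*nLines + 2` x 3 matrix), `roles`
#'   (character labels: `dorsal_l`, `ventral_l`, `leftmost`, `rightmost`)
#'   and `warnings`.
#' @export
sliceSemilandmarks <- function(band, config = pipelineConfig()) {
  b <- as.matrix(band)
  xr <- range(b[, 1])
  W <- diff(xr)
  if (nrow(b) < 2 || W <= 0)
    stop("slice band needs >= 2 points with distinct x", call. = FALSE)
  nl <- config@nLines
  warns <- character()
  outC <- matrix(NA_real_, 2 * nl + 2, 3)
  roles <- character(2 * nl + 2)
  for (l in seq_len(nl)) {
    xl <- xr[1] + l / (nl + 1) * W
    tolw <- config@projectionTolFrac * W
    doubled <- 0L
    repeat {
      win <- which(abs(b[, 1] - xl) <= tolw)
      if (length(win)) break
      if (doubled >= 5L)
        stop(sprintf("projection window empty at line %d after 5 doublings",
                     l), call. = FALSE)
      tolw <- tolw * 2; doubled <- doubled + 1L
    }
    if (doubled > 0)
      warns <- c(warns, sprintf("projection window doubled %d time(s) at line %d",
                                doubled, l))
    w <- b[win, , drop = FALSE]
    w[, 1] <- xl                       # project onto the line
    di <- pickExtremal(w, c(-2, 3, 1)) # dorsal: max y, then min z, min x
    vi <- pickExtremal(w, c(2, 3, 1))  # ventral: min y
    outC[l, ] <- w[di, ];            roles[l] <- sprintf("dorsal_%d", l)
    outC[nl + l, ] <- w[vi, ];       roles[nl + l] <- sprintf("ventral_%d", l)
  }
  li <- pickExtremal(b, c(1, 3, 2))    # leftmost: min x, then min z, min y
  ri <- pickExtremal(b, c(-1, 3, 2))   # rightmost: max x
  outC[2 * nl + 1, ] <- b[li, ]; roles[2 * nl + 1] <- "leftmost"
  outC[2 * nl + 2, ] <- b[ri, ]; roles[2 * nl + 2] <- "rightmost"
  list(coords = outC, roles = roles, warnings = warns)
}

#' Extract the full labeled semilandmark configuration
#'
#' Runs `sliceSemilandmarks` over all `nSlices` bands and appends the global
#' minimum-z point (proximal tip) and maximum-z point (distal tip):
#' `nSlices x (2*nLines + 2) + 2` labeled points in fixed order (802 at the
#' default 50 slices and 7 lines).
#'
#' @param cloud an [AlignedCloud-class].
#' @param config a [PipelineConfig-class].
#' @return a [SemilandmarkSet-class] with centroid size filled in.
#' @examples
#' ph <- generateBone(bonePhantomParams(nPoints = 8000, seed = 1))
#' lms <- extractSemilandmarks(alignBaculum(ph))
#' nrow(coords(lms))   # 802
#' @export
extractSemilandmarks <- function(cloud, config = pipelineConfig()) {
  p <- coords(cloud)
  n <- config@nSlices
  per <- 2 * config@nLines + 2
  outC <- matrix(NA_real_, n * per + 2, 3)
  slice <- rep(NA_integer_, n * per + 2)
  role <- character(n * per + 2)
  for (i in seq_len(n)) {
    bd <- sliceBand(cloud, i, config)
    sl <- sliceSemilandmarks(p[bd$idx, , drop = FALSE], config)
    rows <- (i - 1) * per + seq_len(per)
    outC[rows, ] <- sl$coords
    slice[rows] <- i
    role[rows] <- sl$roles
  }
  pi_ <- pickExtremal(p, c(3, 2, 1))   # proximal tip: min z
  di_ <- pickExtremal(p, c(-3, 2, 1))  # distal tip: max z
  outC[n * per + 1, ] <- p[pi_, ]; role[n * per + 1] <- "proximal_tip"
  outC[n * per + 2, ] <- p[di_, ]; role[n * per + 2] <- "distal_tip"
  lm <- new("SemilandmarkSet", coords = outC,
            labels = data.frame(slice = slice, role = role,
                                stringsAsFactors = FALSE),
            centroidSize = centroidSize(outC),
            specimenId = specimenId(cloud))
  lm
}

#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared distances of the landmarks from
#' their centroid: invariant to rotation and translation, and linear under
#' isotropic scaling.
#'
#' @param x a [SemilandmarkSet-class] or an n x 3 coordinate matrix.
#' @return nonnegative scalar.
#' @examples
#' centroidSize(rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0)))
#' @export
centroidSize <- function(x) {
  p <- if (is(x, "SemilandmarkSet")) x@coords else as.matrix(x)
  if (!nrow(p)) stop("centroidSize needs at least one point", call. = FALSE)
  sqrt(sum(sweep(p, 2, colMeans(p))^2))
}

#' Write semilandmarks to CSV
#'
#' One row per landmark in fixed order: specimen_id, slice, role, x, y, z.
#'
#' @param lms a [SemilandmarkSet-class].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeLandmarksCSV <- function(lms, path) {
  df <- data.frame(specimen_id = specimenId(lms), slice = lms@labels$slice,
                   role = lms@labels$role, x = lms@coords[, 1],
                   y = lms@coords[, 2], z = lms@coords[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read semilandmarks from CSV
#'
#' @param path CSV written by [writeLandmarksCSV()].
#' @return a [SemilandmarkSet-class].
#' @export
readLandmarksCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- unname(as.matrix(df[, c("x", "y", "z")]))
  new("SemilandmarkSet", coords = m,
      labels = data.frame(slice = df$slice, role = df$role,
                          stringsAsFactors = FALSE),
      centroidSize = centroidSize(m), specimenId = df$specimen_id[1])
}
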