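# Convex-hull machinery: 2D minimum bounding rectangle via rotating
# calipers, and an incremental 3D convex hull (with an Akl-Toussaint
# extreme-point pre-filter) used for the cloud diameter and the
# end-slab hull centroids.

#' Minimum-area bounding rectangle of a 2D point set
#'
#' Computes the minimum-area enclosing rectangle by rotating calipers over
#' the edges of the convex hull: the optimal rectangle has one side collinear
#' with a hull edge, so only hull-edge orientations need be examined.
#'
#' @param xy n x 2 numeric matrix, n >= 3, not all collinear.
#' @return list with `angle` (orientation of the long side, radians in
#'   `[0, pi)`), `long`, `short` (side lengths, `long >= short`), and
#'   `area`.
#' @examples
#' rect <- rbind(c(0, 0), c(4, 0), c(4, 2), c(0, 2))
#' mbr2d(rect)$long
#' @export
mbr2d <- function(xy) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3) stop("mbr2d needs at least 3 points", call. = FALSE)
  stopIfNotFinite(xy, "mbr2d input")
  h <- grDevices::chull(xy)
  hp <- xy[h, , drop = FALSE]
  if (nrow(hp) < 3) stop("mbr2d: points are collinear", call. = FALSE)
  # collinearity check via the hull's area (shoelace)
  x <- hp[, 1]; y <- hp[, 2]
  area2 <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y))
  scale <- max(abs(hp)) + 1
  if (area2 < 1e-12 * scale^2)
    stop("mbr2d: points are collinear", call. = FALSE)

  edges <- rbind(hp[-1, , drop = FALSE], hp[1, , drop = FALSE]) - hp
  ang <- atan2(edges[, 2], edges[, 1]) %% pi
  ang <- unique(round(ang, 12))
  best <- NULL
  for (a in ang) {
    ca <- cos(-a); sa <- sin(-a)
    rx <- hp[, 1] * ca - hp[, 2] * sa
    ry <- hp[, 1] * sa + hp[, 2] * ca
    wx <- max(rx) - min(rx)
    wy <- max(ry) - min(ry)
    area <- wx * wy
    if (is.null(best) || area < best$area - 1e-15 * scale^2) {
      long_along_x <- wx >= wy
      best <- list(
        angle = (if (long_along_x) a else a + pi / 2) %% pi,
        long = max(wx, wy), short = min(wx, wy), area = area)
    }
  }
  best
}

## ---- 3D convex hull ------------------------------------------------------

## Initial non-degenerate tetrahedron: indices of 4 affinely independent
## points, or NULL when the cloud is (near-)degenerate.
initialSimplex <- function(p, eps) {
  i1 <- which.min(p[, 1]); i2 <- which.max(p[, 1])
  if (max(p[, 1]) - min(p[, 1]) < eps) {
    i1 <- which.min(p[, 2]); i2 <- which.max(p[, 2])
  }
  d <- p[i2, ] - p[i1, ]
  if (sqrt(sum(d^2)) < eps) return(NULL)
  d <- d / sqrt(sum(d^2))
  rel <- sweep(p, 2, p[i1, ])
  perp <- rel - outer(as.vector(rel %*% d), d)
  i3 <- which.max(rowNorms2(perp))
  if (sqrt(rowNorms2(perp)[i3]) < eps) return(NULL)
  n <- pracmaFreeCross(p[i2, ] - p[i1, ], p[i3, ] - p[i1, ])
  n <- n / sqrt(sum(n^2))
  h <- abs(as.vector(rel %*% n))
  i4 <- which.max(h)
  if (h[i4] < eps) return(NULL)
  c(i1, i2, i3, i4)
}

pracmaFreeCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Akl-Toussaint style pre-filter: points strictly inside the hull of the
## directional extremes can never be hull vertices and are discarded.
aklToussaintFilter <- function(p, eps) {
  dirs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  proj <- p %*% t(dirs)
  ext <- unique(apply(proj, 2, which.max))
  if (length(ext) < 4) return(seq_len(nrow(p)))
  hull <- tryCatch(convexHull3d(p[ext, , drop = FALSE], prefilter = FALSE),
                   error = function(e) NULL)
  if (is.null(hull)) return(seq_len(nrow(p)))
  inside <- rep(TRUE, nrow(p))
  for (f in seq_len(nrow(hull$normals))) {
    inside <- inside &
      (p %*% hull$normals[f, ] <= hull$offsets[f] - eps)
    if (!any(inside)) break
  }
  sort(unique(c(which(!inside), ext)))
}

#' Convex hull of a 3D point set
#'
#' Incremental convex hull. Returns hull vertices and outward-oriented
#' triangular faces; large clouds are pre-filtered by discarding points
#' strictly inside the polytope of directional extremes.
#'
#' @param p n x 3 numeric matrix, n >= 4, not all coplanar.
#' @param prefilter apply the extreme-point pre-filter (default TRUE).
#' @return list with `vertices` (indices into `p` of hull vertices),
#'   `faces` (m x 3 index matrix, outward orientation), `normals`
#'   (m x 3 unit outward normals) and `offsets` (m-vector, face plane is
#'   `normal . x = offset`).
#' @export
convexHull3d <- function(p, prefilter = TRUE) {
  p <- as.matrix(p)
  if (nrow(p) < 4) stop("convexHull3d needs at least 4 points", call. = FALSE)
  scale <- max(abs(p)) + 1
  eps <- 1e-10 * scale
  idx <- seq_len(nrow(p))
  if (prefilter && nrow(p) > 200) {
    keep <- aklToussaintFilter(p, eps)
    idx <- idx[keep]
  }
  q <- p[idx, , drop = FALSE]
  init <- initialSimplex(q, eps)
  if (is.null(init))
    stop("convexHull3d: degenerate (coplanar or collinear) input",
         call. = FALSE)
  interior <- colMeans(q[init, ])

  maxF <- 8L * nrow(q) + 16L
  faceV <- matrix(0L, maxF, 3)        # vertex indices into q
  faceN <- matrix(0, maxF, 3)         # outward normals
  faceD <- numeric(maxF)              # offsets
  alive <- logical(maxF)
  nf <- 0L

  addFace <- function(a, b, c) {
    n <- pracmaFreeCross(q[b, ] - q[a, ], q[c, ] - q[a, ])
    nn <- sqrt(sum(n^2))
    if (nn < eps^2) return(invisible(NULL))   # degenerate sliver, skip
    n <- n / nn
    d <- sum(n * q[a, ])
    if (sum(n * interior) > d) { n <- -n; d <- -d }
    nf <<- nf + 1L
    if (nf > nrow(faceV)) {
      faceV <<- rbind(faceV, matrix(0L, maxF, 3))
      faceN <<- rbind(faceN, matrix(0, maxF, 3))
      faceD <<- c(faceD, numeric(maxF))
      alive <<- c(alive, logical(maxF))
    }
    faceV[nf, ] <<- c(a, b, c)
    faceN[nf, ] <<- n
    faceD[nf] <<- d
    alive[nf] <<- TRUE
    invisible(NULL)
  }

  combs <- utils::combn(4, 3)
  for (j in seq_len(ncol(combs))) {
    v <- init[combs[, j]]
    addFace(v[1], v[2], v[3])
  }

  rest <- setdiff(seq_len(nrow(q)), init)
  for (i in rest) {
    live <- which(alive[seq_len(nf)])
    vis <- live[faceN[live, , drop = FALSE] %*% q[i, ] - faceD[live] > eps]
    if (!length(vis)) next
    # horizon: edges belonging to exactly one visible face
    vv <- faceV[vis, , drop = FALSE]
    e1 <- rbind(vv[, c(1, 2), drop = FALSE], vv[, c(2, 3), drop = FALSE],
                vv[, c(3, 1), drop = FALSE])
    key <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
    tab <- table(key)
    horizon <- e1[key %in% names(tab)[tab == 1L], , drop = FALSE]
    alive[vis] <- FALSE
    for (k in seq_len(nrow(horizon)))
      addFace(horizon[k, 1], horizon[k, 2], i)
  }

  live <- which(alive[seq_len(nf)])
  fv <- faceV[live, , drop = FALSE]
  verts <- sort(unique(as.vector(fv)))
  list(vertices = idx[verts],
       faces = matrix(idx[fv], ncol = 3),
       normals = faceN[live, , drop = FALSE],
       offsets = faceD[live])
}

## Volume-weighted centroid of the hull polyhedron: signed tetrahedral
## decomposition against an interior reference point.
hullVolumeCentroid <- function(p, hull) {
  faces <- hull$faces
  o <- colMeans(p[hull$vertices, , drop = FALSE])
  a <- p[faces[, 1], , drop = FALSE]
  b <- p[faces[, 2], , drop = FALSE]
  c_ <- p[faces[, 3], , drop = FALSE]
  ao <- sweep(a, 2, o); bo <- sweep(b, 2, o); co <- sweep(c_, 2, o)
  cr <- cbind(bo[, 2] * co[, 3] - bo[, 3] * co[, 2],
              bo[, 3] * co[, 1] - bo[, 1] * co[, 3],
              bo[, 1] * co[, 2] - bo[, 2] * co[, 1])
  # `o` is interior to the hull, so the face tetrahedra partition the
  # solid; face winding is arbitrary, hence unsigned volumes
  vol <- abs(rowSums(ao * cr)) / 6
  cent <- (a + b + c_ + matrix(o, nrow(a), 3, byrow = TRUE)) / 4
  tot <- sum(vol)
  if (abs(tot) < 1e-300)
    return(unname(colMeans(p[hull$vertices, , drop = FALSE])))
  unname(colSums(cent * vol) / tot)
}
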