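# Point-cloud input/output and voxel-stack segmentation.

#' Read an xyz point-cloud text file
#'
#' Reads a whitespace- or comma-delimited text file with three numeric
#' columns per row (lines starting with `#` are comments). Coordinates are
#' multiplied by `voxelSize` when `scale = TRUE`, mapping voxel indices to
#' physical units.
#'
#' @param path file path.
#' @param voxelSize physical length per voxel (default 0.0155, i.e. 15.5
#'   micrometres expressed in millimetres).
#' @param specimenId specimen identifier; defaults to the file name without
#'   extension.
#' @param scale multiply coordinates by `voxelSize` (default FALSE: the file
#'   is taken to already be in physical units).
#' @param meta free-form metadata list.
#' @return a [PointCloud-class].
#' @examples
#' f <- tempfile(fileext = ".xyz")
#' writeLines(c("0 0 0", "1 0 0", "0 1 0", "0 0 1"), f)
#' readXYZ(f)
#' @export
readXYZ <- function(path, voxelSize = 0.0155, specimenId = NULL,
                    scale = FALSE, meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (!length(rows)) stop("no data rows in ", path, call. = FALSE)
  pts <- matrix(NA_real_, length(rows), 3)
  for (k in seq_along(rows)) {
    fields <- strsplit(trimws(lines[rows[k]]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 3 || anyNA(vals))
      stop(sprintf("malformed row at line %d of %s: '%s'",
                   rows[k], path, lines[rows[k]]), call. = FALSE)
    pts[k, ] <- vals
  }
  if (nrow(pts) < 4)
    stop("degenerate input: fewer than 4 points in ", path, call. = FALSE)
  if (scale) pts <- pts * voxelSize
  if (is.null(specimenId))
    specimenId <- sub("\\.[^.]*$", "", basename(path))
  new("PointCloud", coords = pts, voxelSize = voxelSize,
      specimenId = specimenId, meta = meta)
}

#' Write a point cloud to an xyz text file
#'
#' Writes three full-precision numeric columns per row; `readXYZ` round-trips
#' the coordinates bit-exactly.
#'
#' @param cloud a [PointCloud-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeXYZ <- function(cloud, path) {
  p <- coords(cloud)
  txt <- paste(format(p[, 1], digits = 17, trim = TRUE, scientific = FALSE),
               format(p[, 2], digits = 17, trim = TRUE, scientific = FALSE),
               format(p[, 3], digits = 17, trim = TRUE, scientific = FALSE))
  writeLines(c(sprintf("# specimen %s, voxel size %.17g", specimenId(cloud),
                       cloud@voxelSize), txt), path)
  invisible(path)
}

#' Read a multi-page TIFF as a voxel stack
#'
#' @param path path to a (multi-page) grayscale TIFF; each page is one
#'   z slice.
#' @return 3D numeric array indexed `[row, col, slice]`.
#' @export
readStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) if (length(dim(m)) == 3) m[, , 1] else m)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Segment bones out of a voxel stack
#'
#' Thresholds a 3D grayscale voxel grid and groups foreground voxels into
#' 26-connected components. Interior voxels are kept (micro-CT bone images
#' include internal structure, not just the surface). Components with at
#' least `minVoxels` voxels are returned as point clouds in physical units
#' (0-based voxel index times `voxelSize`), sorted by size, largest first.
#'
#' @param stack 3D numeric array of intensities.
#' @param threshold intensity threshold; voxels `>= threshold` are foreground.
#' @param minVoxels minimum component size to keep (default 1).
#' @param voxelSize physical length per voxel (default 0.0155).
#' @param idPrefix prefix for generated specimen ids (default "component").
#' @return list of [PointCloud-class] objects (possibly empty, with a
#'   warning, when no component reaches `minVoxels`).
#' @export
segmentStack <- function(stack, threshold, minVoxels = 1L,
                         voxelSize = 0.0155, idPrefix = "component") {
  if (length(dim(stack)) != 3) stop("stack must be a 3D array", call. = FALSE)
  if (!length(stack)) stop("stack is empty", call. = FALSE)
  fg <- which(stack >= threshold)
  if (!length(fg)) {
    warning("no voxels at or above threshold; returning empty list")
    return(list())
  }
  dm <- dim(stack)
  ijk <- arrayInd(fg, dm)
  lab <- labelComponents26(ijk, dm, fg)
  sizes <- table(lab)
  keep <- names(sizes)[sizes >= minVoxels]
  if (!length(keep)) {
    warning("no connected component reaches minVoxels; returning empty list")
    return(list())
  }
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  out <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    pts <- (ijk[lab == keep[k], , drop = FALSE] - 1) * voxelSize
    out[[k]] <- new("PointCloud", coords = pts, voxelSize = voxelSize,
                    specimenId = sprintf("%s_%d", idPrefix, k),
                    meta = list(n_voxels = sum(lab == keep[k])))
  }
  out
}

## 26-connected component labels for foreground voxels. Builds the adjacency
## graph over the 13 forward neighbor shifts and labels with igraph.
labelComponents26 <- function(ijk, dm, linIdx) {
  n <- nrow(ijk)
  pos <- integer(prod(dm))
  pos[linIdx] <- seq_len(n)
  shifts <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  shifts <- shifts[shifts[, 3] > 0 |
                   (shifts[, 3] == 0 & (shifts[, 2] > 0 |
                    (shifts[, 2] == 0 & shifts[, 1] > 0))), , drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (s in seq_len(nrow(shifts))) {
    ni <- ijk[, 1] + shifts[s, 1]
    nj <- ijk[, 2] + shifts[s, 2]
    nk <- ijk[, 3] + shifts[s, 3]
    ok <- ni >= 1 & ni <= dm[1] & nj >= 1 & nj <= dm[2] & nk >= 1 & nk <= dm[3]
    if (!any(ok)) next
    nlin <- ni[ok] + (nj[ok] - 1) * dm[1] + (nk[ok] - 1) * dm[1] * dm[2]
    hit <- pos[nlin]
    present <- hit > 0
    from <- c(from, which(ok)[present])
    to <- c(to, hit[present])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  igraph::components(g)$membership
}
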