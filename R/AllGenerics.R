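#' Coordinates of a geometric object
#'
#' @param x a [PointCloud-class] or [SemilandmarkSet-class].
#' @return numeric n x 3 matrix of coordinates.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "PointCloud", function(x) x@coords)

#' @rdname coords
#' @export
setMethod("coords", "SemilandmarkSet", function(x) x@coords)

#' Specimen identifier
#'
#' @param x a [PointCloud-class] or [SemilandmarkSet-class].
#' @return character scalar.
#' @export
setGeneric("specimenId", function(x) standardGeneric("specimenId"))

#' @rdname specimenId
#' @export
setMethod("specimenId", "PointCloud", function(x) x@specimenId)

#' @rdname specimenId
#' @export
setMethod("specimenId", "SemilandmarkSet", function(x) x@specimenId)

#' Pairwise Procrustes distance matrix of a shape space
#'
#' @param x a [ShapeSpace-class].
#' @return symmetric numeric matrix with specimen ids as dimnames.
#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))

#' @rdname distMatrix
#' @export
setMethod("distMatrix", "ShapeSpace", function(x) {
  d <- x@dist
  dimnames(d) <- list(x@specimenIds, x@specimenIds)
  d
})

#' Per-marker LOD table of a genome scan
#'
#' @param x a [ScanResult-class].
#' @return data.frame with columns marker, chr, pos, lod, effect, r2.
#' @export
setGeneric("lodTable", function(x) standardGeneric("lodTable"))

#' @rdname lodTable
#' @export
setMethod("lodTable", "ScanResult", function(x) x@table)

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n")
  cat("  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", format(object@translation, digits = 6), "\n")
})

setMethod("show", "PointCloud", function(object) {
  cat(class(object), sprintf("'%s': %d points, voxel size %g\n",
      object@specimenId, nrow(object@coords), object@voxelSize))
  rng <- apply(object@coords, 2, range)
  cat(sprintf("  extent: x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g]\n",
      rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(object@meta),
                         sep = "=", collapse = ", "), "\n")
})

setMethod("show", "AlignedCloud", function(object) {
  callNextMethod()
  cat(sprintf("  aligned: z length %.4g, dorsoventral flip %s\n",
      object@zLength, if (object@dvFlipped) "applied" else "not needed"))
  if (length(object@stageWarnings))
    cat("  warnings:", paste(object@stageWarnings, collapse = "; "), "\n")
})

setMethod("show", "SemilandmarkSet", function(object) {
  cat(sprintf("SemilandmarkSet '%s': %d landmarks, centroid size %.5g\n",
      object@specimenId, nrow(object@coords), object@centroidSize))
})

setMethod("show", "ShapeSpace", function(object) {
  cat(sprintf("ShapeSpace: %d specimens, %d landmarks%s\n",
      length(object@specimenIds), nrow(object@consensus),
      if (object@slid) ", slid semilandmarks" else ""))
  d <- object@dist[upper.tri(object@dist)]
  if (length(d))
    cat(sprintf("  pairwise distances: median %.4g, max %.4g\n",
        median(d), max(d)))
  if (!object@converged) cat("  WARNING: superimposition did not converge\n")
})

setMethod("show", "LD1Model", function(object) {
  cat(sprintf("LD1Model: %d training specimens, %d embedding axes\n",
      length(object@trainIds), length(object@eigenvalues)))
  cat(sprintf("  parental means: %s = %.4g, %s = %.4g\n",
      names(object@parentMeans)[1], object@parentMeans[1],
      names(object@parentMeans)[2], object@parentMeans[2]))
})

setMethod("show", "RILPanel", function(object) {
  cat(sprintf("RILPanel: %d strains, %d markers on %d chromosomes\n",
      length(object@strains), nrow(object@markers),
      length(unique(object@markers$chr))))
  miss <- mean(is.na(object@geno))
  cat(sprintf("  missing genotypes: %.1f%%; traits: %s\n", 100 * miss,
      paste(names(object@phenotypes), collapse = ", ")))
})

setMethod("show", "ScanResult", function(object) {
  peak <- object@table[which.max(object@table$lod), ]
  cat(sprintf("ScanResult (%s): %d markers; max LOD %.3f at %s (chr %s, %.1f cM)\n",
      object@trait, nrow(object@table), peak$lod, peak$marker,
      peak$chr, peak$pos))
  if (!is.na(object@threshold))
    cat(sprintf("  %d-permutation significance threshold: %.3f\n",
        object@nPerm, object@threshold))
})
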