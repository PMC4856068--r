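#' @import methods
NULL

#' Rigid transform in three dimensions
#'
#' A proper rigid motion `y = R x + t`: a 3x3 rotation matrix with
#' `det(R) = +1` and a translation 3-vector. Validity enforces orthonormality
#' and proper orientation to 1e-9, so reflections can never sneak into the
#' alignment chain (bacula are chiral).
#'
#' @slot rotation 3x3 orthonormal matrix, determinant +1.
#' @slot translation numeric length-3 translation.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)),
  validity = function(object) {
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
    if (length(object@translation) != 3) return("translation must be length 3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-9) return("rotation not orthonormal")
    if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det +1)")
    TRUE
  })

#' Raw 3D bone point cloud
#'
#' Points of a segmented bone in scanner coordinates, in physical units
#' (voxel index times voxel size). The default voxel size, 15.5 micrometres,
#' matches routine micro-CT scanning of mouse bacula; coordinates are stored
#' in the same length unit the voxel size is expressed in.
#'
#' @slot coords n x 3 numeric matrix of x-y-z coordinates.
#' @slot voxelSize scalar physical length per voxel.
#' @slot specimenId nonempty specimen identifier.
#' @slot meta free-form list (strain, lab, replicate group, ...).
#' @export
setClass("PointCloud",
  representation(coords = "matrix", voxelSize = "numeric",
                 specimenId = "character", meta = "list"),
  prototype(voxelSize = 0.0155, meta = list()),
  validity = function(object) {
    p <- object@coords
    if (ncol(p) != 3) return("coords must have 3 columns")
    if (!all(is.finite(p))) return("coords must be finite")
    if (length(object@specimenId) != 1 || !nzchar(object@specimenId))
      return("specimenId must be a nonempty string")
    if (length(object@voxelSize) != 1 || object@voxelSize <= 0)
      return("voxelSize must be a positive scalar")
    TRUE
  })

#' Canonically aligned bone point cloud
#'
#' A `PointCloud` after the three-step canonical alignment: proximal end-slab
#' centroid at the origin, distal end-slab centroid on +z, the cross-section
#' minimum bounding rectangle long side on x, and dorsal curvature on +y.
#'
#' @slot transform composed [RigidTransform-class] from the raw frame.
#' @slot zLength distal-proximal extent (z range) of the aligned points.
#' @slot dvFlipped whether the dorsoventral 180-degree flip was applied.
#' @slot stageWarnings character vector of audit warnings (DV ambiguity,
#'   band expansion, ...).
#' @export
setClass("AlignedCloud",
  contains = "PointCloud",
  representation(transform = "RigidTransform", zLength = "numeric",
                 dvFlipped = "logical", stageWarnings = "character"),
  prototype(dvFlipped = FALSE, stageWarnings = character()),
  validity = function(object) {
    if (length(object@zLength) != 1 || object@zLength <= 0)
      return("zLength must be a positive scalar")
    TRUE
  })

#' Labeled semilandmark configuration
#'
#' The ordered rule-based semilandmarks of one aligned bone:
#' `n_slices x 16 + 2` points (802 at defaults), labeled by slice and role
#' (`dorsal_1..7`, `ventral_1..7`, `leftmost`, `rightmost`, plus the
#' proximal and distal tips), together with centroid size.
#'
#' @slot coords k x 3 coordinate matrix in fixed label order.
#' @slot labels data.frame with columns `slice` (integer, NA for tips) and
#'   `role` (character).
#' @slot centroidSize square root of summed squared distances from the
#'   configuration centroid.
#' @slot specimenId specimen identifier.
#' @export
setClass("SemilandmarkSet",
  representation(coords = "matrix", labels = "data.frame",
                 centroidSize = "numeric", specimenId = "character"),
  validity = function(object) {
    if (ncol(object@coords) != 3) return("coords must have 3 columns")
    if (nrow(object@labels) != nrow(object@coords))
      return("labels must have one row per landmark")
    if (!all(c("slice", "role") %in% names(object@labels)))
      return("labels must have columns slice and role")
    key <- paste(object@labels$slice, object@labels$role)
    if (anyDuplicated(key)) return("landmark labels must be unique")
    if (object@centroidSize < 0) return("centroidSize must be nonnegative")
    TRUE
  })

#' Procrustes shape space
#'
#' Result of generalized Procrustes superimposition: per-specimen
#' unit-centroid-size aligned configurations, the consensus, and the full
#' pairwise Procrustes distance matrix.
#'
#' @slot configs list of k x 3 superimposed configurations (unit centroid
#'   size), named by specimen.
#' @slot consensus k x 3 consensus configuration, unit centroid size.
#' @slot dist symmetric n x n pairwise distance matrix, zero diagonal.
#' @slot specimenIds specimen identifiers (row/column order of `dist`).
#' @slot converged whether the superimposition converged within `maxIter`.
#' @slot slid whether semilandmark sliding was applied.
#' @slot slideDiagnostics data.frame of per-iteration summed bending energy
#'   before and after sliding (empty when `slid` is FALSE).
#' @export
setClass("ShapeSpace",
  representation(configs = "list", consensus = "matrix", dist = "matrix",
                 specimenIds = "character", converged = "logical",
                 slid = "logical", slideDiagnostics = "data.frame"),
  prototype(converged = TRUE, slid = FALSE,
            slideDiagnostics = data.frame()),
  validity = function(object) {
    d <- object@dist
    if (nrow(d) != ncol(d)) return("dist must be square")
    if (nrow(d) != length(object@specimenIds))
      return("specimenIds must match dist dimension")
    if (max(abs(d - t(d))) > 1e-8) return("dist must be symmetric")
    if (any(diag(d) != 0)) return("dist diagonal must be zero")
    if (any(d < 0)) return("dist must be nonnegative")
    TRUE
  })

#' Parental-anchored linear discriminant shape axis
#'
#' A single discriminant axis (LD1) separating the two parental strains in a
#' principal-coordinate embedding of the pairwise Procrustes distance matrix,
#' with the sign fixed so the first-listed parent scores lower.
#'
#' @slot trainIds specimens of the training shape space (PCoA points).
#' @slot embedding n x k PCoA coordinates of the training specimens.
#' @slot eigenvalues the k retained PCoA eigenvalues.
#' @slot rowMeanD2 row means of the training squared-distance matrix (used by
#'   the out-of-sample embedding extension).
#' @slot scaling discriminant vector in the embedding (length k).
#' @slot center projection center in the embedding.
#' @slot sign +1 or -1; fixed so mean(P1) < mean(P2).
#' @slot parentMeans named length-2 numeric, fit-time parental LD1 means.
#' @slot parentLabels named character: training specimen -> parent class.
#' @export
setClass("LD1Model",
  representation(trainIds = "character", embedding = "matrix",
                 eigenvalues = "numeric", rowMeanD2 = "numeric",
                 scaling = "numeric", center = "numeric", sign = "numeric",
                 parentMeans = "numeric", parentLabels = "character"),
  validity = function(object) {
    if (length(object@parentMeans) != 2) return("parentMeans must be length 2")
    if (!object@sign %in% c(-1, 1)) return("sign must be +1 or -1")
    if (ncol(object@embedding) != length(object@eigenvalues))
      return("embedding/eigenvalues dimension mismatch")
    TRUE
  })

#' Recombinant inbred line panel
#'
#' Genotypes and per-strain phenotype means for a two-parent RIL family
#' (B/D homozygous allele codes, as in the BXD family).
#'
#' @slot strains strain identifiers.
#' @slot markers data.frame with columns `marker`, `chr`, `pos` (cM),
#'   positions nondecreasing within chromosome.
#' @slot geno strains x markers character matrix with entries "B", "D" or NA.
#' @slot phenotypes data.frame of per-strain trait means, rownames = strains.
#' @slot parents identifiers of parental strains (excluded from scans).
#' @export
setClass("RILPanel",
  representation(strains = "character", markers = "data.frame",
                 geno = "matrix", phenotypes = "data.frame",
                 parents = "character"),
  prototype(parents = character()),
  validity = function(object) {
    if (length(object@strains) < 2) return("need at least 2 strains")
    if (!all(c("marker", "chr", "pos") %in% names(object@markers)))
      return("markers must have columns marker, chr, pos")
    if (nrow(object@geno) != length(object@strains))
      return("geno rows must match strains")
    if (ncol(object@geno) != nrow(object@markers))
      return("geno columns must match markers")
    bad <- !(object@geno %in% c("B", "D") | is.na(object@geno))
    if (any(bad)) return("genotype codes must be B, D or NA")
    pos <- split(object@markers$pos, object@markers$chr)
    if (any(vapply(pos, is.unsorted, logical(1))))
      return("marker positions must be nondecreasing within chromosome")
    TRUE
  })

#' Single-QTL genome scan result
#'
#' Per-marker LOD scores from Haley-Knott regression, with the permutation
#' significance threshold and per-chromosome peaks when computed.
#'
#' @slot table data.frame: marker, chr, pos, lod, effect, r2.
#' @slot threshold empirical significance threshold (NA until permutations
#'   are run).
#' @slot nPerm number of permutations behind `threshold` (0 if none).
#' @slot peaks data.frame of per-chromosome maxima.
#' @slot trait name of the scanned trait.
#' @export
setClass("ScanResult",
  representation(table = "data.frame", threshold = "numeric",
                 nPerm = "numeric", peaks = "data.frame", trait = "character"),
  prototype(threshold = NA_real_, nPerm = 0),
  validity = function(object) {
    need <- c("marker", "chr", "pos", "lod", "effect", "r2")
    if (!all(need %in% names(object@table)))
      return("table must have columns marker, chr, pos, lod, effect, r2")
    if (any(object@table$lod < -1e-9)) return("LOD scores must be nonnegative")
    TRUE
  })

#' Morphometric pipeline configuration
#'
#' All tunable fractions and counts of the semilandmark pipeline. Defaults
#' are the published recipe: 50 slices of thickness 0.25% of the z length,
#' 7 interior lines per slice with a 4% projection window, the MBR band at
#' 15.00-15.25% of the length, and 10% end slabs.
#'
#' @slot nSlices number of cross-sectional slices.
#' @slot sliceThicknessFrac slice thickness as a fraction of z length.
#' @slot nLines number of interior x lines per slice.
#' @slot projectionTolFrac projection window as a fraction of slice width.
#' @slot mbrBand length-2 fraction interval for the MBR orientation band.
#' @slot endFrac end-slab fraction for end-centroid registration.
#' @slot distalFrac distal fraction used by the dorsoventral check.
#' @slot endCentroidMode "hull_volume" (volume-weighted centroid of the
#'   end-slab convex hull), "hull_vertex" (mean of hull vertices) or
#'   "plain" (mean of slab points).
#' @slot slide whether semilandmarks slide during superimposition.
#' @export
setClass("PipelineConfig",
  representation(nSlices = "integer", sliceThicknessFrac = "numeric",
                 nLines = "integer", projectionTolFrac = "numeric",
                 mbrBand = "numeric", endFrac = "numeric",
                 distalFrac = "numeric", endCentroidMode = "character",
                 slide = "logical"),
  validity = function(object) {
    fr <- c(object@sliceThicknessFrac, object@projectionTolFrac,
            object@mbrBand, object@endFrac, object@distalFrac)
    if (any(fr <= 0 | fr >= 1)) return("all fractions must lie in (0, 1)")
    if (object@nSlices < 2L) return("nSlices must be >= 2")
    if (object@nLines < 1L) return("nLines must be >= 1")
    if (length(object@mbrBand) != 2 || diff(object@mbrBand) <= 0)
      return("mbrBand must be an increasing length-2 interval")
    if (!object@endCentroidMode %in% c("hull_volume", "hull_vertex", "plain"))
      return("unknown endCentroidMode")
    TRUE
  })

#' Pipeline configuration constructor
#'
#' @param nSlices number of slices (default 50).
#' @param sliceThicknessFrac slice thickness fraction of z length (0.0025).
#' @param nLines interior lines per slice (7).
#' @param projectionTolFrac projection window fraction of slice width (0.04).
#' @param mbrBand MBR orientation band as fractions of length
#'   (c(0.1500, 0.1525)).
#' @param endFrac end-slab fraction (0.10).
#' @param distalFrac distal fraction for the dorsoventral check (0.25).
#' @param endCentroidMode end-slab centroid mode (see
#'   [PipelineConfig-class]).
#' @param slide slide semilandmarks during superimposition (TRUE).
#' @return a [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg@nSlices
#' @export
pipelineConfig <- function(nSlices = 50L, sliceThicknessFrac = 0.0025,
                           nLines = 7L, projectionTolFrac = 0.04,
                           mbrBand = c(0.1500, 0.1525), endFrac = 0.10,
                           distalFrac = 0.25,
                           endCentroidMode = "hull_volume", slide = TRUE) {
  new("PipelineConfig", nSlices = as.integer(nSlices),
      sliceThicknessFrac = sliceThicknessFrac, nLines = as.integer(nLines),
      projectionTolFrac = projectionTolFrac, mbrBand = mbrBand,
      endFrac = endFrac, distalFrac = distalFrac,
      endCentroidMode = endCentroidMode, slide = slide)
}
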