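# Workflow orchestration: align -> landmarks -> shape -> stats -> scan on
# a directory of xyz clouds, with a JSON run manifest (config snapshot,
# per-stage input/output hashes, warnings) enabling deterministic,
# resumable reruns.

configToList <- function(config) {
  list(nSlices = config@nSlices,
       sliceThicknessFrac = config@sliceThicknessFrac,
       nLines = config@nLines,
       projectionTolFrac = config@projectionTolFrac,
       mbrBand = config@mbrBand, endFrac = config@endFrac,
       distalFrac = config@distalFrac,
       endCentroidMode = config@endCentroidMode, slide = config@slide)
}

fileHashes <- function(paths) {
  h <- tools::md5sum(paths)
  as.list(h)
}

#' Read a RIL panel from genotype and phenotype CSV files
#'
#' The genotype CSV has one row per marker with columns `marker`, `chr`,
#' `pos` (cM) followed by one column per strain (cells B, D or empty/NA);
#' the phenotype CSV has a `strain` column plus one column per trait.
#'
#' @param genoFile genotype CSV path.
#' @param phenoFile phenotype CSV path.
#' @param parents character vector of parental strain ids (default none).
#' @return a [RILPanel-class].
#' @export
readRILPanel <- function(genoFile, phenoFile, parents = character()) {
  g <- utils::read.csv(genoFile, stringsAsFactors = FALSE,
                       check.names = FALSE)
  stopifnot(all(c("marker", "chr", "pos") %in% names(g)))
  strains <- setdiff(names(g), c("marker", "chr", "pos"))
  geno <- t(as.matrix(g[, strains, drop = FALSE]))
  geno[geno == ""] <- NA_character_
  geno[!(geno %in% c("B", "D"))] <- NA_character_  # residual codes -> missing
  colnames(geno) <- g$marker
  ph <- utils::read.csv(phenoFile, stringsAsFactors = FALSE)
  stopifnot("strain" %in% names(ph))
  pheno <- ph[match(strains, ph$strain), setdiff(names(ph), "strain"),
              drop = FALSE]
  rownames(pheno) <- strains
  new("RILPanel", strains = strains,
      markers = g[, c("marker", "chr", "pos")], geno = geno,
      phenotypes = pheno, parents = intersect(parents, strains))
}

#' Write a RIL panel to genotype and phenotype CSV files
#'
#' @param panel a [RILPanel-class].
#' @param genoFile,phenoFile output paths.
#' @return invisibly, the two paths.
#' @export
writeRILPanel <- function(panel, genoFile, phenoFile) {
  g <- cbind(panel@markers, as.data.frame(t(panel@geno),
                                          check.names = FALSE))
  utils::write.csv(g, genoFile, row.names = FALSE, na = "")
  ph <- cbind(data.frame(strain = rownames(panel@phenotypes)),
              panel@phenotypes)
  utils::write.csv(ph, phenoFile, row.names = FALSE)
  invisible(c(genoFile, phenoFile))
}

#' Run the full morphometric and mapping workflow
#'
#' Executes the requested stages in order on a directory of `.xyz` point
#' clouds: `align` (canonical alignment, per-specimen transform audit),
#' `landmarks` (semilandmark CSVs), `shape` (Procrustes distance matrix and
#' LD1 scores), `stats` (heritability, strain-mean correlation and, when
#' replicate groups are present, repeatability), and `scan` (Haley-Knott
#' genome scans of the strain means with permutation thresholds). A stage
#' whose recorded input hashes and outputs are unchanged from the previous
#' run is skipped, so interrupted or corrupted runs resume.
#'
#' @param inputDir directory of `.xyz` files (one specimen each).
#' @param metadataFile CSV with columns `specimen_id`, `strain` and
#'   optionally `lab`, `replicate_group`, `parent` (P1/P2 for parental
#'   specimens).
#' @param outDir output directory (created if needed).
#' @param config a [PipelineConfig-class].
#' @param stages stages to run, in order.
#' @param genoFile optional genotype CSV (enables `scan`).
#' @param nPerm permutations for the scan threshold.
#' @param seed seed for the permutation scans.
#' @return the run manifest, invisibly (also written to
#'   `outDir/manifest.json`).
#' @export
runPipeline <- function(inputDir, metadataFile, outDir,
                        config = pipelineConfig(),
                        stages = c("align", "landmarks", "shape", "stats",
                                   "scan"),
                        genoFile = NULL, nPerm = 200, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  meta <- utils::read.csv(metadataFile, stringsAsFactors = FALSE)
  stopifnot(all(c("specimen_id", "strain") %in% names(meta)))
  xyz <- sort(list.files(inputDir, pattern = "\\.xyz$", full.names = TRUE))
  if (!length(xyz)) stop("no .xyz files in ", inputDir, call. = FALSE)

  manifestPath <- file.path(outDir, "manifest.json")
  prev <- if (file.exists(manifestPath))
    tryCatch(jsonlite::read_json(manifestPath), error = function(e) NULL)
  else NULL
  manifest <- list(package = "bacumorph",
                   version = as.character(utils::packageVersion("bacumorph")),
                   config = configToList(config), seed = seed,
                   stages = list())

  upToDate <- function(stage, inHashes, outFiles) {
    rec <- prev$stages[[stage]]
    if (is.null(rec)) return(FALSE)
    if (!identical(lapply(rec$inputs, as.character),
                   lapply(inHashes, as.character))) return(FALSE)
    if (!all(file.exists(outFiles))) return(FALSE)
    now <- fileHashes(outFiles)
    identical(lapply(rec$outputs, as.character),
              lapply(now, as.character))
  }
  record <- function(stage, inHashes, outFiles, warnings = character(),
                     skipped = FALSE) {
    manifest$stages[[stage]] <<- list(
      inputs = inHashes, outputs = fileHashes(outFiles),
      warnings = as.list(warnings), skipped = skipped)
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  alignDir <- file.path(outDir, "aligned")
  lmDir <- file.path(outDir, "landmarks")

  if ("align" %in% stages) {
    inH <- c(fileHashes(xyz), list(.config = jsonlite::toJSON(
      configToList(config), auto_unbox = TRUE)))
    outFiles <- file.path(alignDir, basename(xyz))
    trFiles <- file.path(alignDir, sub("\\.xyz$", "_transform.json",
                                       basename(xyz)))
    if (upToDate("align", inH, c(outFiles, trFiles))) {
      record("align", inH, c(outFiles, trFiles), skipped = TRUE)
    } else {
      dir.create(alignDir, showWarnings = FALSE)
      warns <- character()
      for (i in seq_along(xyz)) {
        cl <- readXYZ(xyz[i])
        al <- alignBaculum(cl, config)
        writeXYZ(al, outFiles[i])
        hom <- rbind(cbind(al@transform@rotation, al@transform@translation),
                     c(0, 0, 0, 1))
        jsonlite::write_json(list(specimen = specimenId(al),
          matrix = hom, dvFlipped = al@dvFlipped,
          warnings = al@stageWarnings), trFiles[i], auto_unbox = TRUE,
          digits = NA)
        warns <- c(warns, paste0(specimenId(al), ": ", al@stageWarnings))
      }
      record("align", inH, c(outFiles, trFiles), warnings = warns)
    }
  }

  if ("landmarks" %in% stages) {
    alFiles <- sort(list.files(alignDir, pattern = "\\.xyz$",
                               full.names = TRUE))
    inH <- fileHashes(alFiles)
    outFiles <- file.path(lmDir, sub("\\.xyz$", "_landmarks.csv",
                                     basename(alFiles)))
    if (upToDate("landmarks", inH, outFiles)) {
      record("landmarks", inH, outFiles, skipped = TRUE)
    } else {
      dir.create(lmDir, showWarnings = FALSE)
      for (i in seq_along(alFiles)) {
        al <- readXYZ(alFiles[i])
        alc <- new("AlignedCloud", coords = coords(al),
                   voxelSize = al@voxelSize, specimenId = specimenId(al),
                   meta = al@meta, transform = new("RigidTransform"),
                   zLength = diff(range(coords(al)[, 3])))
        writeLandmarksCSV(extractSemilandmarks(alc, config), outFiles[i])
      }
      record("landmarks", inH, outFiles)
    }
  }

  specimenTablePath <- file.path(outDir, "specimens.csv")
  distPath <- file.path(outDir, "procrustes_dist.csv")
  scoresPath <- file.path(outDir, "ld1_scores.csv")

  if ("shape" %in% stages) {
    lmFiles <- sort(list.files(lmDir, pattern = "_landmarks\\.csv$",
                               full.names = TRUE))
    inH <- c(fileHashes(c(lmFiles, metadataFile)))
    outFiles <- c(distPath, scoresPath, specimenTablePath)
    if (upToDate("shape", inH, outFiles)) {
      record("shape", inH, outFiles, skipped = TRUE)
    } else {
      lms <- lapply(lmFiles, readLandmarksCSV)
      space <- gpa(lms, slide = config@slide)
      utils::write.csv(distMatrix(space), distPath)
      parentCol <- meta$parent
      scores <- rep(NA_real_, length(space@specimenIds))
      names(scores) <- space@specimenIds
      if (!is.null(parentCol) &&
          sum(!is.na(parentCol) & nzchar(parentCol)) >= 4) {
        lab <- meta$parent[match(space@specimenIds, meta$specimen_id)]
        lab[is.na(lab) | !nzchar(lab)] <- NA
        pl <- stats::setNames(lab[!is.na(lab)],
                              space@specimenIds[!is.na(lab)])
        model <- fitLD1(space, pl)
        scores <- projectLD1(model, space)
      }
      utils::write.csv(data.frame(specimen_id = names(scores),
                                  LD1 = as.numeric(scores)),
                       scoresPath, row.names = FALSE)
      cs <- vapply(lms, function(l) l@centroidSize, numeric(1))
      tab <- data.frame(specimen_id = vapply(lms, specimenId, character(1)),
                        CS = cs, LD1 = as.numeric(scores))
      tab <- merge(tab, meta, by = "specimen_id", all.x = TRUE, sort = TRUE)
      utils::write.csv(tab, specimenTablePath, row.names = FALSE)
      record("shape", inH, outFiles)
    }
  }

  statsPath <- file.path(outDir, "stats.json")
  if ("stats" %in% stages && file.exists(specimenTablePath)) {
    inH <- fileHashes(specimenTablePath)
    if (upToDate("stats", inH, statsPath)) {
      record("stats", inH, statsPath, skipped = TRUE)
    } else {
      tab <- utils::read.csv(specimenTablePath, stringsAsFactors = FALSE)
      out <- list()
      for (tr in c("CS", "LD1")) {
        h <- tryCatch(heritability(tab, tr), error = function(e) NULL)
        if (!is.null(h)) out[[paste0("h2_", tr)]] <- h[c("h2", "F", "p")]
      }
      out$sizeShapeCorrelation <- tryCatch(
        strainMeanCorrelation(tab)[c("r", "p", "n")],
        error = function(e) NULL)
      hasRG <- "replicate_group" %in% names(tab) &&
        any(!is.na(tab$replicate_group) & nzchar(tab$replicate_group))
      if (hasRG) {
        rg <- tab[!is.na(tab$replicate_group) & nzchar(tab$replicate_group), ]
        out$repeatabilitySize <- tryCatch(
          repeatabilitySize(rg$CS, rg$replicate_group),
          error = function(e) NULL)
        d <- as.matrix(utils::read.csv(distPath, row.names = 1,
                                       check.names = FALSE))
        groups <- split(rg$specimen_id, rg$replicate_group)
        out$repeatabilityShape <- tryCatch(
          repeatabilityShape(d, groups), error = function(e) NULL)
      }
      jsonlite::write_json(out, statsPath, auto_unbox = TRUE, digits = NA)
      record("stats", inH, statsPath)
    }
  }

  if ("scan" %in% stages && !is.null(genoFile)) {
    tab <- utils::read.csv(specimenTablePath, stringsAsFactors = FALSE)
    strainMeans <- stats::aggregate(tab[, c("CS", "LD1")],
                                    by = list(strain = tab$strain), mean)
    phenoPath <- file.path(outDir, "strain_means.csv")
    utils::write.csv(strainMeans, phenoPath, row.names = FALSE)
    parents <- if ("parent" %in% names(tab))
      unique(tab$strain[!is.na(tab$parent) & nzchar(tab$parent)])
    else character()
    inH <- fileHashes(c(genoFile, phenoPath))
    scanFiles <- file.path(outDir, c("scan_CS.csv", "scan_LD1.csv",
                                     "scan_summary.json"))
    if (upToDate("scan", inH, scanFiles)) {
      record("scan", inH, scanFiles, skipped = TRUE)
    } else {
      panel <- readRILPanel(genoFile, phenoPath, parents = parents)
      summary_ <- list()
      probs <- imputeGenotypeProbs(panel)
      for (tr in c("CS", "LD1")) {
        if (!tr %in% names(panel@phenotypes)) next
        sc <- scanQTL(panel, tr, probs = probs)
        pt <- permutationThreshold(panel, tr, nPerm = nPerm, seed = seed,
                                   probs = probs)
        sc@threshold <- pt$threshold
        sc@nPerm <- pt$nPerm
        utils::write.csv(sc@table,
                         file.path(outDir, sprintf("scan_%s.csv", tr)),
                         row.names = FALSE)
        sig <- sc@peaks[sc@peaks$lod >= pt$threshold, , drop = FALSE]
        ivs <- lapply(seq_len(nrow(sig)), function(r) {
          iv <- lodSupportInterval(sc, sig$chr[r])
          list(chr = sig$chr[r], peakMarker = sig$marker[r],
               peakLod = sig$lod[r], lo = iv$lo, hi = iv$hi)
        })
        summary_[[tr]] <- list(threshold = pt$threshold, nPerm = pt$nPerm,
                               maxLod = max(sc@table$lod),
                               significant = ivs)
      }
      jsonlite::write_json(summary_, scanFiles[3], auto_unbox = TRUE,
                           digits = NA)
      record("scan", inH, scanFiles)
    }
  }

  invisible(manifest)
}
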