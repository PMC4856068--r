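# Procrustes shape analysis: ordinary superimposition of two
# configurations, generalized Procrustes analysis with sliding
# semilandmarks (thin-plate-spline bending energy objective), the pairwise
# Procrustes distance matrix, and the parental-strain LD1 shape axis.

centerScale <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  cs <- sqrt(sum(m^2))
  if (cs < 1e-300) stop("degenerate configuration: zero centroid size",
                        call. = FALSE)
  m / cs
}

## Optimal proper rotation taking A onto B (both already centered/scaled):
## maximize trace(R' A' B); reflections excluded.
optimalRotation <- function(A, B) {
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Ordinary Procrustes superimposition of two configurations
#'
#' Centers both configurations, scales each to unit centroid size, and
#' rotates the first onto the second with the optimal proper rotation
#' (reflections are never allowed; bacula are chiral). The returned
#' distance is the Euclidean norm between the superimposed unit-size
#' configurations.
#'
#' @param a,b k x 3 landmark matrices (or [SemilandmarkSet-class]s) with
#'   corresponding rows.
#' @return list with `distance`, `rotation` (applied to `a`), and the
#'   superimposed configurations `aAligned`, `bAligned`.
#' @examples
#' a <- matrix(rnorm(15), 5, 3)
#' opa(a, a)$distance    # 0
#' @export
opa <- function(a, b) {
  A <- centerScale(if (is(a, "SemilandmarkSet")) coords(a) else as.matrix(a))
  B <- centerScale(if (is(b, "SemilandmarkSet")) coords(b) else as.matrix(b))
  if (!all(dim(A) == dim(B)))
    stop("configurations must have equal landmark counts", call. = FALSE)
  R <- optimalRotation(A, B)
  Ar <- A %*% R
  list(distance = sqrt(sum((Ar - B)^2)), rotation = R,
       aAligned = Ar, bAligned = B)
}

## ---- thin-plate-spline bending energy ------------------------------------

## Bending-energy matrix of a 3D reference configuration (kernel -|r|,
## conditionally positive definite of order 1). Returns the k x k upper
## block of the inverse TPS system.
bendingEnergyMatrix <- function(ref) {
  k <- nrow(ref)
  K <- -as.matrix(stats::dist(ref))
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4, 4)))
  Li <- tryCatch(solve(L), error = function(e) {
    solve(L + diag(1e-10 * max(abs(K)), k + 4))
  })
  Le <- Li[seq_len(k), seq_len(k)]
  (Le + t(Le)) / 2
}

bendingEnergy <- function(Le, Y, C) {
  D <- Y - C
  sum(vapply(1:3, function(j) sum(D[, j] * (Le %*% D[, j])), numeric(1)))
}

## ---- sliding directions from the landmark labeling -----------------------

## Per-landmark sliding directions derived from neighboring semilandmarks:
## dorsal/ventral landmarks get the within-slice ring tangent and the
## adjacent-slice (along-bone) tangent (a tangent plane); left/rightmost
## landmarks slide only along the lateral margin (adjacent slices); tips
## are fixed. Returns a list of k entries, each a (0|1|2) x 3 matrix.
slideDirections <- function(coordsM, labels) {
  k <- nrow(coordsM)
  nl <- sum(labels$slice %in% labels$slice[1] &
            grepl("^dorsal_", labels$role))
  slices <- sort(unique(labels$slice[!is.na(labels$slice)]))
  rowOf <- function(slice, role) {
    which(labels$slice == slice & labels$role == role)
  }
  # ring order within a slice: leftmost, dorsal_1..nl, rightmost,
  # ventral_nl..1 (a closed loop around the cross-section)
  ringRoles <- c("leftmost", sprintf("dorsal_%d", seq_len(nl)), "rightmost",
                 sprintf("ventral_%d", rev(seq_len(nl))))
  dirs <- vector("list", k)
  unitOrNull <- function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) NULL else v / n
  }
  for (s in slices) {
    ringIdx <- vapply(ringRoles, function(r) rowOf(s, r)[1], integer(1))
    nR <- length(ringIdx)
    si <- match(s, slices)
    sPrev <- if (si > 1) slices[si - 1] else s
    sNext <- if (si < length(slices)) slices[si + 1] else s
    for (j in seq_len(nR)) {
      i <- ringIdx[j]
      role <- ringRoles[j]
      along <- unitOrNull(coordsM[rowOf(sNext, role)[1], ] -
                          coordsM[rowOf(sPrev, role)[1], ])
      if (role %in% c("leftmost", "rightmost")) {
        dirs[[i]] <- if (is.null(along)) matrix(0, 0, 3) else rbind(along)
      } else {
        nxt <- ringIdx[if (j == nR) 1 else j + 1]
        prv <- ringIdx[if (j == 1) nR else j - 1]
        ring <- unitOrNull(coordsM[nxt, ] - coordsM[prv, ])
        d <- rbind(ring, along)
        if (is.null(d)) d <- matrix(0, 0, 3)
        # orthogonalize the second direction against the first
        if (nrow(d) == 2) {
          d[2, ] <- d[2, ] - sum(d[1, ] * d[2, ]) * d[1, ]
          n2 <- sqrt(sum(d[2, ]^2))
          d <- if (n2 < 1e-6) d[1, , drop = FALSE] else
            rbind(d[1, ], d[2, ] / n2)
        }
        dirs[[i]] <- d
      }
    }
  }
  for (i in which(is.na(labels$slice))) dirs[[i]] <- matrix(0, 0, 3)  # tips
  dirs
}

## Slide one configuration toward the consensus, minimizing TPS bending
## energy over tangent moves. Exact minimizer of the quadratic, so the
## bending energy never increases.
slideOne <- function(Y, C, Le, dirs) {
  lmIdx <- integer(0); D <- NULL
  for (i in seq_along(dirs)) {
    nd <- nrow(dirs[[i]])
    if (nd > 0) {
      lmIdx <- c(lmIdx, rep(i, nd))
      D <- rbind(D, dirs[[i]])
    }
  }
  if (!length(lmIdx)) return(Y)
  M <- Le[lmIdx, lmIdx] * tcrossprod(D)
  G <- Le %*% (Y - C)
  rhs <- rowSums(D * G[lmIdx, , drop = FALSE])
  ridge <- 1e-8 * mean(abs(diag(M)))
  t <- -solve(M + diag(ridge, nrow(M)), rhs)
  shift <- matrix(0, nrow(Y), 3)
  upd <- D * t
  for (r in seq_along(lmIdx))
    shift[lmIdx[r], ] <- shift[lmIdx[r], ] + upd[r, ]
  Y + shift
}

## ---- generalized Procrustes analysis -------------------------------------

#' Generalized Procrustes analysis with sliding semilandmarks
#'
#' Iteratively superimposes all configurations (center, unit centroid size,
#' optimal proper rotation to the evolving consensus) until the consensus
#' stabilizes. With `slide = TRUE` (and [SemilandmarkSet-class] inputs
#' carrying slice/role labels), each non-tip semilandmark is then allowed
#' to slide in its tangent plane -- spanned by directions to neighboring
#' semilandmarks on the same slice and on adjacent slices -- to minimize
#' the thin-plate-spline bending energy against the consensus
#' (left/rightmost landmarks slide only along the lateral margin; tips are
#' fixed), after which the superimposition is rerun. The result records
#' the pairwise Euclidean distances between the final superimposed
#' configurations.
#'
#' @param configs list of [SemilandmarkSet-class]s (or k x 3 matrices when
#'   `slide = FALSE`), length >= 2, equal landmark counts.
#' @param slide slide semilandmarks (default FALSE; needs labeled input).
#' @param maxIter maximum superimposition iterations per pass.
#' @param tol consensus-change convergence tolerance.
#' @param slideIter number of slide-and-resuperimpose passes.
#' @return a [ShapeSpace-class].
#' @export
gpa <- function(configs, slide = FALSE, maxIter = 100L, tol = 1e-9,
                slideIter = 3L) {
  if (length(configs) < 2) stop("gpa needs at least 2 configurations",
                                call. = FALSE)
  ids <- vapply(seq_along(configs), function(i) {
    x <- configs[[i]]
    if (is(x, "SemilandmarkSet")) specimenId(x) else
      (names(configs)[i] %||% sprintf("config_%d", i))
  }, character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  X <- lapply(configs, function(x)
    centerScale(if (is(x, "SemilandmarkSet")) coords(x) else as.matrix(x)))
  k <- nrow(X[[1]])
  if (any(vapply(X, nrow, integer(1)) != k))
    stop("configurations must have equal landmark counts", call. = FALSE)
  labels <- if (slide) {
    if (!is(configs[[1]], "SemilandmarkSet"))
      stop("slide = TRUE needs SemilandmarkSet input (labels required)",
           call. = FALSE)
    configs[[1]]@labels
  } else NULL

  superimpose <- function(X) {
    consensus <- X[[1]]
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      X <- lapply(X, function(x) x %*% optimalRotation(x, consensus))
      newC <- centerScale(Reduce(`+`, X) / length(X))
      delta <- sqrt(sum((newC - consensus)^2))
      consensus <- newC
      if (delta < tol) { converged <- TRUE; break }
    }
    list(X = X, consensus = consensus, converged = converged)
  }

  sp <- superimpose(X)
  diag_ <- data.frame()
  if (slide) {
    for (pass in seq_len(slideIter)) {
      Le <- bendingEnergyMatrix(sp$consensus)
      beBefore <- beAfter <- 0
      Xs <- lapply(sp$X, function(Y) {
        dirs <- slideDirections(Y, labels)
        beBefore <<- beBefore + bendingEnergy(Le, Y, sp$consensus)
        Y2 <- slideOne(Y, sp$consensus, Le, dirs)
        beAfter <<- beAfter + bendingEnergy(Le, Y2, sp$consensus)
        centerScale(Y2)
      })
      diag_ <- rbind(diag_, data.frame(pass = pass, beBefore = beBefore,
                                       beAfter = beAfter))
      sp <- superimpose(Xs)
      if (abs(beBefore - beAfter) < tol * max(beBefore, 1e-300)) break
    }
  }

  n <- length(sp$X)
  flat <- do.call(rbind, lapply(sp$X, as.vector))
  D2 <- outer(rowNorms2(flat), rowNorms2(flat), `+`) - 2 * tcrossprod(flat)
  D <- sqrt(pmax(D2, 0))
  diag(D) <- 0
  D <- (D + t(D)) / 2
  names(sp$X) <- ids
  new("ShapeSpace", configs = sp$X, consensus = sp$consensus, dist = D,
      specimenIds = ids, converged = sp$converged, slid = slide,
      slideDiagnostics = diag_)
}

## ---- LD1: parental discriminant axis on the distance matrix --------------

## PCoA (classical MDS) of a distance matrix, keeping components that
## explain >= varFrac of the positive-eigenvalue variance, capped at kMax.
pcoaEmbed <- function(D, varFrac = 0.95, kMax = Inf) {
  n <- nrow(D)
  cmd <- stats::cmdscale(D, k = n - 1, eig = TRUE)
  eig <- cmd$eig[seq_len(ncol(cmd$points))]
  pos <- eig > max(eig) * 1e-9
  X <- cmd$points[, pos, drop = FALSE]
  eig <- eig[pos]
  cum <- cumsum(eig) / sum(eig)
  k <- min(max(which(cum >= varFrac)[1], 1L, na.rm = TRUE), kMax,
           ncol(X))
  k <- max(k, 1L)
  list(X = X[, seq_len(k), drop = FALSE], eig = eig[seq_len(k)])
}

#' Fit the parental LD1 shape axis
#'
#' Embeds the parental block of the pairwise Procrustes distance matrix by
#' principal coordinates (PCoA), keeping components up to the smaller of
#' 95% explained variance and (number of parental specimens - 2), then
#' fits a two-class linear discriminant (via [MASS::lda]) on the parental
#' specimens in that embedding. The single discriminant axis (two classes)
#' is the LD1 shape score; its sign is fixed so the first-listed parent's
#' mean is lower. Non-parental specimens are scored by [projectLD1()],
#' which embeds them from their distances to the parental specimens.
#'
#' @param space a [ShapeSpace-class] containing the parental specimens.
#' @param parentalLabels named character vector mapping specimen id to
#'   parent class; specimens absent from it (or NA) are non-parental. The
#'   first class level (by order of first appearance) is "P1".
#' @param varFrac PCoA variance fraction retained (default 0.95).
#' @return an [LD1Model-class].
#' @export
fitLD1 <- function(space, parentalLabels, varFrac = 0.95) {
  ids <- space@specimenIds
  lab <- parentalLabels[ids[ids %in% names(parentalLabels)]]
  lab <- lab[!is.na(lab)]
  classes <- unique(lab)
  if (length(classes) != 2)
    stop("parentalLabels must define exactly 2 parental classes",
         call. = FALSE)
  if (any(table(lab) < 2))
    stop("each parental class needs at least 2 specimens", call. = FALSE)
  nP <- length(lab)
  trainIds <- names(lab)
  Dtr <- space@dist[match(trainIds, ids), match(trainIds, ids),
                    drop = FALSE]
  emb <- pcoaEmbed(Dtr, varFrac, kMax = max(nP - 2L, 1L))
  rownames(emb$X) <- trainIds
  train <- emb$X
  fit <- tryCatch(MASS::lda(train, grouping = factor(lab, levels = classes)),
                  error = function(e)
    stop("LDA failed (identical parental distributions?): ",
         conditionMessage(e), call. = FALSE))
  w <- as.numeric(fit$scaling[, 1])
  center <- as.numeric(colSums(fit$prior * fit$means))
  score <- as.numeric((train - matrix(center, nP, length(center),
                                      byrow = TRUE)) %*% w)
  m1 <- mean(score[lab == classes[1]])
  m2 <- mean(score[lab == classes[2]])
  sgn <- if (m1 < m2) 1 else -1
  pm <- sgn * c(m1, m2)
  names(pm) <- classes
  new("LD1Model", trainIds = trainIds, embedding = emb$X,
      eigenvalues = emb$eig, rowMeanD2 = rowMeans(Dtr^2), scaling = w,
      center = center, sign = sgn, parentMeans = pm, parentLabels = lab)
}

#' Project specimens onto the LD1 axis
#'
#' Specimens present in the model's training shape space reuse their
#' fit-time embedding coordinates (so training scores are reproduced
#' exactly); other specimens are embedded by the standard PCoA
#' out-of-sample extension from their distances to the training specimens,
#' which must all be present in `space`.
#'
#' @param model an [LD1Model-class].
#' @param space a [ShapeSpace-class] containing the specimens to score and,
#'   for out-of-sample specimens, the training specimens.
#' @param ids specimens to score (default: all of `space`).
#' @return named numeric vector of LD1 scores.
#' @export
projectLD1 <- function(model, space, ids = space@specimenIds) {
  missing_ <- setdiff(ids, space@specimenIds)
  if (length(missing_))
    stop("specimens absent from the distance matrix: ",
         paste(missing_, collapse = ", "), call. = FALSE)
  D <- distMatrix(space)
  k <- length(model@eigenvalues)
  scores <- numeric(length(ids))
  names(scores) <- ids
  newIds <- setdiff(ids, model@trainIds)
  if (length(newIds)) {
    if (!all(model@trainIds %in% space@specimenIds))
      stop("out-of-sample projection needs all training specimens in `space`",
           call. = FALSE)
    Dn <- D[newIds, model@trainIds, drop = FALSE]
  }
  for (id in ids) {
    x <- if (id %in% model@trainIds) {
      model@embedding[match(id, model@trainIds), seq_len(k)]
    } else {
      b <- -0.5 * (Dn[id, ]^2 - model@rowMeanD2)
      as.numeric(crossprod(model@embedding[, seq_len(k), drop = FALSE], b) /
                   model@eigenvalues)
    }
    scores[id] <- model@sign * sum((x - model@center) * model@scaling)
  }
  scores
}
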