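# Internal geometry and RNG helpers.

#' @importFrom stats rnorm runif sd median quantile
NULL

## Rotation matrices about the coordinate axes (right-handed, angle in radians).
rotZMat <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

rotXMat <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

rotYMat <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

## Minimal rotation taking unit vector u onto unit vector v (Rodrigues).
## Falls back to a 180-degree rotation about a perpendicular axis when
## u and v are antiparallel.
rotationBetween <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  cross <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(cross^2))
  cth <- sum(u * v)
  if (s < 1e-14) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u
    ax <- ax / sqrt(sum(ax^2))
    K <- skewMat(ax)
    return(diag(3) + 2 * K %*% K)
  }
  K <- skewMat(cross / s)
  diag(3) + s * K + (1 - cth) * (K %*% K)
}

skewMat <- function(a) {
  matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
}

## Uniform random rotation (QR of a Gaussian matrix, det forced to +1).
randomRotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  Q <- Q %*% d
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Evaluate expr with the RNG seeded at `seed`, restoring the caller's
## RNG state afterwards. Generators stay pure functions of (params, seed).
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Row-wise squared norms.
rowNorms2 <- function(m) rowSums(m * m)

## First row index under a lexicographic (col1, col2, col3, ...) ordering.
lexOrder <- function(m) do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
}
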