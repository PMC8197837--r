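## Internal helpers.

## Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
## state afterwards. seed = NULL leaves the RNG stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Coerce a VitalsCohort or plain numeric matrix to a records-by-features
## numeric matrix. Metric and rule code accepts either.
.featmat <- function(x) {
  if (is(x, "VitalsCohort")) return(featureMatrix(x))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a VitalsCohort or a numeric matrix of records x features")
  x
}

## Symmetric PSD matrix square root by eigendecomposition; tiny negative
## eigenvalues (numerical noise) are clipped to zero.
.matSqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

## Project a symmetric matrix to the nearest positive semi-definite
## correlation matrix (eigenvalue clipping + renormalised unit diagonal).
.nearestPSDCorr <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 1e-10)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  out
}
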