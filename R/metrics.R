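#' Jensen-Shannon divergence between two probability vectors
#'
#' `JS(P, Q) = [KL(P || m) + KL(Q || m)] / 2` with `m` the pointwise mean of
#' `P` and `Q` and base-2 logarithms, so the result lies in `[0, 1]`.
#'
#' @param p,q Non-negative numeric vectors of equal length summing to 1
#'   (within 1e-9).
#' @param eps Optional smoothing added to every bin before renormalising
#'   (avoids `log 0` on empty bins); 0 uses the `0 log 0 = 0` convention.
#' @return JS divergence in `[0, 1]`.
#' @examples
#' jsDivergenceProb(c(0.5, 0.5), c(1, 0))  # ~ 0.3113
#' @export
jsDivergenceProb <- function(p, q, eps = 0) {
  if (length(p) != length(q)) stop("'p' and 'q' must have equal length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    stop("'p' and 'q' must each sum to 1")
  if (eps > 0) {
    p <- (p + eps) / sum(p + eps)
    q <- (q + eps) / sum(q + eps)
  }
  m <- (p + q) / 2
  kl <- function(a) {
    s <- a > 0
    sum(a[s] * log2(a[s] / m[s]))
  }
  (kl(p) + kl(q)) / 2
}

## Shared-edge histogram probabilities for one feature over the pooled range.
.histProbs <- function(a, b, bins, eps) {
  lo <- min(a, b); hi <- max(a, b)
  if (hi <= lo) return(list(p = 1, q = 1))  # identical point mass
  edges <- seq(lo, hi, length.out = bins + 1L)
  cut1 <- pmin(pmax(findInterval(a, edges, rightmost.closed = TRUE), 1L), bins)
  cut2 <- pmin(pmax(findInterval(b, edges, rightmost.closed = TRUE), 1L), bins)
  p <- tabulate(cut1, bins) / length(a)
  q <- tabulate(cut2, bins) / length(b)
  list(p = (p + eps) / sum(p + eps), q = (q + eps) / sum(q + eps))
}

#' Jensen-Shannon divergence between two tabular samples
#'
#' For each predictor feature, both samples are binned into `bins` equal-width
#' histograms over their pooled min-max range, smoothed by `eps` and
#' renormalised; the base-2 JS divergence is computed per feature and averaged
#' over features. The score is symmetric and bounded in `[0, 1]`: 0 for
#' identical samples, approaching 1 for fully disjoint supports.
#'
#' @param A,B [VitalsCohort-class] objects or numeric records-by-features
#'   matrices with matching columns.
#' @param bins Number of histogram bins (>= 2).
#' @param eps Smoothing mass added per bin before renormalising.
#' @return Mean per-feature JS divergence in `[0, 1]`.
#' @export
jsDivergence <- function(A, B, bins = 10L, eps = 1e-10) {
  mA <- .featmat(A); mB <- .featmat(B)
  if (nrow(mA) == 0L || nrow(mB) == 0L) stop("both samples must be non-empty")
  if (bins < 2L) stop("'bins' must be >= 2")
  if (ncol(mA) != ncol(mB)) stop("samples must share the same features")
  js <- vapply(seq_len(ncol(mA)), function(j) {
    h <- .histProbs(mA[, j], mB[, j], bins, eps)
    jsDivergenceProb(h$p, h$q)
  }, numeric(1))
  mean(js)
}

#' Jensen-Shannon divergence between the two classes of one sample
#'
#' In the default `"within"` mode, [jsDivergence()] applied to the class-high
#' subset versus the class-low subset of `S` - a measure of how separated the
#' generator keeps its two conditional distributions. Mode `"cross"` instead
#' compares each class of `S` against the same class of a `reference` sample
#' (mean of the two per-class scores).
#'
#' @param S A [VitalsCohort-class] containing both classes.
#' @param bins,eps Passed to [jsDivergence()].
#' @param mode `"within"` (default) or `"cross"`.
#' @param reference Reference [VitalsCohort-class], required for
#'   `mode = "cross"`.
#' @return JS divergence in `[0, 1]`.
#' @export
jsBetweenClasses <- function(S, bins = 10L, eps = 1e-10,
                             mode = c("within", "cross"), reference = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(S, "VitalsCohort"))
  lab <- classLabels(S)
  if (!all(.CLASS_LEVELS %in% lab))
    stop("both classes must be present; got only '",
         paste(unique(as.character(lab)), collapse = ","), "'")
  if (mode == "within")
    return(jsDivergence(S[, lab == "high"], S[, lab == "low"], bins, eps))
  if (is.null(reference)) stop("mode='cross' requires a 'reference' cohort")
  rlab <- classLabels(reference)
  if (!all(.CLASS_LEVELS %in% rlab))
    stop("reference must contain both classes")
  mean(c(jsDivergence(reference[, rlab == "high"], S[, lab == "high"], bins, eps),
         jsDivergence(reference[, rlab == "low"], S[, lab == "low"], bins, eps)))
}

#' Frechet distance between Gaussian moment summaries of two samples
#'
#' Summarises each sample by its mean vector and covariance matrix and returns
#' the Frechet (2-Wasserstein) distance between the implied Gaussians:
#' `||muA - muB||^2 + Tr(covA + covB - 2 (covA covB)^{1/2})`. The matrix
#' square root is taken of the symmetrised product with tiny negative
#' eigenvalues clipped to zero. Lower is better; 0 means identical moments.
#' The score is sensitive to mode collapse: a generator that concentrates on
#' one mode of a multi-modal reference inflates the covariance mismatch.
#'
#' By default features are standardised (z-scored) by the moments of `A`, the
#' reference sample, so mmHg- and liter-scaled features contribute comparably;
#' `"pooled"` standardises by the moments of the stacked samples (making the
#' score symmetric), `"none"` uses raw units.
#'
#' @param A,B [VitalsCohort-class] objects or numeric matrices with at least
#'   2 records each.
#' @param standardize `"reference"`, `"pooled"` or `"none"`.
#' @param variant `"frechet"` (the distance above) or `"printed"`, an audit
#'   variant using `Tr(covA + covB + 2 covA covB)`, which is not a distance
#'   (nonzero for identical inputs).
#' @param regEps Ridge added to both covariance diagonals.
#' @return Non-negative scalar (for `variant = "frechet"`).
#' @examples
#' a <- matrix(rnorm(200), 100, 2)
#' fidScore(a, a)  # 0
#' @export
fidScore <- function(A, B, standardize = c("reference", "pooled", "none"),
                     variant = c("frechet", "printed"), regEps = 1e-10) {
  standardize <- match.arg(standardize)
  variant <- match.arg(variant)
  mA <- .featmat(A); mB <- .featmat(B)
  if (nrow(mA) < 2L || nrow(mB) < 2L)
    stop("both samples need >= 2 records (covariance undefined)")
  if (ncol(mA) != ncol(mB)) stop("samples must share the same features")
  if (standardize != "none") {
    ref <- if (standardize == "reference") mA else rbind(mA, mB)
    ctr <- colMeans(ref)
    scl <- apply(ref, 2, sd)
    if (any(scl == 0))
      stop("constant feature in the standardisation reference: ",
           paste(colnames(ref)[scl == 0], collapse = ", "))
    mA <- sweep(sweep(mA, 2, ctr), 2, scl, "/")
    mB <- sweep(sweep(mB, 2, ctr), 2, scl, "/")
  }
  muA <- colMeans(mA); muB <- colMeans(mB)
  covA <- cov(mA) + diag(regEps, ncol(mA))
  covB <- cov(mB) + diag(regEps, ncol(mB))
  if (variant == "printed")
    return(sum((muA - muB)^2) + sum(diag(covA + covB + 2 * covA %*% covB)))
  sA <- .matSqrt(covA)
  M <- sA %*% covB %*% sA
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  out <- sum((muA - muB)^2) + sum(diag(covA)) + sum(diag(covB)) -
    2 * sum(sqrt(pmax(ev, 0)))
  if (!is.finite(out))
    stop("non-finite Frechet distance (mean shift ",
         format(sum((muA - muB)^2)), ", traces ",
         format(sum(diag(covA))), "/", format(sum(diag(covB))), ")")
  max(out, 0)
}
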