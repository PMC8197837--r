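#' Min-max feature scaling
#'
#' `fitScaler()` learns per-feature minima and maxima on a reference dataset;
#' `applyScaler()` maps each predictor linearly onto `[0, 1]` over the fitted
#' range; `invertScaler()` is the exact inverse. The generator trains on
#' scaled features (its output activation is bounded), so every synthetic
#' sample is inverse-scaled back to physical units before use.
#'
#' Applying a transform fitted on one dataset to another may legitimately
#' produce values outside `[0, 1]`; this is allowed and flagged with a
#' message.
#'
#' @param x A [VitalsCohort-class] or a numeric records-by-predictors matrix.
#' @param transform A fitted [ScalingTransform-class].
#' @return `fitScaler()`: a [ScalingTransform-class]. `applyScaler()` /
#'   `invertScaler()`: an object of the same type as `x` with transformed
#'   features.
#' @examples
#' co <- simulateCohort(20, seed = 1)
#' sc <- fitScaler(co)
#' range(featureMatrix(applyScaler(co, sc)))
#' @export
fitScaler <- function(x) {
  m <- .featmat(x)
  if (nrow(m) < 2L) stop("fitting a scaler requires at least 2 records")
  mn <- apply(m, 2, min)
  mx <- apply(m, 2, max)
  const <- which(mx <= mn)
  if (length(const))
    stop("constant feature cannot be scaled: ",
         paste(colnames(m)[const], collapse = ", "))
  new("ScalingTransform", min = mn, max = mx)
}

.scaleCore <- function(x, transform, invert) {
  stopifnot(is(transform, "ScalingTransform"))
  m <- .featmat(x)
  if (!identical(colnames(m), names(transform@min)))
    m <- m[, names(transform@min), drop = FALSE]
  rng <- transform@max - transform@min
  out <- if (invert) sweep(sweep(m, 2, rng, "*"), 2, transform@min, "+")
         else sweep(sweep(m, 2, transform@min, "-"), 2, rng, "/")
  if (!invert && (any(out < 0) || any(out > 1)))
    message("scaled values fall outside [0, 1]: input exceeds the fitted range")
  if (is(x, "VitalsCohort")) {
    a <- assay(x, "vitals")
    a[] <- t(out)
    SummarizedExperiment::assay(x, "vitals") <- a
    x
  } else out
}

#' @rdname fitScaler
#' @export
applyScaler <- function(x, transform) .scaleCore(x, transform, invert = FALSE)

#' @rdname fitScaler
#' @export
invertScaler <- function(x, transform) .scaleCore(x, transform, invert = TRUE)

setMethod("show", "ScalingTransform", function(object) {
  cat("ScalingTransform (min-max) over", length(object@min), "features\n")
  print(rbind(min = object@min, max = object@max))
})
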