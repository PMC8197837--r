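#' Cohort simulator parameters
#'
#' Builds a [CohortParams-class] with physiologically plausible defaults for a
#' single monitored COPD subject. Class-conditional effects are placed on the
#' features the rule-based analysis is expected to pick up: FEV1 (2.6 L vs
#' 2.0 L, sd 0.25), PEF (440 vs 360 L/min, sd 30 - the label source), heart
#' rate from both devices (70 vs 80 bpm, sd 6; lower in the PEF-high class)
#' and MAP (95 vs 88 mmHg, sd 6). Remaining features are class-independent.
#' Default correlations: FEV1-PEF 0.7, systolic-MAP 0.8, diastolic-MAP 0.8,
#' systolic-diastolic 0.64 (consistent with both pressures driving MAP), and
#' 0.9 between the two heart-rate channels.
#'
#' A user-supplied correlation matrix that is not positive semi-definite is
#' projected to the nearest PSD correlation with a warning.
#'
#' @param meanHigh,meanLow,sd Named numeric vectors over [vitalFeatures()];
#'   partial vectors override the defaults feature-by-feature.
#' @param corr Optional 11 x 11 correlation matrix with dimnames over
#'   [vitalFeatures()].
#' @param pHigh Prevalence of the PEF-high class (default 0.5).
#' @param rho AR(1) day-to-day autocorrelation coefficient (default 0).
#' @return A [CohortParams-class].
#' @export
CohortParams <- function(meanHigh = NULL, meanLow = NULL, sd = NULL,
                         corr = NULL, pHigh = 0.5, rho = 0) {
  f <- vitalFeatures()
  mh <- c(oxygen = 94, body_temperature = 36.6, heart_rate = 70,
          heart_rate_master = 70, weight = 78, bmi = 26, fev1 = 2.6,
          pef = 440, map = 95, diastolic_pressure = 72,
          systolic_pressure = 125)[f]
  ml <- mh
  ml[c("heart_rate", "heart_rate_master")] <- 80
  ml["fev1"] <- 2.0
  ml["pef"] <- 360
  ml["map"] <- 88
  sdv <- c(oxygen = 2, body_temperature = 0.3, heart_rate = 6,
           heart_rate_master = 6, weight = 2, bmi = 0.7, fev1 = 0.25,
           pef = 30, map = 6, diastolic_pressure = 7,
           systolic_pressure = 9)[f]
  .override <- function(base, user) {
    if (is.null(user)) return(base)
    stopifnot(!is.null(names(user)), all(names(user) %in% f))
    base[names(user)] <- user
    base
  }
  mh <- .override(mh, meanHigh); ml <- .override(ml, meanLow)
  sdv <- .override(sdv, sd)
  if (is.null(corr)) {
    corr <- diag(11)
    dimnames(corr) <- list(f, f)
    .set <- function(a, b, v) { corr[a, b] <<- v; corr[b, a] <<- v }
    .set("fev1", "pef", 0.7)
    .set("systolic_pressure", "map", 0.8)
    .set("diastolic_pressure", "map", 0.8)
    .set("systolic_pressure", "diastolic_pressure", 0.64)
    .set("heart_rate", "heart_rate_master", 0.9)
  } else {
    stopifnot(identical(dim(corr), c(11L, 11L)))
    if (is.null(dimnames(corr))) dimnames(corr) <- list(f, f)
    corr <- corr[f, f]
    if (min(eigen((corr + t(corr)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8) {
      warning("correlation matrix is not positive semi-definite; ",
              "projecting to the nearest PSD correlation")
      corr <- .nearestPSDCorr(corr)
    }
  }
  new("CohortParams", meanHigh = mh, meanLow = ml, sd = sdv, corr = corr,
      pHigh = pHigh, rho = rho)
}

setMethod("show", "CohortParams", function(object) {
  eff <- names(which(object@meanHigh != object@meanLow))
  cat(sprintf("CohortParams: pHigh=%.2f, rho=%.2f\n", object@pHigh, object@rho))
  cat("  class-conditional effects on:", paste(eff, collapse = ", "), "\n")
})

#' Simulate a labeled vital-sign cohort
#'
#' Draws a tentative class per record from the prevalence, then a feature
#' vector (all 11 features, PEF included) from the class-conditional
#' multivariate Gaussian obtained by scaling the correlation matrix with the
#' per-feature standard deviations (Cholesky factorisation). With `rho != 0`
#' the standardised residuals follow an AR(1) process over record order,
#' emulating day-to-day autocorrelation of a single monitored subject.
#' Features are clamped to the plausibility bounds of [physioBounds()], and
#' each record's final label is re-derived from its simulated PEF via
#' [deriveLabel()], so label and PEF are consistent by construction.
#'
#' @param n Number of records (>= 1).
#' @param params A [CohortParams-class].
#' @param seed Optional seed; the same seed yields an identical cohort.
#' @return A [VitalsCohort-class] with provenance `"simulated"` and raw PEF
#'   values stored.
#' @examples
#' co <- simulateCohort(43, seed = 7)
#' table(classLabels(co))
#' @export
simulateCohort <- function(n, params = CohortParams(), seed = NULL) {
  stopifnot(is(params, "CohortParams"))
  validObject(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  f <- vitalFeatures()
  .withSeed(seed, {
    cls <- rbinom(n, 1L, params@pHigh)  # 1 = high
    e <- matrix(rnorm(n * 11L), n, 11L)
    if (params@rho != 0 && n > 1L) {
      r <- params@rho
      for (i in 2:n) e[i, ] <- r * e[i - 1L, ] + sqrt(1 - r^2) * e[i, ]
    }
    u <- chol(params@corr)
    z <- e %*% u
    mu <- rbind(params@meanLow, params@meanHigh)[cls + 1L, , drop = FALSE]
    x <- mu + sweep(z, 2, params@sd, "*")
    colnames(x) <- f
    for (ff in f) {
      b <- .VITAL_BOUNDS[[ff]]
      x[, ff] <- pmin(pmax(x[, ff], b[1]), b[2])
    }
    pef <- x[, "pef"]
    VitalsCohort(x[, predictorNames(), drop = FALSE],
                 labels = deriveLabel(pef), pef = pef,
                 provenance = "simulated")
  })
}
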