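# Fixtures built in code, shared across test files.

# Baseline feature values for constructing hand-crafted cohorts: plausible
# resting vitals; individual tests override the features they exercise.
baselineFeatureRow <- function() {
  c(oxygen = 94, body_temperature = 36.6, heart_rate = 75,
    heart_rate_master = 75, weight = 78, bmi = 26, fev1 = 2.3,
    map = 92, diastolic_pressure = 72, systolic_pressure = 125)
}

# n records of baseline vitals with selected features overridden by vectors.
makeFeatures <- function(n, ...) {
  m <- matrix(rep(baselineFeatureRow(), each = n), nrow = n,
              dimnames = list(NULL, predictorNames()))
  over <- list(...)
  for (f in names(over)) m[, f] <- over[[f]]
  m
}

# Linearly separable toy: three low records (fev1 1.8-2.0) vs three high
# (fev1 2.4-2.6); every other feature constant.
makeSeparableToy <- function() {
  VitalsCohort(makeFeatures(6, fev1 = c(1.8, 1.9, 2.0, 2.4, 2.5, 2.6)),
               labels = c("low", "low", "low", "high", "high", "high"))
}

# XOR pattern on heart_rate x fev1 with k records per quadrant: the class is
# "high" exactly when one of the two features is elevated, so no single
# axis-aligned split has positive Gini gain.
makeXORToy <- function(k = 5) {
  hr <- rep(c(60, 60, 90, 90), each = k)
  fev <- rep(c(2.0, 3.0, 2.0, 3.0), each = k)
  lab <- ifelse(xor(hr > 75, fev > 2.5), "high", "low")
  VitalsCohort(makeFeatures(4 * k, heart_rate = hr, fev1 = fev), labels = lab)
}

# Random cohort with labels independent of the (noisy) features.
makeNullCohort <- function(n, seed) {
  withr::with_seed(seed, {
    m <- makeFeatures(n,
      fev1 = rnorm(n, 2.3, 0.3), heart_rate = rnorm(n, 75, 8),
      map = rnorm(n, 92, 7), oxygen = rnorm(n, 94, 2))
    VitalsCohort(m, labels = sample(rep(c("low", "high"), length.out = n)))
  })
}

# Shuffle a cohort's labels relative to its features (negative control).
permuteLabels <- function(co, seed) {
  withr::with_seed(seed,
    VitalsCohort(featureMatrix(co),
                 labels = sample(as.character(classLabels(co))),
                 provenance = "synthetic"))
}

# Exhaustive hypergeometric tail oracle for the one-sided Fisher test,
# computed from binomial coefficients only.
fetOracle <- function(a, b, cc, d) {
  n <- a + b + cc + d
  if (a + b == 0 || cc + d == 0) return(1)
  xs <- a:min(a + b, a + cc)
  sum(choose(a + cc, xs) * choose(b + d, a + b - xs)) / choose(n, a + b)
}

# Direct evaluation of the histogram JS divergence, independent of the
# package's binning code: hist() counts over the pooled range, explicit
# KL-to-mean sums in base 2.
jsOracle <- function(a, b, bins = 10, eps = 1e-10) {
  stopifnot(ncol(a) == ncol(b))
  per <- vapply(seq_len(ncol(a)), function(j) {
    lo <- min(a[, j], b[, j]); hi <- max(a[, j], b[, j])
    if (hi <= lo) return(0)
    br <- seq(lo, hi, length.out = bins + 1)
    p <- hist(a[, j], breaks = br, plot = FALSE)$counts / nrow(a)
    q <- hist(b[, j], breaks = br, plot = FALSE)$counts / nrow(b)
    p <- (p + eps) / sum(p + eps); q <- (q + eps) / sum(q + eps)
    m <- (p + q) / 2
    kl <- function(x) { s <- x > 0; sum(x[s] * log2(x[s] / m[s])) }
    (kl(p) + kl(q)) / 2
  }, numeric(1))
  mean(per)
}

# Random scored rule over a random feature subset (for property tests).
randomRule <- function(m) {
  k <- sample(1:2, 1)
  feats <- sample(colnames(m), k)
  conds <- lapply(feats, function(f)
    data.frame(feature = f, op = sample(c("<", "<=", ">", ">="), 1),
               threshold = as.numeric(quantile(m[, f], runif(1, .2, .8)))))
  Rule(do.call(rbind, conds), sample(c("low", "high"), 1))
}
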