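test_that("JS on probability vectors matches the hand-derived two-bin case", {
  # P=(.5,.5), Q=(1,0): m=(.75,.25); KL(P||m)=.20752, KL(Q||m)=.41504
  expect_equal(jsDivergenceProb(c(0.5, 0.5), c(1, 0)), 0.3112781, tolerance = 1e-6)
  expect_equal(jsDivergenceProb(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(jsDivergenceProb(c(1, 0), c(0, 1)), 1)  # disjoint support
  expect_error(jsDivergenceProb(c(0.6, 0.6), c(0.5, 0.5)), "sum to 1")
})

test_that("sample JS divergence: identity, disjoint supports, bounds, symmetry", {
  co <- simulateCohort(100, seed = 1)
  expect_equal(jsDivergence(co, co), 0)
  a <- matrix(runif(200, 0, 1), ncol = 1)
  b <- matrix(runif(200, 2, 3), ncol = 1)
  expect_equal(jsDivergence(a, b), 1, tolerance = 1e-6)
  expect_error(jsDivergence(a, b, bins = 1), "bins")
  expect_error(jsDivergence(a[0, , drop = FALSE], b), "non-empty")
})

test_that("JS equals direct histogram evaluation on random sample pairs", {
  withr::with_seed(42, {
    for (i in 1:50) {
      f <- sample(1:4, 1)
      a <- matrix(rnorm(30 * f, sample(0:3, 1)), ncol = f)
      b <- matrix(rnorm(40 * f, sample(0:3, 1), sd = runif(1, .5, 2)), ncol = f)
      got <- jsDivergence(a, b)
      expect_equal(got, jsOracle(a, b), tolerance = 1e-8)
      expect_equal(got, jsDivergence(b, a), tolerance = 1e-12)  # symmetric
      expect_gte(got, 0); expect_lte(got, 1)
    }
  })
})

test_that("between-class JS separates shifted classes and rejects single-class input", {
  co <- simulateCohort(2000, seed = 3)
  lab <- classLabels(co)
  within <- jsBetweenClasses(co)
  expect_gt(within, 0)
  expect_equal(within,
               jsOracle(featureMatrix(co)[lab == "high", ],
                        featureMatrix(co)[lab == "low", ]),
               tolerance = 1e-8)

  # identical class-conditionals: duplicate one class's features under both labels
  m <- featureMatrix(co)[lab == "low", ][1:50, ]
  same <- VitalsCohort(rbind(m, m), labels = rep(c("low", "high"), each = 50))
  expect_equal(jsBetweenClasses(same), 0)

  onecls <- VitalsCohort(m, labels = rep("low", 50))
  expect_error(jsBetweenClasses(onecls), "both classes")

  # cross mode compares against the same class of a reference sample
  ref <- simulateCohort(2000, seed = 4)
  expect_lt(jsBetweenClasses(co, mode = "cross", reference = ref), within)
})

test_that("Frechet distance matches its 1-D closed forms exactly", {
  # sample moments constructed exactly: mean 0/1, variance 1 -> FID 1
  a <- matrix(c(-1, 1) / sqrt(2), ncol = 1)
  b <- matrix(1 + c(-1, 1) / sqrt(2), ncol = 1)
  expect_equal(fidScore(a, b, standardize = "none", regEps = 0), 1,
               tolerance = 1e-9)
  # (mu=0, var=4) vs (mu=0, var=1): 0 + (4 + 1 - 2*2) = 1
  a2 <- matrix(c(-1, 1) * sqrt(2), ncol = 1)
  b2 <- matrix(c(-1, 1) / sqrt(2), ncol = 1)
  expect_equal(fidScore(a2, b2, standardize = "none", regEps = 0), 1,
               tolerance = 1e-9)
})

test_that("Frechet distance is zero on identical samples and symmetric when pooled", {
  co <- simulateCohort(100, seed = 5)
  expect_equal(fidScore(co, co), 0, tolerance = 1e-6)
  other <- simulateCohort(150, seed = 6)
  expect_equal(fidScore(co, other, standardize = "pooled"),
               fidScore(other, co, standardize = "pooled"), tolerance = 1e-8)
  expect_error(fidScore(featureMatrix(co)[1, , drop = FALSE], co), ">= 2")
})

test_that("Frechet distance is monotone in the mean shift", {
  withr::with_seed(8, {
    a <- matrix(rnorm(500), ncol = 5)
    b0 <- matrix(rnorm(500), ncol = 5)
    fids <- vapply(c(0, 0.5, 1, 2, 4), function(shift)
      fidScore(a, b0 + shift, standardize = "none"), numeric(1))
    expect_true(all(diff(fids) > 0))  # fixed covariances, growing mean shift
  })
})

test_that("Frechet distance is sensitive to mode collapse", {
  withr::with_seed(9, {
    ref <- matrix(c(rnorm(300, -3, .5), rnorm(300, 3, .5)), ncol = 1)
    twoMode <- matrix(c(rnorm(300, -3, .5), rnorm(300, 3, .5)), ncol = 1)
    oneMode <- matrix(rnorm(600, 3, .5), ncol = 1)
    expect_gt(fidScore(ref, oneMode), fidScore(ref, twoMode))
  })
})

test_that("the printed-form audit variant is not a distance", {
  a <- matrix(rnorm(100), ncol = 2)
  expect_gt(fidScore(a, a, variant = "printed"), 0)
})
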