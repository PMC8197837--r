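test_that("printed rules parse to the expected conditions", {
  r1 <- parseRule("if((FEV1<2.23))then low")
  expect_equal(r1@premise$feature, "fev1")
  expect_equal(r1@premise$op, "<")
  expect_equal(r1@premise$threshold, 2.23)
  expect_equal(r1@consequence, "low")

  r2 <- parseRule("if((heartrate<74)∧(diastolicpressure>67))then high")
  expect_equal(nrow(r2@premise), 2)
  expect_setequal(r2@premise$feature, c("heart_rate", "diastolic_pressure"))
  expect_equal(r2@consequence, "high")

  r3 <- parseRule("if((FEV1>2.18)&(MAP>90.39))then high")
  expect_equal(r3@premise$feature, c("fev1", "map"))
  r4 <- parseRule("if((FEV1<=2.23)&(MAP<=104.18))then low")
  expect_equal(r4@premise$op, c("<=", "<="))

  # annotations round-trip into the statistics slots
  r5 <- parseRule("if((FEV1<2.23))then low (C = 41%) (r = 4.7%)")
  expect_equal(r5@covering, 0.41)
  expect_equal(r5@error, 0.047)

  expect_error(parseRule("if((FEV1<2.23))maybe low"), "malformed")
  expect_error(parseRule("if((pef<400))then low"), "pef")
  expect_error(parseRule("if((nosuch<1))then low"), "nosuch")
})

test_that("parseRule is the left inverse of formatRule", {
  withr::with_seed(11, {
    m <- featureMatrix(simulateCohort(30, seed = 1))
    for (i in 1:25) {
      r <- randomRule(m)
      back <- parseRule(formatRule(r))
      expect_equal(back@premise[order(back@premise$feature), ],
                   r@premise[order(r@premise$feature), ],
                   ignore_attr = TRUE, tolerance = 1e-5)
      expect_identical(back@consequence, r@consequence)
    }
  })
})

test_that("contradictory or duplicate bounds are rejected", {
  expect_error(Rule(data.frame(feature = c("fev1", "fev1"),
                               op = c(">", "<"), threshold = c(3, 2)), "low"),
               "contradictory")
  expect_error(Rule(data.frame(feature = c("map", "map"),
                               op = c("<", "<="), threshold = c(90, 95)),
                    "high"), "more than one bound")
  expect_error(Rule(data.frame(feature = "fev1", op = "<", threshold = Inf),
                    "low"), "finite")
})

test_that("covering and error are class-conditional proportions", {
  # 10 high of which 7 satisfy; 10 low of which 1 satisfies
  m <- makeFeatures(20, fev1 = c(rep(3, 7), rep(2, 3), 3, rep(2, 9)))
  co <- VitalsCohort(m, labels = rep(c("high", "low"), each = 10))
  r <- parseRule("if((FEV1>2.5))then high")
  expect_equal(coveringError(r, co), c(C = 0.7, r = 0.1))

  # perfect rule
  co2 <- VitalsCohort(makeFeatures(43, fev1 = c(rep(3, 20), rep(2, 23))),
                      labels = c(rep("high", 20), rep("low", 23)))
  expect_equal(coveringError(r, co2), c(C = 1, r = 0))

  onecls <- VitalsCohort(makeFeatures(5), labels = rep("low", 5))
  expect_error(coveringError(r, onecls), "absent")
})

test_that("covering/error equal brute-force counting on random rules", {
  withr::with_seed(13, {
    co <- simulateCohort(80, seed = 2)
    m <- featureMatrix(co)
    lab <- as.character(classLabels(co))
    for (i in 1:30) {
      r <- randomRule(m)
      sat <- vapply(seq_len(nrow(m)), function(k) {
        all(vapply(seq_len(nrow(r@premise)), function(q) {
          x <- m[k, r@premise$feature[q]]; t <- r@premise$threshold[q]
          switch(r@premise$op[q], "<" = x < t, "<=" = x <= t,
                 ">" = x > t, ">=" = x >= t)
        }, logical(1)))
      }, logical(1))
      cr <- coveringError(r, co)
      expect_equal(unname(cr["C"]),
                   sum(sat & lab == r@consequence) / sum(lab == r@consequence))
      expect_equal(unname(cr["r"]),
                   sum(sat & lab != r@consequence) / sum(lab != r@consequence))
    }
  })
})

test_that("dropping a condition can only widen a rule (monotone C and r)", {
  withr::with_seed(17, {
    co <- simulateCohort(60, seed = 3)
    m <- featureMatrix(co)
    for (i in 1:20) {
      r <- randomRule(m)
      if (nrow(r@premise) < 2) next
      full <- coveringError(r, co)
      for (drop in seq_len(nrow(r@premise))) {
        sub <- Rule(r@premise[-drop, ], r@consequence)
        rel <- coveringError(sub, co)
        expect_gte(rel["C"], full["C"])
        expect_gte(rel["r"], full["r"])
      }
    }
  })
})

test_that("the tree inducer separates the 1-feature toy at depth 1", {
  toy <- makeSeparableToy()
  rs <- induceRulesTree(toy, maxDepth = 1, minLeaf = 2)
  expect_equal(nRules(rs), 2)
  for (r in rules(rs)) {
    expect_equal(r@premise$feature, "fev1")
    expect_gt(r@premise$threshold, 2.0)
    expect_lt(r@premise$threshold, 2.4)
    expect_equal(r@covering, 1)
    expect_equal(r@error, 0)
  }
  expect_setequal(vapply(rules(rs), function(r) r@consequence, character(1)),
                  c("low", "high"))
  expect_error(induceRulesTree(toy, maxDepth = 0), ">= 1")
  onecls <- VitalsCohort(makeFeatures(5), labels = rep("low", 5))
  expect_error(induceRulesTree(onecls), "both classes")
})

test_that("the tree inducer recovers an XOR interaction at depth 2", {
  rs <- induceRulesTree(makeXORToy(5), maxDepth = 2, minLeaf = 2)
  expect_equal(nRules(rs), 4)
  for (r in rules(rs)) {
    expect_equal(r@covering, 0.5)
    expect_equal(r@error, 0)
    expect_setequal(r@premise$feature, c("heart_rate", "fev1"))
  }
})

test_that("the greedy inducer separates the toy within one bin of the gap", {
  toy <- makeSeparableToy()
  rs <- induceRulesGreedy(toy, qBins = 4, maxError = 0)
  expect_equal(nRules(rs), 2)
  for (r in rules(rs)) {
    expect_equal(r@premise$feature, rep("fev1", nrow(r@premise)))
    expect_equal(r@covering, 1)
    expect_equal(r@error, 0)
    # thresholds are bin edges; the gap between classes is (2.0, 2.4)
    binWidth <- diff(range(c(1.8, 2.6))) / 4
    expect_true(all(abs(r@premise$threshold - 2.2) <= binWidth + 1e-9))
  }
  expect_setequal(vapply(rules(rs), function(r) r@consequence, character(1)),
                  c("low", "high"))
})

test_that("a binding max_conditions budget lowers covering", {
  # class high occupies a corner needing two conditions
  withr::with_seed(19, {
    n <- 120
    hr <- runif(n, 55, 95); fev <- runif(n, 1.6, 3.0)
    lab <- ifelse(hr < 75 & fev > 2.3, "high", "low")
    co <- VitalsCohort(makeFeatures(n, heart_rate = hr, fev1 = fev),
                       labels = lab)
    unconstrained <- induceRulesGreedy(co, qBins = 4, maxConditions = 3,
                                       maxError = 0.05)
    constrained <- induceRulesGreedy(co, qBins = 4, maxConditions = 1,
                                     maxError = 0.05)
    covHigh <- function(rs) {
      hi <- Filter(function(r) r@consequence == "high", rules(rs))
      if (!length(hi)) 0 else max(vapply(hi, function(r) r@covering, numeric(1)))
    }
    expect_lt(covHigh(constrained), covHigh(unconstrained))
  })
})

test_that("an unattainable error budget yields an empty set with a warning", {
  co <- makeNullCohort(40, seed = 23)
  expect_warning(rs <- induceRulesGreedy(co, qBins = 2, maxConditions = 1,
                                         maxError = 0), "empty rule set")
  expect_equal(nRules(rs), 0)
})

test_that("tree and greedy rules agree on the separable toy and classify perfectly", {
  toy <- makeSeparableToy()
  for (rs in list(induceRulesTree(toy, maxDepth = 1, minLeaf = 2),
                  induceRulesGreedy(toy, qBins = 4, maxError = 0))) {
    ev <- evaluateRuleSet(rs, toy)
    expect_equal(unname(ev["accuracy"]), 1)
    expect_equal(unname(ev["f1"]), 1)
  }
})

test_that("classification aggregates firing rules by C*(1-r) weights", {
  # weights from the printed baseline statistics: high 0.43*0.955 beats
  # low 0.41*0.953
  high <- Rule(data.frame(feature = "heart_rate", op = "<", threshold = 74),
               "high", covering = 0.43, error = 0.045)
  low <- Rule(data.frame(feature = "fev1", op = "<", threshold = 2.23),
              "low", covering = 0.41, error = 0.047)
  rs <- RuleSet(list(high, low), defaultClass = "low")
  rec <- makeFeatures(1, heart_rate = 70, fev1 = 2.0)  # fires both
  expect_equal(as.character(predictClass(rs, rec)), "high")

  # a record firing no rule falls back to the default class
  rec2 <- makeFeatures(1, heart_rate = 80, fev1 = 3.0)
  expect_equal(as.character(predictClass(rs, rec2)), "low")

  # single firing rule wins regardless of the default
  rs2 <- RuleSet(list(Rule(data.frame(feature = "map", op = ">",
                                      threshold = 90), "high",
                           covering = 0.5, error = 0)),
                 defaultClass = "low")
  expect_equal(as.character(predictClass(rs2, makeFeatures(1, map = 95))),
               "high")

  # unscored rules cannot vote
  rs3 <- RuleSet(list(Rule(data.frame(feature = "map", op = ">",
                                      threshold = 90), "high")))
  expect_error(predictClass(rs3, rec), "scored")
})
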