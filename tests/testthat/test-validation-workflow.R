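test_that("the rule FET p-value matches exhaustive enumeration and fisher.test", {
  # worked 2x2 example a=8, b=1, c=2, d=9: hand enumeration gives
  # [C(10,8)C(10,1) + C(10,9)C(10,0)] / C(20,9) = 460/167960
  expect_equal(fetOracle(8, 1, 2, 9), 460 / 167960)
  expect_equal(copdGAN:::.fetTablePvalue(8, 1, 2, 9), fetOracle(8, 1, 2, 9),
               ignore_attr = TRUE)

  # exported path on a constructed cohort realising the same table
  m <- makeFeatures(20, fev1 = c(rep(3, 8), rep(2, 2), 3, rep(2, 9)))
  co <- VitalsCohort(m, labels = rep(c("high", "low"), each = 10))
  r <- parseRule("if((FEV1>2.5))then high")
  p <- fetRulePvalue(r, co)
  expect_equal(as.numeric(p), 460 / 167960)
  expect_equal(unname(attr(p, "table")[1, ]), c(8, 1))
  expect_equal(as.numeric(p),
               fisher.test(attr(p, "table"), alternative = "greater")$p.value)

  # premise never firing on the consequence class carries no evidence
  m0 <- makeFeatures(10, fev1 = c(rep(2, 5), rep(3, 5)))
  co0 <- VitalsCohort(m0, labels = rep(c("high", "low"), each = 5))
  expect_equal(as.numeric(fetRulePvalue(parseRule("if((FEV1>2.5))then high"),
                                        co0)), 1)

  # degenerate margins (fires on all records) are flagged, not an error
  pAll <- fetRulePvalue(parseRule("if((FEV1>0.5))then high"), co0)
  expect_equal(as.numeric(pAll), 1)
  expect_true(attr(pAll, "degenerate"))
})

test_that("enrichment p-values are invariant under relabelling the classes", {
  withr::with_seed(31, {
    for (i in 1:20) {
      a <- sample(0:8, 1); b <- sample(0:8, 1)
      cc <- sample(0:8, 1); d <- sample(0:8, 1)
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
      p1 <- as.numeric(copdGAN:::.fetTablePvalue(a, b, cc, d))
      # swap which class is "other" and flip the alternative direction
      p2 <- fisher.test(matrix(c(b, d, a, cc), 2),
                        alternative = "less")$p.value
      expect_equal(p1, p2, tolerance = 1e-12)
    }
  })
})

test_that("FET keeps its nominal type-I level on class-independent rules", {
  hits <- 0L
  for (s in 1:100) {
    co <- makeNullCohort(60, seed = 4000 + s)
    r <- Rule(data.frame(feature = "fev1", op = "<",
                         threshold = median(featureMatrix(co)[, "fev1"])),
              "low")
    if (as.numeric(fetRulePvalue(r, co)) < 0.05) hits <- hits + 1L
  }
  expect_lte(hits / 100, 0.06)
})

test_that("FET filtering keeps signal rules, drops noise, respects alpha", {
  co <- simulateCohort(43, seed = 7)
  signal <- parseRule("if((FEV1<2.25))then low")
  noise <- parseRule("if((weight>78))then high")  # class-independent feature
  rs <- RuleSet(list(signal, noise), defaultClass = "low")
  kept <- filterRulesFET(scoreRules(rs, co), co)
  expect_equal(nRules(kept), 1)
  expect_equal(rules(kept)[[1]]@premise$feature, "fev1")
  expect_lt(rules(kept)[[1]]@pvalue, 0.05)

  expect_equal(nRules(filterRulesFET(RuleSet(), co)), 0)
  expect_equal(nRules(filterRulesFET(rs, co, alpha = 1.0)), 2)

  # shrinking alpha never enlarges the filtered set
  pset <- filterRulesFET(rs, co, alpha = 0.05)
  pset2 <- filterRulesFET(rs, co, alpha = 0.01)
  expect_true(all(vapply(rules(pset2), formatRule, character(1)) %in%
                  vapply(rules(pset), formatRule, character(1))))

  # BH adjustment is at least as conservative as no adjustment
  expect_lte(nRules(filterRulesFET(rs, co, adjust = "BH")), nRules(kept) + 1)
})

test_that("rule-set evaluation reproduces closed-form accuracy and F1", {
  # empty set, default low, 60% low records
  m <- makeFeatures(10)
  co <- VitalsCohort(m, labels = c(rep("low", 6), rep("high", 4)))
  ev <- evaluateRuleSet(RuleSet(defaultClass = "low"), co)
  expect_equal(unname(ev), c(0.6, 0))

  # constant-high classifier on balanced data: acc .5, F1 = 2/3
  co2 <- VitalsCohort(makeFeatures(10), labels = rep(c("low", "high"), 5))
  allHigh <- RuleSet(list(Rule(data.frame(feature = "fev1", op = ">",
                                          threshold = 0), "high",
                               covering = 1, error = 1)),
                     defaultClass = "high")
  ev2 <- evaluateRuleSet(allHigh, co2)
  expect_equal(unname(ev2["accuracy"]), 0.5)
  expect_equal(unname(ev2["f1"]), 2 / 3, tolerance = 1e-9)
})

test_that("the augmentation workflow relates its three models correctly", {
  real <- simulateCohort(43, seed = 7)

  # synthetic == real: deterministic induction makes candidate == baseline
  wf <- runAugmentationWorkflow(real, real)
  expect_setequal(
    vapply(rules(candidateRules(wf)), formatRule, character(1)),
    vapply(rules(baselineRules(wf)), formatRule, character(1)))

  # augmented is always a subset of candidate (premise+consequence identity)
  synth <- simulateCohort(1000, seed = 8)
  wf2 <- runAugmentationWorkflow(real, synth)
  expect_true(all(vapply(rules(augmentedRules(wf2)), formatRule, character(1))
                  %in% vapply(rules(candidateRules(wf2)), formatRule,
                              character(1))))
  expect_true(isValidWorkflow(wf2))
  met <- workflowMetrics(wf2)
  expect_setequal(met$model, c("baseline", "candidate_augmented", "augmented"))
  expect_true(all(met$accuracy >= 0 & met$accuracy <= 1))

  # permuted-label synthetic data should not validate
  noise <- permuteLabels(simulateCohort(1000, seed = 9), seed = 10)
  wf3 <- runAugmentationWorkflow(real, noise)
  expect_equal(nRules(augmentedRules(wf3)), 0)
})

test_that("good synthetic data yields real-data accuracy close to baseline", {
  real <- simulateCohort(43, seed = 7)
  gaps <- vapply(1:5, function(s) {
    synth <- simulateCohort(1000, seed = 100 + s)
    met <- workflowMetrics(runAugmentationWorkflow(real, synth))
    base <- met$accuracy[met$model == "baseline"]
    aug <- met$accuracy[met$model == "augmented" & met$data == "real"]
    abs(base - aug)
  }, numeric(1))
  expect_lt(mean(gaps), 0.15)
})
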