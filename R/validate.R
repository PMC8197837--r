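#' Fisher's exact test p-value for a rule
#'
#' Builds the 2x2 contingency table of premise satisfaction against class
#' membership (a: premise & consequence class, b: premise & other class,
#' c: no premise & consequence class, d: no premise & other class) and returns
#' the one-sided Fisher exact p-value for enrichment of the premise in the
#' consequence class, computed from the hypergeometric distribution. A rule is
#' a directional claim (premise implies class), so the one-sided alternative
#' is the default; `alternative = "two.sided"` delegates to
#' [stats::fisher.test()].
#'
#' Degenerate margins (the premise fires on none or all records) carry no
#' evidence: p = 1 is returned with attribute `degenerate = TRUE`.
#'
#' @param rule A [Rule-class].
#' @param D A [VitalsCohort-class] with both classes present.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return p-value in `(0, 1]`, with attribute `table` (the 2x2 counts).
#' @examples
#' co <- simulateCohort(43, seed = 7)
#' fetRulePvalue(parseRule("if((FEV1<2.3))then low"), co)
#' @export
fetRulePvalue <- function(rule, D, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is(rule, "Rule"), is(D, "VitalsCohort"))
  lab <- as.character(classLabels(D))
  if (length(unique(lab)) < 2L) stop("both classes must be present")
  fires <- .ruleFires(rule, featureMatrix(D))
  inCls <- lab == rule@consequence
  a <- sum(fires & inCls); b <- sum(fires & !inCls)
  cc <- sum(!fires & inCls); d <- sum(!fires & !inCls)
  tab <- matrix(c(a, cc, b, d), 2L,
                dimnames = list(premise = c("yes", "no"),
                                class = c("consequence", "other")))
  p <- .fetTablePvalue(a, b, cc, d, alternative)
  attr(p, "table") <- tab
  p
}

## One-sided (enrichment) Fisher exact p from the 2x2 counts. Degenerate
## premise margins (fires on none or all records) carry no evidence -> p = 1
## flagged via attribute.
.fetTablePvalue <- function(a, b, cc, d, alternative = "greater") {
  if ((a + b) == 0L || (cc + d) == 0L) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  p <- if (alternative == "greater")
    phyper(a - 1L, a + cc, b + d, a + b, lower.tail = FALSE)
  else
    fisher.test(matrix(c(a, cc, b, d), 2L),
                alternative = "two.sided")$p.value
  attr(p, "degenerate") <- FALSE
  p
}

#' Filter a rule set by Fisher's exact test
#'
#' Keeps the rules whose FET p-value on `D` is below `alpha`, annotating each
#' kept rule with its p-value. The paper-style default validates each rule
#' individually; `adjust = "BH"` optionally applies Benjamini-Hochberg
#' correction across the set first.
#'
#' @param rs A [RuleSet-class].
#' @param D A [VitalsCohort-class] with both classes.
#' @param alpha Significance threshold.
#' @param adjust `"none"` (default) or `"BH"`.
#' @param alternative Passed to [fetRulePvalue()].
#' @return The filtered [RuleSet-class]; the accepted count is available as
#'   `nRules()` and is also attached as attribute `accepted`.
#' @export
filterRulesFET <- function(rs, D, alpha = 0.05, adjust = c("none", "BH"),
                           alternative = "greater") {
  adjust <- match.arg(adjust)
  stopifnot(is(rs, "RuleSet"))
  if (nRules(rs) == 0L) {
    attr(rs, "accepted") <- 0L
    return(rs)
  }
  p <- vapply(rs@rules, function(r)
    as.numeric(fetRulePvalue(r, D, alternative)), numeric(1))
  if (adjust == "BH") p <- p.adjust(p, method = "BH")
  keep <- p < alpha
  kept <- mapply(function(r, pv) { r@pvalue <- pv; r },
                 rs@rules[keep], p[keep], SIMPLIFY = FALSE)
  out <- RuleSet(kept, defaultClass = rs@defaultClass,
                 provenance = rs@provenance)
  attr(out, "accepted") <- sum(keep)
  out
}

#' Accuracy and F1 of a rule set on a dataset
#'
#' Applies [predictClass()] to every record. Accuracy is the fraction of
#' correct predictions; F1 is the harmonic mean of precision and recall with
#' class `"high"` as the positive class (0 when precision and recall are both
#' undefined or zero).
#'
#' @param rs A [RuleSet-class] (scored rules).
#' @param D A non-empty [VitalsCohort-class].
#' @return Named numeric vector `c(accuracy = ..., f1 = ...)`.
#' @export
evaluateRuleSet <- function(rs, D) {
  stopifnot(is(D, "VitalsCohort"))
  truth <- classLabels(D)
  pred <- predictClass(rs, D)
  acc <- mean(pred == truth)
  tp <- sum(pred == "high" & truth == "high")
  fp <- sum(pred == "high" & truth == "low")
  fn <- sum(pred == "low" & truth == "high")
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = acc, f1 = f1)
}

#' Baseline / candidate-augmented / augmented model workflow
#'
#' The statistical acceptance procedure for a synthetic dataset:
#' \enumerate{
#'   \item \strong{baseline}: rules induced and FET-filtered on the real data;
#'   \item \strong{candidate augmented}: rules induced and FET-filtered on the
#'     synthetic data;
#'   \item \strong{augmented}: the candidate rules re-scored (covering/error)
#'     on the real data - not re-induced - and FET-filtered on the real data.
#' }
#' The augmentation is considered valid when the augmented rule set is
#' non-empty. Quality metrics (accuracy, F1, accepted rule count) are reported
#' for the baseline on real data, the candidate on synthetic and on real data,
#' and the augmented model on real data; the augmented-on-real numbers are the
#' headline.
#'
#' @param real,synthetic [VitalsCohort-class] objects sharing the schema, each
#'   with both classes present.
#' @param inducer `"tree"` ([induceRulesTree()]) or `"greedy"`
#'   ([induceRulesGreedy()]).
#' @param alpha FET significance threshold.
#' @param ... Passed to the inducer.
#' @return A [WorkflowResult-class].
#' @examples
#' real <- simulateCohort(43, seed = 7)
#' synth <- simulateCohort(300, seed = 8)
#' runAugmentationWorkflow(real, synth)
#' @export
runAugmentationWorkflow <- function(real, synthetic,
                                    inducer = c("tree", "greedy"),
                                    alpha = 0.05, ...) {
  inducer <- match.arg(inducer)
  stopifnot(is(real, "VitalsCohort"), is(synthetic, "VitalsCohort"))
  induce <- switch(inducer, tree = induceRulesTree, greedy = induceRulesGreedy)
  baseline <- filterRulesFET(induce(real, ...), real, alpha)
  baseline@provenance <- "baseline"
  candidate <- filterRulesFET(induce(synthetic, ...), synthetic, alpha)
  candidate@provenance <- "candidate_augmented"
  augmented <- if (nRules(candidate))
    filterRulesFET(scoreRules(candidate, real, tag = "real"), real, alpha)
  else candidate
  augmented@provenance <- "augmented"
  rows <- list(
    c(model = "baseline", data = "real"),
    c(model = "candidate_augmented", data = "synthetic"),
    c(model = "candidate_augmented", data = "real"),
    c(model = "augmented", data = "real"))
  sets <- list(baseline, candidate, candidate, augmented)
  datasets <- list(real, synthetic, real, real)
  metrics <- do.call(rbind, lapply(seq_along(rows), function(i) {
    ev <- evaluateRuleSet(sets[[i]], datasets[[i]])
    data.frame(model = rows[[i]]["model"], data = rows[[i]]["data"],
               n_rules = nRules(sets[[i]]), accuracy = ev[["accuracy"]],
               f1 = ev[["f1"]], row.names = NULL)
  }))
  new("WorkflowResult", baseline = baseline, candidate = candidate,
      augmented = augmented, metrics = metrics,
      valid = nRules(augmented) > 0L)
}

#' WorkflowResult accessors
#'
#' @param x A [WorkflowResult-class].
#' @return The corresponding slot: rule sets, metrics table, or validity flag.
#' @export
baselineRules <- function(x) { stopifnot(is(x, "WorkflowResult")); x@baseline }

#' @rdname baselineRules
#' @export
candidateRules <- function(x) { stopifnot(is(x, "WorkflowResult")); x@candidate }

#' @rdname baselineRules
#' @export
augmentedRules <- function(x) { stopifnot(is(x, "WorkflowResult")); x@augmented }

#' @rdname baselineRules
#' @export
workflowMetrics <- function(x) { stopifnot(is(x, "WorkflowResult")); x@metrics }

#' @rdname baselineRules
#' @export
isValidWorkflow <- function(x) { stopifnot(is(x, "WorkflowResult")); x@valid }

setMethod("show", "WorkflowResult", function(object) {
  cat(sprintf("WorkflowResult: %s (augmented rules: %d)\n",
              if (object@valid) "VALID" else "NOT valid",
              nRules(object@augmented)))
  print(object@metrics, row.names = FALSE)
})
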