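## S4 class definitions. Accessors and methods live next to their module code.

#' VitalsCohort: labeled vital-sign records
#'
#' A `SummarizedExperiment` holding one assay `"vitals"` (10 predictor
#' features x n records) with per-record class labels (and, when available,
#' the raw PEF values the labels were derived from) in `colData`, and a
#' provenance tag (`"real"`, `"synthetic"` or `"simulated"`) in `metadata`.
#'
#' @slot ... inherited from [SummarizedExperiment::SummarizedExperiment].
#' @seealso [VitalsCohort()] (constructor), [featureMatrix()],
#'   [classLabels()], [readVitals()]
#' @export
setClass("VitalsCohort", contains = "SummarizedExperiment")

setValidity("VitalsCohort", function(object) {
  msg <- character()
  if (!"vitals" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'vitals' is missing")
  else {
    a <- assay(object, "vitals")
    if (!identical(rownames(a), predictorNames()))
      msg <- c(msg, "assay rows must be the 10 canonical predictors in order")
    if (ncol(a) < 1L) msg <- c(msg, "at least one record is required")
    if (any(!is.finite(a))) msg <- c(msg, "features contain missing/non-finite values")
  }
  cd <- colData(object)
  if (!"class" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'class' column")
  else {
    cl <- cd$class
    if (!is.factor(cl) || !identical(levels(cl), .CLASS_LEVELS))
      msg <- c(msg, "class must be a factor with levels low, high")
    if (anyNA(cl)) msg <- c(msg, "class labels contain NA")
  }
  prov <- metadata(object)$provenance
  if (is.null(prov) || !prov %in% c("real", "synthetic", "simulated"))
    msg <- c(msg, "metadata provenance must be one of real, synthetic, simulated")
  if (length(msg)) msg else TRUE
})

#' ScalingTransform: per-feature min-max scaling
#'
#' Fitted feature ranges mapping each predictor linearly onto `[0, 1]`.
#' Applying and then inverting the transform reproduces the input to within
#' 1e-9 relative tolerance. Values outside the fitted range (possible when a
#' transform fitted on real data is applied to synthetic data) map outside
#' `[0, 1]` and are flagged with a message, not an error.
#'
#' @slot min,max Named numeric vectors over the predictor features.
#' @seealso [fitScaler()], [applyScaler()], [invertScaler()]
#' @export
setClass("ScalingTransform",
  representation(min = "numeric", max = "numeric"))

setValidity("ScalingTransform", function(object) {
  if (!identical(names(object@min), names(object@max)))
    return("min and max must cover the same features")
  if (any(!is.finite(object@min)) || any(!is.finite(object@max)))
    return("fitted ranges must be finite")
  if (any(object@max <= object@min))
    return(paste0("degenerate (constant) feature: ",
                  names(object@min)[which(object@max <= object@min)[1L]]))
  TRUE
})

#' CohortParams: parameters of the vital-sign cohort simulator
#'
#' Class-conditional means and standard deviations for the 11 vital-sign
#' features, a cross-feature correlation matrix, the prevalence of the
#' PEF-high class, and an optional AR(1) coefficient for day-to-day
#' autocorrelation of consecutive records.
#'
#' @slot meanHigh,meanLow,sd Named numeric vectors over [vitalFeatures()].
#' @slot corr 11 x 11 correlation matrix (symmetric, unit diagonal, positive
#'   semi-definite; non-PSD input is projected to the nearest PSD correlation
#'   with a warning by the constructor).
#' @slot pHigh Prevalence of class `"high"` used when drawing records.
#' @slot rho AR(1) coefficient, `|rho| < 1`; 0 disables autocorrelation.
#' @seealso [CohortParams()], [simulateCohort()]
#' @export
setClass("CohortParams",
  representation(meanHigh = "numeric", meanLow = "numeric", sd = "numeric",
                 corr = "matrix", pHigh = "numeric", rho = "numeric"))

setValidity("CohortParams", function(object) {
  f <- vitalFeatures()
  msg <- character()
  for (nm in c("meanHigh", "meanLow", "sd"))
    if (!identical(names(slot(object, nm)), f))
      msg <- c(msg, sprintf("'%s' must be named over the 11 vital features", nm))
  if (any(object@sd <= 0)) msg <- c(msg, "all standard deviations must be > 0")
  cm <- object@corr
  if (!identical(dim(cm), c(11L, 11L)) || !isTRUE(all.equal(cm, t(cm))) ||
      !isTRUE(all.equal(unname(diag(cm)), rep(1, 11))))
    msg <- c(msg, "corr must be a symmetric 11 x 11 matrix with unit diagonal")
  else if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    msg <- c(msg, "corr must be positive semi-definite")
  if (length(object@pHigh) != 1L || object@pHigh < 0 || object@pHigh > 1)
    msg <- c(msg, "pHigh must lie in [0, 1]")
  if (length(object@rho) != 1L || abs(object@rho) >= 1)
    msg <- c(msg, "|rho| must be < 1")
  if (length(msg)) msg else TRUE
})

#' GanConfig: hyper-parameters of the conditional GAN
#'
#' @slot noiseDim Dimension of the generator's Gaussian noise input.
#' @slot genWidths,discWidths Hidden-layer widths of generator/discriminator.
#' @slot epochs Full passes over the real dataset.
#' @slot batchSize Mini-batch size.
#' @slot lr Adam learning rate.
#' @slot beta1,beta2 Adam moment parameters.
#' @slot seed Integer governing parameter initialisation, noise draws and
#'   batch shuffling jointly.
#' @slot dSteps Discriminator updates per generator update.
#' @slot fidEvery Log a Frechet-distance probe every this many epochs
#'   (epoch 1 and the final epoch are always probed); 0 disables extra probes.
#' @seealso [GanConfig()], [trainCGAN()]
#' @export
setClass("GanConfig",
  representation(noiseDim = "integer", genWidths = "integer",
                 discWidths = "integer", epochs = "integer",
                 batchSize = "integer", lr = "numeric", beta1 = "numeric",
                 beta2 = "numeric", seed = "integer", dSteps = "integer",
                 fidEvery = "integer"))

setValidity("GanConfig", function(object) {
  msg <- character()
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@batchSize < 2L) msg <- c(msg, "batchSize must be >= 2")
  if (object@noiseDim < 1L) msg <- c(msg, "noiseDim must be >= 1")
  if (any(c(object@genWidths, object@discWidths) < 1L))
    msg <- c(msg, "all hidden widths must be >= 1")
  if (object@lr <= 0) msg <- c(msg, "lr must be positive")
  if (object@dSteps < 1L) msg <- c(msg, "dSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' GeneratorModel: a trained conditional generator
#'
#' Bundles the generator network parameters with the scaling transform fitted
#' on its training data and the one-hot class encoding
#' (high -> (1,0), low -> (0,1)), so sampling is self-contained. Sampling with
#' the same seed and count is reproducible bit-for-bit.
#'
#' @slot net Generator parameters (list of weight matrices and bias vectors).
#' @slot scaler The [ScalingTransform-class] fitted on the training data.
#' @slot labelLevels Order of classes in the one-hot encoding.
#' @slot config The [GanConfig-class] snapshot used for training.
#' @seealso [trainCGAN()], [sampleSynthetic()]
#' @export
setClass("GeneratorModel",
  representation(net = "list", scaler = "ScalingTransform",
                 labelLevels = "character", config = "GanConfig"))

#' Rule: a conjunction of interval conditions implying a class
#'
#' An if-then rule `if((cond) & (cond) & ...) then class`. Each condition is
#' an inequality on one predictor. Covering `C` is the fraction of records of
#' the rule's own class that satisfy the premise; error `r` is the fraction of
#' the opposite class that satisfies it. Both refer to the evaluation dataset
#' named in `evalTag` and are `NA` until scored.
#'
#' @slot premise `data.frame` with columns `feature`, `op`
#'   (one of `<, <=, >, >=`) and `threshold`.
#' @slot consequence `"low"` or `"high"`.
#' @slot covering,error,pvalue Numeric scalars, `NA` until computed.
#' @slot evalTag Name of the dataset `covering`/`error` were computed on.
#' @seealso [Rule()], [parseRule()], [coveringError()]
#' @export
setClass("Rule",
  representation(premise = "data.frame", consequence = "character",
                 covering = "numeric", error = "numeric", pvalue = "numeric",
                 evalTag = "character"))

setValidity("Rule", function(object) {
  pr <- object@premise
  msg <- character()
  if (nrow(pr) == 0L) msg <- c(msg, "premise must contain at least one condition")
  if (!all(c("feature", "op", "threshold") %in% colnames(pr)))
    return("premise needs columns feature, op, threshold")
  if (!all(pr$feature %in% predictorNames()))
    msg <- c(msg, paste0("premise may only use predictor features (never pef); got: ",
                         paste(setdiff(pr$feature, predictorNames()), collapse = ", ")))
  if (!all(pr$op %in% c("<", "<=", ">", ">=")))
    msg <- c(msg, "operators must be one of <, <=, >, >=")
  if (any(!is.finite(pr$threshold))) msg <- c(msg, "thresholds must be finite")
  for (f in unique(pr$feature)) {
    sub <- pr[pr$feature == f, ]
    lo <- sub$op %in% c(">", ">="); hi <- sub$op %in% c("<", "<=")
    if (sum(lo) > 1L || sum(hi) > 1L)
      msg <- c(msg, sprintf("feature '%s' has more than one bound in the same direction", f))
    if (sum(lo) == 1L && sum(hi) == 1L &&
        sub$threshold[lo] >= sub$threshold[hi])
      msg <- c(msg, sprintf("contradictory bounds on feature '%s'", f))
  }
  if (!object@consequence %in% .CLASS_LEVELS)
    msg <- c(msg, "consequence must be 'low' or 'high'")
  for (nm in c("covering", "error")) {
    v <- slot(object, nm)
    if (!is.na(v) && (v < 0 || v > 1)) msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
  }
  if (length(msg)) msg else TRUE
})

#' RuleSet: an ordered collection of rules with a default class
#'
#' The interpretable classifier: all rules whose premise a record satisfies
#' fire, and the predicted class maximises the sum of firing-rule weights
#' `C * (1 - r)`; records firing no rule (or on an exact tie) receive the
#' default class.
#'
#' @slot rules List of [Rule-class] objects (pairwise distinct).
#' @slot defaultClass Class assigned when no rule fires.
#' @slot provenance One of `"baseline"`, `"candidate_augmented"`,
#'   `"augmented"`, `"unspecified"`.
#' @seealso [induceRulesTree()], [induceRulesGreedy()], [predictClass()]
#' @export
setClass("RuleSet",
  representation(rules = "list", defaultClass = "character",
                 provenance = "character"))

setValidity("RuleSet", function(object) {
  msg <- character()
  if (!all(vapply(object@rules, is, logical(1), class2 = "Rule")))
    msg <- c(msg, "all elements of 'rules' must be Rule objects")
  else {
    keys <- vapply(object@rules, function(r) formatRule(r), character(1))
    if (anyDuplicated(keys)) msg <- c(msg, "rules must be pairwise distinct")
  }
  if (!object@defaultClass %in% .CLASS_LEVELS)
    msg <- c(msg, "defaultClass must be 'low' or 'high'")
  if (!object@provenance %in% c("baseline", "candidate_augmented", "augmented",
                                "unspecified"))
    msg <- c(msg, "invalid provenance tag")
  if (length(msg)) msg else TRUE
})

#' WorkflowResult: outcome of the augmentation validation workflow
#'
#' Holds the three rule sets of the baseline / candidate-augmented / augmented
#' procedure together with their quality metrics. The workflow is valid when
#' the augmented rule set (candidate rules that also pass Fisher's exact test
#' on the real data) is non-empty.
#'
#' @slot baseline,candidate,augmented [RuleSet-class] objects.
#' @slot metrics `data.frame` of per-model accuracy/F1/rule counts.
#' @slot valid Logical: is the augmented rule set non-empty?
#' @seealso [runAugmentationWorkflow()]
#' @export
setClass("WorkflowResult",
  representation(baseline = "RuleSet", candidate = "RuleSet",
                 augmented = "RuleSet", metrics = "data.frame",
                 valid = "logical"))
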