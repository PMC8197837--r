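#' Construct a rule
#'
#' @param premise `data.frame` with columns `feature`, `op`, `threshold`, or a
#'   list of such one-row frames / `c(feature=, op=, threshold=)` vectors.
#' @param consequence `"low"` or `"high"`.
#' @param covering,error,pvalue Optional statistics (see [Rule-class]).
#' @param evalTag Name of the dataset the statistics refer to.
#' @return A [Rule-class].
#' @examples
#' Rule(data.frame(feature = "fev1", op = "<", threshold = 2.23), "low")
#' @export
Rule <- function(premise, consequence, covering = NA_real_, error = NA_real_,
                 pvalue = NA_real_, evalTag = NA_character_) {
  if (is.list(premise) && !is.data.frame(premise))
    premise <- do.call(rbind, lapply(premise, as.data.frame))
  premise <- data.frame(feature = as.character(premise$feature),
                        op = as.character(premise$op),
                        threshold = as.numeric(premise$threshold))
  new("Rule", premise = premise, consequence = as.character(consequence),
      covering = covering, error = error, pvalue = pvalue, evalTag = evalTag)
}

#' Format a rule in the printable if-then syntax
#'
#' Serialises a rule as `if((feature op value) & ...)then class`, optionally
#' followed by `(C = ..%) (r = ..%) (p = ..)` annotations. The output is
#' parseable by [parseRule()].
#'
#' @param rule A [Rule-class].
#' @param annotate Append covering/error/p-value annotations when available.
#' @param digits Significant digits for thresholds.
#' @return A character scalar.
#' @export
formatRule <- function(rule, annotate = FALSE, digits = 6) {
  stopifnot(is(rule, "Rule"))
  conds <- sprintf("(%s%s%s)", rule@premise$feature, rule@premise$op,
                   format(signif(rule@premise$threshold, digits),
                          trim = TRUE, scientific = FALSE))
  out <- sprintf("if(%s)then %s", paste(conds, collapse = " & "),
                 rule@consequence)
  if (annotate) {
    ann <- character()
    if (!is.na(rule@covering))
      ann <- c(ann, sprintf("(C = %.3g%%)", 100 * rule@covering))
    if (!is.na(rule@error))
      ann <- c(ann, sprintf("(r = %.3g%%)", 100 * rule@error))
    if (!is.na(rule@pvalue))
      ann <- c(ann, sprintf("(p = %.3g)", rule@pvalue))
    if (length(ann)) out <- paste(out, paste(ann, collapse = " "))
  }
  out
}

#' Parse a rule from its printed syntax
#'
#' Accepts strings such as `"if((FEV1<2.23))then low"` or
#' `"if((heartrate<74) & (diastolicpressure>67))then high"`. Conditions are
#' joined by `&` or the AND symbol `∧`; operators `<`, `<=`, `>`, `>=`
#' are supported; feature names are matched case/space-insensitively and
#' normalised to the canonical schema identifiers. Trailing
#' `(C = ..%) (r/error = ..%) (p = ..)` annotations are parsed into the
#' corresponding slots when present.
#'
#' @param text A rule string.
#' @return A [Rule-class] (covering/error unset unless annotated).
#' @examples
#' parseRule("if((FEV1<2.23))then low")
#' @export
parseRule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("\\s+", "", text)
  s <- gsub("∧", "&", s)
  covering <- error <- pvalue <- NA_real_
  ann <- regmatches(s, gregexpr("\\((C|r|error|p)=[-0-9.eE+]+%?\\)", s))[[1]]
  for (a in ann) {
    key <- sub("^\\((C|r|error|p)=.*", "\\1", a)
    val <- as.numeric(gsub("[()%=Crerorp]", "", sub("^\\((C|r|error|p)=", "", a)))
    if (grepl("%", a)) val <- val / 100
    if (key == "C") covering <- val
    else if (key %in% c("r", "error")) error <- val
    else pvalue <- val
    s <- sub(a, "", s, fixed = TRUE)
  }
  m <- regexec("^if\\((.*)\\)then([A-Za-z]+)$", s)
  parts <- regmatches(s, m)[[1]]
  if (length(parts) != 3L)
    stop("malformed rule (expected 'if((cond)&(cond))then class'): ", text)
  cls <- tolower(parts[3])
  if (!cls %in% .CLASS_LEVELS)
    stop("unknown consequence class '", parts[3], "' in: ", text)
  condStr <- strsplit(parts[2], ")&(", fixed = TRUE)[[1]]
  condStr <- gsub("^\\(|\\)$", "", condStr)
  conds <- lapply(seq_along(condStr), function(i) {
    cm <- regexec("^([A-Za-z0-9_]+)(<=|>=|<|>)(-?[0-9.]+(?:[eE][-+]?[0-9]+)?)$",
                  condStr[i])
    cp <- regmatches(condStr[i], cm)[[1]]
    if (length(cp) != 4L)
      stop("malformed condition ", i, " ('", condStr[i], "') in: ", text)
    feat <- .normalizeName(cp[2])
    if (is.na(feat) || !feat %in% predictorNames())
      stop("unknown predictor '", cp[2], "' in condition ", i, " of: ", text)
    data.frame(feature = feat, op = cp[3], threshold = as.numeric(cp[4]))
  })
  Rule(do.call(rbind, conds), cls, covering = covering, error = error,
       pvalue = pvalue)
}

setMethod("show", "Rule", function(object) {
  cat(formatRule(object, annotate = TRUE), "\n")
})

## Logical vector: which records satisfy the premise.
.ruleFires <- function(rule, m) {
  fires <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(rule@premise))) {
    x <- m[, rule@premise$feature[i]]
    t <- rule@premise$threshold[i]
    fires <- fires & switch(rule@premise$op[i],
                            "<" = x < t, "<=" = x <= t,
                            ">" = x > t, ">=" = x >= t)
  }
  fires
}

#' Covering and error of a rule on a dataset
#'
#' Covering `C` is the fraction of records of the rule's consequence class
#' whose features satisfy the premise; error `r` is the fraction of records of
#' the opposite class satisfying it. Both are class-conditional proportions.
#'
#' @param rule A [Rule-class].
#' @param D A [VitalsCohort-class] containing at least one record of the
#'   rule's consequence class.
#' @return Named numeric vector `c(C = ..., r = ...)`.
#' @examples
#' co <- simulateCohort(43, seed = 7)
#' coveringError(parseRule("if((FEV1<2.3))then low"), co)
#' @export
coveringError <- function(rule, D) {
  stopifnot(is(rule, "Rule"), is(D, "VitalsCohort"))
  m <- featureMatrix(D)
  lab <- as.character(classLabels(D))
  inCls <- lab == rule@consequence
  if (!any(inCls))
    stop("consequence class '", rule@consequence, "' absent from the dataset")
  fires <- .ruleFires(rule, m)
  C <- mean(fires[inCls])
  r <- if (any(!inCls)) mean(fires[!inCls]) else 0
  c(C = C, r = r)
}

#' Score every rule of a set on a dataset
#'
#' Recomputes covering and error of each rule with [coveringError()] and
#' stamps the evaluation tag. Existing p-values are cleared (they refer to the
#' previous dataset).
#'
#' @param rs A [RuleSet-class].
#' @param D A [VitalsCohort-class].
#' @param tag Label recorded in each rule's `evalTag`.
#' @return The rescored [RuleSet-class].
#' @export
scoreRules <- function(rs, D, tag = cohortProvenance(D)) {
  stopifnot(is(rs, "RuleSet"))
  rs@rules <- lapply(rs@rules, function(r) {
    cr <- coveringError(r, D)
    r@covering <- unname(cr["C"]); r@error <- unname(cr["r"])
    r@pvalue <- NA_real_; r@evalTag <- tag
    r
  })
  rs
}

#' Construct a rule set
#'
#' @param rules List of [Rule-class] objects.
#' @param defaultClass Class predicted when no rule fires.
#' @param provenance Workflow stage tag (see [RuleSet-class]).
#' @return A [RuleSet-class].
#' @export
RuleSet <- function(rules = list(), defaultClass = "low",
                    provenance = "unspecified") {
  new("RuleSet", rules = rules, defaultClass = defaultClass,
      provenance = provenance)
}

#' RuleSet accessors
#'
#' @param rs A [RuleSet-class].
#' @return `rules()`: the list of [Rule-class] objects; `nRules()`: their
#'   count; `defaultClass()`: the fallback class.
#' @export
rules <- function(rs) { stopifnot(is(rs, "RuleSet")); rs@rules }

#' @rdname rules
#' @export
nRules <- function(rs) length(rules(rs))

#' @rdname rules
#' @export
defaultClass <- function(rs) { stopifnot(is(rs, "RuleSet")); rs@defaultClass }

setMethod("show", "RuleSet", function(object) {
  cat(sprintf("RuleSet (%s): %d rule(s), default class '%s'\n",
              object@provenance, nRules(object), object@defaultClass))
  for (r in object@rules) cat(" ", formatRule(r, annotate = TRUE), "\n")
})

#' Classify records with a rule set
#'
#' Every rule whose premise a record satisfies fires; the predicted class
#' maximises the sum of firing-rule weights `C * (1 - r)`. Records firing no
#' rule, or producing an exact weight tie, receive the default class. All
#' rules must be scored (non-`NA` covering/error) first.
#'
#' @param rs A [RuleSet-class].
#' @param D A [VitalsCohort-class] or records-by-predictors matrix.
#' @return Factor of predicted classes with levels `c("low", "high")`.
#' @export
predictClass <- function(rs, D) {
  stopifnot(is(rs, "RuleSet"))
  m <- .featmat(D)
  if (nRules(rs) == 0L)
    return(factor(rep(rs@defaultClass, nrow(m)), levels = .CLASS_LEVELS))
  w <- vapply(rs@rules, function(r) {
    if (is.na(r@covering) || is.na(r@error))
      stop("rules must be scored (covering/error set) before classification; ",
           "see scoreRules()")
    r@covering * (1 - r@error)
  }, numeric(1))
  cls <- vapply(rs@rules, function(r) r@consequence, character(1))
  fires <- vapply(rs@rules, function(r) .ruleFires(r, m),
                  logical(nrow(m)))
  fires <- matrix(fires, nrow = nrow(m))
  wLow <- as.numeric(fires %*% (w * (cls == "low")))
  wHigh <- as.numeric(fires %*% (w * (cls == "high")))
  pred <- ifelse(wHigh > wLow, "high", ifelse(wLow > wHigh, "low",
                                              rs@defaultClass))
  factor(pred, levels = .CLASS_LEVELS)
}

## ---- decision-tree rule induction -----------------------------------------

.gini <- function(lab) {
  p <- mean(lab == "high")
  2 * p * (1 - p)
}

## Deterministic CART-style binary tree on Gini impurity. Candidate
## thresholds are midpoints of consecutive distinct feature values; splits
## send x < t left and x >= t right. The best split maximises the impurity
## decrease; ties (including zero gain, which arises on parity-style
## interactions) are broken toward the lowest feature index, then the lowest
## threshold, and impure nodes are split even at zero gain so that e.g. an
## XOR pattern is recoverable at depth 2.
.treeGrow <- function(m, lab, idx, depth, maxDepth, minLeaf, defaultCls) {
  makeLeaf <- function() {
    tab <- table(factor(lab[idx], levels = .CLASS_LEVELS))
    cls <- if (tab[["high"]] > tab[["low"]]) "high"
           else if (tab[["low"]] > tab[["high"]]) "low" else defaultCls
    list(leaf = TRUE, class = cls)
  }
  if (depth >= maxDepth || length(idx) < 2L * minLeaf ||
      .gini(lab[idx]) == 0) return(makeLeaf())
  best <- NULL
  nIdx <- length(idx)
  parentImp <- .gini(lab[idx]) * nIdx
  totHigh <- sum(lab[idx] == "high")
  for (j in seq_len(ncol(m))) {
    x <- m[idx, j]
    ord <- order(x)
    xs <- x[ord]
    ys <- lab[idx][ord] == "high"
    ## split points between distinct consecutive values, in O(n log n)
    cut <- which(xs[-nIdx] < xs[-1L])
    if (!length(cut)) next
    nl <- cut
    nr <- nIdx - nl
    ok <- nl >= minLeaf & nr >= minLeaf
    if (!any(ok)) next
    cut <- cut[ok]; nl <- nl[ok]; nr <- nr[ok]
    hl <- cumsum(ys)[cut]
    hr <- totHigh - hl
    pl <- hl / nl; pr <- hr / nr
    gain <- parentImp - nl * 2 * pl * (1 - pl) - nr * 2 * pr * (1 - pr)
    b <- which.max(gain)  # first maximum = lowest threshold on ties
    if (is.null(best) || gain[b] > best$gain + 1e-12) {
      t <- (xs[cut[b]] + xs[cut[b] + 1L]) / 2
      best <- list(gain = gain[b], j = j, t = t, left = x < t)
    }
  }
  if (is.null(best)) return(makeLeaf())
  list(leaf = FALSE, feature = colnames(m)[best$j], threshold = best$t,
       left = .treeGrow(m, lab, idx[best$left], depth + 1L, maxDepth, minLeaf,
                        defaultCls),
       right = .treeGrow(m, lab, idx[!best$left], depth + 1L, maxDepth,
                         minLeaf, defaultCls))
}

## Collect root-to-leaf paths as (feature, op, threshold) condition lists.
.treePaths <- function(node, path = list()) {
  if (node$leaf) return(list(list(path = path, class = node$class)))
  c(.treePaths(node$left, c(path, list(list(feature = node$feature, op = "<",
                                            threshold = node$threshold)))),
    .treePaths(node$right, c(path, list(list(feature = node$feature,
                                             op = ">=",
                                             threshold = node$threshold)))))
}

## Per feature keep only the tightest bound in each direction.
.mergeBounds <- function(conds) {
  df <- do.call(rbind, lapply(conds, as.data.frame))
  out <- list()
  for (f in unique(df$feature)) {
    sub <- df[df$feature == f, ]
    up <- sub[sub$op %in% c("<", "<="), ]
    lo <- sub[sub$op %in% c(">", ">="), ]
    if (nrow(up)) out[[length(out) + 1L]] <- up[which.min(up$threshold), ]
    if (nrow(lo)) out[[length(out) + 1L]] <- lo[which.max(lo$threshold), ]
  }
  do.call(rbind, out)
}

#' Induce rules from a classification tree
#'
#' Fits a binary classification tree (Gini criterion, axis-aligned threshold
#' splits, deterministic tie-breaks: lowest feature index, then lowest
#' threshold) and converts each leaf's root-to-leaf path into one rule whose
#' consequence is the leaf's majority class (ties fall to the dataset's
#' majority class). Redundant bounds on the same feature are merged, and
#' covering/error of every rule are computed on `D`.
#'
#' @param D A [VitalsCohort-class] with both classes present and
#'   `n >= 2 * minLeaf`.
#' @param maxDepth Maximum tree depth (>= 1).
#' @param minLeaf Minimum records per leaf.
#' @return A [RuleSet-class] whose default class is the majority class of `D`.
#' @examples
#' co <- simulateCohort(43, seed = 7)
#' induceRulesTree(co, maxDepth = 2, minLeaf = 3)
#' @export
induceRulesTree <- function(D, maxDepth = 2L, minLeaf = 2L) {
  stopifnot(is(D, "VitalsCohort"))
  if (maxDepth < 1L) stop("'maxDepth' must be >= 1")
  lab <- as.character(classLabels(D))
  if (length(unique(lab)) < 2L)
    stop("both classes must be present to induce rules")
  if (length(lab) < 2L * minLeaf)
    stop("need at least 2 * minLeaf records")
  m <- featureMatrix(D)
  defaultCls <- if (sum(lab == "high") > sum(lab == "low")) "high" else "low"
  tree <- .treeGrow(m, lab, seq_along(lab), 0L, maxDepth, minLeaf, defaultCls)
  if (tree$leaf)
    stop("the tree did not split (degenerate features?)")
  ruleList <- lapply(.treePaths(tree), function(p) {
    Rule(.mergeBounds(p$path), p$class)
  })
  rs <- RuleSet(ruleList, defaultClass = defaultCls)
  scoreRules(rs, D, tag = cohortProvenance(D))
}

## ---- greedy discretised rule induction ------------------------------------

#' Induce rules by greedy covering on discretised features
#'
#' A rule learner in the spirit of clustering-based logic extraction: each
#' predictor is discretised into `qBins` equal-frequency intervals, and for
#' each class a premise is grown greedily - at every step the single
#' interval-condition (a contiguous union of bins on one unconstrained
#' feature) that maximises covering of the still-uncovered class records,
#' subject to class-conditional error `<= maxError` and at most
#' `maxConditions` conditions, is added. Interval bounds are emitted as
#' `>` / `<=` threshold conditions. Accepted rules remove the class records
#' they cover; induction for a class stops when no rule with positive
#' coverage gain and admissible error exists. `qBins` and `maxError` realise
#' the precision-versus-generalisation trade-off: finer bins and a smaller
#' admissible error give more, narrower rules.
#'
#' @param D A [VitalsCohort-class] with both classes present.
#' @param qBins Number of equal-frequency bins per feature (>= 2).
#' @param maxConditions Maximum number of interval conditions per rule.
#' @param maxError Largest admissible class-conditional error of a rule.
#' @return A [RuleSet-class]; empty (with a warning) when no rule satisfies
#'   `maxError`.
#' @export
induceRulesGreedy <- function(D, qBins = 4L, maxConditions = 3L,
                              maxError = 0.1) {
  stopifnot(is(D, "VitalsCohort"))
  if (qBins < 2L) stop("'qBins' must be >= 2")
  lab <- as.character(classLabels(D))
  if (length(unique(lab)) < 2L)
    stop("both classes must be present to induce rules")
  m <- featureMatrix(D)
  n <- nrow(m)
  ## interior equal-frequency cut points per feature
  cuts <- lapply(seq_len(ncol(m)), function(j) {
    q <- unique(quantile(m[, j], probs = seq(0, 1, length.out = qBins + 1L),
                         names = FALSE, type = 7))
    q <- q[-c(1L, length(q))]
    q
  })
  ## candidate interval conditions: (lo, hi] unions of contiguous bins,
  ## excluding the vacuous full range; ordered by start then end
  cands <- list()
  for (j in seq_len(ncol(m))) {
    edges <- c(-Inf, cuts[[j]], Inf)
    k <- length(edges) - 1L
    if (k < 2L) next
    for (i in seq_len(k)) for (jj in i:k) {
      if (i == 1L && jj == k) next
      cands[[length(cands) + 1L]] <-
        list(j = j, lo = edges[i], hi = edges[jj + 1L],
             fires = m[, j] > edges[i] & m[, j] <= edges[jj + 1L])
    }
  }
  defaultCls <- if (sum(lab == "high") > sum(lab == "low")) "high" else "low"
  ruleList <- list()
  for (cls in .CLASS_LEVELS) {
    other <- lab != cls
    uncovered <- which(lab == cls)
    repeat {
      fires <- rep(TRUE, n)
      used <- integer(0)
      sel <- list()
      repeat {
        if (length(sel) >= maxConditions) break
        best <- NULL
        for (ci in seq_along(cands)) {
          cand <- cands[[ci]]
          if (cand$j %in% used) next
          nf <- fires & cand$fires
          gain <- sum(nf[uncovered])
          if (gain == 0L) next
          r <- if (any(other)) mean(nf[other]) else 0
          feasible <- r <= maxError
          ## prefer feasible candidates by gain; otherwise reduce error
          key <- c(feasible, if (feasible) gain else -r)
          if (is.null(best) ||
              (key[1] > best$key[1]) ||
              (key[1] == best$key[1] && key[2] > best$key[2] + 1e-12)) {
            best <- list(key = key, ci = ci, fires = nf, r = r, gain = gain)
          }
        }
        if (is.null(best)) break
        sel[[length(sel) + 1L]] <- cands[[best$ci]]
        used <- c(used, cands[[best$ci]]$j)
        fires <- best$fires
        if (best$r <= maxError) break  # admissible rule reached
      }
      if (!length(sel)) break
      rFinal <- if (any(other)) mean(fires[other]) else 0
      gFinal <- sum(fires[uncovered])
      if (rFinal > maxError || gFinal == 0L) break
      conds <- list()
      for (s in sel) {
        f <- colnames(m)[s$j]
        if (is.finite(s$lo))
          conds[[length(conds) + 1L]] <- list(feature = f, op = ">",
                                              threshold = s$lo)
        if (is.finite(s$hi))
          conds[[length(conds) + 1L]] <- list(feature = f, op = "<=",
                                              threshold = s$hi)
      }
      ruleList[[length(ruleList) + 1L]] <- Rule(.mergeBounds(conds), cls)
      uncovered <- uncovered[!fires[uncovered]]
      if (!length(uncovered)) break
    }
  }
  ## drop exact duplicates (possible when both classes stall on one premise)
  if (length(ruleList)) {
    keys <- vapply(ruleList, formatRule, character(1))
    ruleList <- ruleList[!duplicated(keys)]
  }
  if (!length(ruleList))
    warning("no rule satisfies maxError = ", maxError,
            "; returning an empty rule set")
  rs <- RuleSet(ruleList, defaultClass = defaultCls)
  if (nRules(rs)) rs <- scoreRules(rs, D, tag = cohortProvenance(D))
  rs
}
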