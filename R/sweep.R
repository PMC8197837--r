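#' Epoch sweep: train, sample, score and validate at several epoch counts
#'
#' For each epoch count (and replicate seed) the sweep trains a conditional
#' GAN from scratch on `real`, samples `nSynth` synthetic records at the real
#' class mix, computes the three quality scores (JS real-vs-fake, JS between
#' the synthetic classes, Frechet distance real-vs-fake), runs the
#' baseline / candidate / augmented validation workflow, and emits one report
#' row. A failed setting is recorded as a row with `NA` metrics and the error
#' message in `note`, not as a crash of the sweep.
#'
#' The returned table carries two attributes: `recommended_epochs`, the
#' FID-minimising setting (the Frechet distance is used as the selection
#' criterion because it tracks downstream rule quality), and
#' `fid_accuracy_spearman`, the rank correlation between FID and real-data
#' accuracy across rows, so the claimed alignment between the two can be
#' inspected on any run.
#'
#' @param real A [VitalsCohort-class].
#' @param epochList Integer vector of epoch counts (non-empty).
#' @param config Base [GanConfig-class]; its `epochs` and `seed` are
#'   overridden per row.
#' @param nSynth Synthetic sample size per row (default 1000).
#' @param classMix Proportion of class `"high"` among synthetic records;
#'   `NULL` uses the real-data prevalence.
#' @param seed Base seed; each (epoch, replicate) derives its own seed from it.
#' @param replicates Number of independent replicate runs per epoch count
#'   whose metrics are averaged (GAN training on tiny datasets is
#'   high-variance).
#' @param inducer,alpha,... Passed to [runAugmentationWorkflow()].
#' @return `data.frame` with columns `epochs`, `js_real_fake`,
#'   `js_between_classes`, `fid`, `rules_accepted_fet` (augmented model on
#'   real data), `accuracy`, `f1` (augmented model on real data),
#'   `accuracy_candidate_synth`, `f1_candidate_synth`, `seed`, `note`.
#' @examples
#' \donttest{
#' real <- simulateCohort(43, seed = 7)
#' rep <- epochSweep(real, c(100, 500), nSynth = 200, seed = 1)
#' attr(rep, "recommended_epochs")
#' }
#' @export
epochSweep <- function(real, epochList, config = GanConfig(), nSynth = 1000L,
                       classMix = NULL, seed = 1L, replicates = 1L,
                       inducer = "tree", alpha = 0.05, ...) {
  stopifnot(is(real, "VitalsCohort"), length(epochList) >= 1L)
  if (is.null(classMix)) classMix <- mean(classLabels(real) == "high")
  oneRun <- function(ep, runSeed) {
    cfg <- config
    cfg@epochs <- as.integer(ep)
    cfg@seed <- as.integer(runSeed)
    fit <- trainCGAN(real, cfg)
    synth <- sampleSynthetic(fit$model, nSynth, classMix, seed = runSeed + 1L)
    wf <- runAugmentationWorkflow(real, synth, inducer = inducer,
                                  alpha = alpha, ...)
    met <- workflowMetrics(wf)
    aug <- met[met$model == "augmented" & met$data == "real", ]
    cand <- met[met$model == "candidate_augmented" & met$data == "synthetic", ]
    c(js_real_fake = jsDivergence(real, synth),
      js_between_classes = jsBetweenClasses(synth),
      fid = fidScore(real, synth),
      rules_accepted_fet = aug$n_rules,
      accuracy = aug$accuracy, f1 = aug$f1,
      accuracy_candidate_synth = cand$accuracy,
      f1_candidate_synth = cand$f1)
  }
  rows <- lapply(seq_along(epochList), function(i) {
    ep <- epochList[i]
    reps <- lapply(seq_len(replicates), function(k) {
      runSeed <- seed + 1000L * i + k
      tryCatch(list(val = oneRun(ep, runSeed), note = ""),
               error = function(e) list(val = NULL, note = conditionMessage(e)))
    })
    ok <- !vapply(reps, function(r) is.null(r$val), logical(1))
    if (!any(ok)) {
      vals <- rep(NA_real_, 8)
      names(vals) <- c("js_real_fake", "js_between_classes", "fid",
                       "rules_accepted_fet", "accuracy", "f1",
                       "accuracy_candidate_synth", "f1_candidate_synth")
      note <- paste(unique(vapply(reps, `[[`, character(1), "note")),
                    collapse = "; ")
    } else {
      vals <- colMeans(do.call(rbind, lapply(reps[ok], `[[`, "val")))
      note <- if (all(ok)) "" else
        sprintf("%d/%d replicate(s) failed", sum(!ok), replicates)
    }
    data.frame(epochs = ep, t(vals), seed = seed, note = note)
  })
  out <- do.call(rbind, rows)
  finite <- is.finite(out$fid)
  attr(out, "recommended_epochs") <-
    if (any(finite)) out$epochs[finite][which.min(out$fid[finite])] else NA
  attr(out, "fid_accuracy_spearman") <-
    if (sum(finite) >= 2L)
      suppressWarnings(cor(out$fid[finite], out$accuracy[finite],
                           method = "spearman"))
    else NA_real_
  out
}

#' Write / format a quality report
#'
#' `writeQualityReport()` serialises a sweep table (plus its recommended
#' setting and FID-accuracy rank correlation) to JSON;
#' `formatQualityTable()` renders an aligned text table in the column order
#' epochs | JS real-fake | JS between classes | FID | rules accepted by FET |
#' accuracy | F1.
#'
#' @param report A sweep `data.frame` from [epochSweep()].
#' @param path Output JSON path.
#' @return `writeQualityReport()`: `path`, invisibly.
#'   `formatQualityTable()`: character vector of table lines.
#' @export
writeQualityReport <- function(report, path) {
  payload <- list(
    rows = report,
    recommended_epochs = attr(report, "recommended_epochs"),
    fid_accuracy_spearman = attr(report, "fid_accuracy_spearman"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeQualityReport
#' @export
formatQualityTable <- function(report) {
  cols <- c("epochs", "js_real_fake", "js_between_classes", "fid",
            "rules_accepted_fet", "accuracy", "f1")
  hdr <- c("Epochs", "JS Real-Fake", "JS between Classes", "FID",
           "Rules Accepted by FET", "Accuracy", "F1 Score")
  body <- vapply(cols, function(cc) {
    v <- report[[cc]]
    if (is.numeric(v)) formatC(v, digits = 4, format = "g") else as.character(v)
  }, character(nrow(report)))
  body <- matrix(body, nrow = nrow(report))
  w <- pmax(nchar(hdr), apply(nchar(body), 2, max))
  pad <- function(x, w) formatC(x, width = w)
  lines <- c(paste(mapply(pad, hdr, w), collapse = "  "),
             apply(body, 1, function(r)
               paste(mapply(pad, r, w), collapse = "  ")))
  rec <- attr(report, "recommended_epochs")
  if (!is.null(rec) && !is.na(rec))
    lines <- c(lines, sprintf("recommended (min FID): %s epochs", rec))
  lines
}
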