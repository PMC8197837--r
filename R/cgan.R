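#' Conditional GAN configuration
#'
#' Hyper-parameters for [trainCGAN()]. Defaults are sized for the tiny-n,
#' 10-feature regime this package targets: compact two-hidden-layer MLPs for
#' both networks, Adam with learning rate 2e-4 and moment parameters
#' (0.5, 0.999), batch size 16, one discriminator update per generator update.
#'
#' @param epochs Full passes over the real dataset (>= 1).
#' @param noiseDim Generator noise dimension.
#' @param genWidths,discWidths Integer vectors of hidden-layer widths.
#' @param batchSize Mini-batch size (>= 2).
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment parameters.
#' @param seed Seed governing parameter initialisation, noise draws and batch
#'   shuffling jointly; two runs with identical data, config and seed produce
#'   identical generators.
#' @param dSteps Discriminator updates per generator update.
#' @param fidEvery Probe the Frechet distance of a synthetic sample against
#'   the training data every `fidEvery` epochs (epoch 1 and the final epoch
#'   are always probed); 0 probes only those two.
#' @return A [GanConfig-class].
#' @export
GanConfig <- function(epochs = 2000L, noiseDim = 32L,
                      genWidths = c(64L, 64L), discWidths = c(64L, 64L),
                      batchSize = 16L, lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                      seed = 1L, dSteps = 1L, fidEvery = 0L) {
  new("GanConfig", noiseDim = as.integer(noiseDim),
      genWidths = as.integer(genWidths), discWidths = as.integer(discWidths),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      lr = lr, beta1 = beta1, beta2 = beta2, seed = as.integer(seed),
      dSteps = as.integer(dSteps), fidEvery = as.integer(fidEvery))
}

setMethod("show", "GanConfig", function(object) {
  cat(sprintf(
    "GanConfig: %d epochs, noise %d, G[%s], D[%s], batch %d, lr %g, seed %d\n",
    object@epochs, object@noiseDim, paste(object@genWidths, collapse = ","),
    paste(object@discWidths, collapse = ","), object@batchSize, object@lr,
    object@seed))
})

## One-hot encoding of classes: high -> (1,0), low -> (0,1).
.ONEHOT_LEVELS <- c("high", "low")

.oneHot <- function(labels) {
  idx <- match(as.character(labels), .ONEHOT_LEVELS)
  out <- matrix(0, length(idx), 2L)
  out[cbind(seq_along(idx), idx)] <- 1
  out
}

#' Train a class-conditional GAN on a labeled cohort
#'
#' Adversarial training of a generator/discriminator pair on the 10 predictor
#' features, each network conditioned on the record's one-hot class. Features
#' are min-max scaled to `[0, 1]` internally (the generator's output
#' activation is a sigmoid, so samples respect the training envelope). Per
#' mini-batch: (i) a discriminator step on real records with their true labels
#' (target real) and generator samples with their conditioning labels (target
#' fake), binary cross-entropy from logits; (ii) a generator step maximising
#' the discriminator's real-belief on fresh samples, backpropagating through
#' the frozen discriminator. One epoch is one full pass over the real dataset.
#'
#' @param real A [VitalsCohort-class] with at least 2 records per class.
#' @param config A [GanConfig-class].
#' @return A list with elements `model` (a [GeneratorModel-class]) and `log`
#'   (a `data.frame` with one row per epoch: `epoch`, `d_loss`, `g_loss`,
#'   `fid` - `NA` on epochs without a probe).
#' @examples
#' co <- simulateCohort(43, seed = 7)
#' fit <- trainCGAN(co, GanConfig(epochs = 5, seed = 1))
#' head(fit$log)
#' @export
trainCGAN <- function(real, config = GanConfig()) {
  stopifnot(is(real, "VitalsCohort"), is(config, "GanConfig"))
  validObject(config)
  labels <- classLabels(real)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("each class needs at least 2 records; got low=", tab[["low"]],
         " high=", tab[["high"]])
  scaler <- fitScaler(real)
  X <- applyScaler(featureMatrix(real), scaler)
  Y <- .oneHot(labels)
  n <- nrow(X); nf <- ncol(X)
  cfg <- config
  .withSeed(cfg@seed, {
    G <- .nnInit(c(cfg@noiseDim + 2L, cfg@genWidths, nf))
    D <- .nnInit(c(nf + 2L, cfg@discWidths, 1L))
    sG <- .adamInit(G); sD <- .adamInit(D)
    log <- data.frame(epoch = seq_len(cfg@epochs), d_loss = NA_real_,
                      g_loss = NA_real_, fid = NA_real_)
    for (ep in seq_len(cfg@epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = cfg@batchSize)
      dl <- gl <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg@batchSize - 1L, n)]
        b <- length(idx)
        xb <- X[idx, , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        for (k in seq_len(cfg@dSteps)) {
          z <- matrix(rnorm(b * cfg@noiseDim), b)
          fake <- .nnForward(G, cbind(z, yb), out = "sigmoid")$out
          din <- rbind(cbind(xb, yb), cbind(fake, yb))
          tgt <- c(rep(1, b), rep(0, b))
          fwD <- .nnForward(D, din, out = "linear")
          dZ <- matrix((.sigmoid(fwD$out) - tgt) / (2 * b), ncol = 1L)
          gD <- .nnBackward(D, fwD, dZ)
          up <- .adamStep(D, gD, sD, cfg@lr, cfg@beta1, cfg@beta2)
          D <- up$net; sD <- up$state
          dLoss <- .bceFromLogits(fwD$out, tgt)
        }
        z <- matrix(rnorm(b * cfg@noiseDim), b)
        fwG <- .nnForward(G, cbind(z, yb), out = "sigmoid")
        fwD <- .nnForward(D, cbind(fwG$out, yb), out = "linear")
        dZ <- matrix((.sigmoid(fwD$out) - 1) / b, ncol = 1L)
        bD <- .nnBackward(D, fwD, dZ)
        dFake <- bD$dX[, seq_len(nf), drop = FALSE]
        dZg <- dFake * fwG$out * (1 - fwG$out)  # sigmoid output layer
        gG <- .nnBackward(G, fwG, dZg)
        up <- .adamStep(G, gG, sG, cfg@lr, cfg@beta1, cfg@beta2)
        G <- up$net; sG <- up$state
        gLoss <- .bceFromLogits(fwD$out, rep(1, b))
        if (!is.finite(dLoss) || !is.finite(gLoss))
          stop(sprintf("non-finite loss at epoch %d (d=%.3g, g=%.3g); ",
                       ep, dLoss, gLoss),
               "try a lower learning rate or a larger batch")
        dl <- dl + dLoss * b; gl <- gl + gLoss * b
      }
      log$d_loss[ep] <- dl / n
      log$g_loss[ep] <- gl / n
      if (ep == 1L || ep == cfg@epochs ||
          (cfg@fidEvery > 0L && ep %% cfg@fidEvery == 0L)) {
        z <- matrix(rnorm(n * cfg@noiseDim), n)
        probe <- .nnForward(G, cbind(z, Y), out = "sigmoid")$out
        colnames(probe) <- colnames(X)
        log$fid[ep] <- fidScore(featureMatrix(real), invertScaler(probe, scaler))
      }
    }
    model <- new("GeneratorModel", net = G, scaler = scaler,
                 labelLevels = .ONEHOT_LEVELS, config = cfg)
    list(model = model, log = log)
  })
}

setMethod("show", "GeneratorModel", function(object) {
  cat(sprintf("GeneratorModel: noise %d + one-hot class -> %d features (%s)\n",
              object@config@noiseDim, length(object@scaler@min),
              paste(object@config@genWidths, collapse = "-")))
  cat(sprintf("  trained %d epochs, seed %d\n", object@config@epochs,
              object@config@seed))
})

#' Sample synthetic records from a trained generator
#'
#' Draws `round(n * classMix)` records conditioned on class `"high"` and the
#' rest conditioned on `"low"`, inverse-scales the generator output back to
#' physical units, and labels each record with its conditioning class.
#'
#' @param model A [GeneratorModel-class] from [trainCGAN()].
#' @param n Number of records to draw (> 0).
#' @param classMix Proportion of records conditioned on class `"high"`.
#' @param seed Optional seed; the same model, `n`, `classMix` and seed yield
#'   an identical sample.
#' @return A [VitalsCohort-class] with provenance `"synthetic"`.
#' @examples
#' co <- simulateCohort(43, seed = 7)
#' fit <- trainCGAN(co, GanConfig(epochs = 5))
#' synth <- sampleSynthetic(fit$model, 100, classMix = 0.5, seed = 2)
#' @export
sampleSynthetic <- function(model, n, classMix = 0.5, seed = NULL) {
  stopifnot(is(model, "GeneratorModel"))
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("'n' must be a positive count")
  if (classMix < 0 || classMix > 1) stop("'classMix' must lie in [0, 1]")
  n <- as.integer(n)
  nHigh <- as.integer(round(n * classMix))
  labels <- factor(c(rep("high", nHigh), rep("low", n - nHigh)),
                   levels = .CLASS_LEVELS)
  .withSeed(seed, {
    z <- matrix(rnorm(n * model@config@noiseDim), n)
    out <- .nnForward(model@net, cbind(z, .oneHot(labels)), out = "sigmoid")$out
    colnames(out) <- names(model@scaler@min)
    feats <- invertScaler(out, model@scaler)
    VitalsCohort(feats, labels = labels, provenance = "synthetic")
  })
}
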