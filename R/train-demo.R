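# A runnable, scaled-down segmentation demo: a width-reduced U-Net trained
# on small synthetic phantom slices with the built-in engine, following the
# subject-level k-fold protocol, with test predictions averaged over the
# fold models and thresholded at 0.5.

#' Generate a small synthetic training/test dataset
#'
#' Builds one phantom per subject (seeded geometry and lesion-size jitter:
#' core diameter uniform in 8-12 mm, penumbra 5 mm, center jittered up to
#' 2 px inside white matter), solves the bioheat equation once per subject,
#' and renders `slicesPerSubject` noisy grayscale slices per subject, each
#' paired with its penumbra ground-truth mask.
#'
#' @param nSubjects number of synthetic subjects.
#' @param slicesPerSubject noisy slices rendered per subject.
#' @param size square image size in pixels (divisible by 16), default 32.
#' @param spacing pixel size, mm.
#' @param noise Gaussian noise level fraction, default 0.05.
#' @param seed master seed; every per-subject and per-slice seed derives
#'   from it.
#' @param tol solver tolerance used for the per-subject fields.
#' @return List with `images` (list of matrices in [0, 1]), `masks` (binary
#'   matrices), `subjects` and `slices` (integer vectors).
#' @export
makeDemoDataset <- function(nSubjects = 10, slicesPerSubject = 3, size = 32,
                            spacing = 2, noise = 0.05, seed = 1,
                            tol = 1e-6) {
  stopifnot(size %% 16 == 0)
  jit <- withSeed(seed, matrix(runif(nSubjects * 3), nSubjects, 3))
  images <- list(); masks <- list(); subjects <- integer(); slices <- integer()
  cfg <- solverConfig(tol = tol)
  for (s in seq_len(nSubjects)) {
    ph <- generateBrainPhantom(size, size, spacing = spacing,
                               seed = seed + 17 * s)
    center <- c(round(ph@geometry$ci + (jit[s, 2] - 0.5) * 4),
                round(ph@geometry$cj + (jit[s, 3] - 0.5) * 4))
    les <- lesionSpec(center = center,
                      core_diameter = 8 + 4 * jit[s, 1],
                      penumbra_thickness = 5)
    ph <- embedLesion(ph, les)
    fld <- solveBioheat(ph, tissuePropertyTable(lesion = les), cfg = cfg)
    for (sl in seq_len(slicesPerSubject)) {
      img <- renderThermalImage(fld, ph, noise = noise,
                                seed = seed + 1000L * s + sl,
                                crop = c(size, size))
      images[[length(images) + 1L]] <- pixelMatrix(img)
      masks[[length(masks) + 1L]] <- imageMask(img)
      subjects <- c(subjects, s)
      slices <- c(slices, sl)
    }
  }
  list(images = images, masks = masks, subjects = subjects, slices = slices)
}

sumGrads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(a)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

scaleGrads <- function(g, f) {
  for (nm in names(g)) {
    g[[nm]]$W <- g[[nm]]$W * f
    g[[nm]]$b <- g[[nm]]$b * f
  }
  g
}

#' Train the width-reduced U-Net demo
#'
#' Trains one width-reduced U-Net per crossvalidation fold on the training
#' dataset (subject-level splits) with the built-in engine — Adam, soft-Dice
#' loss, dropout at the two deepest blocks — then predicts the test images
#' as the pixelwise average of the fold models' sigmoid outputs, thresholded
#' at 0.5. Fully seeded: fold splits, weight init, batch order and dropout
#' all derive from `seed`.
#'
#' @param train,test datasets from [makeDemoDataset()] (or the same list
#'   structure).
#' @param scaleFactor channel width multiplier relative to the full 64-wide
#'   network, default 1/16.
#' @param k number of crossvalidation folds, default 3.
#' @param cfg a [trainingConfig()]; the demo default uses 50 epochs, a 5e-3
#'   learning rate and batch size 4 — at a few hundred gradient steps the
#'   full-scale recipe (1e-4, batch 22, 100 epochs) barely moves the
#'   weights, so the step size is scaled up with the problem scaled down.
#' @param dropout_p dropout probability at encoder blocks 4 and 5.
#' @param seed master RNG seed.
#' @param verbose print per-epoch mean loss?
#' @return List with `foldLoss` (final-epoch mean training loss per fold),
#'   `predictions` (binary matrices for the test images), `probabilities`
#'   (averaged sigmoid outputs), `testDice` (mean per-image Dice),
#'   `baselineDice` (mean Dice of an all-positive prediction), `spec` (the
#'   width-reduced layer table) and `params` (per-fold trained weights).
#' @export
trainDemo <- function(train, test = NULL, scaleFactor = 1 / 16, k = 3,
                      cfg = trainingConfig(learning_rate = 5e-3,
                                           max_epochs = 50, batch_size = 4),
                      dropout_p = 0.5, seed = 1, verbose = FALSE) {
  d <- dim(train$images[[1]])
  if (d[1] != d[2]) stop("demo images must be square")
  spec <- buildUnetSpec(d[1], d[2], widthScale = scaleFactor)
  channels <- attr(spec, "channels")
  df <- data.frame(subject = train$subjects, idx = seq_along(train$images))
  folds <- kfoldSplit(df, k = k, seed = seed)
  models <- list(); foldLoss <- numeric(k)
  for (i in seq_len(k)) {
    trIdx <- folds[[i]]$train$idx
    params <- initUnetParams(channels, seed = seed + i,
                             weight_init_sd = cfg$weight_init_sd,
                             bias_init = cfg$bias_init)
    state <- adamInit(params)
    res <- withSeed(seed * 1000L + i, {
      lastLoss <- NA_real_
      for (ep in seq_len(cfg$max_epochs)) {
        ord <- sample(trIdx)
        losses <- numeric(0)
        for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
          batch <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
          acc <- NULL; bl <- 0
          for (ix in batch) {
            lg <- unetLossGrad(train$images[[ix]], train$masks[[ix]],
                               params, training = TRUE,
                               dropout_p = dropout_p, eps = cfg$dice_eps)
            acc <- sumGrads(acc, lg$grads)
            bl <- bl + lg$loss
          }
          acc <- scaleGrads(acc, 1 / length(batch))
          st <- adamStep(params, acc, state, lr = cfg$learning_rate)
          params <- st$params; state <- st$state
          losses <- c(losses, bl / length(batch))
        }
        lastLoss <- mean(losses)
        if (verbose)
          message(sprintf("fold %d epoch %d: mean dice loss %.4f",
                          i, ep, lastLoss))
      }
      list(params = params, loss = lastLoss)
    })
    models[[i]] <- res$params
    foldLoss[i] <- res$loss
  }
  out <- list(foldLoss = foldLoss, spec = spec, params = models)
  if (!is.null(test)) {
    probs <- lapply(test$images, function(img) {
      p <- 0
      for (i in seq_len(k))
        p <- p + unetForward(img, models[[i]], training = FALSE)$pred
      p / k
    })
    preds <- lapply(probs, function(p) (p >= 0.5) + 0)
    dice1 <- function(pred, truth)
      segmentationMetrics(confusionCounts(pred, truth))$values[["dice"]]
    out$probabilities <- probs
    out$predictions <- preds
    out$testDice <- mean(mapply(dice1, preds, test$masks))
    out$baselineDice <- mean(mapply(
      function(m) dice1(array(1, dim(m)), m), test$masks))
  }
  out
}
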