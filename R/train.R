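# Training, inference and evaluation with the reference protocol:
# Adam (default betas), learning rate 0.001, batch size 1, dropout 0.2,
# batch normalization, inverse-frequency weighted cross-entropy.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with default beta values,
#' initial learning rate 0.001, batch size 1, 100 epochs, dropout 0.2,
#' weighted cross-entropy loss. \code{maxSteps} optionally caps the total
#' number of optimization steps (for desk-scale runs); otherwise training
#' runs \code{epochs} full passes.
#'
#' @param learningRate positive learning rate.
#' @param epochs number of passes over the training set.
#' @param batchSize currently 1 (the protocol's value).
#' @param loss "weighted_ce", "ce" or "dice".
#' @param dropout dropout probability used at realization time.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param maxSteps optional cap on total steps (NULL = no cap).
#' @param freqScope "image" recomputes class frequencies per image at loss
#'   time; "dataset" uses frequencies pooled over the training set.
#' @param seed RNG seed covering shuffling and dropout.
#' @return a TrainConfig list.
#' @export
trainConfig <- function(learningRate = 0.001, epochs = 100L, batchSize = 1L,
                        loss = c("weighted_ce", "ce", "dice"),
                        dropout = 0.2, beta1 = 0.9, beta2 = 0.999,
                        epsilon = 1e-8, maxSteps = NULL,
                        freqScope = c("image", "dataset"), seed = 1L) {
  loss <- match.arg(loss)
  freqScope <- match.arg(freqScope)
  stopifnot(learningRate >= 0, epochs >= 1L, batchSize >= 1L)
  structure(list(learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), loss = loss,
                 dropout = dropout, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, maxSteps = maxSteps,
                 freqScope = freqScope, seed = as.integer(seed)),
            class = "TrainConfig")
}

adam_new <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(opt, net, grads, cfg) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- opt$m[[nm]]; v <- opt$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- cfg$beta1 * m + (1 - cfg$beta1) * g
    v <- cfg$beta2 * v + (1 - cfg$beta2) * g * g
    opt$m[[nm]] <- m; opt$v[[nm]] <- v
    net$params[[nm]] <- net$params[[nm]] -
      cfg$learningRate * (m / bc1) / (sqrt(v / bc2) + cfg$epsilon)
  }
}

# one forward/backward step; returns loss value and parameter gradients
loss_step <- function(rn, x, labels, cfg, freqs) {
  tp <- tape_new()
  hl <- net_forward(rn, x, training = TRUE, tape = tp)
  if (cfg$loss == "dice") {
    hp <- ad_softmax(tp, hl)
    fused <- dice_fused(tp_val(tp, hp), labels)
    seedNode <- hp
  } else {
    f <- if (cfg$loss == "weighted_ce") {
      if (is.null(freqs)) classFrequencies(labels,
                                           rn@spec@config@nClasses)
      else freqs
    } else NULL
    fused <- softmax_ce_fused(tp_val(tp, hl), labels, f)
    seedNode <- hl
  }
  bk <- tp_backward_seeded(tp, seedNode, fused$grad)
  list(value = fused$value, grads = bk)
}

tp_backward_seeded <- function(tp, node, seedGrad) {
  grads <- vector("list", length(tp$vals))
  grads[[node]] <- seedGrad
  for (op in rev(tp$ops)) {
    g <- grads[[op$out]]
    if (is.null(g)) next
    gs <- op$bw(g)
    for (j in seq_along(op$ins)) {
      gj <- gs[[j]]
      if (is.null(gj)) next
      id <- op$ins[j]
      grads[[id]] <- if (is.null(grads[[id]])) gj else grads[[id]] + gj
    }
    grads[op$out] <- list(NULL)
  }
  lapply(tp$pids, function(id) grads[[id]])
}

#' Train a realized network
#'
#' Batch-1 stochastic training with Adam under the reference protocol.
#' Shuffling, dropout and everything else downstream of \code{cfg$seed} is
#' deterministic in single-threaded CPU mode: the same seed reproduces the
#' same history. When validation data are supplied, the parameters of the
#' epoch with the best validation mean Dice index are restored into the
#' returned network (best-checkpoint selection).
#'
#' @param rn a [RealizedNetwork-class] (modified in place).
#' @param trainData list of samples, each a list with \code{image}
#'   (preprocessed matrix at the network's input side) and \code{labels}
#'   (binary mask of the same size).
#' @param cfg a [trainConfig()] list.
#' @param valData optional validation samples in the same format.
#' @param verbose print one line per epoch.
#' @return list with \code{network}, \code{history} (data.frame: epoch,
#'   trainLoss, valLoss, valMeanDI), \code{bestEpoch}, and
#'   \code{gradientTouched} (named logical: did each parameter ever receive
#'   a nonzero gradient).
#' @export
trainNetwork <- function(rn, trainData, cfg = trainConfig(),
                         valData = NULL, verbose = FALSE) {
  if (!length(trainData)) stop("empty training set")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  net <- rn@net
  opt <- adam_new()
  freqs <- NULL
  if (cfg$loss == "weighted_ce" && cfg$freqScope == "dataset") {
    all <- unlist(lapply(trainData, function(s) s$labels))
    freqs <- classFrequencies(matrix(all, ncol = 1),
                              rn@spec@config@nClasses)
  }
  touched <- stats::setNames(logical(length(net$params)),
                             names(net$params))
  stepsDone <- 0L
  hist <- list()
  bestDI <- -Inf; bestEpoch <- NA_integer_; bestParams <- NULL
  bestState <- NULL
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(trainData))
    losses <- numeric(0)
    for (i in ord) {
      if (!is.null(cfg$maxSteps) && stepsDone >= cfg$maxSteps) break
      s <- trainData[[i]]
      st <- loss_step(rn, s$image, s$labels, cfg, freqs)
      if (!is.finite(st$value))
        stop("non-finite loss at step ", stepsDone + 1L,
             " (epoch ", ep, "); aborting")
      adam_step(opt, net, st$grads, cfg)
      for (nm in names(st$grads))
        if (!is.null(st$grads[[nm]]) && any(st$grads[[nm]] != 0))
          touched[nm] <- TRUE
      losses <- c(losses, st$value)
      stepsDone <- stepsDone + 1L
    }
    if (!length(losses)) break
    valLoss <- NA_real_; valDI <- NA_real_
    if (!is.null(valData) && length(valData)) {
      ev <- vapply(valData, function(s) {
        p <- forwardPass(rn, s$image, training = FALSE)
        cc <- confusionCounts(apply(p, c(1, 2), which.max) - 1L, s$labels)
        c(crossEntropy(p, s$labels)$value, diceIndex(cc))
      }, numeric(2))
      valLoss <- mean(ev[1, ]); valDI <- mean(ev[2, ])
      if (valDI > bestDI) {
        bestDI <- valDI; bestEpoch <- ep
        bestParams <- net$params
        bestState <- lapply(net$state, function(e)
          list(mean = e$mean, var = e$var))
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, trainLoss = mean(losses),
                             valLoss = valLoss, valMeanDI = valDI)
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f  val DI %s", ep,
                      mean(losses),
                      if (is.na(valDI)) "-" else sprintf("%.4f", valDI)))
    if (!is.null(cfg$maxSteps) && stepsDone >= cfg$maxSteps) break
  }
  if (!is.null(bestParams)) {
    net$params <- bestParams
    for (nm in names(bestState)) {
      net$state[[nm]]$mean <- bestState[[nm]]$mean
      net$state[[nm]]$var <- bestState[[nm]]$var
    }
  }
  list(network = rn, history = do.call(rbind, hist),
       bestEpoch = bestEpoch, gradientTouched = touched,
       steps = stepsDone)
}

#' Turn phantoms into preprocessed training samples
#'
#' Applies the standard preprocessing to each phantom image and binarizes
#' its mask at the network input side.
#'
#' @param phantoms list of [Phantom-class].
#' @param side network input side.
#' @return list of samples suitable for [trainNetwork()].
#' @export
phantomSamples <- function(phantoms, side) {
  lapply(phantoms, function(p)
    list(image = preprocessImage(p@image, side = side),
         labels = binarizeMask(p@mask, side = side)))
}

#' Predict a binary tumor mask
#'
#' Runs the network at its input side and argmaxes the per-pixel class
#' probabilities (for two classes this is thresholding the tumor
#' probability at 0.5), then resizes the mask back to the source image's
#' original size with nearest-neighbor interpolation. Inference is
#' deterministic: batch norm uses running statistics and dropout is off.
#'
#' @param rn a trained [RealizedNetwork-class].
#' @param img a [MammogramImage-class], [Phantom-class] or numeric matrix
#'   (raw intensities; preprocessing is applied internally).
#' @return binary integer mask at the original image size.
#' @export
predictMask <- function(rn, img) {
  px <- if (is(img, "MammogramImage")) img@pixels
        else if (is(img, "Phantom")) img@image
        else img
  side <- rn@spec@config@inputSide
  x <- preprocessImage(px, side = side)
  p <- forwardPass(rn, x, training = FALSE)
  m <- (p[, , 2] >= p[, , 1]) + 0L
  m <- resize_matrix(m, nrow(px), ncol(px), "nearest")
  m <- (m > 0) + 0L
  storage.mode(m) <- "integer"
  m
}

#' Evaluate a trained network over a dataset
#'
#' Predicts every image, compares against ground truth and reports
#' per-image and mean DI / PA / IOU.
#'
#' @param rn a trained [RealizedNetwork-class].
#' @param dataset list of samples with \code{image} (matrix,
#'   [MammogramImage-class] or [Phantom-class]), \code{truth} (binary mask
#'   at the image's size; for a Phantom this defaults to its own mask) and
#'   optional \code{id}.
#' @param reportPath optional CSV path written via [writeMetricReport()].
#' @return a [MetricReport-class].
#' @export
evaluateModel <- function(rn, dataset, reportPath = NULL) {
  pairs <- lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    if (is(s, "Phantom")) s <- list(image = s)
    img <- s$image
    truth <- s$truth %||% (if (is(img, "Phantom")) img@mask else
      stop("sample ", i, " has no ground-truth mask"))
    list(pred = predictMask(rn, img), truth = truth,
         id = s$id %||% as.character(i))
  })
  rep <- evaluateSet(pairs)
  if (!is.null(reportPath)) writeMetricReport(rep, reportPath)
  rep
}

#' Save / load a self-describing network checkpoint
#'
#' The checkpoint embeds the generating architecture configuration together
#' with all parameters and batch-norm running statistics, so inference needs
#' nothing but the file.
#'
#' @param rn a [RealizedNetwork-class].
#' @param path checkpoint file (RDS).
#' @return `loadNetwork` returns the restored [RealizedNetwork-class].
#' @export
saveNetwork <- function(rn, path) {
  cfg <- rn@spec@config
  saveRDS(list(
    config = list(growthRate = cfg@growthRate,
                  layersPerBlock = cfg@layersPerBlock,
                  nTransitions = cfg@nTransitions,
                  asppRates = cfg@asppRates, useASPP = cfg@useASPP,
                  initialFeatures = cfg@initialFeatures,
                  asppBranchChannels = cfg@asppBranchChannels,
                  dropoutRate = cfg@dropoutRate, nClasses = cfg@nClasses,
                  inputSide = cfg@inputSide),
    params = rn@net$params,
    state = lapply(rn@net$state, function(e)
      list(mean = e$mean, var = e$var)),
    seed = rn@seed), path)
  invisible(path)
}

#' @rdname saveNetwork
#' @export
loadNetwork <- function(path) {
  ck <- readRDS(path)
  spec <- assembleNetwork(do.call(archConfig, ck$config))
  rn <- realizeNetwork(spec, seed = ck$seed)
  rn@net$params <- ck$params
  for (nm in names(ck$state)) {
    rn@net$state[[nm]]$mean <- ck$state[[nm]]$mean
    rn@net$state[[nm]]$var <- ck$state[[nm]]$var
  }
  rn
}

setMethod("show", "RealizedNetwork", function(object) {
  cat(sprintf(
    "RealizedNetwork: %d counted layers, %d parameters, input %dx%d\n",
    countLayers(object@spec), nParameters(object),
    object@spec@config@inputSide, object@spec@config@inputSide))
})
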