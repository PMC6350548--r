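# Training losses: inverse-class-frequency weighted cross-entropy (the
# method's loss), plain cross-entropy, and soft Dice (the two ablation
# comparators).

PROB_FLOOR <- 1e-7   # p_i clamp before log
FREQ_FLOOR <- 1e-4   # f_l floor so tumor-free images keep a finite weight

#' Per-class pixel frequencies of a label mask
#'
#' For each class l, \code{f_l} is the fraction of pixels carrying label l;
#' frequencies sum to 1. Classes absent from the mask are floored at 1e-4
#' (so the inverse-frequency weight stays finite on tumor-free images) and
#' the remaining frequencies renormalized.
#'
#' @param labels integer matrix with values in \code{0:(nClasses-1)}.
#' @param nClasses number of classes.
#' @return named numeric vector of class frequencies (names "0", "1", ...).
#' @examples
#' m <- matrix(0L, 10, 10); m[1:2, 1:5] <- 1L
#' classFrequencies(m)   # f_1 = 0.1, f_0 = 0.9
#' @export
classFrequencies <- function(labels, nClasses = 2L) {
  if (!length(labels)) stop("empty label mask")
  if (any(labels < 0L | labels >= nClasses))
    stop("labels must lie in 0:(nClasses-1)")
  f <- tabulate(as.integer(labels) + 1L, nbins = nClasses) / length(labels)
  low <- f < FREQ_FLOOR
  if (any(low)) {
    f[low] <- FREQ_FLOOR
    f[!low] <- f[!low] * (1 - sum(f[low])) / sum(f[!low])
  }
  names(f) <- as.character(seq_len(nClasses) - 1L)
  f
}

check_probs <- function(probs, labels) {
  probs <- as_hwc(probs)
  if (!identical(dim(probs)[1:2], dim(labels)))
    stop("probability field and label mask shapes differ")
  probs
}

true_class_probs <- function(probs, labels) {
  d <- dim(probs)
  pm <- probs; dim(pm) <- c(d[1] * d[2], d[3])
  pm[cbind(seq_len(d[1] * d[2]), as.integer(labels) + 1L)]
}

#' Inverse-frequency weighted cross-entropy
#'
#' The pixelwise cross-entropy where each pixel's term is weighted by the
#' inverse frequency of its true class:
#' \deqn{L = -\frac{1}{N} \sum_{i=1}^{N} \frac{1}{f_{y_i}} \log p_i,}
#' with \eqn{N} the pixel count, \eqn{y_i} the true label of pixel i,
#' \eqn{p_i} the predicted probability of that label and \eqn{f_{y_i}} its
#' class frequency. Upweighting the rare tumor class counters the extreme
#' foreground/background imbalance of whole-mammogram segmentation.
#' Natural log; probabilities are clamped at 1e-7 so the loss is finite.
#'
#' @param probs array \code{H x W x nClasses} of per-pixel class
#'   probabilities.
#' @param labels integer matrix of true labels.
#' @param freqs class frequencies; defaults to the per-image frequencies of
#'   \code{labels} (pass dataset-wide frequencies for the dataset-scope
#'   variant).
#' @return list with \code{value} (nonnegative scalar) and \code{nPixels}.
#' @export
weightedCrossEntropy <- function(probs, labels,
                                 freqs = classFrequencies(labels,
                                                          dim(as_hwc(probs))[3])) {
  probs <- check_probs(probs, labels)
  p <- pmin(pmax(true_class_probs(probs, labels), PROB_FLOOR), 1)
  w <- 1 / freqs[as.integer(labels) + 1L]
  list(value = -mean(w * log(p)), nPixels = length(labels))
}

#' Plain (unweighted) cross-entropy
#'
#' @inheritParams weightedCrossEntropy
#' @return list with \code{value} and \code{nPixels}.
#' @export
crossEntropy <- function(probs, labels) {
  probs <- check_probs(probs, labels)
  p <- pmin(pmax(true_class_probs(probs, labels), PROB_FLOOR), 1)
  list(value = -mean(log(p)), nPixels = length(labels))
}

#' Soft Dice loss
#'
#' \eqn{1 - (2\sum_i p_i g_i + s) / (\sum_i p_i + \sum_i g_i + s)} with soft
#' foreground probabilities p, binary ground truth g and smoothing s
#' (default 1, which also makes the empty/empty case well defined).
#'
#' @inheritParams weightedCrossEntropy
#' @param smooth smoothing term s.
#' @return list with \code{value} (in [0, 1]) and \code{nPixels}.
#' @export
diceLoss <- function(probs, labels, smooth = 1) {
  probs <- check_probs(probs, labels)
  if (dim(probs)[3] != 2L) stop("diceLoss is defined for the binary problem")
  p <- probs[, , 2L]
  g <- labels == 1L
  inter <- sum(p[g])
  list(value = 1 - (2 * inter + smooth) / (sum(p) + sum(g) + smooth),
       nPixels = length(labels))
}

## ---- fused training-time losses (logits in, gradient out) ------------------

# Weighted/plain CE from logits with the softmax folded in; returns value and
# the gradient with respect to the logits. weights = NULL gives plain CE.
softmax_ce_fused <- function(logits, labels, freqs = NULL) {
  d <- dim(logits)
  p <- softmax_hwc(logits)
  n <- d[1] * d[2]
  pm <- p; dim(pm) <- c(n, d[3])
  yi <- as.integer(labels) + 1L
  pt <- pmax(pm[cbind(seq_len(n), yi)], PROB_FLOOR)
  w <- if (is.null(freqs)) rep(1, n) else 1 / freqs[yi]
  value <- -sum(w * log(pt)) / n
  onehot <- matrix(0, n, d[3])
  onehot[cbind(seq_len(n), yi)] <- 1
  dz <- (pm - onehot) * (w / n)
  dim(dz) <- d
  list(value = value, grad = dz)
}

# Soft Dice from probabilities; returns value and gradient wrt probabilities.
dice_fused <- function(p, labels, smooth = 1) {
  d <- dim(p)
  g <- as.numeric(labels == 1L)
  pf <- p[, , 2L]
  inter <- sum(pf * g)
  den <- sum(pf) + sum(g) + smooth
  num <- 2 * inter + smooth
  value <- 1 - num / den
  dpf <- -(2 * g * den - num) / den^2
  dp <- array(0, d)
  dp[, , 2L] <- dpf
  list(value = value, grad = dp)
}
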