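# Dice / pixel-accuracy / IoU evaluation from pixel confusion counts.

#' Confusion counts between predicted and true binary masks
#'
#' TP counts pixels correctly labelled tumor, FP background pixels labelled
#' tumor, FN tumor pixels labelled background, TN the rest; the four counts
#' partition the image.
#'
#' @param pred,truth binary matrices (0/1 or logical) of identical shape.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask shapes differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"))
  p <- pred > 0; g <- truth > 0
  new("ConfusionCounts",
      tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g),
      tn = sum(!p & !g))
}

empty_union_warn <- function(what) {
  warning("both masks empty: ", what, " defined as 1 (perfect agreement)",
          call. = FALSE)
  1
}

#' Dice index
#'
#' \eqn{DI = 2TP / (2TP + FP + FN)}, the overlap between predicted and true
#' tumor regions. When both masks are empty (TP = FP = FN = 0) the index is
#' defined as 1 with a warning.
#'
#' @param x a [ConfusionCounts-class].
#' @return fraction in [0, 1].
#' @export
diceIndex <- function(x) {
  d <- 2 * x@tp + x@fp + x@fn
  if (d == 0) return(empty_union_warn("DI"))
  2 * x@tp / d
}

#' Pixel accuracy (foreground recall)
#'
#' \eqn{PA = TP / (TP + FN)}: the fraction of true tumor pixels recovered.
#' Despite the name this is recall/sensitivity of the tumor class, not
#' global accuracy -- it is driven entirely by the false-negative rate.
#' Defined as 1 (with a warning) when the true mask is empty.
#'
#' @param x a [ConfusionCounts-class].
#' @return fraction in [0, 1].
#' @export
pixelAccuracy <- function(x) {
  d <- x@tp + x@fn
  if (d == 0) return(empty_union_warn("PA"))
  x@tp / d
}

#' Intersection over union
#'
#' \eqn{IOU = TP / (TP + FN + FP)}. Satisfies \eqn{DI = 2 IOU / (1 + IOU)},
#' so \eqn{IOU \le DI} always. Defined as 1 (with a warning) when the union
#' is empty.
#'
#' @param x a [ConfusionCounts-class].
#' @return fraction in [0, 1].
#' @export
iou <- function(x) {
  d <- x@tp + x@fn + x@fp
  if (d == 0) return(empty_union_warn("IOU"))
  x@tp / d
}

#' Evaluate a set of mask pairs into a metric report
#'
#' Computes DI, PA and IOU per image and their unweighted arithmetic means
#' (the "mean Dice Index" convention). Pooled mode sums confusion counts
#' over the set before computing the three metrics once.
#'
#' @param pairs list; each element a list with components \code{pred},
#'   \code{truth} and optionally \code{id}.
#' @param pooled logical, aggregate by pooling counts instead of averaging
#'   per-image metrics.
#' @return a [MetricReport-class].
#' @export
evaluateSet <- function(pairs, pooled = FALSE) {
  if (!length(pairs)) stop("empty evaluation set")
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    cc <- confusionCounts(pr$pred, pr$truth)
    data.frame(id = pr$id %||% as.character(i),
               DI = diceIndex(cc), PA = pixelAccuracy(cc), IOU = iou(cc),
               tp = cc@tp, fp = cc@fp, fn = cc@fn, tn = cc@tn,
               stringsAsFactors = FALSE)
  })
  new("MetricReport", perImage = do.call(rbind, rows), pooled = pooled)
}

#' @describeIn evaluateSet mean Dice index of a report.
#' @param report a [MetricReport-class].
#' @export
meanDI <- function(report) report_mean(report, "DI")

#' @describeIn evaluateSet mean pixel accuracy of a report.
#' @export
meanPA <- function(report) report_mean(report, "PA")

#' @describeIn evaluateSet mean intersection over union of a report.
#' @export
meanIOU <- function(report) report_mean(report, "IOU")

report_mean <- function(report, which) {
  if (report@pooled) {
    cc <- new("ConfusionCounts",
              tp = sum(report@perImage$tp), fp = sum(report@perImage$fp),
              fn = sum(report@perImage$fn), tn = sum(report@perImage$tn))
    switch(which, DI = diceIndex(cc), PA = pixelAccuracy(cc), IOU = iou(cc))
  } else {
    mean(report@perImage[[which]])
  }
}

#' Write a metric report to CSV (id, DI, PA, IOU + summary row)
#'
#' @param report a [MetricReport-class].
#' @param path output file.
#' @export
writeMetricReport <- function(report, path) {
  df <- report@perImage[, c("id", "DI", "PA", "IOU")]
  df <- rbind(df, data.frame(id = "mean", DI = meanDI(report),
                             PA = meanPA(report), IOU = meanIOU(report)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read back a metric report written by [writeMetricReport()]
#' @param path CSV path.
#' @return a [MetricReport-class] (per-image rows only, means recomputed).
#' @export
readMetricReport <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$id != "mean", , drop = FALSE]
  rownames(df) <- NULL
  new("MetricReport", perImage = df, pooled = FALSE)
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %g  FP %g  FN %g  TN %g\n",
              object@tp, object@fp, object@fn, object@tn))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf(
    "MetricReport (%d images%s): mean DI %.4f  IOU %.4f  PA %.4f\n",
    nrow(object@perImage), if (object@pooled) ", pooled" else "",
    meanDI(object), meanIOU(object), meanPA(object)))
})
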