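# Classical double-threshold segmentation baseline and connected-component
# postprocessing.

#' Iterative (ISODATA / Ridler-Calvard) global threshold
#'
#' Starting from the global mean, iterates
#' \eqn{t \leftarrow (\mu_{<t} + \mu_{\ge t}) / 2} until the threshold moves
#' less than \code{tol} (or \code{maxIter} iterations), where the two means
#' are taken over the pixels below/at-or-above the current threshold.
#'
#' @param image numeric matrix; must not be constant.
#' @param tol convergence tolerance on the threshold.
#' @param maxIter iteration cap.
#' @return the converged threshold (intensity).
#' @export
iterativeThreshold <- function(image, tol = 1e-3, maxIter = 100L) {
  v <- as.numeric(image)
  if (!length(v) || !is.finite(diff(range(v))) || diff(range(v)) == 0)
    stop("iterative threshold undefined for a constant image")
  t <- mean(v)
  for (i in seq_len(maxIter)) {
    hi <- v >= t
    mhi <- mean(v[hi])
    mlo <- if (all(hi)) min(v) else mean(v[!hi])
    tNew <- (mhi + mlo) / 2
    if (abs(tNew - t) < tol) return(tNew)
    t <- tNew
  }
  t
}

#' Double-threshold tumor segmentation
#'
#' First pass: the iterative threshold selects a candidate bright region.
#' Second pass: the mean intensity of that region becomes the second
#' threshold, re-applied to the whole image; pixels at or above it form the
#' final mask. The second threshold can only exceed the first, so the mask
#' shrinks toward the brightest (tumor-like) structures.
#'
#' @param image numeric matrix.
#' @return list with \code{firstThreshold}, \code{secondThreshold} and the
#'   binary \code{mask}.
#' @export
doubleThresholdSegment <- function(image) {
  t1 <- iterativeThreshold(image)
  region1 <- image >= t1
  if (!any(region1)) stop("first-pass region is empty")
  t2 <- mean(image[region1])
  mask <- (image >= t2) + 0L
  storage.mode(mask) <- "integer"
  list(firstThreshold = t1, secondThreshold = t2, mask = mask)
}

# 8-connected component labelling via the pixel adjacency graph
label_components <- function(mask) {
  fg <- which(mask > 0)
  if (!length(fg)) return(list(labels = integer(0), pixels = fg))
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_along(fg)
  rows <- (fg - 1L) %% nr + 1L
  cols <- (fg - 1L) %/% nr + 1L
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + d[1]; c2 <- cols + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- idx[cbind(r2[ok], c2[ok])]
    has <- nb > 0L
    edges <- c(edges, rbind(idx[fg][ok][has], nb[has]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  list(labels = igraph::components(g)$membership, pixels = fg)
}

#' Delete isolated small connected regions
#'
#' Removes 8-connected foreground components with area below
#' \code{minArea}; larger components pass through untouched. Idempotent.
#'
#' @param mask binary matrix.
#' @param minArea minimum surviving component area in pixels; the default is
#'   0.1 percent of the image.
#' @return binary integer matrix.
#' @export
removeSmallComponents <- function(mask, minArea = ceiling(0.001 *
                                                          length(mask))) {
  lab <- label_components(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (length(lab$pixels)) {
    sizes <- tabulate(lab$labels)
    keep <- sizes[lab$labels] >= minArea
    out[lab$pixels[keep]] <- 1L
  }
  out
}
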