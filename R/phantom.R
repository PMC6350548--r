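# Synthetic mammogram phantoms: a bright half-elliptical breast over a dark
# background, multiscale parenchymal texture, an optional pectoral wedge
# (MLO-like) and lobulated elliptical tumors with exact ground-truth masks.
# A test double for clinical data: it reproduces the geometry, intensity
# ordering and foreground/background imbalance the segmentation method
# assumes, not the radiographic physics of real parenchyma.

#' Phantom generator configuration
#'
#' Defaults emulate the clinical regime: tumor diameters map the 200-800
#' pixel interval observed at 4096-pixel image height proportionally onto
#' \code{canvasSide}, tumors occupy a small fraction of the image (the class
#' imbalance that motivates inverse-frequency loss weighting), and contrast
#' is moderate with \code{tumorContrast = 0.3}; set it near \code{noiseSd}
#' for the hard low-contrast regime.
#'
#' @param canvasSide phantom side in pixels (default 1024).
#' @param tumorSizeRange min/max tumor bounding-box side in pixels; default
#'   scales 200-800 by \code{canvasSide / 4096}.
#' @param nTumors tumors per phantom: a single count or a length-2 range.
#' @param tumorContrast intensity offset of tumors over local tissue.
#' @param textureScale amplitude of parenchymal texture.
#' @param includePectoral add a bright pectoral wedge (MLO-like view).
#' @param noiseSd sd of pixelwise Gaussian noise.
#' @param seed default generator seed.
#' @return a [PhantomConfig-class].
#' @export
phantomConfig <- function(canvasSide = 1024L,
                          tumorSizeRange = round(c(200, 800) *
                                                 canvasSide / 4096),
                          nTumors = 1L, tumorContrast = 0.3,
                          textureScale = 0.08, includePectoral = FALSE,
                          noiseSd = 0.02, seed = 1L) {
  new("PhantomConfig", canvasSide = as.integer(canvasSide),
      tumorSizeRange = as.numeric(tumorSizeRange),
      nTumors = as.integer(nTumors), tumorContrast = tumorContrast,
      textureScale = textureScale, includePectoral = isTRUE(includePectoral),
      noiseSd = noiseSd, seed = as.integer(seed))
}

# smooth multiscale texture: 2-3 octaves of Gaussian-smoothed white noise
multiscale_texture <- function(n, scale) {
  sigmas <- pmax(n / c(8, 16, 32), 1)
  amps <- c(1, 0.5, 0.25)
  tex <- matrix(0, n, n)
  for (j in seq_along(sigmas)) {
    o <- EBImage::imageData(EBImage::gblur(
      EBImage::Image(matrix(stats::rnorm(n * n), n, n)),
      sigma = sigmas[j]))
    tex <- tex + amps[j] * o / max(stats::sd(o), 1e-12)
  }
  scale * tex / max(stats::sd(tex), 1e-12)
}

# support of one lobulated ellipse on the canvas
tumor_support <- function(n, cx, cy, a, b, theta, amp, lobes, phase) {
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- col - cx; dy <- row - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  r <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  r <= 1 + amp * sin(lobes * phi + phase)
}

bbox_sides <- function(support) {
  if (!any(support)) return(c(0L, 0L))
  rows <- range(which(rowSums(support) > 0))
  cols <- range(which(colSums(support) > 0))
  c(rows[2] - rows[1] + 1L, cols[2] - cols[1] + 1L)
}

#' Generate one synthetic mammogram phantom
#'
#' Renders the breast as a bright half-ellipse anchored at the chest-wall
#' (left) edge over a dark background, adds multiscale texture, optionally a
#' brighter pectoral wedge in the upper-left corner, then places tumors as
#' rotated ellipses with sinusoidal (lobulated) boundary perturbation whose
#' intensity is the local tissue plus \code{tumorContrast}. The returned
#' mask is exactly the union of the rendered tumor supports. Bit-identical
#' given the same (config, seed).
#'
#' @param cfg a [PhantomConfig-class].
#' @param seed overrides \code{cfg@seed}.
#' @return a [Phantom-class].
#' @export
generatePhantom <- function(cfg, seed = cfg@seed) {
  validObject(cfg)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- cfg@canvasSide
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)

  # breast: half-ellipse on the left (chest wall) edge
  cy <- n * stats::runif(1, 0.45, 0.55)
  av <- n * stats::runif(1, 0.42, 0.48)   # vertical semi-axis
  bh <- n * stats::runif(1, 0.70, 0.85)   # horizontal semi-axis
  rr <- ((row - cy) / av)^2 + (col / bh)^2
  breast <- rr <= 1

  img <- matrix(0.05, n, n)
  tissue <- 0.35 + 0.25 * pmax(1 - rr, 0)  # brighter toward the chest wall
  img[breast] <- tissue[breast]
  img <- img + multiscale_texture(n, cfg@textureScale) * breast

  if (cfg@includePectoral) {
    slope <- stats::runif(1, 0.8, 1.4)
    wedge <- breast & (col < slope * (0.45 * n - row))
    img[wedge] <- img[wedge] + 0.2
  }

  # tumors
  nt <- if (length(cfg@nTumors) == 2L)
    sample(cfg@nTumors[1]:cfg@nTumors[2], 1L) else cfg@nTumors
  lo <- cfg@tumorSizeRange[1]; hi <- cfg@tumorSizeRange[2]
  mask <- matrix(FALSE, n, n)
  specs <- list()
  inner <- rr <= 0.7  # placement region well inside the breast
  for (ti in seq_len(nt)) {
    placed <- FALSE
    for (attempt in seq_len(100L)) {
      d <- stats::runif(1, lo + 0.15 * (hi - lo), hi - 0.15 * (hi - lo))
      amp <- stats::runif(1, 0.05, 0.2)
      a <- d / 2 / (1 + amp)
      b <- a * stats::runif(1, 0.75, 1)
      theta <- stats::runif(1, 0, pi)
      lobes <- sample(3:7, 1L)
      phase <- stats::runif(1, 0, 2 * pi)
      cand <- which(inner, arr.ind = TRUE)
      pick <- cand[sample(nrow(cand), 1L), ]
      supp <- tumor_support(n, pick[2], pick[1], a, b, theta, amp,
                            lobes, phase)
      bb <- bbox_sides(supp)
      if (!any(supp) || any(bb < lo) || any(bb > hi)) next
      if (!all(breast[supp])) next          # must fit inside the breast
      mask <- mask | supp
      sm <- EBImage::imageData(EBImage::gblur(
        EBImage::Image(supp + 0), sigma = max(d / 40, 0.8)))
      img <- img + cfg@tumorContrast * sm
      specs[[length(specs) + 1L]] <- data.frame(
        centerRow = pick[1], centerCol = pick[2], axisA = a, axisB = b,
        rotation = theta, contrast = cfg@tumorContrast,
        bboxRows = bb[1], bboxCols = bb[2])
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place tumor ", ti, " inside the breast region ",
           "after 100 attempts (size range too large for the canvas?)")
  }

  img <- img + matrix(stats::rnorm(n * n, 0, cfg@noiseSd), n, n)
  img <- pmin(pmax(img, 0), 1)
  m <- mask + 0L
  storage.mode(m) <- "integer"
  new("Phantom", image = img, mask = m,
      tumorSpecs = if (length(specs)) do.call(rbind, specs)
                   else data.frame(),
      viewLike = if (cfg@includePectoral) "MLO" else "CC")
}

#' Generate a phantom dataset with manifest
#'
#' Derives independent per-item seeds from the master seed, renders each
#' phantom, and (when \code{dir} is given) writes image and mask PNGs plus a
#' manifest CSV that [readManifest()] / the training tools consume.
#' Re-running with the same arguments reproduces identical files.
#'
#' @param n number of phantoms.
#' @param cfg a [PhantomConfig-class].
#' @param dir output directory, or NULL to keep everything in memory.
#' @param seed master seed.
#' @param split partition label written into the manifest (recycled).
#' @return list with \code{phantoms} (list of [Phantom-class]),
#'   \code{manifest} (data.frame) and \code{itemSeeds}.
#' @export
generateDataset <- function(n, cfg, dir = NULL, seed = cfg@seed,
                            split = "train") {
  stopifnot(n >= 1L)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  itemSeeds <- sample.int(.Machine$integer.max - 1L, n)
  phantoms <- lapply(itemSeeds, function(s) generatePhantom(cfg, seed = s))
  ids <- sprintf("phantom%03d", seq_len(n))
  manifest <- data.frame(
    id = ids,
    image = if (is.null(dir)) "" else file.path(dir, paste0(ids, ".png")),
    mask = if (is.null(dir)) "" else file.path(dir, paste0(ids, "_mask.png")),
    view = vapply(phantoms, function(p) p@viewLike, ""),
    patient = ids,
    split = rep_len(split, n),
    stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      EBImage::writeImage(EBImage::Image(t(phantoms[[i]]@image)),
                          manifest$image[i])
      EBImage::writeImage(EBImage::Image(t(phantoms[[i]]@mask + 0)),
                          manifest$mask[i])
    }
    writeManifest(manifest, file.path(dir, "manifest.csv"))
  }
  list(phantoms = phantoms, manifest = manifest, itemSeeds = itemSeeds)
}

#' Histogram of rendered tumor sizes
#'
#' Tabulates the larger bounding-box side of every rendered tumor over the
#' given bin breaks -- the check that the generator matches its configured
#' size range. The histogram total equals the number of tumors.
#'
#' @param phantoms list of [Phantom-class].
#' @param breaks bin breaks (default: 8 bins spanning the observed range).
#' @return named integer vector of bin counts (empty for tumor-free sets).
#' @export
tumorSizeSummary <- function(phantoms, breaks = NULL) {
  sizes <- unlist(lapply(phantoms, function(p)
    if (nrow(p@tumorSpecs)) pmax(p@tumorSpecs$bboxRows,
                                 p@tumorSpecs$bboxCols) else numeric()))
  if (!length(sizes)) return(integer(0))
  if (is.null(breaks)) breaks <- pretty(range(sizes), 8)
  idx <- findInterval(sizes, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  stats::setNames(counts,
                  paste0("[", utils::head(breaks, -1), ",",
                         utils::tail(breaks, -1), ")"))
}

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom %dx%d (%s-like): %d tumor(s), foreground %.2f%%\n",
              nrow(object@image), ncol(object@image), object@viewLike,
              nrow(object@tumorSpecs),
              100 * mean(object@mask > 0)))
})
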