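# Clinical-format input handling: image loading, the standard preprocessing
# (resize to the network side, 0-1 normalization, mean subtraction), mask
# binarization and dataset splitting.

# Positional resize of a [rows, cols] matrix. EBImage stores images with x
# (width) as the first dimension, so dimension 1 maps to `w`.
resize_matrix <- function(m, rows, cols, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (nrow(m) == rows && ncol(m) == cols) return(m)
  out <- EBImage::resize(EBImage::Image(m), w = rows, h = cols,
                         filter = if (method == "bilinear") "bilinear"
                                  else "none")
  EBImage::imageData(out)
}

#' Load a grayscale mammogram (DICOM, PNG or TIFF)
#'
#' Multi-channel images are collapsed to luminance; DICOM MONOCHROME1 (where
#' low values are bright) is inverted so higher always means brighter.
#'
#' @param path file path; format chosen by extension (.dcm/.dicom, .png,
#'   .tif/.tiff).
#' @param view "CC", "MLO" or "unknown".
#' @param patientId patient identifier string.
#' @return a [MammogramImage-class]; pixel matrix rows are image rows.
#' @export
loadImage <- function(path, view = "unknown", patientId = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    dcm = , dicom = readDicom(path)$pixels,
    png = , tif = , tiff = {
      img <- tryCatch(EBImage::readImage(path),
                      error = function(e) stop("cannot read ", path, ": ",
                                               conditionMessage(e)))
      d <- EBImage::imageData(img)
      if (length(dim(d)) == 3L) {
        wch <- c(0.299, 0.587, 0.114, 0)[seq_len(dim(d)[3])]
        d <- apply(sweep(d, 3L, wch / sum(wch), "*"), c(1, 2), sum)
      }
      t(d)  # EBImage x/y -> matrix rows = image rows
    },
    stop("unsupported image format: .", ext))
  if (!all(is.finite(px))) stop("non-finite pixel values in ", path)
  new("MammogramImage", pixels = px,
      originalSize = c(ncol(px), nrow(px)),
      view = view, patientId = patientId, sourcePath = path)
}

#' The standard network preprocessing
#'
#' Resizes to \code{side x side} (bilinear), rescales intensities into
#' [0, 1] and subtracts the mean, so the network input is zero-mean with
#' range inside [-1, 1]. A constant image maps to all zeros.
#'
#' @param img a [MammogramImage-class] or a numeric matrix.
#' @param side output side length (default 512).
#' @param normalization "minmax" rescales by the per-image min/max;
#'   "fixed" divides by \code{maxValue} (e.g. the bit-depth maximum).
#' @param meanScope "image" subtracts the per-image mean; "value" subtracts
#'   the supplied \code{meanValue} (e.g. a dataset mean).
#' @param maxValue,meanValue used by the fixed-range / dataset-mean modes.
#' @return numeric \code{side x side} matrix.
#' @export
preprocessImage <- function(img, side = 512L,
                            normalization = c("minmax", "fixed"),
                            meanScope = c("image", "value"),
                            maxValue = NULL, meanValue = NULL) {
  normalization <- match.arg(normalization)
  meanScope <- match.arg(meanScope)
  px <- if (is(img, "MammogramImage")) img@pixels else img
  px <- resize_matrix(px, side, side, "bilinear")
  if (normalization == "minmax") {
    rg <- range(px)
    px <- if (rg[2] > rg[1]) (px - rg[1]) / (rg[2] - rg[1])
          else array(0, dim(px))
  } else {
    if (is.null(maxValue)) stop("fixed normalization needs maxValue")
    px <- px / maxValue
  }
  mu <- if (meanScope == "image") mean(px)
        else meanValue %||% stop("meanScope='value' needs meanValue")
  px - mu
}

#' Binarize (and optionally resize) an annotation mask
#'
#' Any value above zero becomes 1. Resizing uses nearest-neighbor so the
#' result stays strictly binary.
#'
#' @param mask a [MammogramImage-class] or numeric matrix.
#' @param side optional output side; NULL keeps the original size.
#' @return integer 0/1 matrix.
#' @export
binarizeMask <- function(mask, side = NULL) {
  px <- if (is(mask, "MammogramImage")) mask@pixels else mask
  if (!is.null(side)) px <- resize_matrix(px, side, side, "nearest")
  m <- (px > 0) + 0L
  storage.mode(m) <- "integer"
  m
}

#' Deterministic train/validation/test split
#'
#' Randomly partitions sample ids into disjoint train/validation/test sets
#' of the requested sizes (the clinical convention is 230/75/75 of 380).
#' With \code{patientAware}, all samples of one patient (e.g. the CC and MLO
#' views) are kept inside a single partition; sizes are then met as closely
#' as whole-patient assignment allows.
#'
#' @param ids character vector of sample ids.
#' @param sizes integer length-3: train, validation, test; must sum to
#'   \code{length(ids)}.
#' @param seed integer seed; the split is a pure function of (ids, sizes,
#'   seed).
#' @param patientAware logical.
#' @param patientIds character vector parallel to \code{ids} (required when
#'   \code{patientAware}).
#' @return list with character vectors \code{train}, \code{validation},
#'   \code{test}.
#' @export
splitDataset <- function(ids, sizes, seed = 1L, patientAware = FALSE,
                         patientIds = NULL) {
  if (sum(sizes) != length(ids))
    stop("sizes sum to ", sum(sizes), " but there are ", length(ids), " ids")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (!patientAware) {
    perm <- sample(ids)
    return(list(train = perm[seq_len(sizes[1])],
                validation = perm[sizes[1] + seq_len(sizes[2])],
                test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])]))
  }
  if (is.null(patientIds) || length(patientIds) != length(ids))
    stop("patientAware split needs patientIds parallel to ids")
  groups <- split(ids, patientIds)
  groups <- groups[sample(length(groups))]
  out <- list(train = character(), validation = character(),
              test = character())
  want <- c(train = sizes[1], validation = sizes[2], test = sizes[3])
  for (g in groups) {
    deficit <- want - lengths(out)
    k <- names(which.max(deficit))
    out[[k]] <- c(out[[k]], g)
  }
  out
}

#' Write / read a dataset manifest CSV
#'
#' Columns: id, image, mask, view, patient, split. The manifest is the
#' interchange format between the phantom generator, the trainer and the
#' evaluator.
#'
#' @param df data.frame with those columns.
#' @param path CSV path.
#' @return `readManifest` returns the data.frame.
#' @export
writeManifest <- function(df, path) {
  need <- c("id", "image", "mask", "view", "patient", "split")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing columns: ",
                         paste(miss, collapse = ", "))
  utils::write.csv(df[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = "character")
}
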