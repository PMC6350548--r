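#' @import methods
NULL

#' Architecture configuration for (ASPP-)FC-DenseNet networks
#'
#' Declarative hyperparameters of the segmentation network. The proposed
#' network uses 4 transitions per path with an ASPP bottleneck (atrous rates
#' 6/12/18); the FC-DenseNet56 baseline uses 5 transitions and a dense
#' bottleneck. Growth rate and layers per dense block default to 12 and 4.
#'
#' @slot growthRate integer, feature maps added by each dense layer.
#' @slot layersPerBlock integer, dense layers per dense block.
#' @slot nTransitions integer, downsampling (and upsampling) steps.
#' @slot asppRates integer vector of atrous sampling rates, strictly
#'   increasing.
#' @slot useASPP logical, ASPP bottleneck (proposed) vs dense bottleneck
#'   (baseline).
#' @slot initialFeatures integer, channels produced by the first convolution.
#' @slot asppBranchChannels integer, feature maps per ASPP branch.
#' @slot dropoutRate numeric in [0, 1).
#' @slot nClasses integer, output classes (background, tumor).
#' @slot inputSide integer, spatial side the network expects; must be
#'   divisible by \code{2^nTransitions}.
#' @exportClass ArchConfig
setClass("ArchConfig", representation(
  growthRate = "integer",
  layersPerBlock = "integer",
  nTransitions = "integer",
  asppRates = "integer",
  useASPP = "logical",
  initialFeatures = "integer",
  asppBranchChannels = "integer",
  dropoutRate = "numeric",
  nClasses = "integer",
  inputSide = "integer"
))

setValidity("ArchConfig", function(object) {
  msg <- character()
  scalar <- c("growthRate", "layersPerBlock", "nTransitions", "useASPP",
              "initialFeatures", "asppBranchChannels", "dropoutRate",
              "nClasses", "inputSide")
  if (any(vapply(scalar, function(s) length(slot(object, s)) != 1L,
                 logical(1))))
    return("all scalar slots must have length 1")
  if (object@growthRate < 1L) msg <- c(msg, "growthRate must be >= 1")
  if (object@layersPerBlock < 1L) msg <- c(msg, "layersPerBlock must be >= 1")
  if (object@nTransitions < 1L) msg <- c(msg, "nTransitions must be >= 1")
  if (length(object@asppRates) &&
      (any(object@asppRates < 1L) || is.unsorted(object@asppRates, strictly = TRUE)))
    msg <- c(msg, "asppRates must be >= 1 and strictly increasing")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@inputSide %% 2L^object@nTransitions != 0L)
    msg <- c(msg, sprintf("inputSide (%d) must be divisible by 2^nTransitions (%d)",
                          object@inputSide, 2L^object@nTransitions))
  if (length(msg)) msg else TRUE
})

#' Assembled network specification
#'
#' Ordered block list with full channel and resolution bookkeeping, plus the
#' skip edges connecting encoder concatenations to decoder dense blocks.
#' Produced by [assembleNetwork()]; realized into an executable network by
#' [realizeNetwork()].
#'
#' @slot blocks list of block records (kind, layers, channels, resolution).
#' @slot skipEdges data.frame with columns \code{src}, \code{dst}.
#' @slot config the [ArchConfig-class] the spec was assembled from.
#' @exportClass NetworkSpec
setClass("NetworkSpec", representation(
  blocks = "list",
  skipEdges = "data.frame",
  config = "ArchConfig"
))

#' Pixel-level confusion counts between a predicted and a true binary mask
#'
#' @slot tp,fp,fn,tn numeric pixel counts; they partition the image.
#' @exportClass ConfusionCounts
setClass("ConfusionCounts", representation(
  tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric"
))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0)) "counts must be nonnegative" else TRUE
})

#' Per-image and aggregated segmentation metrics
#'
#' @slot perImage data.frame with columns \code{id}, \code{DI}, \code{PA},
#'   \code{IOU} (one row per evaluated image).
#' @slot pooled logical; FALSE (default) means the summary means are
#'   unweighted arithmetic means of per-image values, TRUE means they were
#'   computed from pooled confusion counts.
#' @exportClass MetricReport
setClass("MetricReport", representation(
  perImage = "data.frame",
  pooled = "logical"
))

#' Synthetic mammogram phantom configuration
#'
#' Controls the generator that emulates the structure of a screening
#' mammogram: a bright half-elliptical breast region over a dark background,
#' multiscale parenchymal texture, an optional pectoral wedge (MLO-like
#' views), and one or more lobulated tumor blobs. Tumor diameters are drawn
#' from \code{tumorSizeRange}; the default range maps the clinical 200-800
#' pixel interval (at 4096-pixel image height) proportionally onto
#' \code{canvasSide}.
#'
#' @slot canvasSide integer, phantom side length in pixels.
#' @slot tumorSizeRange numeric length-2, min/max tumor diameter in pixels.
#' @slot nTumors integer length-1 or length-2 (range) tumors per phantom.
#' @slot tumorContrast numeric, intensity offset of tumor over local tissue;
#'   values close to \code{noiseSd} give the hard low-contrast regime.
#' @slot textureScale numeric, amplitude of the parenchymal texture.
#' @slot includePectoral logical, add the bright pectoral wedge (MLO-like).
#' @slot noiseSd numeric, sd of pixelwise Gaussian noise.
#' @slot seed integer, generator seed.
#' @exportClass PhantomConfig
setClass("PhantomConfig", representation(
  canvasSide = "integer",
  tumorSizeRange = "numeric",
  nTumors = "integer",
  tumorContrast = "numeric",
  textureScale = "numeric",
  includePectoral = "logical",
  noiseSd = "numeric",
  seed = "integer"
))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  r <- object@tumorSizeRange
  if (length(r) != 2L || r[1] <= 0 || r[1] > r[2] || r[2] >= object@canvasSide)
    msg <- c(msg, "tumorSizeRange must satisfy 0 < min <= max < canvasSide")
  if (object@tumorContrast < 0) msg <- c(msg, "tumorContrast must be >= 0")
  if (any(object@nTumors < 0L)) msg <- c(msg, "nTumors must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A paired synthetic image and exact ground-truth tumor mask
#'
#' @slot image numeric matrix in [0, 1].
#' @slot mask binary integer matrix, 1 on rendered tumor support.
#' @slot tumorSpecs data.frame of rendered tumor geometry (center, axes,
#'   rotation, contrast).
#' @slot viewLike character, "CC" or "MLO".
#' @exportClass Phantom
setClass("Phantom", representation(
  image = "matrix",
  mask = "matrix",
  tumorSpecs = "data.frame",
  viewLike = "character"
))

#' A loaded grayscale mammogram
#'
#' @slot pixels numeric matrix (rows = image rows).
#' @slot originalSize integer length-2 (width, height).
#' @slot view character, "CC", "MLO" or "unknown".
#' @slot patientId character.
#' @slot sourcePath character.
#' @exportClass MammogramImage
setClass("MammogramImage", representation(
  pixels = "matrix",
  originalSize = "integer",
  view = "character",
  patientId = "character",
  sourcePath = "character"
))

#' An executable network: a spec bound to parameters and batch-norm state
#'
#' Created by [realizeNetwork()]; consumed by [forwardPass()],
#' [trainNetwork()] and [predictMask()]. Parameters and running statistics
#' are held in environments so optimizer updates are in-place.
#'
#' @slot spec the [NetworkSpec-class].
#' @slot net environment with \code{params} (named arrays) and \code{state}
#'   (batch-norm running means/variances).
#' @slot seed integer used for weight initialization.
#' @exportClass RealizedNetwork
setClass("RealizedNetwork", representation(
  spec = "NetworkSpec",
  net = "environment",
  seed = "integer"
))
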