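#' Effective kernel side of an atrous convolution
#'
#' An atrous (dilated) convolution with sampling rate \code{r} inserts
#' \code{r - 1} zeros between consecutive taps of a \code{k x k} filter,
#' enlarging its support to side \code{k + (k - 1)(r - 1)} without adding
#' parameters. Rate 1 is standard convolution.
#'
#' @param k odd positive integer, kernel side.
#' @param r positive integer, atrous sampling rate.
#' @return integer, side length of the enlarged (effective) kernel.
#' @examples
#' effectiveKernelSize(3, 2)  # 5: a 3x3 kernel at rate 2 sees a 5x5 field
#' effectiveKernelSize(3, 3)  # 7
#' @export
effectiveKernelSize <- function(k, r) {
  k <- as.integer(k); r <- as.integer(r)
  if (is.na(k) || k < 1L || k %% 2L == 0L)
    stop("k must be a positive odd integer")
  if (is.na(r) || r < 1L) stop("r must be a positive integer")
  k + (k - 1L) * (r - 1L)
}

#' Explicitly dilate a convolution kernel
#'
#' Builds the zero-inserted kernel equivalent to applying the original kernel
#' with atrous rate \code{r}: the k^2 original weights land at positions
#' spaced \code{r} apart, every other entry is exactly zero. Used as the
#' ground-truth construction when testing the backend's dilated convolution.
#'
#' @param kernel square numeric matrix.
#' @param r positive integer sampling rate.
#' @return numeric matrix of side \code{effectiveKernelSize(nrow(kernel), r)}.
#' @export
dilateKernel <- function(kernel, r) {
  if (!is.matrix(kernel) || nrow(kernel) != ncol(kernel))
    stop("kernel must be a square matrix")
  r <- as.integer(r)
  if (is.na(r) || r < 1L) stop("r must be a positive integer")
  k <- nrow(kernel)
  if (r == 1L || k == 1L) return(kernel)
  side <- k + (k - 1L) * (r - 1L)
  out <- matrix(0, side, side)
  pos <- seq.int(1L, by = r, length.out = k)
  out[pos, pos] <- kernel
  out
}

## ---- block builders --------------------------------------------------------

layer_spec <- function(kind, kernel = 1L, stride = 1L, dilation = 1L,
                       inChannels = 0L, outChannels = inChannels,
                       padding = "same") {
  list(kind = kind, kernel = as.integer(kernel), stride = as.integer(stride),
       dilation = as.integer(dilation), inChannels = as.integer(inChannels),
       outChannels = as.integer(outChannels), padding = padding)
}

block_spec <- function(name, kind, layers, inChannels, outChannels,
                       countedLayers, attrs = list()) {
  structure(list(name = name, kind = kind, layers = layers,
                 inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels),
                 countedLayers = as.integer(countedLayers),
                 attrs = attrs),
            class = "BlockSpec")
}

#' Build a dense block
#'
#' Each dense layer is BN -> ReLU -> 3x3 same convolution producing
#' \code{growth} feature maps -> dropout, and receives the concatenation of
#' the block input with all previous layers' outputs. The block output is the
#' concatenation of the layer outputs only (\code{nLayers * growth} channels);
#' the block input is not concatenated into the output, which keeps the
#' channel count from growing linearly along the upsampling path.
#'
#' @param inChannels channels entering the block.
#' @param nLayers dense layers in the block.
#' @param growth feature maps added per layer.
#' @param dropout dropout probability.
#' @param name block name.
#' @return a block record; its convolutions count as \code{nLayers} layers.
#' @export
buildDenseBlock <- function(inChannels, nLayers, growth, dropout = 0.2,
                            name = "dense") {
  stopifnot(inChannels >= 1L, nLayers >= 1L, growth >= 1L)
  layers <- list()
  for (i in seq_len(nLayers)) {
    cin <- inChannels + (i - 1L) * growth
    layers <- c(layers, list(
      layer_spec("batch_norm", inChannels = cin),
      layer_spec("relu", inChannels = cin),
      layer_spec("conv", kernel = 3L, inChannels = cin, outChannels = growth),
      layer_spec("dropout", inChannels = growth)
    ))
  }
  block_spec(name, "dense_block", layers, inChannels,
             nLayers * growth, countedLayers = nLayers,
             attrs = list(nLayers = as.integer(nLayers),
                          growth = as.integer(growth), dropout = dropout))
}

#' Build a transition-down block
#'
#' BN -> ReLU -> 1x1 convolution conserving the number of feature maps ->
#' dropout -> 3x3 stride-2 same convolution (replacing the 2x2 pooling of the
#' original design, to reduce the information loss of max pooling). Halves
#' the spatial side; conserves channels. Counts as one layer under the
#' FC-DenseNet accounting convention (see [countLayers()]).
#'
#' @param inChannels channels entering (and leaving) the block.
#' @param dropout dropout probability.
#' @param name block name.
#' @export
buildTransitionDown <- function(inChannels, dropout = 0.2, name = "td") {
  stopifnot(inChannels >= 1L)
  layers <- list(
    layer_spec("batch_norm", inChannels = inChannels),
    layer_spec("relu", inChannels = inChannels),
    layer_spec("conv", kernel = 1L, inChannels = inChannels),
    layer_spec("dropout", inChannels = inChannels),
    layer_spec("conv", kernel = 3L, stride = 2L, inChannels = inChannels)
  )
  block_spec(name, "transition_down", layers, inChannels, inChannels,
             countedLayers = 1L, attrs = list(dropout = dropout))
}

#' Build a transition-up block
#'
#' A single 3x3 transposed convolution with stride 2, doubling the spatial
#' side. It is applied only to the feature maps produced by the preceding
#' dense block, never to the running concatenation.
#'
#' @param inChannels,outChannels channels in/out.
#' @param name block name.
#' @export
buildTransitionUp <- function(inChannels, outChannels = inChannels,
                              name = "tu") {
  stopifnot(inChannels >= 1L, outChannels >= 1L)
  layers <- list(
    layer_spec("transposed_conv", kernel = 3L, stride = 2L,
               inChannels = inChannels, outChannels = outChannels)
  )
  block_spec(name, "transition_up", layers, inChannels, outChannels,
             countedLayers = 1L)
}

#' Build the atrous-spatial-pyramid-pooling bottleneck
#'
#' Parallel branches over the same input: one 1x1 convolution plus one 3x3
#' atrous convolution per sampling rate, each producing
#' \code{branchChannels} maps and preserving spatial size. The branch outputs
#' are concatenated together with the block input, then fused by a final 1x1
#' convolution. With rates 6/12/18 this contributes 5 counted layers.
#'
#' @param inChannels channels entering the block.
#' @param branchChannels feature maps per branch.
#' @param rates strictly increasing atrous sampling rates.
#' @param outChannels channels after the fusion convolution.
#' @param featureSide spatial side the block will see; if a rate's effective
#'   kernel exceeds it a warning (not an error) is raised.
#' @param name block name.
#' @export
buildASPP <- function(inChannels, branchChannels, rates,
                      outChannels = branchChannels, featureSide = NA,
                      name = "aspp") {
  rates <- as.integer(rates)
  if (!length(rates) || any(rates < 1L) ||
      is.unsorted(rates, strictly = TRUE))
    stop("rates must be nonempty, >= 1 and strictly increasing")
  if (!is.na(featureSide)) {
    eff <- vapply(rates, function(r) effectiveKernelSize(3L, r), integer(1))
    if (any(eff > featureSide))
      warning("ASPP rate(s) ", paste(rates[eff > featureSide], collapse = ", "),
              " give effective kernels larger than the ", featureSide,
              "-pixel feature map")
  }
  layers <- list(layer_spec("conv", kernel = 1L, inChannels = inChannels,
                            outChannels = branchChannels))
  for (r in rates)
    layers <- c(layers, list(
      layer_spec("conv", kernel = 3L, dilation = r,
                 inChannels = inChannels, outChannels = branchChannels)))
  concatChannels <- inChannels + (1L + length(rates)) * branchChannels
  layers <- c(layers, list(
    layer_spec("concat", inChannels = concatChannels),
    layer_spec("conv", kernel = 1L, inChannels = concatChannels,
               outChannels = outChannels)))
  block_spec(name, "aspp", layers, inChannels, outChannels,
             countedLayers = 2L + length(rates),
             attrs = list(rates = rates,
                          branchChannels = as.integer(branchChannels)))
}

## ---- configuration constructors -------------------------------------------

#' Architecture configurations
#'
#' `archConfig()` with no arguments gives the proposed ASPP-FC-DenseNet:
#' growth rate 12, 4 layers per dense block, 4 transitions per path and an
#' ASPP bottleneck with rates 6/12/18 (47 counted layers).
#' `baselineArchConfig()` gives the FC-DenseNet56 baseline: 5 transitions and
#' a dense bottleneck (56 counted layers).
#'
#' @param growthRate,layersPerBlock,nTransitions,asppRates,useASPP,
#'   initialFeatures,asppBranchChannels,dropoutRate,nClasses,inputSide see
#'   [ArchConfig-class].
#' @return an [ArchConfig-class] object.
#' @examples
#' countLayers(assembleNetwork(archConfig()))          # 47
#' countLayers(assembleNetwork(baselineArchConfig()))  # 56
#' @export
archConfig <- function(growthRate = 12L, layersPerBlock = 4L,
                       nTransitions = 4L, asppRates = c(6L, 12L, 18L),
                       useASPP = TRUE, initialFeatures = 48L,
                       asppBranchChannels = layersPerBlock * growthRate,
                       dropoutRate = 0.2, nClasses = 2L, inputSide = 512L) {
  new("ArchConfig",
      growthRate = as.integer(growthRate),
      layersPerBlock = as.integer(layersPerBlock),
      nTransitions = as.integer(nTransitions),
      asppRates = as.integer(asppRates),
      useASPP = isTRUE(useASPP),
      initialFeatures = as.integer(initialFeatures),
      asppBranchChannels = as.integer(asppBranchChannels),
      dropoutRate = dropoutRate,
      nClasses = as.integer(nClasses),
      inputSide = as.integer(inputSide))
}

#' @rdname archConfig
#' @export
baselineArchConfig <- function(nTransitions = 5L, useASPP = FALSE, ...) {
  archConfig(nTransitions = nTransitions, useASPP = useASPP, ...)
}

#' Small configuration for desk-scale experiments
#'
#' Growth 4, 2 layers per block, 2 transitions, ASPP rates 2 and 4, 64-pixel
#' input: trains in minutes on one CPU while exercising every block kind.
#'
#' @param ... overrides passed to [archConfig()].
#' @export
tinyArchConfig <- function(...) {
  args <- list(growthRate = 4L, layersPerBlock = 2L, nTransitions = 2L,
               asppRates = c(2L, 4L), initialFeatures = 16L,
               inputSide = 64L)
  override <- list(...)
  args[names(override)] <- override
  do.call(archConfig, args)
}

## ---- assembly --------------------------------------------------------------

#' Assemble the full encoder-decoder network specification
#'
#' Initial 3x3 convolution, then per transition a dense block (whose output
#' is concatenated with its input on the downsampling path, forming the skip
#' tensor) followed by a transition down; the bottleneck (ASPP, or a dense
#' block for the baseline); then per transition a transition up, a
#' concatenation with the same-resolution skip tensor, and a dense block;
#' finally a 1x1 classifier convolution with softmax.
#'
#' @param config an [ArchConfig-class].
#' @return a [NetworkSpec-class] with complete channel and resolution
#'   bookkeeping.
#' @export
assembleNetwork <- function(config) {
  validObject(config)
  g <- config@growthRate; nl <- config@layersPerBlock
  t <- config@nTransitions
  side <- config@inputSide
  blocks <- list()
  skips <- data.frame(src = character(), dst = character())

  add <- function(b, inSide, outSide) {
    b$inSide <- as.integer(inSide); b$outSide <- as.integer(outSide)
    blocks[[length(blocks) + 1L]] <<- b
  }

  add(block_spec("initial", "initial_conv",
                 list(layer_spec("conv", kernel = 3L, inChannels = 1L,
                                 outChannels = config@initialFeatures)),
                 1L, config@initialFeatures, countedLayers = 1L),
      side, side)

  ch <- config@initialFeatures
  skipChannels <- integer(t)
  for (i in seq_len(t)) {
    db <- buildDenseBlock(ch, nl, g, config@dropoutRate,
                          name = sprintf("down%d.dense", i))
    # the skip tensor is concat(block input, block output)
    skipChannels[i] <- ch + db$outChannels
    add(db, side, side)
    td <- buildTransitionDown(skipChannels[i], config@dropoutRate,
                              name = sprintf("down%d.td", i))
    add(td, side, side %/% 2L)
    side <- side %/% 2L
    ch <- skipChannels[i]
  }

  if (config@useASPP) {
    bt <- buildASPP(ch, config@asppBranchChannels, config@asppRates,
                    outChannels = nl * g, featureSide = side,
                    name = "bottleneck")
  } else {
    bt <- buildDenseBlock(ch, nl, g, config@dropoutRate, name = "bottleneck")
  }
  add(bt, side, side)
  ch <- bt$outChannels

  for (i in seq_len(t)) {
    tu <- buildTransitionUp(ch, ch, name = sprintf("up%d.tu", i))
    add(tu, side, side * 2L)
    side <- side * 2L
    sc <- skipChannels[t + 1L - i]
    db <- buildDenseBlock(ch + sc, nl, g, config@dropoutRate,
                          name = sprintf("up%d.dense", i))
    add(db, side, side)
    skips <- rbind(skips, data.frame(
      src = sprintf("down%d.dense", t + 1L - i),
      dst = sprintf("up%d.dense", i)))
    ch <- db$outChannels
  }

  add(block_spec("classifier", "classifier",
                 list(layer_spec("conv", kernel = 1L, inChannels = ch,
                                 outChannels = config@nClasses),
                      layer_spec("softmax", inChannels = config@nClasses)),
                 ch, config@nClasses, countedLayers = 1L),
      side, side)

  spec <- new("NetworkSpec", blocks = blocks, skipEdges = skips,
              config = config)
  validateNetworkSpec(spec)
  spec
}

#' Structural validation of an assembled specification
#'
#' Checks the channel bookkeeping of every layer (declared in-channels equal
#' the concatenation arithmetic of its inputs), encoder/decoder symmetry
#' (equal numbers of transitions, mirrored resolution sequences, output
#' resolution equal to input resolution) and that every skip edge joins
#' blocks at equal spatial resolution.
#'
#' @param spec a [NetworkSpec-class].
#' @return invisibly TRUE; stops with a message on the first inconsistency.
#' @export
validateNetworkSpec <- function(spec) {
  b <- spec@blocks
  kinds <- vapply(b, `[[`, "", "kind")
  names(b) <- vapply(b, `[[`, "", "name")
  ntd <- sum(kinds == "transition_down"); ntu <- sum(kinds == "transition_up")
  if (ntd != ntu)
    stop("unbalanced transitions: ", ntd, " down vs ", ntu, " up")
  if (b[[1L]]$inSide != b[[length(b)]]$outSide)
    stop("output resolution differs from input resolution")
  downSides <- vapply(b[kinds == "transition_down"], `[[`, 0L, "outSide")
  upSides <- vapply(b[kinds == "transition_up"], `[[`, 0L, "inSide")
  if (!identical(unname(downSides), unname(rev(upSides))))
    stop("encoder and decoder resolution sequences are not mirrored")
  for (e in seq_len(nrow(spec@skipEdges))) {
    s <- b[[spec@skipEdges$src[e]]]; d <- b[[spec@skipEdges$dst[e]]]
    if (s$outSide != d$inSide)
      stop("skip edge ", spec@skipEdges$src[e], " -> ",
           spec@skipEdges$dst[e], " joins unequal resolutions")
  }
  # per-layer channel walk inside each block
  for (blk in b) {
    if (blk$kind == "dense_block") {
      for (i in seq_len(blk$attrs$nLayers)) {
        want <- blk$inChannels + (i - 1L) * blk$attrs$growth
        conv <- blk$layers[[(i - 1L) * 4L + 3L]]
        if (conv$inChannels != want)
          stop(blk$name, ": dense layer ", i, " declares ", conv$inChannels,
               " in-channels, concatenation arithmetic gives ", want)
      }
      if (blk$outChannels != blk$attrs$nLayers * blk$attrs$growth)
        stop(blk$name, ": output channels inconsistent")
    } else if (blk$kind == "aspp") {
      nb <- 1L + length(blk$attrs$rates)
      want <- blk$inChannels + nb * blk$attrs$branchChannels
      fuse <- blk$layers[[length(blk$layers)]]
      if (fuse$inChannels != want)
        stop(blk$name, ": fusion conv declares ", fuse$inChannels,
             " in-channels, concatenation arithmetic gives ", want)
    } else {
      prev <- blk$inChannels
      for (ly in blk$layers) {
        if (ly$kind %in% c("conv", "transposed_conv") &&
            ly$inChannels != prev)
          stop(blk$name, ": layer declares ", ly$inChannels,
               " in-channels, expected ", prev)
        prev <- ly$outChannels
      }
    }
  }
  invisible(TRUE)
}

#' Count learnable layers under the FC-DenseNet convention
#'
#' Counts the initial convolution, every dense-layer convolution, one layer
#' per transition (down or up), each ASPP convolution, and the final
#' classifier convolution. The proposed configuration gives 47; the
#' FC-DenseNet56 baseline gives 56.
#'
#' @param spec a [NetworkSpec-class] (an empty spec counts 0).
#' @return integer layer count.
#' @export
countLayers <- function(spec) {
  if (!length(spec@blocks)) return(0L)
  sum(vapply(spec@blocks, `[[`, 0L, "countedLayers"))
}

#' Overall downsampling factor of the encoder
#'
#' Product of all encoder strides; \code{2^nTransitions} (32 for the
#' 5-transition baseline, 16 for the proposed 4-transition network).
#'
#' @param spec a [NetworkSpec-class].
#' @return integer downsample factor.
#' @export
downsampleFactor <- function(spec) {
  if (!length(spec@blocks)) return(1L)
  f <- 1L
  for (blk in spec@blocks)
    if (blk$kind == "transition_down")
      for (ly in blk$layers)
        if (ly$kind == "conv") f <- f * ly$stride
  f
}

setMethod("show", "ArchConfig", function(object) {
  cat(sprintf(paste0(
    "ArchConfig: growth %d, %d layers/block, %d transitions, %s bottleneck\n",
    "  initial features %d, dropout %.2g, %d classes, input %dx%d\n"),
    object@growthRate, object@layersPerBlock, object@nTransitions,
    if (object@useASPP)
      paste0("ASPP[", paste(object@asppRates, collapse = ","), "]")
    else "dense",
    object@initialFeatures, object@dropoutRate, object@nClasses,
    object@inputSide, object@inputSide))
})

setMethod("show", "NetworkSpec", function(object) {
  cat("NetworkSpec with", length(object@blocks), "blocks,",
      countLayers(object), "counted layers, downsample factor",
      downsampleFactor(object), "\n")
  for (b in object@blocks)
    cat(sprintf("  %-14s %-15s %4d -> %4d ch   %4d -> %4d px\n",
                b$name, b$kind, b$inChannels, b$outChannels,
                b$inSide, b$outSide))
  if (nrow(object@skipEdges))
    cat("  skips:", paste(object@skipEdges$src, "->", object@skipEdges$dst,
                          collapse = ", "), "\n")
})

## ---- serialization ---------------------------------------------------------

#' Write / read a network specification as YAML
#'
#' The file stores the generating configuration plus the assembled block
#' table (kinds, channels, strides, dilations, counted layers, skip edges),
#' so architectures are diffable and pinnable in tests. Reading re-assembles
#' from the stored configuration and verifies the stored block table matches.
#'
#' @param spec a [NetworkSpec-class].
#' @param path file path.
#' @return `readNetworkSpec` returns the [NetworkSpec-class].
#' @export
writeNetworkSpec <- function(spec, path) {
  cfg <- spec@config
  doc <- list(
    config = list(growthRate = cfg@growthRate,
                  layersPerBlock = cfg@layersPerBlock,
                  nTransitions = cfg@nTransitions,
                  asppRates = as.list(cfg@asppRates),
                  useASPP = cfg@useASPP,
                  initialFeatures = cfg@initialFeatures,
                  asppBranchChannels = cfg@asppBranchChannels,
                  dropoutRate = cfg@dropoutRate,
                  nClasses = cfg@nClasses,
                  inputSide = cfg@inputSide),
    blocks = lapply(spec@blocks, function(b)
      list(name = b$name, kind = b$kind,
           inChannels = b$inChannels, outChannels = b$outChannels,
           inSide = b$inSide, outSide = b$outSide,
           countedLayers = b$countedLayers)),
    skipEdges = if (nrow(spec@skipEdges))
      lapply(seq_len(nrow(spec@skipEdges)), function(i)
        list(src = spec@skipEdges$src[i], dst = spec@skipEdges$dst[i]))
      else list())
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname writeNetworkSpec
#' @export
readNetworkSpec <- function(path) {
  doc <- yaml::read_yaml(path)
  cfg <- do.call(archConfig, c(
    doc$config[setdiff(names(doc$config), "asppRates")],
    list(asppRates = unlist(doc$config$asppRates))))
  spec <- assembleNetwork(cfg)
  stored <- vapply(doc$blocks, function(b)
    paste(b$name, b$kind, b$inChannels, b$outChannels, b$countedLayers),
    character(1))
  built <- vapply(spec@blocks, function(b)
    paste(b$name, b$kind, b$inChannels, b$outChannels, b$countedLayers),
    character(1))
  if (!identical(stored, built))
    stop("stored block table does not match re-assembled architecture")
  spec
}
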