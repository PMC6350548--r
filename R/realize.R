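# Binding a NetworkSpec to parameters and executing it.

he_uniform <- function(shape, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(shape), -lim, lim), shape)
}

bn_state <- function(c) {
  e <- new.env(parent = emptyenv())
  e$mean <- rep(0, c); e$var <- rep(1, c)
  e
}

add_conv_params <- function(net, name, k, cin, cout) {
  net$params[[paste0(name, ".w")]] <- he_uniform(c(k, k, cin, cout),
                                                 k * k * cin)
  net$params[[paste0(name, ".b")]] <- rep(0, cout)
}

add_bn_params <- function(net, name, c) {
  net$params[[paste0(name, ".gamma")]] <- rep(1, c)
  net$params[[paste0(name, ".beta")]] <- rep(0, c)
  net$state[[paste0(name, ".run")]] <- bn_state(c)
}

#' Realize a network specification into an executable network
#'
#' Allocates every parameter the spec declares (He-uniform convolution
#' weights scaled by fan-in, zero biases, identity-initialized batch norm)
#' under a fixed seed, so realization is fully reproducible.
#'
#' @param spec a [NetworkSpec-class].
#' @param seed integer seed for weight initialization.
#' @return a [RealizedNetwork-class].
#' @export
realizeNetwork <- function(spec, seed = 1L) {
  validateNetworkSpec(spec)
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$state <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in spec@blocks) {
    switch(b$kind,
      initial_conv = add_conv_params(net, paste0(b$name, ".conv"), 3L,
                                     b$inChannels, b$outChannels),
      classifier = add_conv_params(net, paste0(b$name, ".conv"), 1L,
                                   b$inChannels, b$outChannels),
      dense_block = {
        for (i in seq_len(b$attrs$nLayers)) {
          cin <- b$inChannels + (i - 1L) * b$attrs$growth
          pre <- sprintf("%s.d%d", b$name, i)
          add_bn_params(net, paste0(pre, ".bn"), cin)
          add_conv_params(net, paste0(pre, ".conv"), 3L, cin, b$attrs$growth)
        }
      },
      transition_down = {
        add_bn_params(net, paste0(b$name, ".bn"), b$inChannels)
        add_conv_params(net, paste0(b$name, ".conv1"), 1L, b$inChannels,
                        b$inChannels)
        add_conv_params(net, paste0(b$name, ".conv2"), 3L, b$inChannels,
                        b$inChannels)
      },
      transition_up = add_conv_params(net, paste0(b$name, ".tconv"), 3L,
                                      b$inChannels, b$outChannels),
      aspp = {
        add_conv_params(net, paste0(b$name, ".b0"), 1L, b$inChannels,
                        b$attrs$branchChannels)
        for (r in b$attrs$rates)
          add_conv_params(net, sprintf("%s.r%d", b$name, r), 3L,
                          b$inChannels, b$attrs$branchChannels)
        nb <- 1L + length(b$attrs$rates)
        add_conv_params(net, paste0(b$name, ".fuse"), 1L,
                        b$inChannels + nb * b$attrs$branchChannels,
                        b$outChannels)
      },
      stop("unknown block kind: ", b$kind))
  }
  new("RealizedNetwork", spec = spec, net = net, seed = as.integer(seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Total learnable parameter count
#' @param rn a [RealizedNetwork-class].
#' @return integer.
#' @export
nParameters <- function(rn) {
  sum(vapply(rn@net$params, length, integer(1)))
}

dense_block_forward <- function(tp, net, b, hin, training) {
  drop <- b$attrs$dropout %||% 0
  feats <- list(hin)
  outs <- list()
  for (i in seq_len(b$attrs$nLayers)) {
    pre <- sprintf("%s.d%d", b$name, i)
    h <- if (length(feats) == 1L) feats[[1L]] else ad_concat(tp, feats)
    h <- ad_bn(tp, net, h, paste0(pre, ".bn.gamma"), paste0(pre, ".bn.beta"),
               paste0(pre, ".bn.run"), training)
    h <- ad_relu(tp, h)
    h <- ad_conv(tp, net, h, paste0(pre, ".conv.w"), paste0(pre, ".conv.b"),
                 pad = 1L)
    h <- ad_dropout(tp, h, drop, training)
    feats <- c(feats, list(h))
    outs <- c(outs, list(h))
  }
  if (length(outs) == 1L) outs[[1L]] else ad_concat(tp, outs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Walk the spec and produce the logits handle (channel axis = classes).
# strict = TRUE refuses odd spatial sides at a transition down.
net_forward <- function(rn, x, training = FALSE, tape = NULL,
                        strict = TRUE) {
  net <- rn@net
  spec <- rn@spec
  x <- as_hwc(x)
  dsf <- 2L^spec@config@nTransitions
  if (dim(x)[1] %% dsf != 0L || dim(x)[2] %% dsf != 0L)
    stop("input sides ", dim(x)[1], "x", dim(x)[2],
         " must be divisible by the downsample factor ", dsf)
  tp <- tape
  h <- if (is.null(tp)) x else tp_leaf(tp, x)
  skipStore <- list()
  for (b in spec@blocks) {
    switch(b$kind,
      initial_conv = {
        h <- ad_conv(tp, net, h, paste0(b$name, ".conv.w"),
                     paste0(b$name, ".conv.b"), pad = 1L)
      },
      dense_block = {
        isDown <- grepl("^down", b$name)
        isUp <- grepl("^up", b$name)
        if (isUp) {
          e <- spec@skipEdges
          src <- e$src[e$dst == b$name]
          h <- ad_concat(tp, list(h, skipStore[[src]]))
        }
        hin <- h
        hout <- dense_block_forward(tp, net, b, hin, training)
        if (isDown) {
          h <- ad_concat(tp, list(hin, hout))
          skipStore[[b$name]] <- h
        } else {
          h <- hout
        }
      },
      transition_down = {
        side <- dim(as_hwc(tp_val(tp, h)))[1]
        if (strict && side %% 2L != 0L)
          stop("odd spatial side ", side, " at ", b$name,
               " under strict same-padding stride-2")
        drop <- b$attrs$dropout %||% 0
        h <- ad_bn(tp, net, h, paste0(b$name, ".bn.gamma"),
                   paste0(b$name, ".bn.beta"), paste0(b$name, ".bn.run"),
                   training)
        h <- ad_relu(tp, h)
        h <- ad_conv(tp, net, h, paste0(b$name, ".conv1.w"),
                     paste0(b$name, ".conv1.b"))
        h <- ad_dropout(tp, h, drop, training)
        h <- ad_conv(tp, net, h, paste0(b$name, ".conv2.w"),
                     paste0(b$name, ".conv2.b"), stride = 2L, pad = 1L)
      },
      transition_up = {
        h <- ad_tconv(tp, net, h, paste0(b$name, ".tconv.w"),
                      paste0(b$name, ".tconv.b"))
      },
      aspp = {
        hin <- h
        branches <- list(hin,
          ad_conv(tp, net, hin, paste0(b$name, ".b0.w"),
                  paste0(b$name, ".b0.b")))
        for (r in b$attrs$rates)
          branches <- c(branches, list(
            ad_conv(tp, net, hin, sprintf("%s.r%d.w", b$name, r),
                    sprintf("%s.r%d.b", b$name, r),
                    dilation = r, pad = r)))
        h <- ad_concat(tp, branches)
        h <- ad_conv(tp, net, h, paste0(b$name, ".fuse.w"),
                     paste0(b$name, ".fuse.b"))
      },
      classifier = {
        h <- ad_conv(tp, net, h, paste0(b$name, ".conv.w"),
                     paste0(b$name, ".conv.b"))
      })
  }
  h
}

#' Run a forward pass and return per-pixel class probabilities
#'
#' @param rn a [RealizedNetwork-class].
#' @param image numeric matrix (or H x W x 1 array); sides must be divisible
#'   by the network's downsample factor.
#' @param training logical; TRUE uses batch statistics and active dropout.
#' @return array \code{H x W x nClasses}; each pixel's probabilities sum
#'   to 1.
#' @export
forwardPass <- function(rn, image, training = FALSE) {
  logits <- net_forward(rn, image, training = training, tape = NULL)
  softmax_hwc(logits)
}
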