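# Low-level CPU tensor kernels for the network backend.
#
# Feature maps are dense arrays of dim c(H, W, C) (single image, batch size 1
# throughout -- the training protocol uses batch 1). Convolution is implemented
# as im2col + BLAS matrix multiply; the transposed convolution is the exact
# adjoint of the strided convolution, which is what makes the stride-2 decoder
# invert the stride-2 encoder spatially.

as_hwc <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 3L)
  x
}

pad_hwc <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  out
}

unpad_hwc <- function(x, pad, h, w) {
  if (pad == 0L) return(x)
  x[(pad + 1L):(pad + h), (pad + 1L):(pad + w), , drop = FALSE]
}

#' @noRd
conv_out_side <- function(side, k, stride, dilation, pad) {
  keff <- k + (k - 1L) * (dilation - 1L)
  (side + 2L * pad - keff) %/% stride + 1L
}

# Linear spatial indices into the padded plane for every (output position, tap)
# pair. Rows ordered output-row fastest (matching column-major [H, W] layout),
# columns ordered kernel-row fastest (matching as.vector of a [k, k, ...] array).
im2col_index <- function(hp, wp, k, stride, dilation, hout, wout) {
  or <- seq.int(1L, by = stride, length.out = hout)
  oc <- seq.int(1L, by = stride, length.out = wout)
  base <- as.vector(outer(or, (oc - 1L) * hp, "+"))
  taps <- as.vector(outer(0L:(k - 1L) * dilation,
                          (0L:(k - 1L)) * dilation * hp, "+"))
  outer(base, taps, "+")
}

# Forward convolution (cross-correlation, the deep-learning convention).
# x: [H, W, Cin]; w: [k, k, Cin, Cout]; b: length-Cout or NULL.
# Returns list(out, cols, idx, pdim) -- cols/idx retained for the backward pass
# unless keep = FALSE (inference).
conv_fwd <- function(x, w, b = NULL, stride = 1L, dilation = 1L,
                     pad = 0L, keep = TRUE) {
  x <- as_hwc(x)
  d <- dim(x); k <- dim(w)[1]
  stopifnot(dim(w)[2] == k, dim(w)[3] == d[3])
  cout <- dim(w)[4]
  hout <- conv_out_side(d[1], k, stride, dilation, pad)
  wout <- conv_out_side(d[2], k, stride, dilation, pad)
  if (hout < 1L || wout < 1L)
    stop("convolution output would be empty: input ", d[1], "x", d[2],
         " with effective kernel ", k + (k - 1L) * (dilation - 1L))
  xp <- pad_hwc(x, pad)
  pd <- dim(xp)
  idx <- im2col_index(pd[1], pd[2], k, stride, dilation, hout, wout)
  flat <- xp; dim(flat) <- c(pd[1] * pd[2], pd[3])
  cols <- flat[as.vector(idx), , drop = FALSE]
  dim(cols) <- c(hout * wout, k * k * d[3])
  out <- cols %*% matrix(w, k * k * d[3], cout)
  if (!is.null(b)) out <- out + rep(b, each = hout * wout)
  dim(out) <- c(hout, wout, cout)
  res <- list(out = out, hin = d[1], win = d[2], cin = d[3],
              k = k, stride = stride, dilation = dilation, pad = pad,
              pdim = pd)
  if (keep) { res$cols <- cols; res$idx <- idx }
  res
}

# Scatter-accumulate column gradients back onto the (padded) input plane.
# dcols: [npos, k*k*Cin]; returns [H, W, Cin] gradient.
col2im <- function(dcols, idx, pdim, pad, hin, win, k, cin) {
  gp <- matrix(0, pdim[1] * pdim[2], cin)
  kk <- k * k
  for (t in seq_len(kk)) {
    cols_t <- dcols[, t + kk * (seq_len(cin) - 1L), drop = FALSE]
    ii <- idx[, t]
    gp[ii, ] <- gp[ii, ] + cols_t
  }
  dim(gp) <- c(pdim[1], pdim[2], cin)
  unpad_hwc(gp, pad, hin, win)
}

# Backward pass of conv_fwd. g: gradient at the output, [Hout, Wout, Cout].
conv_bwd <- function(g, f, w, need_dx = TRUE) {
  cout <- dim(w)[4]
  gm <- g; dim(gm) <- c(prod(dim(g)[1:2]), cout)
  wm <- matrix(w, , cout)
  dw <- crossprod(f$cols, gm)
  dim(dw) <- dim(w)
  db <- colSums(gm)
  dx <- NULL
  if (need_dx) {
    dcols <- tcrossprod(gm, wm)
    dx <- col2im(dcols, f$idx, f$pdim, f$pad, f$hin, f$win, f$k, f$cin)
  }
  list(dx = dx, dw = dw, db = db)
}

# Gradient of a convolution with respect to its *input*, given only the output
# gradient -- also the forward map of the transposed convolution.
conv_input_grad <- function(g, w, hin, win, stride = 1L, dilation = 1L,
                            pad = 0L) {
  g <- as_hwc(g)
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  stopifnot(dim(g)[3] == cout)
  hp <- hin + 2L * pad; wp <- win + 2L * pad
  hout <- dim(g)[1]; wout <- dim(g)[2]
  idx <- im2col_index(hp, wp, k, stride, dilation, hout, wout)
  gm <- g; dim(gm) <- c(hout * wout, cout)
  dcols <- tcrossprod(gm, matrix(w, , cout))
  col2im(dcols, idx, c(hp, wp, cin), pad, hin, win, k, cin)
}

# Transposed convolution, stride 2, kernel 3, exact spatial doubling
# (the adjoint of a k=3 / stride=2 / pad=1 convolution mapping 2H -> H).
# w: [k, k, Cin, Cout] where Cin = channels of x.
tconv_fwd <- function(x, w, b = NULL, stride = 2L, pad = 1L) {
  x <- as_hwc(x)
  d <- dim(x)
  v <- aperm(w, c(1, 2, 4, 3))            # weights of the adjoint convolution
  out <- conv_input_grad(x, v, d[1] * stride, d[2] * stride,
                         stride = stride, pad = pad)
  if (!is.null(b)) out <- out + rep(b, each = prod(dim(out)[1:2]))
  out
}

tconv_bwd <- function(g, x, w, stride = 2L, pad = 1L) {
  x <- as_hwc(x); g <- as_hwc(g)
  v <- aperm(w, c(1, 2, 4, 3))
  fg <- conv_fwd(g, v, NULL, stride = stride, pad = pad, keep = TRUE)
  dx <- fg$out
  xm <- x; dim(xm) <- c(prod(dim(x)[1:2]), dim(x)[3])
  dv <- crossprod(fg$cols, xm)
  dim(dv) <- dim(v)
  db <- colSums(matrix(g, , dim(g)[3]))
  list(dx = dx, dw = aperm(dv, c(1, 2, 4, 3)), db = db)
}

# Channel-wise batch normalization over the spatial plane (batch size 1).
bn_fwd <- function(x, gamma, beta, running, training, momentum = 0.1,
                   eps = 1e-5) {
  x <- as_hwc(x)
  d <- dim(x); m <- d[1] * d[2]
  xm <- x; dim(xm) <- c(m, d[3])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    va <- colSums(xc * xc) / m
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var  <- (1 - momentum) * running$var  + momentum * va
  } else {
    mu <- running$mean; va <- running$var
    xc <- sweep(xm, 2, mu)
  }
  isd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, isd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  dim(y) <- d
  list(out = y, xhat = xhat, isd = isd, m = m, d = d)
}

bn_bwd <- function(g, f, gamma) {
  gm <- g; dim(gm) <- c(f$m, f$d[3])
  dgamma <- colSums(gm * f$xhat)
  dbeta <- colSums(gm)
  dxhat <- sweep(gm, 2, gamma, "*")
  # dx = isd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * f$xhat)
  dx <- sweep(f$m * dxhat, 2, s1) - sweep(f$xhat, 2, s2, "*")
  dx <- sweep(dx, 2, f$isd / f$m, "*")
  dim(dx) <- f$d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Per-pixel softmax over the channel axis, numerically stabilized.
softmax_hwc <- function(z) {
  z <- as_hwc(z)
  d <- dim(z)
  zm <- z; dim(zm) <- c(d[1] * d[2], d[3])
  zm <- zm - apply(zm, 1, max)
  e <- exp(zm)
  p <- e / rowSums(e)
  dim(p) <- d
  p
}
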