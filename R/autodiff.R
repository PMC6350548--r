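# Minimal reverse-mode tape.
#
# A "handle" is an integer node id when a tape is active, or the raw value
# when tape = NULL (pure inference: nothing is recorded or cached).
# Parameters live in net$params (named arrays); each op that owns parameters
# registers them as leaves the first time it touches them on a given tape,
# so parameter gradients can be collected by name after the backward sweep.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$ops <- list()
  tp$pids <- list()      # parameter name -> leaf id
  tp
}

tp_leaf <- function(tp, val) {
  id <- length(tp$vals) + 1L
  tp$vals[[id]] <- val
  id
}

tp_val <- function(tp, h) if (is.null(tp)) h else tp$vals[[h]]

# Record an op: ins is an integer vector of parent ids, bw(g) must return a
# list of gradients aligned with ins (NULL entries allowed).
tp_record <- function(tp, val, ins, bw) {
  id <- tp_leaf(tp, val)
  tp$ops[[length(tp$ops) + 1L]] <- list(out = id, ins = ins, bw = bw)
  id
}

tp_param <- function(tp, net, name) {
  id <- tp$pids[[name]]
  if (is.null(id)) {
    id <- tp_leaf(tp, net$params[[name]])
    tp$pids[[name]] <- id
  }
  id
}

# Backward sweep from a scalar loss node. Returns list(grads = by node id,
# param_grads = by parameter name).
tp_backward <- function(tp, loss_id) {
  grads <- vector("list", length(tp$vals))
  grads[[loss_id]] <- 1
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
    grads[op$out] <- list(NULL)      # free memory; keep list length stable
  }
  pg <- lapply(tp$pids, function(id) grads[[id]])
  list(grads = grads, param_grads = pg)
}

## ---- tape-aware ops --------------------------------------------------------

ad_conv <- function(tp, net, hx, wname, bname, stride = 1L, dilation = 1L,
                    pad = 0L) {
  x <- tp_val(tp, hx)
  w <- net$params[[wname]]; b <- net$params[[bname]]
  f <- conv_fwd(x, w, b, stride = stride, dilation = dilation, pad = pad,
                keep = !is.null(tp))
  if (is.null(tp)) return(f$out)
  ins <- c(hx, tp_param(tp, net, wname), tp_param(tp, net, bname))
  tp_record(tp, f$out, ins, function(g) {
    bw <- conv_bwd(g, f, w)
    list(bw$dx, bw$dw, bw$db)
  })
}

ad_tconv <- function(tp, net, hx, wname, bname) {
  x <- tp_val(tp, hx)
  w <- net$params[[wname]]; b <- net$params[[bname]]
  out <- tconv_fwd(x, w, b)
  if (is.null(tp)) return(out)
  ins <- c(hx, tp_param(tp, net, wname), tp_param(tp, net, bname))
  tp_record(tp, out, ins, function(g) {
    bw <- tconv_bwd(g, x, w)
    list(bw$dx, bw$dw, bw$db)
  })
}

ad_bn <- function(tp, net, hx, gname, bname, rname, training) {
  x <- tp_val(tp, hx)
  gamma <- net$params[[gname]]; beta <- net$params[[bname]]
  f <- bn_fwd(x, gamma, beta, net$state[[rname]], training = training)
  if (is.null(tp)) return(f$out)
  ins <- c(hx, tp_param(tp, net, gname), tp_param(tp, net, bname))
  tp_record(tp, f$out, ins, function(g) {
    bw <- bn_bwd(g, f, gamma)
    list(bw$dx, bw$dgamma, bw$dbeta)
  })
}

ad_relu <- function(tp, hx) {
  x <- tp_val(tp, hx)
  out <- pmax(x, 0)
  if (is.null(tp)) return(out)
  tp_record(tp, out, hx, function(g) list(g * (x > 0)))
}

# Inverted dropout: scales kept units by 1/(1-rate) so inference needs no
# rescaling. Draws from the current RNG stream (seeded by the caller).
ad_dropout <- function(tp, hx, rate, training) {
  x <- tp_val(tp, hx)
  if (!training || rate <= 0) {
    if (is.null(tp)) return(x)
    return(tp_record(tp, x, hx, function(g) list(g)))
  }
  mask <- array(stats::rbinom(length(x), 1L, 1 - rate), dim(x)) / (1 - rate)
  out <- x * mask
  if (is.null(tp)) return(out)
  tp_record(tp, out, hx, function(g) list(g * mask))
}

ad_concat <- function(tp, hs) {
  xs <- lapply(hs, function(h) as_hwc(tp_val(tp, h)))
  ch <- vapply(xs, function(x) dim(x)[3], integer(1))
  out <- array(0, c(dim(xs[[1]])[1:2], sum(ch)))
  at <- 0L
  for (x in xs) { out[, , at + seq_len(dim(x)[3])] <- x; at <- at + dim(x)[3] }
  if (is.null(tp)) return(out)
  tp_record(tp, out, as.integer(hs), function(g) {
    gs <- vector("list", length(ch))
    pos <- 0L
    for (j in seq_along(ch)) {
      gs[[j]] <- g[, , pos + seq_len(ch[j]), drop = FALSE]
      pos <- pos + ch[j]
    }
    gs
  })
}

ad_softmax <- function(tp, hx) {
  x <- tp_val(tp, hx)
  p <- softmax_hwc(x)
  if (is.null(tp)) return(p)
  tp_record(tp, p, hx, function(g) {
    d <- dim(p)
    pm <- p; dim(pm) <- c(d[1] * d[2], d[3])
    gm <- g; dim(gm) <- c(d[1] * d[2], d[3])
    dx <- pm * (gm - rowSums(gm * pm))
    dim(dx) <- d
    list(dx)
  })
}
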