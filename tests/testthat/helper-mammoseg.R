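# Shared fixtures and independent oracles (kept deliberately naive: loops
# and set operations, no shared code with the implementation under test).

# O(n^4) cross-correlation with stride/dilation/zero padding
naive_conv2d <- function(x, w, stride = 1L, dilation = 1L, pad = 0L) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  d <- dim(x); k <- dim(w)[1]; cout <- dim(w)[4]
  xp <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  keff <- k + (k - 1) * (dilation - 1)
  ho <- (dim(xp)[1] - keff) %/% stride + 1
  wo <- (dim(xp)[2] - keff) %/% stride + 1
  out <- array(0, c(ho, wo, cout))
  for (oi in seq_len(ho)) for (oj in seq_len(wo)) for (co in seq_len(cout)) {
    s <- 0
    for (a in 0:(k - 1)) for (b in 0:(k - 1)) for (ci in seq_len(d[3]))
      s <- s + xp[(oi - 1) * stride + 1 + a * dilation,
                  (oj - 1) * stride + 1 + b * dilation, ci] *
               w[a + 1, b + 1, ci, co]
    out[oi, oj, co] <- s
  }
  out
}

# per-pixel loop evaluation of the weighted cross-entropy definition
wce_loop_oracle <- function(probs, labels, freqs) {
  n <- length(labels)
  total <- 0
  for (i in seq_len(nrow(labels))) for (j in seq_len(ncol(labels))) {
    y <- labels[i, j]
    p <- max(probs[i, j, y + 1], 1e-7)
    total <- total + (1 / freqs[y + 1]) * log(p)
  }
  unname(-total / n)
}

# metrics from explicit pixel index sets
set_metrics_oracle <- function(pred, truth) {
  P <- which(pred > 0); G <- which(truth > 0)
  i <- length(intersect(P, G))
  list(DI = 2 * i / (length(P) + length(G)),
       PA = i / length(G),
       IOU = i / length(union(P, G)))
}

micro_arch <- function(...) {
  archConfig(growthRate = 2L, layersPerBlock = 1L, nTransitions = 1L,
             asppRates = 2L, initialFeatures = 3L, dropoutRate = 0,
             inputSide = 16L, ...)
}

random_probs <- function(h, w, k = 2L) {
  z <- array(stats::runif(h * w * k), c(h, w, k))
  s <- apply(z, c(1, 2), sum)
  sweep(z, c(1, 2), s, "/")
}
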