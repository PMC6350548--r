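# The CPU tensor backend against independent oracles: naive loop
# convolution, explicit zero-inserted kernels, and central differences.

test_that("backend convolution matches the naive loop oracle", {
  set.seed(101)
  for (rep in 1:5) {
    x <- array(rnorm(7 * 9 * 2), c(7, 9, 2))
    w <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
    for (cfg in list(list(s = 1L, d = 1L, p = 1L),
                     list(s = 2L, d = 1L, p = 1L),
                     list(s = 1L, d = 2L, p = 2L))) {
      got <- mammoseg:::conv_fwd(x, w, NULL, stride = cfg$s,
                                 dilation = cfg$d, pad = cfg$p)$out
      want <- naive_conv2d(x, w, cfg$s, cfg$d, cfg$p)
      expect_lt(max(abs(got - want)), 1e-10)
    }
  }
})

test_that("atrous convolution equals standard convolution with the
           zero-inserted kernel", {
  set.seed(202)
  for (r in c(1L, 2L, 3L, 6L)) {
    K <- matrix(rnorm(9), 3, 3)
    D <- dilateKernel(K, r)
    keff <- effectiveKernelSize(3L, r)
    side <- 2L * keff + 3L
    x <- matrix(rnorm(side * side), side, side)
    atrous <- mammoseg:::conv_fwd(x, array(K, c(3, 3, 1, 1)), NULL,
                                  dilation = r, pad = (keff - 1L) %/% 2L)$out
    plain <- mammoseg:::conv_fwd(x, array(D, c(keff, keff, 1, 1)), NULL,
                                 pad = (keff - 1L) %/% 2L)$out
    expect_lt(max(abs(atrous - plain)), 1e-10)
  }
})

test_that("convolution and transposed-convolution gradients match central
           differences", {
  set.seed(303)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  b <- rnorm(2)
  tgt <- naive_conv2d(x, w, 2L, 1L, 1L) * 0 + rnorm(18)
  f <- mammoseg:::conv_fwd(x, w, b, stride = 2L, pad = 1L)
  bw <- mammoseg:::conv_bwd(array(tgt, dim(f$out)), f, w)
  num <- function(get, set, ref) {
    g <- ref * 0
    for (i in seq_along(ref)) {
      e <- 1e-5
      set(i, ref[i] + e)
      lp <- sum(mammoseg:::conv_fwd(x, w, b, stride = 2L, pad = 1L)$out * tgt)
      set(i, ref[i] - e)
      lm <- sum(mammoseg:::conv_fwd(x, w, b, stride = 2L, pad = 1L)$out * tgt)
      set(i, ref[i])
      g[i] <- (lp - lm) / (2 * e)
    }
    g
  }
  gw <- num(NULL, function(i, v) w[i] <<- v, w)
  expect_lt(max(abs(bw$dw - gw)), 1e-6)
  gx <- num(NULL, function(i, v) x[i] <<- v, x)
  expect_lt(max(abs(bw$dx - gx)), 1e-6)

  # transposed convolution: exact doubling and adjoint identity
  xt <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
  wt <- array(rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  yt <- mammoseg:::tconv_fwd(xt, wt, NULL)
  expect_identical(dim(yt), c(8L, 10L, 3L))
  # <conv(z), x> == <z, tconv(x)> for the paired strided convolution
  z <- array(rnorm(8 * 10 * 3), c(8, 10, 3))
  v <- aperm(wt, c(1, 2, 4, 3))
  lhs <- sum(mammoseg:::conv_fwd(z, v, NULL, stride = 2L, pad = 1L)$out * xt)
  expect_equal(lhs, sum(z * yt), tolerance = 1e-10)
})

test_that("realized networks emit valid probability fields with the
           spec's shapes", {
  spec <- assembleNetwork(micro_arch())
  rn <- realizeNetwork(spec, seed = 9)
  x <- matrix(rnorm(64), 8, 8)
  p <- forwardPass(rn, x)
  expect_identical(dim(p), c(8L, 8L, 2L))
  expect_true(all(p >= 0))
  expect_equal(max(abs(apply(p, c(1, 2), sum) - 1)), 0, tolerance = 1e-12)
  # same seed -> identical parameters; different seed -> different
  rn2 <- realizeNetwork(spec, seed = 9)
  expect_identical(rn@net$params, rn2@net$params)
  rn3 <- realizeNetwork(spec, seed = 10)
  expect_false(identical(rn@net$params, rn3@net$params))
  # input not divisible by the downsample factor is refused
  expect_error(forwardPass(rn, matrix(0, 9, 9)), "divisible")
})

test_that("a mid-sized assembled network maps input side to output side", {
  cfg <- archConfig(inputSide = 128L)
  rn <- realizeNetwork(suppressWarnings(assembleNetwork(cfg)), seed = 1)
  p <- forwardPass(rn, matrix(rnorm(128 * 128), 128, 128))
  expect_identical(dim(p), c(128L, 128L, 2L))
  expect_equal(range(apply(p, c(1, 2), sum)), c(1, 1), tolerance = 1e-9)
})
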