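test_that("class frequencies count pixels and handle absent classes", {
  m <- matrix(0L, 10, 10); m[1, 1:10] <- 1L
  f <- classFrequencies(m)
  expect_equal(unname(f), c(0.9, 0.1))
  expect_equal(sum(f), 1)
  half <- matrix(rep(0:1, 50), 10, 10)
  expect_equal(unname(classFrequencies(half)), c(0.5, 0.5))
  # tumor-free mask: tumor frequency floored, background ~ 1
  empty <- matrix(0L, 8, 8)
  fe <- classFrequencies(empty)
  expect_gt(fe["1"], 0)
  expect_equal(unname(fe["1"]), 1e-4)
  expect_equal(sum(fe), 1)
  expect_error(classFrequencies(matrix(integer(), 0, 0)), "empty")
  expect_error(classFrequencies(matrix(3L, 2, 2)), "labels")
})

test_that("weighted cross-entropy reproduces the hand-computed example", {
  # 4 pixels: 3 background + 1 tumor, f = (0.75, 0.25), all true-class
  # probabilities 0.5 -> -(1/4)(3/0.75 + 1/0.25) ln 0.5 = 2 ln 2
  labels <- matrix(c(0L, 0L, 0L, 1L), 2, 2)
  probs <- array(0.5, c(2, 2, 2))
  out <- weightedCrossEntropy(probs, labels)
  expect_equal(out$value, 2 * log(2), tolerance = 1e-12)
  expect_identical(out$nPixels, 4L)
  # perfect predictions give zero loss
  perfect <- array(0, c(2, 2, 2))
  perfect[, , 1] <- (labels == 0L); perfect[, , 2] <- (labels == 1L)
  expect_equal(weightedCrossEntropy(perfect, labels)$value, 0)
  expect_equal(crossEntropy(perfect, labels)$value, 0)
  # single pixel at p = 0.5 under plain CE
  expect_equal(crossEntropy(array(c(0.5, 0.5), c(1, 1, 2)),
                            matrix(1L))$value, log(2))
})

test_that("uniform frequencies make weighted CE exactly twice plain CE", {
  set.seed(7)
  labels <- matrix(rbinom(64, 1, 0.5), 8, 8)
  probs <- random_probs(8, 8)
  w <- weightedCrossEntropy(probs, labels, freqs = c("0" = 0.5, "1" = 0.5))
  u <- crossEntropy(probs, labels)
  expect_equal(w$value, 2 * u$value, tolerance = 1e-12)
})

test_that("weighted CE matches a per-pixel loop oracle on random fields", {
  set.seed(77)
  for (rep in 1:10) {
    labels <- matrix(rbinom(64, 1, runif(1, 0.05, 0.5)), 8, 8)
    probs <- random_probs(8, 8)
    f <- classFrequencies(labels)
    expect_equal(weightedCrossEntropy(probs, labels, f)$value,
                 wce_loop_oracle(probs, labels, f), tolerance = 1e-6)
  }
})

test_that("soft Dice loss matches closed-form cases", {
  labels <- matrix(0L, 10, 10); labels[1, 1:10] <- 1L
  # uniform p = 0.5 with 10 of 100 foreground, s = 0: 1 - 10/60 = 5/6
  probs <- array(0.5, c(10, 10, 2))
  expect_equal(diceLoss(probs, labels, smooth = 0)$value, 5 / 6)
  # perfect hard prediction -> ~0; complete miss -> ~1 (s -> 0)
  hard <- array(0, c(10, 10, 2))
  hard[, , 2] <- labels; hard[, , 1] <- 1 - labels
  expect_lt(diceLoss(hard, labels)$value, 0.05)
  miss <- array(0, c(10, 10, 2))
  miss[, , 2] <- 1 - labels; miss[, , 1] <- labels
  expect_equal(diceLoss(miss, labels, smooth = 1e-9)$value, 1,
               tolerance = 1e-6)
})

test_that("all losses are nonnegative and decrease as true-class
           probability rises", {
  set.seed(11)
  labels <- matrix(rbinom(36, 1, 0.3), 6, 6)
  onehot <- array(0, c(6, 6, 2))
  onehot[, , 2] <- labels; onehot[, , 1] <- 1 - labels
  base <- random_probs(6, 6)
  for (a in c(0.2, 0.5, 0.8)) {
    # nested family: closer to the one-hot truth as a grows
    pa <- (1 - a) * base + a * onehot
    pb <- (1 - a - 0.15) * base + (a + 0.15) * onehot
    for (fn in list(function(p) weightedCrossEntropy(p, labels)$value,
                    function(p) crossEntropy(p, labels)$value,
                    function(p) diceLoss(p, labels)$value)) {
      expect_gte(fn(pa), 0)
      expect_lt(fn(pb), fn(pa))
    }
  }
})

test_that("inverse-frequency weighting scales gradients by the frequency
           ratio", {
  # two pixels, one per class, f_tumor = 0.01: the tumor pixel's logit
  # gradient must be 99x the background pixel's at equal predicted
  # probability
  labels <- matrix(c(0L, 1L), 1, 2)
  logits <- array(0, c(1, 2, 2))       # both pixels predict 0.5/0.5
  fused <- mammoseg:::softmax_ce_fused(logits, labels,
                                       c("0" = 0.99, "1" = 0.01))
  gbg <- max(abs(fused$grad[1, 1, ]))
  gtum <- max(abs(fused$grad[1, 2, ]))
  expect_equal(gtum / gbg, 99, tolerance = 1e-9)
})

test_that("fused training losses agree with the reference definitions", {
  set.seed(13)
  labels <- matrix(rbinom(48, 1, 0.25), 6, 8)
  logits <- array(rnorm(96), c(6, 8, 2))
  p <- mammoseg:::softmax_hwc(logits)
  f <- classFrequencies(labels)
  fused <- mammoseg:::softmax_ce_fused(logits, labels, f)
  expect_equal(fused$value, weightedCrossEntropy(p, labels, f)$value,
               tolerance = 1e-10)
  plain <- mammoseg:::softmax_ce_fused(logits, labels, NULL)
  expect_equal(plain$value, crossEntropy(p, labels)$value,
               tolerance = 1e-10)
  dd <- mammoseg:::dice_fused(p, labels)
  expect_equal(dd$value, diceLoss(p, labels)$value, tolerance = 1e-10)
})
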