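test_that("effective kernel size follows the atrous enlargement formula", {
  expect_identical(effectiveKernelSize(3, 2), 5L)
  expect_identical(effectiveKernelSize(3, 1), 3L)
  expect_identical(effectiveKernelSize(3, 3), 7L)
  # support of the explicitly zero-inserted kernel agrees for k in {1,3,5}
  for (k in c(1L, 3L, 5L)) for (r in 1:6) {
    K <- matrix(seq_len(k * k), k, k)
    expect_identical(nrow(dilateKernel(K, r)), effectiveKernelSize(k, r))
  }
  expect_error(effectiveKernelSize(2, 2), "odd")
  expect_error(effectiveKernelSize(-3, 2), "odd")
  expect_error(effectiveKernelSize(3, 0), "positive")
})

test_that("kernel dilation inserts exact zeros at non-tap positions", {
  K <- matrix(1, 3, 3)
  D <- dilateKernel(K, 2)
  expect_identical(dim(D), c(5L, 5L))
  expect_identical(sum(D == 1), 9L)
  expect_identical(sum(D == 0), 16L)
  # taps sit at positions that are multiples of the rate
  expect_true(all(D[seq(1, 5, 2), seq(1, 5, 2)] == 1))
  # identity cases
  K2 <- matrix(rnorm(9), 3, 3)
  expect_identical(dilateKernel(K2, 1), K2)
  K1 <- matrix(2, 1, 1)
  expect_identical(dilateKernel(K1, 5), K1)
  expect_error(dilateKernel(matrix(1, 2, 3), 2), "square")
})

test_that("dense block concatenation arithmetic is exact", {
  b <- buildDenseBlock(48L, 4L, 12L)
  expect_identical(b$outChannels, 48L)
  convs <- Filter(function(l) l$kind == "conv", b$layers)
  expect_length(convs, 4L)
  expect_identical(convs[[3]]$inChannels, 72L)  # 48 + 2 * 12
  expect_identical(b$countedLayers, 4L)
  b1 <- buildDenseBlock(10L, 1L, 7L)
  expect_identical(b1$outChannels, 7L)
  b2 <- buildDenseBlock(112L, 4L, 12L)
  expect_identical(sum(vapply(b2$layers, function(l) l$kind == "conv",
                              NA)), 4L)
})

test_that("transitions conserve channels and count as one layer each", {
  td <- buildTransitionDown(100L)
  expect_identical(td$outChannels, 100L)
  expect_identical(td$countedLayers, 1L)
  # both the channel-conserving 1x1 and the stride-2 3x3 conv are present
  convs <- Filter(function(l) l$kind == "conv", td$layers)
  expect_length(convs, 2L)
  expect_identical(convs[[1]]$kernel, 1L)
  expect_identical(convs[[2]]$stride, 2L)
  tu <- buildTransitionUp(48L, 48L)
  expect_identical(tu$countedLayers, 1L)
  expect_identical(tu$layers[[1]]$kind, "transposed_conv")
  expect_identical(tu$layers[[1]]$stride, 2L)
})

test_that("ASPP block has one 1x1 + one branch per rate + fusion conv", {
  b <- buildASPP(240L, 48L, c(6L, 12L, 18L))
  expect_identical(b$countedLayers, 5L)
  fuse <- b$layers[[length(b$layers)]]
  expect_identical(fuse$inChannels, 240L + 4L * 48L)
  expect_error(buildASPP(10L, 4L, c(12L, 6L)), "increasing")
  expect_warning(buildASPP(10L, 4L, c(2L, 30L), featureSide = 16L),
                 "larger than")
  # rate-1 branch degenerates to a standard 3x3 convolution spec
  b1 <- buildASPP(10L, 4L, 1L)
  atrous <- b1$layers[[2]]
  expect_identical(atrous$dilation, 1L)
  expect_identical(atrous$kernel, 3L)
})

test_that("assembled architectures reproduce the published layer totals", {
  proposed <- suppressWarnings(assembleNetwork(archConfig()))
  baseline <- assembleNetwork(baselineArchConfig())
  expect_identical(countLayers(proposed), 47L)
  expect_identical(countLayers(baseline), 56L)
  expect_identical(countLayers(proposed) - countLayers(baseline), -9L)
  expect_identical(downsampleFactor(proposed), 16L)
  expect_identical(downsampleFactor(baseline), 32L)
  expect_identical(countLayers(new("NetworkSpec")), 0L)
  # spatial symmetry: network output side equals input side
  blocks <- proposed@blocks
  expect_identical(blocks[[1]]$inSide, blocks[[length(blocks)]]$outSide)
  expect_true(validateNetworkSpec(proposed))
  expect_true(validateNetworkSpec(baseline))
})

test_that("configuration invariants are enforced", {
  expect_error(archConfig(inputSide = 100L), "divisible")
  expect_error(archConfig(growthRate = 0L), "growthRate")
  expect_error(archConfig(asppRates = c(6L, 6L)), "increasing")
  expect_error(archConfig(dropoutRate = 1), "dropoutRate")
})

test_that("network spec serializes to YAML and back", {
  spec <- assembleNetwork(tinyArchConfig())
  f <- withr::local_tempfile(fileext = ".yaml")
  writeNetworkSpec(spec, f)
  back <- readNetworkSpec(f)
  expect_identical(countLayers(back), countLayers(spec))
  expect_identical(back@config@asppRates, spec@config@asppRates)
  expect_identical(vapply(back@blocks, `[[`, "", "name"),
                   vapply(spec@blocks, `[[`, "", "name"))
})
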