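test_that("phantom generation is bit-identical under a fixed seed", {
  cfg <- phantomConfig(canvasSide = 96L, seed = 3L)
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  expect_identical(a@image, b@image)
  expect_identical(a@mask, b@mask)
  expect_false(identical(a@image, generatePhantom(cfg, seed = 4L)@image))
})

test_that("tumor-free configurations give empty masks", {
  cfg <- phantomConfig(canvasSide = 64L, nTumors = 0L, seed = 1L)
  p <- generatePhantom(cfg)
  expect_true(all(p@mask == 0L))
  expect_identical(nrow(p@tumorSpecs), 0L)
  expect_identical(tumorSizeSummary(list(p)), integer(0))
})

test_that("rendered tumors respect the configured size range and the
           breast geometry", {
  cfg <- phantomConfig(canvasSide = 96L, seed = 8L)
  lo <- cfg@tumorSizeRange[1]; hi <- cfg@tumorSizeRange[2]
  phs <- generateDataset(40, cfg, seed = 8L)$phantoms
  for (p in phs) {
    expect_identical(sort(unique(as.vector(p@mask))),
                     if (any(p@mask > 0)) c(0L, 1L) else 0L)
    for (r in seq_len(nrow(p@tumorSpecs))) {
      expect_gte(min(p@tumorSpecs$bboxRows[r], p@tumorSpecs$bboxCols[r]), lo)
      expect_lte(max(p@tumorSpecs$bboxRows[r], p@tumorSpecs$bboxCols[r]), hi)
    }
  }
  # foreground stays a small fraction: the class imbalance the weighted
  # loss is built for
  expect_lt(max(vapply(phs, function(p) mean(p@mask > 0), 0)), 0.10)
  # size histogram conserves the tumor count
  h <- tumorSizeSummary(phs)
  expect_identical(sum(h), sum(vapply(phs, function(p)
    nrow(p@tumorSpecs), 0L)))
})

test_that("the default size range maps the clinical 200-800 interval onto
           the canvas", {
  cfg <- phantomConfig(canvasSide = 1024L)
  expect_equal(cfg@tumorSizeRange, c(50, 200))
  cfg2 <- phantomConfig(canvasSide = 64L)
  expect_equal(cfg2@tumorSizeRange, round(c(200, 800) * 64 / 4096))
})

test_that("impossible tumor placements fail loudly", {
  cfg <- phantomConfig(canvasSide = 32L, tumorSizeRange = c(28, 31),
                       seed = 1L)
  expect_error(generatePhantom(cfg), "100 attempts")
})

test_that("MLO-like phantoms carry a bright pectoral wedge", {
  cfg <- phantomConfig(canvasSide = 96L, includePectoral = TRUE, seed = 5L)
  p <- generatePhantom(cfg)
  expect_identical(p@viewLike, "MLO")
  q <- generatePhantom(phantomConfig(canvasSide = 96L, seed = 5L))
  # wedge adds intensity in the upper-left corner region
  expect_gt(mean(p@image[1:20, 1:20]), mean(q@image[1:20, 1:20]))
})

test_that("dataset generation writes a readable manifest with distinct
           per-item seeds", {
  dir <- withr::local_tempdir()
  cfg <- phantomConfig(canvasSide = 64L, seed = 6L)
  ds <- generateDataset(5, cfg, dir = dir, seed = 6L)
  expect_identical(anyDuplicated(ds$itemSeeds), 0L)
  mf <- readManifest(file.path(dir, "manifest.csv"))
  expect_identical(nrow(mf), 5L)
  img <- loadImage(mf$image[1])
  expect_identical(dim(img@pixels), c(64L, 64L))
  msk <- binarizeMask(loadImage(mf$mask[1])@pixels)
  expect_identical(msk, ds$phantoms[[1]]@mask)
  # re-running reproduces identical bytes
  dir2 <- withr::local_tempdir()
  generateDataset(5, cfg, dir = dir2, seed = 6L)
  for (i in 1:5)
    expect_identical(unname(tools::md5sum(mf$image[i])),
                     unname(tools::md5sum(file.path(dir2,
                       basename(mf$image[i])))))
})

test_that("low-contrast tumors defeat the threshold baseline more than
           high-contrast ones", {
  blDI <- function(contrast) {
    phs <- generateDataset(8, phantomConfig(canvasSide = 96L,
                                            tumorContrast = contrast,
                                            seed = 33L),
                           seed = 33L)$phantoms
    mean(vapply(phs, function(p) {
      m <- removeSmallComponents(doubleThresholdSegment(p@image)$mask)
      diceIndex(confusionCounts(m, p@mask))
    }, 0))
  }
  expect_lt(blDI(0.03), blDI(0.4))
})
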