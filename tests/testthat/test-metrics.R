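cc <- function(tp, fp, fn, tn = 0) new("ConfusionCounts", tp = tp, fp = fp,
                                       fn = fn, tn = tn)

test_that("confusion counts partition the image", {
  truth <- matrix(0L, 10, 10); truth[1, 1:10] <- 1L
  x <- confusionCounts(truth, truth)
  expect_equal(c(x@tp, x@fp, x@fn, x@tn), c(10, 0, 0, 90))
  allfg <- matrix(1L, 10, 10)
  y <- confusionCounts(allfg, truth)
  expect_equal(c(y@tp, y@fp, y@fn, y@tn), c(10, 90, 0, 0))
  disjoint <- matrix(0L, 10, 10); disjoint[5, 1:10] <- 1L
  expect_equal(confusionCounts(disjoint, truth)@tp, 0)
  expect_error(confusionCounts(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("DI, PA and IOU evaluate their formulas", {
  x <- cc(6, 2, 2)
  expect_equal(diceIndex(x), 0.75)
  expect_equal(iou(x), 0.6)
  expect_equal(pixelAccuracy(cc(8, 0, 2)), 0.8)
  expect_equal(diceIndex(cc(5, 0, 0)), 1)
  expect_equal(pixelAccuracy(cc(5, 0, 0)), 1)
  expect_equal(diceIndex(cc(0, 3, 4)), 0)
  expect_equal(pixelAccuracy(cc(0, 0, 4)), 0)
  expect_warning(v <- diceIndex(cc(0, 0, 0)), "empty")
  expect_equal(v, 1)
  expect_warning(pixelAccuracy(cc(0, 5, 0)), "empty")
  expect_warning(iou(cc(0, 0, 0, 10)), "empty")
})

test_that("DI = 2 IOU / (1 + IOU) holds across random confusion counts", {
  set.seed(42)
  for (i in 1:1000) {
    x <- cc(sample(0:50, 1), sample(0:50, 1), sample(0:50, 1))
    if (x@tp + x@fp + x@fn == 0) next
    di <- diceIndex(x); jo <- iou(x)
    expect_equal(di, 2 * jo / (1 + jo), tolerance = 1e-12)
    expect_lte(jo, di)
  }
})

test_that("count-based metrics equal set-operation oracles on random
           masks", {
  set.seed(99)
  for (i in 1:20) {
    pred <- matrix(rbinom(256, 1, 0.3), 16, 16)
    truth <- matrix(rbinom(256, 1, 0.3), 16, 16)
    if (!sum(truth) || !sum(pred)) next
    x <- confusionCounts(pred, truth)
    o <- set_metrics_oracle(pred, truth)
    expect_equal(diceIndex(x), o$DI)
    expect_equal(pixelAccuracy(x), o$PA)
    expect_equal(iou(x), o$IOU)
    # invariance under simultaneous transposition
    xt <- confusionCounts(t(pred), t(truth))
    expect_equal(diceIndex(xt), diceIndex(x))
    expect_equal(iou(xt), iou(x))
    expect_equal(pixelAccuracy(xt), pixelAccuracy(x))
  }
})

test_that("set evaluation reports per-image rows and arithmetic means", {
  t1 <- matrix(0L, 10, 10); t1[1:2, 1:5] <- 1L
  p1 <- t1                                  # DI 1
  p2 <- matrix(0L, 10, 10); p2[1, 1:5] <- 1L  # DI 2*5/(5+10) = 2/3
  rep <- evaluateSet(list(list(pred = p1, truth = t1, id = "a"),
                          list(pred = p2, truth = t1, id = "b")))
  expect_identical(nrow(rep@perImage), 2L)
  expect_equal(meanDI(rep), mean(c(1, 2 / 3)))
  expect_equal(meanDI(rep), mean(rep@perImage$DI))  # brute recomputation
  # pooled aggregation differs from per-image averaging
  pooled <- evaluateSet(list(list(pred = p1, truth = t1),
                             list(pred = p2, truth = t1)), pooled = TRUE)
  expect_equal(meanDI(pooled), 2 * 15 / (2 * 15 + 0 + 5))
  # all-perfect set
  perfect <- evaluateSet(list(list(pred = t1, truth = t1)))
  expect_equal(c(meanDI(perfect), meanPA(perfect), meanIOU(perfect)),
               c(1, 1, 1))
  expect_error(evaluateSet(list()), "empty")
})

test_that("metric reports round-trip through CSV", {
  t1 <- matrix(0L, 8, 8); t1[3:4, 3:6] <- 1L
  p1 <- matrix(0L, 8, 8); p1[3:4, 4:7] <- 1L
  rep <- evaluateSet(list(list(pred = p1, truth = t1, id = "img1"),
                          list(pred = t1, truth = t1, id = "img2")))
  f <- withr::local_tempfile(fileext = ".csv")
  writeMetricReport(rep, f)
  back <- readMetricReport(f)
  expect_equal(back@perImage$DI, rep@perImage$DI, tolerance = 1e-12)
  expect_equal(meanDI(back), meanDI(rep), tolerance = 1e-12)
  expect_identical(back@perImage$id, c("img1", "img2"))
})
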