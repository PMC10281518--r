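test_that("roundness behaves at the canonical shape extremes", {
  expect_gte(computeRoundness(diskMask(20L)), 0.95)
  line <- matrix(FALSE, 10, 60)
  line[5, 5:54] <- TRUE
  expect_lt(computeRoundness(line), 0.2)
  expect_error(computeRoundness(matrix(FALSE, 5, 5)), "empty")
})

test_that("the Crofton perimeter matches the brute-force oracle exactly", {
  rect <- matrix(FALSE, 20, 30)
  rect[6:15, 6:25] <- TRUE  # 10 x 20 rectangle
  expect_equal(croftonPerimeter(rect), oracleCroftonPerimeter(rect),
               tolerance = 1e-12)
  r <- 4 * pi * sum(rect) / oracleCroftonPerimeter(rect)^2
  expect_equal(computeRoundness(rect), min(1, r), tolerance = 1e-12)
  shapes <- randomShapeMasks(100L, seed = 70L)
  for (m in shapes)
    expect_equal(croftonPerimeter(m), oracleCroftonPerimeter(m),
                 tolerance = 1e-12)
})

test_that("segmentation recovers blanks, separated and touching nuclei", {
  expect_equal(max(segmentNuclei(matrix(0, 64, 64))), 0L)
  expect_equal(max(segmentNuclei(matrix(7, 64, 64))), 0L)

  p <- RenderParams(nNuclei = 10L, focusBlurSigma = 0.5,
                    noiseGaussianSd = 50)
  w <- renderWellImage(p, 6000, seed = 11)
  mask <- segmentNuclei(w$dapi)
  expect_equal(max(mask), 10L)
  feats <- nucleusFeatures(mask, w$yfp)
  for (i in seq_len(nrow(feats))) {
    d <- sqrt((w$truth$centroid_row - feats$centroid_row[i])^2 +
                (w$truth$centroid_col - feats$centroid_col[i])^2)
    expect_lt(min(d), 1)
  }

  # two overlapping disks with a clear neck are split by the watershed
  m <- matrix(0, 100, 100)
  for (i in 1:100) for (j in 1:100)
    if ((i - 40)^2 + (j - 45)^2 <= 15^2 ||
        (i - 68)^2 + (j - 55)^2 <= 15^2) m[i, j] <- 8000
  expect_equal(max(segmentNuclei(m, blurSigma = 0)), 2L)
})

test_that("nucleus filtering honors threshold, border and idempotence", {
  rec <- data.frame(label = 1:4,
                    roundness = c(0.774, 0.775, 0.9, 0.95),
                    touches_border = c(FALSE, FALSE, TRUE, FALSE),
                    mean_yfp = c(10, 20, 30, 40))
  kept <- filterNuclei(rec)
  # strictly-below excluded, exactly-at kept, border-touching excluded
  expect_equal(kept$label, c(2L, 4L))
  expect_identical(filterNuclei(kept), kept)
  expect_equal(filterNuclei(rec, excludeBorder = FALSE)$label, c(2L, 3L, 4L))
  # kept set shrinks monotonically in the threshold
  n <- vapply(c(0, 0.775, 0.9, 1.1),
              function(th) nrow(filterNuclei(rec, th)), 0L)
  expect_true(all(diff(n) <= 0))
})

test_that("well summaries are unweighted means, order-invariant", {
  rec <- data.frame(label = 1:2, mean_yfp = c(10, 30),
                    area = c(100, 300))
  s <- summarizeWell(rec)
  expect_equal(s$well_mean_of_means, 20)  # not the area-weighted 25
  expect_equal(summarizeWell(rec[1, ])$well_mean_of_means, 10)
  perm <- rec[2:1, ]
  expect_equal(summarizeWell(perm)$well_mean_of_means,
               s$well_mean_of_means)
  s0 <- summarizeWell(rec[0, ], nTotal = 5L)
  expect_true(is.na(s0$well_mean_of_means))
  expect_equal(s0$n_nuclei_total, 5L)
})

test_that("quantifyWell reproduces rendered per-nucleus means closely", {
  p <- RenderParams(nNuclei = 50L, radiusRange = c(5, 9),
                    focusBlurSigma = 0.5, noiseGaussianSd = 100)
  w <- renderWellImage(p, 8000, seed = 21)
  q <- quantifyWell(w$dapi, w$yfp)
  truthMean <- mean(w$truth$true_mean_yfp)
  expect_lt(abs(q$well$well_mean_of_means - truthMean) / truthMean, 0.02)
  expect_equal(q$well$n_nuclei_total, 50L)
})
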