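test_that("zero nuclei render to blank images with an empty truth table", {
  p <- RenderParams(nNuclei = 0L, focusBlurSigma = 0, noiseGaussianSd = 0)
  w <- renderWellImage(p, 5000, seed = 1)
  expect_equal(nrow(w$truth), 0L)
  expect_true(all(w$mask == 0L))
  expect_true(all(w$yfp == 0))
  expect_true(all(w$dapi == p@dapiBackground))
})

test_that("truth tables are consistent with the emitted label mask", {
  p <- RenderParams(nNuclei = 10L, focusBlurSigma = 0, noiseGaussianSd = 0)
  w <- renderWellImage(p, 6000, seed = 2)
  expect_equal(max(w$mask), 10L)
  for (k in seq_len(10L)) {
    px <- which(w$mask == k, arr.ind = TRUE)
    expect_equal(nrow(px), w$truth$area[k])
    expect_equal(mean(px[, 1]), w$truth$centroid_row[k])
    expect_equal(mean(px[, 2]), w$truth$centroid_col[k])
    expect_equal(computeRoundness(w$mask == k), w$truth$roundness[k])
  }
  # per-nucleus YFP means hit the target exactly without blur or foci
  expect_equal(w$truth$true_mean_yfp, rep(6000, 10L))
})

test_that("irregular shapes score lower roundness than equal-seed disks", {
  pIrr <- RenderParams(nNuclei = 8L, irregularity = 0.85,
                       focusBlurSigma = 0, noiseGaussianSd = 0)
  pDisk <- RenderParams(nNuclei = 8L, irregularity = 0,
                        focusBlurSigma = 0, noiseGaussianSd = 0)
  wi <- renderWellImage(pIrr, 5000, seed = 5)
  wd <- renderWellImage(pDisk, 5000, seed = 5)
  expect_lt(mean(wi$truth$roundness), mean(wd$truth$roundness))
  expect_gt(min(wd$truth$roundness), 0.9)
})

test_that("rendering is reproducible under a fixed seed", {
  p <- RenderParams(nNuclei = 6L)
  a <- renderWellImage(p, 4000, seed = 9)
  b <- renderWellImage(p, 4000, seed = 9)
  expect_identical(a$yfp, b$yfp)
  expect_identical(a$mask, b$mask)
  c_ <- renderWellImage(p, 4000, seed = 10)
  expect_false(identical(a$mask, c_$mask))
})

test_that("metaphase spreads render additive truncated Gaussian spots", {
  sp <- renderMetaphaseSpread(8, 400, 0, background = 100, noiseSd = 0,
                              seed = 3)
  expect_true(all(sp$spots$spot_class == "centromeric"))
  expect_equal(nrow(sp$spots), 8L)
  for (i in seq_len(nrow(sp$spots)))
    expect_equal(sp$image[sp$spots$row[i], sp$spots$col[i]], 500)
  # arm spots appear when requested, and placement is seed-stable
  sp2 <- renderMetaphaseSpread(8, 400, 150, background = 100, seed = 3)
  expect_equal(sum(sp2$spots$spot_class == "noncentromeric"), 8L)
  sp3 <- renderMetaphaseSpread(8, 400, 150, background = 100, seed = 3)
  expect_identical(sp2$spots, sp3$spots)
  # the cytoplasm mask stays clear of every spot
  for (i in seq_len(nrow(sp2$spots)))
    expect_false(sp2$cytoplasm_mask[sp2$spots$row[i], sp2$spots$col[i]])
})
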