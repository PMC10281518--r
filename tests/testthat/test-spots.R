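test_that("box maxima capture rendered spot peaks, even off-center", {
  flat <- matrix(42, 40, 40)
  expect_equal(spotMaxInBox(flat, c(20, 20)), 42)
  expect_error(spotMaxInBox(flat, c(2, 20)), "clipped")

  sp <- renderMetaphaseSpread(5, 400, 0, background = 100, noiseSd = 0,
                              spotSigma = 1.5, seed = 2)
  s1 <- sp$spots[1, ]
  expect_equal(spotMaxInBox(sp$image, c(s1$row, s1$col)), 500)
  # an 8x8 box still holds the peak when the center is off by 3 px
  expect_equal(spotMaxInBox(sp$image, c(s1$row - 3, s1$col + 3)), 500)
})

test_that("background boxes are exact on flat images and reproducible", {
  img <- matrix(123, 64, 64)
  mask <- matrix(TRUE, 64, 64)
  b1 <- estimateBackground(img, mask, seed = 5)
  expect_equal(b1$background, 123)
  expect_equal(nrow(b1$boxes), 4L)
  b2 <- estimateBackground(img, mask, seed = 5)
  expect_identical(b1, b2)
  # boxes are mutually disjoint
  for (i in 1:3) for (j in (i + 1):4)
    expect_true(abs(b1$boxes$row[i] - b1$boxes$row[j]) >= 8 ||
                  abs(b1$boxes$col[i] - b1$boxes$col[j]) >= 8)
  expect_error(estimateBackground(img, matrix(FALSE, 64, 64)), "boxes")
})

test_that("noisy background estimates sit inside the exhaustive oracle", {
  set.seed(8)
  img <- matrix(100 + rnorm(48 * 48, 0, 5), 48, 48)
  mask <- matrix(TRUE, 48, 48)
  est <- estimateBackground(img, mask, seed = 9)$background
  pool <- oracleBackgroundDistribution(img, mask)
  # the estimate averages 4 draws from the per-box-maximum pool
  expect_lt(abs(est - mean(pool)), 3 * sd(pool))
})

test_that("corrected intensities subtract background, kept when negative", {
  expect_equal(as.numeric(correctedIntensity(500, 100)), 400)
  expect_equal(as.numeric(correctedIntensity(77, 77)), 0)
  neg <- correctedIntensity(50, 80)
  expect_equal(as.numeric(neg), -30)
  expect_true(attr(neg, "negative"))
})

test_that("spot correction is invariant to a global intensity offset", {
  sp <- renderMetaphaseSpread(10, 400, 0, background = 100, noiseSd = 4,
                              seed = 12)
  m1 <- measureSpots(sp$image, sp$spots, sp$cytoplasm_mask, seed = 3)
  m2 <- measureSpots(sp$image + 250, sp$spots, sp$cytoplasm_mask, seed = 3)
  expect_equal(m1$corrected, m2$corrected, tolerance = 1e-10)
})

test_that("rendered spot amplitudes are recovered after correction", {
  vals <- c()
  for (s in 1:5) {
    sp <- renderMetaphaseSpread(20, 400, 0, background = 100, noiseSd = 5,
                                seed = s)
    m <- measureSpots(sp$image, sp$spots, sp$cytoplasm_mask, seed = s * 7)
    vals <- c(vals, m$corrected)
  }
  expect_gte(length(vals), 100L)
  expect_lt(abs(mean(vals) - 400) / 400, 0.05)
})

test_that("condition summaries give mean, sem and fold change", {
  s <- conditionSummary(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_equal(conditionSummary(c(4, 6), c(4, 6))$fold_change_vs_reference,
               1)
  expect_error(conditionSummary(c(1, 2), c(-1, 1)), "zero mean")
  # sem scales as 1/sqrt(n) on resampled values
  set.seed(10)
  v <- rnorm(400, 100, 10)
  s1 <- conditionSummary(v[1:100])
  s2 <- conditionSummary(v)
  expect_equal(s2$sem * sqrt(4), s1$sem, tolerance = 0.35)
})

test_that("the t-test matches the closed-form oracle and conventions", {
  a <- c(1, 2, 3, 4)
  b <- c(2, 3, 4, 5)
  res <- twoSampleTTest(a, b)
  orc <- oracleTTest(a, b)
  expect_equal(res$t, orc$t, tolerance = 1e-10)
  expect_equal(res$df, orc$df)
  expect_equal(res$p, orc$p, tolerance = 1e-10)

  same <- twoSampleTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const <- twoSampleTTest(c(2, 2), c(2, 2))
  expect_equal(const$t, 0)
  expect_equal(const$p, 1)
  welch <- twoSampleTTest(a, c(b, 30), varEqual = FALSE)
  expect_lt(welch$df, 5)
})

test_that("ANOVA + Tukey match the sums-of-squares oracle", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 6, 7))
  values <- unlist(g)
  group <- rep(names(g), lengths(g))
  res <- anovaTukey(values, group)
  orc <- oracleAnovaF(g)
  expect_equal(res$F, orc$F, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  # Tukey-adjusted p is never smaller than the unadjusted pairwise test
  # on the same pooled error (the multiplicity adjustment only inflates)
  mse <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0)) / (9 - 3)
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    tstat <- (mean(g[[pr[2]]]) - mean(g[[pr[1]]])) /
      sqrt(mse * (1 / 3 + 1 / 3))
    praw <- 2 * pt(-abs(tstat), df = 6)
    padj <- res$tukey$p_adj[res$tukey$comparison ==
                              paste(pr[2], pr[1], sep = "-")]
    expect_gte(padj + 1e-12, praw)
  }
  ident <- anovaTukey(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(ident$F, 0)
  expect_equal(ident$p, 1)
  expect_true(all(ident$tukey$p_adj == 1))
})
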