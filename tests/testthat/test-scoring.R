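test_that("an exactly additive plate collapses to the degeneracy rule", {
  values <- outer(1:16 * 10, 1:24, "+") + 500
  libMask <- matrix(FALSE, 16, 24)
  libMask[, 1:22] <- TRUE
  bs <- bscorePlate(values, libMask)
  expect_true(bs$degenerate)
  expect_true(all(bs$bscore == 0))
})

test_that("B-scores are invariant to plate-wide shift and scaling", {
  pl <- simulatedPlate(seed = 41)
  b0 <- bscorePlate(pl$values, pl$libraryMask)
  b1 <- bscorePlate(pl$values + 137, pl$libraryMask)
  b2 <- bscorePlate(pl$values * 3.7, pl$libraryMask)
  expect_equal(b0$bscore, b1$bscore, tolerance = 1e-8)
  expect_equal(b0$bscore, b2$bscore, tolerance = 1e-8)
})

test_that("extreme control wells cannot move library B-scores", {
  pl <- simulatedPlate(seed = 42)
  spiked <- pl$values
  ctrl <- !pl$libraryMask & !is.na(spiked)
  spiked[ctrl] <- spiked[ctrl] + 10000
  b0 <- bscorePlate(pl$values, pl$libraryMask)
  b1 <- bscorePlate(spiked, pl$libraryMask)
  expect_identical(b0$bscore[pl$libraryMask], b1$bscore[pl$libraryMask])
})

test_that("B-score removes simulated row/column artifacts", {
  pl <- simulatedPlate(seed = 43)
  bs <- bscorePlate(pl$values, pl$libraryMask)
  libB <- bs$bscore
  libB[!pl$libraryMask] <- NA
  expect_lt(max(abs(apply(libB, 1, median, na.rm = TRUE)), na.rm = TRUE),
            0.2)
  expect_lt(max(abs(apply(libB, 2, median, na.rm = TRUE)), na.rm = TRUE),
            0.2)
  # variance adjustment: scaled MAD of library B-scores is 1 by design
  expect_equal(mad(libB[pl$libraryMask]), 1, tolerance = 0.05)
})

test_that("robust Z-scores match the median/MAD oracle", {
  lib <- rep(c(1, 2, 3, 4, 100), 2)
  z <- zscoreReplicate(lib, rep(TRUE, 10))
  expect_false(z$degenerate)
  expect_equal(z$z, oracleRobustZ(lib, c(1, 2, 3, 4, 100)),
               tolerance = 1e-12)
  # a well at the library median scores zero
  expect_equal(z$z[3], 0)
  # location invariance
  z2 <- zscoreReplicate(lib + 55, rep(TRUE, 10))
  expect_equal(z$z, z2$z, tolerance = 1e-12)
  # classical variant centers on the mean
  zc <- zscoreReplicate(lib, rep(TRUE, 10), method = "classical")
  expect_equal(zc$z, (lib - mean(lib)) / sd(lib), tolerance = 1e-12)
  # degenerate scale
  zd <- zscoreReplicate(rep(3, 10), rep(TRUE, 10))
  expect_true(zd$degenerate)
  expect_true(all(zd$z == 0))
})

test_that("siRNA scores average available replicates", {
  ws <- data.frame(
    sirna_id = c("s1", "s1", "s2"),
    gene_id = c("g1", "g1", "g1"),
    replicate = c(1L, 2L, 1L),
    z = c(2, 4, 1.5))
  st <- sirnaScores(ws)
  expect_equal(st$sirna_level_z[st$sirna_id == "s1"], 3)
  expect_equal(st$n_replicates[st$sirna_id == "s1"], 2L)
  expect_equal(st$sirna_level_z[st$sirna_id == "s2"], 1.5)
  expect_equal(st$n_replicates[st$sirna_id == "s2"], 1L)
  expect_identical(st, sirnaScores(ws[c(3, 1, 2), ]))
})

test_that("gene scores are the median over siblings, ranked and tied", {
  st <- data.frame(
    sirna_id = paste0("s", 1:8),
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gB", "gC", "gC"),
    sirna_level_z = c(5, 3, 1, 8, 0.1, -0.2, 2, 4),
    n_replicates = 2L)
  gt <- geneScores(st)
  expect_equal(gt$gene_median_z[gt$gene_id == "gA"], 3)
  # one strong siRNA does not carry a gene
  expect_equal(gt$gene_median_z[gt$gene_id == "gB"], 0.1)
  # two siRNAs: median of two = mean
  expect_equal(gt$gene_median_z[gt$gene_id == "gC"], 3)
  expect_equal(gt$rank, seq_len(nrow(gt)))
  # deterministic tie-break on gene id
  expect_equal(gt$gene_id[1:2], c("gA", "gC"))

  expect_equal(nrow(callHits(gt, Inf)), 0L)
  expect_equal(nrow(callHits(gt, -Inf)), 3L)
  expect_equal(callHits(gt, 3)$gene_id, c("gA", "gC"))
})

test_that("zero-noise ranking places spiked effects in their true order", {
  # With zero noise and no plate artifacts the score chain is monotone up
  # to the (bounded) signal the median polish absorbs from dense true
  # effects, so hits separated by more than that margin rank in their
  # exact true order ahead of the background.
  des <- ScreenDesign(nGenes = 40L)
  lay <- buildScreenLayout(des)
  tm <- newTruthModel(lay, seed = 5L, noiseSd = 0,
                      rowEffectRange = c(0, 0), colEffectRange = c(0, 0))
  genes <- sort(unique(lay$gene_id[lay$content_class == "library"]))
  set.seed(51)
  tm@geneEffect[genes] <- runif(length(genes), 0, 5)  # keeps the MAD > 0
  hits <- c("GENE007", "GENE013", "GENE021", "GENE029", "GENE035")
  tm@geneEffect[hits] <- c(200, 160, 120, 80, 40)
  wells <- simulateWellValues(lay, tm, des, seed = 6)
  sc <- scoreScreen(wells, lay, des)
  expect_equal(sc$geneTable$gene_id[1:5], hits)
})
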