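zeroTruth <- function(lay, ...) {
  newTruthModel(lay, seed = 1L, noiseSd = 0,
                rowEffectRange = c(0, 0), colEffectRange = c(0, 0), ...)
}

test_that("the degenerate model returns the baseline exactly", {
  des <- smallDesign(4L)
  lay <- buildScreenLayout(des)
  tm <- zeroTruth(lay)
  wells <- simulateWellValues(lay, tm, des, seed = 3)
  lib <- wells[wells$well %in% lay$well[lay$content_class == "library"], ]
  expect_true(all(lib$raw_value == 1000))
  neg <- wells[wells$well %in% lay$well[lay$content_class == "neg_control"], ]
  expect_true(all(neg$raw_value == 1000))
  pos <- wells[wells$well %in% lay$well[lay$content_class == "pos_control"], ]
  expect_true(all(pos$raw_value == 1300))
  empty <- wells[wells$well %in% lay$well[lay$content_class == "empty"], ]
  expect_true(all(is.na(empty$raw_value)))
  expect_true(all(empty$n_nuclei == 0L))
})

test_that("an additive row artifact shifts exactly that row", {
  des <- ScreenDesign(nGenes = 20L, nReplicates = 1L)
  lay <- buildScreenLayout(des)
  fx <- list(`1:P01` = list(row = c(50, rep(0, 15)), col = rep(0, 24)))
  tm <- zeroTruth(lay, fixedEffects = fx)
  wells <- simulateWellValues(lay, tm, des, seed = 3)
  rc <- parseWellName(wells$well)
  lib <- lay$well[lay$content_class == "library"]
  a <- wells$raw_value[rc$row == 1 & wells$well %in% lib]
  b <- wells$raw_value[rc$row == 2 & wells$well %in% lib]
  expect_equal(median(a) - median(b), 50)
})

test_that("simulation is seed-deterministic and seed-sensitive", {
  des <- smallDesign(6L)
  lay <- buildScreenLayout(des)
  tm <- newTruthModel(lay, seed = 2L)
  w1 <- simulateWellValues(lay, tm, des, seed = 11)
  w2 <- simulateWellValues(lay, tm, des, seed = 11)
  expect_identical(w1, w2)
  w3 <- simulateWellValues(lay, tm, des, seed = 12)
  expect_false(isTRUE(all.equal(w1$raw_value, w3$raw_value)))
})

test_that("the truth constructor draws valid potencies and spikes", {
  lay <- buildScreenLayout(smallDesign(10L))
  tm <- newTruthModel(lay, hitGenes = "GENE002", hitEffect = 40,
                      decoyGenes = "GENE005", decoyEffect = 80, seed = 4L)
  expect_true(all(tm@sirnaPotency >= 0.5 & tm@sirnaPotency <= 1))
  expect_equal(unname(tm@geneEffect["GENE002"]), 40)
  # hit siblings are fully potent so all three siRNAs carry the effect
  sib <- grep("^GENE002_", names(tm@sirnaPotency))
  expect_true(all(tm@sirnaPotency[sib] == 1))
  # decoy: exactly one siRNA carries an off-target effect
  expect_equal(sum(tm@sirnaEffect != 0), 1L)
  expect_match(names(which(tm@sirnaEffect != 0)), "^GENE005_")
  expect_error(newTruthModel(lay, hitGenes = "NOPE"), "absent")
  expect_error(TruthModel(noiseSd = -1), "noiseSd")
})
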