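test_that("well names format and parse as a round trip, rejecting junk", {
  expect_equal(wellName(1, 1), "A01")
  expect_equal(wellName(16, 24), "P24")
  w <- wellName(rep(1:16, each = 24), rep(1:24, 16))
  rc <- parseWellName(w)
  expect_equal(wellName(rc$row, rc$col), w)
  expect_error(parseWellName("A1"), "malformed")
  expect_error(parseWellName("a01"), "malformed")
  expect_error(parseWellName("A00"), "out of range")
})

test_that("the reference design spills 1563 siRNAs over 5 plates", {
  des <- ScreenDesign()
  expect_equal(libraryWellsPerPlate(des), 352L)
  expect_equal(nPlatesNeeded(des), 5L)
  lay <- buildScreenLayout(des)
  expect_equal(length(unique(lay$plate_id)), 5L)
  lib <- lay[lay$content_class == "library", ]
  expect_equal(nrow(lib), 1563L)
  # every library siRNA exactly once across the plate set
  expect_equal(anyDuplicated(lib$sirna_id), 0L)
  expect_equal(length(unique(lib$gene_id)), 521L)
  # per-plate control counts dictated by the scheme
  for (p in unique(lay$plate_id)) {
    pl <- lay[lay$plate_id == p, ]
    expect_equal(sum(pl$content_class == "neg_control"), 8L)
    expect_equal(sum(pl$content_class == "pos_control"), 16L)
  }
  # 5th plate partially empty: 4 x 352 + 155 = 1563
  p5 <- lay[lay$plate_id == "P05", ]
  expect_equal(sum(p5$content_class == "library"), 1563L - 4L * 352L)
  expect_gt(sum(p5$content_class == "empty" & p5$col <= 22), 0L)
})

test_that("a one-gene design places siRNAs and controls per the scheme", {
  lay <- buildScreenLayout(ScreenDesign(nGenes = 1))
  expect_equal(length(unique(lay$plate_id)), 1L)
  get <- function(w) lay[lay$well == w, ]
  expect_equal(get("A01")$content_class, "library")
  expect_equal(get("A02")$content_class, "library")
  expect_equal(get("A03")$content_class, "library")
  expect_equal(get("A04")$content_class, "empty")
  expect_equal(get("A23")$content_class, "neg_control")
  expect_equal(get("B23")$content_class, "empty")
  expect_equal(get("A24")$content_class, "pos_control")
  expect_equal(get("B24")$content_class, "pos_control")
  # positive-control ids alternate by row parity
  expect_false(get("A24")$sirna_id == get("B24")$sirna_id)
  expect_equal(get("A24")$sirna_id, get("C24")$sirna_id)
  # sibling siRNAs share the gene and land consecutively
  expect_equal(unique(lay$gene_id[lay$content_class == "library"]),
               "GENE001")
})

test_that("a plate too narrow for the control columns is rejected", {
  expect_error(ScreenDesign(plateCols = 2), "control columns")
})

test_that("layout validation catches duplicates and misplaced wells", {
  lay <- buildScreenLayout(ScreenDesign(nGenes = 2))
  expect_silent(validatePlateLayout(lay))
  dup <- rbind(lay, lay[lay$well == "A01", ])
  expect_error(validatePlateLayout(dup), "A01")
  bad <- lay
  bad$content_class[bad$well == "A23"] <- "library"
  expect_error(validatePlateLayout(bad), "control columns")
  cls <- lay
  cls$content_class[1] <- "mystery"
  expect_error(validatePlateLayout(cls), "content_class")
})
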