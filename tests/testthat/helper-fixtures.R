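# Small in-code fixtures shared across test files.

smallDesign <- function(nGenes = 20L, ...) {
  ScreenDesign(nGenes = nGenes, ...)
}

# one fully measured 16x24 plate with library/control masks, simulated
# from the additive model with explicit row/column artifacts
simulatedPlate <- function(seed = 1L, noiseSd = 10, rowRange = c(-200, 200),
                           colRange = c(-100, 100), baseline = 1000) {
  des <- ScreenDesign(nGenes = 118L)  # 354 siRNAs: plate 1 full (352 lib)
  lay <- buildScreenLayout(des)
  tm <- newTruthModel(lay, seed = seed, baseline = baseline,
                      noiseSd = noiseSd, rowEffectRange = rowRange,
                      colEffectRange = colRange)
  wells <- simulateWellValues(lay, tm, des, seed = seed + 1L)
  lay1 <- lay[lay$plate_id == "P01", ]
  w1 <- wells[wells$plate_id == "P01" & wells$replicate == 1L, ]
  rc <- parseWellName(lay1$well)
  values <- matrix(NA_real_, 16, 24)
  libMask <- matrix(FALSE, 16, 24)
  values[cbind(rc$row, rc$col)] <- w1$raw_value[match(lay1$well, w1$well)]
  libMask[cbind(rc$row, rc$col)] <- lay1$content_class == "library"
  list(values = values, libraryMask = libMask, layout = lay1)
}

# binary disk mask
diskMask <- function(radius, pad = 5L) {
  n <- 2L * (radius + pad) + 1L
  c0 <- radius + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= radius^2)
}

# a bank of random blob masks cut from rendered truth masks
randomShapeMasks <- function(n = 100L, seed = 7L) {
  shapes <- list()
  s <- seed
  while (length(shapes) < n) {
    s <- s + 1L
    w <- renderWellImage(
      RenderParams(nNuclei = 10L, radiusRange = c(4, 9),
                   irregularity = stats::runif(1, 0, 1),
                   imageShape = c(160L, 160L), focusBlurSigma = 0,
                   noiseGaussianSd = 0),
      1000, seed = s)
    for (k in seq_len(max(w$mask))) {
      px <- which(w$mask == k, arr.ind = TRUE)
      r0 <- range(px[, 1]); c0 <- range(px[, 2])
      sub <- w$mask[r0[1]:r0[2], c0[1]:c0[2], drop = FALSE] == k
      shapes[[length(shapes) + 1L]] <- sub
      if (length(shapes) == n) break
    }
  }
  shapes
}
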