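# Synthetic image renderers. Both renderers emit the image(s) together
# with exact ground truth (label masks / spot lists), so downstream
# quantification can be validated pixel for pixel.

# rasterize one perturbed ellipse; returns integer matrix indices (pixels)
rasterizeNucleus <- function(shape, centerR, centerC, ax, ay, rot,
                             irregularity, harmonics) {
  rmax <- max(ax, ay) * (1 + 0.6 * irregularity) + 1
  r0 <- max(1L, floor(centerR - rmax)):min(shape[1], ceiling(centerR + rmax))
  c0 <- max(1L, floor(centerC - rmax)):min(shape[2], ceiling(centerC + rmax))
  dr <- rep(r0 - centerR, times = length(c0))
  dc <- rep(c0 - centerC, each = length(r0))
  x <- cos(rot) * dr + sin(rot) * dc
  y <- -sin(rot) * dr + cos(rot) * dc
  rho <- sqrt((x / ax)^2 + (y / ay)^2)
  inside <- rho <= 1
  if (irregularity > 0) {
    phi <- atan2(y, x)
    pert <- rep(0, length(phi))
    for (h in seq_len(nrow(harmonics)))
      pert <- pert + harmonics$amp[h] *
        cos(harmonics$k[h] * phi + harmonics$phase[h])
    inside <- rho <= 1 + 0.45 * irregularity * pert
  }
  idx <- which(inside)
  cbind(row = r0[(idx - 1L) %% length(r0) + 1L],
        col = c0[(idx - 1L) %/% length(r0) + 1L])
}

#' Render a synthetic two-channel well image with ground truth
#'
#' Places \code{params@nNuclei} mutually non-touching, optionally
#' boundary-perturbed ellipses on a flat background, renders a DAPI
#' channel (constant nuclear level with mild per-nucleus variation) and a
#' YFP channel whose per-nucleus mean is the requested target, then
#' applies Gaussian focus blur and pixel noise. A ground-truth label mask
#' and a per-nucleus truth table are always emitted; the recorded
#' \code{true_mean_yfp} is the mean of the pre-noise (post-blur) YFP
#' channel over each nucleus mask, i.e. the exact ground truth of the
#' emitted image (equal to \code{targetMeanYfp} when blur and foci are
#' off).
#'
#' @param params a \code{\linkS4class{RenderParams}}.
#' @param targetMeanYfp target per-nucleus mean YFP intensity, either a
#'   scalar or one value per nucleus.
#' @param seed integer seed.
#' @return list with components \code{dapi}, \code{yfp} (numeric
#'   matrices), \code{mask} (integer label matrix, background 0) and
#'   \code{truth} (data.frame: \code{label}, \code{area},
#'   \code{centroid_row}, \code{centroid_col}, \code{roundness},
#'   \code{touches_border}, \code{true_mean_yfp}).
#' @examples
#' w <- renderWellImage(RenderParams(nNuclei = 5), 8000, seed = 1)
#' w$truth
#' @export
renderWellImage <- function(params, targetMeanYfp, seed = 1L) {
  stopifnot(is(params, "RenderParams"))
  validObject(params)
  set.seed(as.integer(seed))
  shape <- params@imageShape
  n <- params@nNuclei
  target <- rep_len(targetMeanYfp, max(n, 1L))
  mask <- matrix(0L, shape[1], shape[2])
  yfp0 <- matrix(0, shape[1], shape[2])
  dapi0 <- matrix(params@dapiBackground, shape[1], shape[2])

  placed <- 0L
  while (placed < n) {
    ok <- FALSE
    for (try in seq_len(300L)) {
      r0 <- stats::runif(1, params@radiusRange[1], params@radiusRange[2])
      u <- stats::runif(1, 0, params@eccentricity)
      ax <- r0 * (1 + u)
      ay <- r0 / (1 + u)
      margin <- ax * (1 + 0.6 * params@irregularity) + 2
      if (2 * margin + 2 >= min(shape))
        stop("nucleus radius too large for the image")
      centerR <- stats::runif(1, margin, shape[1] - margin)
      centerC <- stats::runif(1, margin, shape[2] - margin)
      rot <- stats::runif(1, 0, pi)
      harmonics <- data.frame(
        k = 2:4,
        amp = stats::runif(3, 0.3, 1) / (2:4) * 2,
        phase = stats::runif(3, 0, 2 * pi)
      )
      px <- rasterizeNucleus(shape, centerR, centerC, ax, ay, rot,
                             params@irregularity, harmonics)
      if (nrow(px) < 9L) next
      # require one background pixel of clearance (8-neighborhood)
      nbr <- expand.grid(dr = -1:1, dc = -1:1)
      clash <- FALSE
      for (v in seq_len(nrow(nbr))) {
        rr <- pmin(pmax(px[, 1] + nbr$dr[v], 1L), shape[1])
        cc <- pmin(pmax(px[, 2] + nbr$dc[v], 1L), shape[2])
        if (any(mask[cbind(rr, cc)] != 0L)) { clash <- TRUE; break }
      }
      if (clash) next
      placed <- placed + 1L
      mask[px] <- placed
      dapi0[px] <- params@dapiLevel * stats::runif(1, 0.85, 1.15)
      yfp0[px] <- target[placed]
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place ", n, " non-touching nuclei; placed ", placed)
  }

  if (params@fociPerNucleus > 0L && placed > 0L) {
    sigma <- 1
    for (k in seq_len(placed)) {
      px <- which(mask == k, arr.ind = TRUE)
      pick <- px[sample.int(nrow(px), min(params@fociPerNucleus, nrow(px))),
                 , drop = FALSE]
      for (f in seq_len(nrow(pick)))
        yfp0 <- addGaussianSpot(yfp0, pick[f, 1], pick[f, 2],
                                params@fociAmplitude, sigma)
    }
  }

  if (params@focusBlurSigma > 0) {
    dapi0 <- gblurMatrix(dapi0, params@focusBlurSigma)
    yfp0 <- gblurMatrix(yfp0, params@focusBlurSigma)
  }

  truth <- if (placed > 0L) {
    labs <- seq_len(placed)
    idx <- cbind(as.vector(row(mask)), as.vector(col(mask)), as.vector(mask))
    idx <- idx[idx[, 3] > 0L, , drop = FALSE]
    area <- tabulate(idx[, 3], placed)
    cr <- vapply(labs, function(k) mean(idx[idx[, 3] == k, 1]), 0)
    cc <- vapply(labs, function(k) mean(idx[idx[, 3] == k, 2]), 0)
    tm <- vapply(labs, function(k) mean(yfp0[mask == k]), 0)
    rd <- vapply(labs, function(k) computeRoundness(mask == k), 0)
    tb <- vapply(labs, function(k) {
      px <- which(mask == k, arr.ind = TRUE)
      any(px[, 1] %in% c(1L, shape[1])) || any(px[, 2] %in% c(1L, shape[2]))
    }, NA)
    data.frame(label = labs, area = area, centroid_row = cr,
               centroid_col = cc, roundness = rd, touches_border = tb,
               true_mean_yfp = tm)
  } else {
    data.frame(label = integer(), area = integer(),
               centroid_row = numeric(), centroid_col = numeric(),
               roundness = numeric(), touches_border = logical(),
               true_mean_yfp = numeric())
  }

  dapi <- addPixelNoise(dapi0, params)
  yfp <- addPixelNoise(yfp0, params)
  list(dapi = dapi, yfp = yfp, mask = mask, truth = truth)
}

# Gaussian blur via EBImage, keeping plain-matrix semantics
gblurMatrix <- function(m, sigma) {
  EBImage::imageData(EBImage::gblur(EBImage::as.Image(m), sigma = sigma))
}

addPixelNoise <- function(m, params) {
  if (params@noisePoisson) {
    pos <- pmax(m, 0)
    m <- matrix(stats::rpois(length(m), pos), nrow(m), ncol(m))
  }
  if (params@noiseGaussianSd > 0)
    m <- m + stats::rnorm(length(m), 0, params@noiseGaussianSd)
  m
}

# add a Gaussian bump truncated at 5 sigma (exactly zero beyond)
addGaussianSpot <- function(img, centerR, centerC, amplitude, sigma) {
  ext <- ceiling(5 * sigma)
  r0 <- max(1L, centerR - ext):min(nrow(img), centerR + ext)
  c0 <- max(1L, centerC - ext):min(ncol(img), centerC + ext)
  dr <- outer(r0 - centerR, rep(1, length(c0)))
  dc <- outer(rep(1, length(r0)), c0 - centerC)
  img[r0, c0] <- img[r0, c0] +
    amplitude * exp(-(dr^2 + dc^2) / (2 * sigma^2))
  img
}

#' Render a synthetic metaphase-spread image with ground truth spots
#'
#' Each simulated chromosome contributes one bright centromeric Gaussian
#' spot and optionally dimmer arm ("non-centromeric") spots, all on a flat
#' background. Spot centers sit on integer pixels at a guaranteed minimum
#' separation and Gaussian support is truncated at five sigma, so with
#' zero noise the pixel value at a spot center is exactly
#' \code{background + amplitude}. The returned cytoplasm mask marks
#' background pixels far from every spot, suitable for drawing background
#' boxes.
#'
#' @param nChromosomes number of chromosomes.
#' @param centromereAmplitude peak intensity of centromeric spots above
#'   background.
#' @param noncentromericAmplitude peak intensity of arm spots; 0 disables
#'   arm spots.
#' @param background flat background level.
#' @param noiseSd Gaussian pixel noise sd (0 = none).
#' @param imageShape integer(2) image size.
#' @param spotSigma Gaussian sigma of spots in pixels.
#' @param seed integer seed.
#' @return list with \code{image} (numeric matrix), \code{spots}
#'   (data.frame: \code{spot_id}, \code{cell_id}, \code{row}, \code{col},
#'   \code{spot_class}, \code{amplitude}) and \code{cytoplasm_mask}
#'   (logical matrix).
#' @examples
#' sp <- renderMetaphaseSpread(5, 400, 100, background = 100, seed = 1)
#' table(sp$spots$spot_class)
#' @export
renderMetaphaseSpread <- function(nChromosomes, centromereAmplitude,
                                  noncentromericAmplitude = 0,
                                  background = 100, noiseSd = 0,
                                  imageShape = c(256L, 256L),
                                  spotSigma = 1.5, seed = 1L) {
  stopifnot(nChromosomes >= 0, centromereAmplitude >= 0,
            noncentromericAmplitude >= 0, noiseSd >= 0)
  set.seed(as.integer(seed))
  shape <- as.integer(imageShape)
  img <- matrix(background, shape[1], shape[2])
  centers <- matrix(numeric(0), 0, 2)
  minSep <- max(14, 2 * ceiling(5 * spotSigma))
  margin <- ceiling(5 * spotSigma) + 9L

  place <- function(centers) {
    for (try in seq_len(500L)) {
      p <- c(sample(seq(margin, shape[1] - margin), 1),
             sample(seq(margin, shape[2] - margin), 1))
      if (!nrow(centers) ||
          min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >=
            minSep)
        return(p)
    }
    stop("could not place ", nChromosomes,
         " chromosomes at the required spot separation")
  }

  spots <- list()
  sid <- 0L
  for (k in seq_len(nChromosomes)) {
    p <- place(centers)
    centers <- rbind(centers, p)
    sid <- sid + 1L
    spots[[sid]] <- data.frame(spot_id = sid, cell_id = 1L,
                               row = p[1], col = p[2],
                               spot_class = "centromeric",
                               amplitude = centromereAmplitude)
    img <- addGaussianSpot(img, p[1], p[2], centromereAmplitude, spotSigma)
    if (noncentromericAmplitude > 0) {
      arm <- place(centers)
      centers <- rbind(centers, arm)
      sid <- sid + 1L
      spots[[sid]] <- data.frame(spot_id = sid, cell_id = 1L,
                                 row = arm[1], col = arm[2],
                                 spot_class = "noncentromeric",
                                 amplitude = noncentromericAmplitude)
      img <- addGaussianSpot(img, arm[1], arm[2], noncentromericAmplitude,
                             spotSigma)
    }
  }
  spots <- if (sid > 0L) do.call(rbind, spots) else
    data.frame(spot_id = integer(), cell_id = integer(), row = integer(),
               col = integer(), spot_class = character(),
               amplitude = numeric())

  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  cyto <- matrix(TRUE, shape[1], shape[2])
  cyto[c(1:4, (shape[1] - 3):shape[1]), ] <- FALSE
  cyto[, c(1:4, (shape[2] - 3):shape[2])] <- FALSE
  for (s in seq_len(nrow(spots)))
    cyto <- cyto & ((rows - spots$row[s])^2 + (cols - spots$col[s])^2 >
                      12^2)

  if (noiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, noiseSd)
  list(image = img, spots = spots, cytoplasm_mask = cyto)
}
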