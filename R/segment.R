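# Nuclear segmentation and per-nucleus measurement. The segmentation
# recipe is deliberately plain and deterministic: Gaussian smoothing,
# global Otsu threshold, hole filling, distance-transform watershed to
# split touching nuclei, minimum-area speckle filter.

#' Crofton perimeter of a binary region
#'
#' Perimeter estimate based on the Cauchy--Crofton formula discretized
#' over four directions, computed from the counts of the sixteen 2x2
#' pixel configurations of the zero-padded mask. This estimator is close
#' to the true Euclidean perimeter for smooth digitized shapes (unlike
#' raw boundary-pixel or chain-step counts, which are biased), which
#' keeps the roundness of a digitized disk near 1 without clipping.
#'
#' @param mask logical (or 0/1) matrix; pixels > 0 form the region.
#' @return perimeter estimate in pixel units.
#' @examples
#' m <- matrix(0, 9, 9); m[3:7, 3:7] <- 1
#' croftonPerimeter(m)
#' @export
croftonPerimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) + 0L
  nr <- nrow(m)
  nc <- ncol(m)
  # 2x2 window configuration index: top-left 8, top-right 2, bottom-left 4,
  # bottom-right 1
  tl <- m[-nr, -nc]
  tr <- m[-nr, -1]
  bl <- m[-1, -nc]
  br <- m[-1, -1]
  idx <- 8L * tl + 2L * tr + 4L * bl + br
  h <- tabulate(idx + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

#' Roundness of a binary region
#'
#' Isoperimetric shape factor \eqn{4 \pi A / P^2} with the Crofton
#' four-direction perimeter estimator (\code{\link{croftonPerimeter}}),
#' clipped to [0, 1]. A digitized disk scores close to 1; thin or ragged
#' shapes score low. Holes are ignored (the region is filled before
#' measuring) so that internal voids produced by segmentation do not
#' masquerade as irregular outlines.
#'
#' @param mask logical (or 0/1) matrix with a non-empty region.
#' @return roundness in [0, 1].
#' @examples
#' disk <- outer(-25:25, -25:25, function(i, j) i^2 + j^2 <= 20^2)
#' computeRoundness(disk)
#' @export
computeRoundness <- function(mask) {
  m <- (mask > 0) + 0
  a <- sum(m)
  if (a == 0) stop("empty region")
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::as.Image(m)))
  a <- sum(filled)
  p <- croftonPerimeter(filled)
  min(1, max(0, 4 * pi * a / p^2))
}

#' Segment nuclei from a DAPI image
#'
#' Gaussian smoothing, global Otsu threshold, hole filling, watershed on
#' the distance transform (to split touching nuclei), minimum-area
#' filter, sequential relabeling. A constant (e.g. blank) image yields an
#' empty mask rather than an error.
#'
#' @param dapi single-channel 2D numeric matrix.
#' @param blurSigma Gaussian smoothing sigma in pixels (default 1).
#' @param minArea minimum object area in pixels (default 50, tuned to a
#'   256 x 256 field with nucleus radii of roughly 5--15 px).
#' @param watershedTolerance minimum object-height separation in the
#'   distance transform for a split (default 1).
#' @return integer label matrix, background 0.
#' @export
segmentNuclei <- function(dapi, blurSigma = 1, minArea = 50L,
                          watershedTolerance = 1) {
  if (length(dim(dapi)) != 2L)
    stop("dapi must be a single-channel 2D image")
  rng <- range(dapi)
  if (diff(rng) == 0)
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  img <- (dapi - rng[1]) / diff(rng)
  if (blurSigma > 0)
    img <- gblurMatrix(img, blurSigma)
  img <- pmin(pmax(img, 0), 1)
  th <- EBImage::otsu(EBImage::as.Image(img))
  bw <- EBImage::as.Image((img > th) + 0)
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  lab <- EBImage::imageData(EBImage::watershed(dm,
                                               tolerance = watershedTolerance))
  lab <- matrix(as.integer(lab), nrow(dapi), ncol(dapi))
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L], max(lab))
    keep <- which(areas >= minArea)
    relabel <- integer(max(lab))
    relabel[keep] <- seq_along(keep)
    lab[lab > 0L] <- relabel[lab[lab > 0L]]
  }
  lab
}

#' Measure per-nucleus features over a label mask
#'
#' @param mask integer label matrix (background 0).
#' @param yfp numeric matrix of the intensity channel, same geometry.
#' @return data.frame with one row per label: \code{label}, \code{area},
#'   \code{perimeter} (Crofton), \code{roundness}, \code{touches_border},
#'   \code{centroid_row}, \code{centroid_col}, \code{mean_yfp}.
#' @export
nucleusFeatures <- function(mask, yfp) {
  stopifnot(identical(dim(mask), dim(yfp)))
  n <- max(mask)
  if (n == 0L)
    return(data.frame(label = integer(), area = integer(),
                      perimeter = numeric(), roundness = numeric(),
                      touches_border = logical(), centroid_row = numeric(),
                      centroid_col = numeric(), mean_yfp = numeric()))
  labs <- seq_len(n)
  res <- lapply(labs, function(k) {
    sel <- mask == k
    px <- which(sel, arr.ind = TRUE)
    per <- croftonPerimeter(sel)
    data.frame(
      label = k,
      area = nrow(px),
      perimeter = per,
      roundness = computeRoundness(sel),
      touches_border = any(px[, 1] %in% c(1L, nrow(mask))) ||
        any(px[, 2] %in% c(1L, ncol(mask))),
      centroid_row = mean(px[, 1]),
      centroid_col = mean(px[, 2]),
      mean_yfp = mean(yfp[sel])
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Filter nucleus records by roundness and border contact
#'
#' Nuclei with roundness strictly below the threshold (mostly
#' segmentation artifacts) and, optionally, nuclei touching the image
#' border are excluded; a record exactly at the threshold is kept. The
#' operation is idempotent.
#'
#' @param records data.frame from \code{\link{nucleusFeatures}}.
#' @param minRoundness roundness threshold (default 0.775).
#' @param excludeBorder drop border-touching nuclei (default TRUE).
#' @return the kept records.
#' @export
filterNuclei <- function(records, minRoundness = 0.775,
                         excludeBorder = TRUE) {
  stopifnot(all(c("roundness", "touches_border") %in% names(records)))
  keep <- records$roundness >= minRoundness
  if (excludeBorder) keep <- keep & !records$touches_border
  records[keep, , drop = FALSE]
}

#' Summarize kept nuclei into per-well statistics
#'
#' The well readout is the unweighted mean of the per-nucleus mean YFP
#' intensities (each cell weighted equally, not pixel-pooled and not
#' area-weighted). The secondary \code{yfp_per_nucleus_ratio} readout is
#' the summed per-nucleus mean YFP divided by the total (pre-filter)
#' nuclei count, echoing a signal-per-nucleus ratio readout.
#'
#' @param records kept nucleus records (after \code{\link{filterNuclei}}).
#' @param nTotal total segmented nuclei before filtering (defaults to
#'   \code{nrow(records)}).
#' @return one-row data.frame: \code{n_nuclei_total}, \code{n_nuclei_kept},
#'   \code{well_mean_of_means} (NA if no nucleus was kept),
#'   \code{yfp_per_nucleus_ratio}.
#' @export
summarizeWell <- function(records, nTotal = nrow(records)) {
  nKept <- nrow(records)
  data.frame(
    n_nuclei_total = as.integer(nTotal),
    n_nuclei_kept = as.integer(nKept),
    well_mean_of_means = if (nKept >= 1L) mean(records$mean_yfp) else
      NA_real_,
    yfp_per_nucleus_ratio = if (nKept >= 1L && nTotal >= 1L)
      sum(records$mean_yfp) / nTotal else NA_real_
  )
}

#' Quantify one well from its image pair
#'
#' Runs segmentation, feature extraction, roundness/border filtering and
#' the per-well summary in one call.
#'
#' @param dapi,yfp numeric image matrices of the two channels.
#' @param minRoundness,excludeBorder filter settings
#'   (see \code{\link{filterNuclei}}).
#' @param ... further arguments passed to \code{\link{segmentNuclei}}.
#' @return list with \code{records} (all segmented nuclei, with a logical
#'   \code{kept} column) and \code{well} (the one-row summary).
#' @export
quantifyWell <- function(dapi, yfp, minRoundness = 0.775,
                         excludeBorder = TRUE, ...) {
  mask <- segmentNuclei(dapi, ...)
  records <- nucleusFeatures(mask, yfp)
  kept <- filterNuclei(records, minRoundness, excludeBorder)
  records$kept <- records$label %in% kept$label
  list(records = records,
       well = summarizeWell(kept, nTotal = nrow(records)))
}
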