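# Box-based spot intensity quantification with cytoplasmic background
# correction, and the two significance tests used on such measurements.

# 1-based inclusive box bounds: a box of size b centered at p spans
# p - floor((b-1)/2) .. p + ceiling((b-1)/2) (for b = 8: p-3 .. p+4)
boxBounds <- function(center, boxSize) {
  lo <- center - floor((boxSize - 1) / 2)
  c(lo, lo + boxSize - 1L)
}

#' Maximum intensity in a square box around a spot
#'
#' @param image numeric matrix.
#' @param center integer (row, col) of the spot center, 1-based.
#' @param boxSize box side in pixels (default 8).
#' @return maximum pixel value inside the box.
#' @export
spotMaxInBox <- function(image, center, boxSize = 8L) {
  r <- boxBounds(center[1], boxSize)
  c_ <- boxBounds(center[2], boxSize)
  if (r[1] < 1L || c_[1] < 1L || r[2] > nrow(image) || c_[2] > ncol(image))
    stop("spot box clipped by the image edge at (", center[1], ", ",
         center[2], ")")
  max(image[r[1]:r[2], c_[1]:c_[2]])
}

#' Estimate cytoplasmic background from random boxes
#'
#' Draws \code{nBoxes} mutually disjoint square boxes at seeded-random
#' positions fully inside the cytoplasm mask, takes the maximum intensity
#' of each box, and returns their average. This mirrors taking box
#' maxima at random cytoplasmic areas of the same cell; on a flat
#' background the estimate is exact.
#'
#' @param image numeric matrix.
#' @param mask logical matrix marking admissible (cytoplasmic) pixels.
#' @param nBoxes number of background boxes (default 4).
#' @param boxSize box side in pixels (default 8).
#' @param seed integer seed for the box placement.
#' @return list with \code{background} (mean of the per-box maxima) and
#'   \code{boxes} (data.frame of the chosen top-left corners).
#' @export
estimateBackground <- function(image, mask, nBoxes = 4L, boxSize = 8L,
                               seed = 1L) {
  stopifnot(identical(dim(image), dim(mask)))
  # admissible top-left corners: the whole box inside the mask
  cs <- rbind(0, apply(mask + 0, 2, cumsum))
  ii <- cbind(0, t(apply(cs, 1, cumsum)))
  boxSum <- function(r, c_)
    ii[r + boxSize, c_ + boxSize] - ii[r, c_ + boxSize] -
      ii[r + boxSize, c_] + ii[r, c_]
  nr <- nrow(mask) - boxSize + 1L
  nc <- ncol(mask) - boxSize + 1L
  if (nr < 1L || nc < 1L) stop("mask smaller than the box")
  tl <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  full <- mapply(boxSum, tl$row, tl$col) == boxSize^2
  cand <- tl[full, , drop = FALSE]
  if (nrow(cand) < nBoxes)
    stop("mask admits only ", nrow(cand), " boxes; ", nBoxes, " requested")
  set.seed(as.integer(seed))
  chosen <- cand[0, ]
  ord <- sample.int(nrow(cand))
  for (i in ord) {
    b <- cand[i, ]
    if (nrow(chosen) &&
        any(abs(chosen$row - b$row) < boxSize &
              abs(chosen$col - b$col) < boxSize))
      next
    chosen <- rbind(chosen, b)
    if (nrow(chosen) == nBoxes) break
  }
  if (nrow(chosen) < nBoxes)
    stop("could not place ", nBoxes, " disjoint background boxes")
  maxima <- mapply(function(r, c_)
    max(image[r:(r + boxSize - 1L), c_:(c_ + boxSize - 1L)]),
    chosen$row, chosen$col)
  list(background = mean(maxima), boxes = chosen)
}

#' Background-corrected spot intensity
#'
#' @param rawMax spot box maximum.
#' @param background background estimate.
#' @return \code{rawMax - background}; negative values are reported as-is
#'   (clipping would bias condition means), flagged via an attribute.
#' @export
correctedIntensity <- function(rawMax, background) {
  stopifnot(is.finite(rawMax), is.finite(background))
  out <- rawMax - background
  attr(out, "negative") <- out < 0
  out
}

#' Measure a table of spots on one image
#'
#' For every listed spot, takes the box maximum; per cell, estimates the
#' cytoplasmic background from random disjoint boxes in that cell's mask
#' and subtracts it.
#'
#' @param image numeric matrix.
#' @param spots data.frame with \code{row}, \code{col}, \code{spot_class}
#'   and optionally \code{cell_id} (defaults to one cell).
#' @param mask logical cytoplasm mask (shared by the image's cells).
#' @param boxSize,nBackgroundBoxes box settings.
#' @param seed integer seed (per-cell backgrounds use derived seeds).
#' @return data.frame: the input spot columns plus \code{raw_max},
#'   \code{background}, \code{corrected}, \code{negative} flag.
#' @export
measureSpots <- function(image, spots, mask, boxSize = 8L,
                         nBackgroundBoxes = 4L, seed = 1L) {
  stopifnot(all(c("row", "col", "spot_class") %in% names(spots)))
  if (is.null(spots$cell_id)) spots$cell_id <- 1L
  cells <- unique(spots$cell_id)
  bg <- vapply(seq_along(cells), function(i)
    estimateBackground(image, mask, nBoxes = nBackgroundBoxes,
                       boxSize = boxSize,
                       seed = as.integer(seed) + i - 1L)$background, 0)
  names(bg) <- as.character(cells)
  spots$raw_max <- vapply(seq_len(nrow(spots)), function(i)
    spotMaxInBox(image, c(spots$row[i], spots$col[i]), boxSize), 0)
  spots$background <- bg[as.character(spots$cell_id)]
  spots$corrected <- spots$raw_max - spots$background
  spots$negative <- spots$corrected < 0
  rownames(spots) <- NULL
  spots
}

#' Per-condition summary of corrected spot intensities
#'
#' Mean, standard error of the mean (sample sd over the square root of
#' the number of measurement units, per-spot by default) and, when a
#' reference is given, the fold change of means versus the reference
#' condition.
#'
#' @param values numeric vector of corrected intensities (n >= 2).
#' @param reference optional numeric vector for the reference condition.
#' @return one-row data.frame: \code{n}, \code{mean}, \code{sem},
#'   \code{fold_change_vs_reference} (NA without a reference).
#' @export
conditionSummary <- function(values, reference = NULL) {
  stopifnot(length(values) >= 2L)
  fc <- NA_real_
  if (!is.null(reference)) {
    rm_ <- mean(reference)
    if (rm_ == 0) stop("reference condition has zero mean")
    fc <- mean(values) / rm_
  }
  data.frame(n = length(values), mean = mean(values),
             sem = stats::sd(values) / sqrt(length(values)),
             fold_change_vs_reference = fc)
}

#' Unpaired two-sample t-test
#'
#' Student's unpaired two-tailed test with pooled variance by default
#' (Welch's correction available). Two groups that are both constant and
#' equal give t = 0, p = 1 by convention rather than an error.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param varEqual pooled-variance Student test if TRUE (default), Welch
#'   otherwise.
#' @return data.frame: \code{t}, \code{df}, \code{p}.
#' @export
twoSampleTTest <- function(a, b, varEqual = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(data.frame(t = 0, df = length(a) + length(b) - 2, p = 1))
    return(data.frame(t = sign(mean(a) - mean(b)) * Inf,
                      df = length(a) + length(b) - 2, p = 0))
  }
  res <- stats::t.test(a, b, var.equal = varEqual, paired = FALSE,
                       alternative = "two.sided")
  data.frame(t = unname(res$statistic), df = unname(res$parameter),
             p = res$p.value)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Standard one-way analysis of variance followed by Tukey's honestly
#' significant difference pairwise comparisons (studentized-range
#' distribution). Fully degenerate input (every group constant with
#' equal means) gives F = 0, p = 1 and all pairwise p = 1.
#'
#' @param values numeric vector of measurements.
#' @param group factor/character of group labels (>= 3 groups, each
#'   n >= 2).
#' @return list with \code{F}, \code{p}, and \code{tukey} (data.frame of
#'   pairwise comparisons: \code{comparison}, \code{diff}, \code{p_adj}).
#' @export
anovaTukey <- function(values, group) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 3L, all(table(group) >= 2L),
            length(values) == length(group))
  pairs <- utils::combn(levels(group), 2)
  cmp <- paste(pairs[2, ], pairs[1, ], sep = "-")
  if (stats::var(values) == 0) {
    tukey <- data.frame(comparison = cmp, diff = 0, p_adj = 1)
    return(list(F = 0, p = 1, tukey = tukey))
  }
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  th <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                      p_adj = th[, "p adj"], row.names = NULL)
  list(F = tab[1, "F value"], p = tab[1, "Pr(>F)"], tukey = tukey)
}
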