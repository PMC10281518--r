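# Screen statistics: per-plate B-score, per-replicate Z-score, siRNA- and
# gene-level aggregation, ranking, hit calling.

#' B-score normalize one plate
#'
#' Fits a two-way median polish to the plate's library wells only
#' (control and empty wells are treated as missing during the fit, so an
#' extreme control cannot shift the normalization; the polish overall
#' term is the plate's library median, the centrality parameter).
#' Residuals against the fitted additive surface are computed for every
#' measured well (controls included) and divided by 1.4826 times the
#' median absolute deviation of the plate's library-well residuals (the
#' per-plate variance adjustment; the 1.4826 factor makes the MAD
#' consistent with a Gaussian sd). If that MAD is zero all B-scores are
#' set to 0 and the fit is flagged degenerate.
#'
#' @param values numeric matrix of raw well values (rows x columns of the
#'   plate; NA for unmeasured wells).
#' @param libraryMask logical matrix marking library wells; at least 8
#'   required.
#' @param maxIter,tol polish settings (see \code{\link{medianPolish}}).
#' @return list with \code{bscore} (matrix, NA where the value was NA),
#'   \code{fit} (the \code{\linkS4class{MedianPolishFit}} on library
#'   wells), \code{scale} (1.4826 x MAD of library residuals) and
#'   \code{degenerate} (logical).
#' @export
bscorePlate <- function(values, libraryMask, maxIter = 100L, tol = 1e-9) {
  stopifnot(is.matrix(values), is.logical(libraryMask),
            identical(dim(values), dim(libraryMask)))
  if (sum(libraryMask & !is.na(values)) < 8L)
    stop("fewer than 8 measured library wells on the plate")
  libOnly <- values
  libOnly[!libraryMask] <- NA
  # the control columns are all-missing by construction of the
  # library-only fit; the polish warning is expected there
  fit <- suppressWarnings(medianPolish(libOnly, maxIter = maxIter,
                                       tol = tol))
  resid <- values - polishFitted(fit)
  s <- stats::mad(resid[libraryMask], na.rm = TRUE)  # constant 1.4826
  if (!is.finite(s) || s == 0) {
    b <- resid
    b[!is.na(b)] <- 0
    return(list(bscore = b, fit = fit, scale = s, degenerate = TRUE))
  }
  list(bscore = resid / s, fit = fit, scale = s, degenerate = FALSE)
}

#' Z-score wells of one biological replicate
#'
#' Scores every well of a replicate against the replicate's library
#' wells pooled across plates: \code{z = (b - center) / scale}. The
#' robust variant (default) uses the library median and 1.4826 x MAD;
#' the classical variant uses the library mean and sd. A zero scale
#' yields all-zero scores with a degeneracy flag.
#'
#' @param b numeric vector of B-scores for all wells of the replicate.
#' @param libraryMask logical vector marking library wells (>= 8
#'   required).
#' @param method \code{"robust"} (default) or \code{"classical"}.
#' @return list with \code{z} (numeric vector, NA where \code{b} was NA),
#'   \code{center}, \code{scale}, \code{degenerate}.
#' @export
zscoreReplicate <- function(b, libraryMask,
                            method = c("robust", "classical")) {
  method <- match.arg(method)
  stopifnot(length(b) == length(libraryMask))
  lib <- b[libraryMask]
  if (sum(!is.na(lib)) < 8L)
    stop("fewer than 8 scored library wells in the replicate")
  if (method == "robust") {
    center <- stats::median(lib, na.rm = TRUE)
    scale <- stats::mad(lib, na.rm = TRUE)
  } else {
    center <- mean(lib, na.rm = TRUE)
    scale <- stats::sd(lib, na.rm = TRUE)
  }
  if (!is.finite(scale) || scale == 0) {
    z <- b
    z[!is.na(z)] <- 0
    return(list(z = z, center = center, scale = scale, degenerate = TRUE))
  }
  list(z = (b - center) / scale, center = center, scale = scale,
       degenerate = FALSE)
}

# assemble the (row x col) value and library-mask matrices of one plate
plateMatrix <- function(wells, layout, plateId, replicate, plateRows,
                        plateCols) {
  lay <- layout[layout$plate_id == plateId, , drop = FALSE]
  w <- wells[wells$plate_id == plateId & wells$replicate == replicate, ,
             drop = FALSE]
  rc <- parseWellName(lay$well)
  values <- matrix(NA_real_, plateRows, plateCols)
  libMask <- matrix(FALSE, plateRows, plateCols)
  libMask[cbind(rc$row, rc$col)] <- lay$content_class == "library"
  m <- match(lay$well, w$well)
  values[cbind(rc$row, rc$col)] <- w$raw_value[m]
  list(values = values, libraryMask = libMask)
}

#' siRNA-level scores from per-replicate well Z-scores
#'
#' The siRNA-level Z-score is the arithmetic mean of the siRNA's
#' available replicate Z-scores (an siRNA missing from one replicate,
#' e.g. through an empty well, keeps the remaining replicates and a
#' reduced \code{n_replicates}).
#'
#' @param wellScores data.frame with columns \code{sirna_id},
#'   \code{gene_id}, \code{replicate}, \code{z} (library wells only).
#' @return data.frame: \code{sirna_id}, \code{gene_id},
#'   \code{sirna_level_z}, \code{n_replicates}.
#' @export
sirnaScores <- function(wellScores) {
  stopifnot(all(c("sirna_id", "gene_id", "replicate", "z") %in%
                  names(wellScores)))
  ok <- !is.na(wellScores$z)
  if (!any(ok)) stop("no scored siRNA wells")
  sp <- split(wellScores$z[ok], wellScores$sirna_id[ok])
  ids <- names(sp)
  data.frame(
    sirna_id = ids,
    gene_id = wellScores$gene_id[match(ids, wellScores$sirna_id)],
    sirna_level_z = vapply(sp, mean, 0),
    n_replicates = vapply(sp, length, 0L),
    row.names = NULL
  )
}

#' Gene-level scores by median over sibling siRNAs
#'
#' The gene-level Z-score is the median of the gene's available
#' siRNA-level Z-scores; with the usual three siRNAs per gene this is the
#' second strongest siRNA's score, so a single-oligonucleotide (likely
#' off-target) effect cannot carry a gene. Genes are ranked by descending
#' gene-level Z, ties broken lexicographically on gene id for
#' determinism.
#'
#' @param sirnaTable data.frame from \code{\link{sirnaScores}}.
#' @return data.frame ordered by rank: \code{gene_id}, \code{n_sirnas},
#'   \code{gene_median_z}, \code{rank}.
#' @export
geneScores <- function(sirnaTable) {
  sp <- split(sirnaTable$sirna_level_z, sirnaTable$gene_id)
  out <- data.frame(
    gene_id = names(sp),
    n_sirnas = vapply(sp, length, 0L),
    gene_median_z = vapply(sp, stats::median, 0),
    row.names = NULL
  )
  out <- out[order(-out$gene_median_z, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Call hits above a gene-level Z threshold
#'
#' @param geneTable data.frame from \code{\link{geneScores}}.
#' @param zThreshold finite threshold; hits are genes with
#'   \code{gene_median_z >= zThreshold}.
#' @return the hit rows, ordered by rank, with a \code{hit} column set.
#' @export
callHits <- function(geneTable, zThreshold = 3) {
  stopifnot(is.finite(zThreshold) || is.infinite(zThreshold))
  geneTable$hit <- geneTable$gene_median_z >= zThreshold
  geneTable[geneTable$hit, , drop = FALSE]
}

#' Run the full screen statistics chain
#'
#' Per plate and replicate: B-score normalization on the library-only
#' median-polish fit. Per replicate: Z-scores of all wells against the
#' replicate's pooled library wells. Then siRNA-level means over
#' replicates, gene-level medians, ranking, hit calling, and a plate QC
#' summary (per-row/column medians of library B-scores and the
#' negative/positive control separation in robust Z units).
#'
#' @param wells well table (\code{plate_id}, \code{well},
#'   \code{replicate}, \code{raw_value}).
#' @param layout plate layout table.
#' @param design a \code{\linkS4class{ScreenDesign}}.
#' @param zMethod \code{"robust"} or \code{"classical"}
#'   (see \code{\link{zscoreReplicate}}).
#' @param zThreshold hit-calling threshold on the gene-level Z.
#' @param maxIter,tol polish settings per plate.
#' @return list with \code{wellScores} (per well: b, z, content),
#'   \code{sirnaTable}, \code{geneTable}, \code{hits}, \code{qc}
#'   (per-plate diagnostics), \code{flags} (character vector of
#'   degeneracy warnings, empty when clean).
#' @export
scoreScreen <- function(wells, layout, design, zMethod = "robust",
                        zThreshold = 3, maxIter = 100L, tol = 1e-9) {
  stopifnot(is(design, "ScreenDesign"))
  validatePlateLayout(layout, design@plateRows, design@plateCols)
  plates <- unique(layout$plate_id)
  replicates <- sort(unique(wells$replicate))
  flags <- character()
  rc <- parseWellName(layout$well)

  wellScores <- list()
  qc <- list()
  for (rep_ in replicates) {
    bAll <- numeric(0)
    libAll <- logical(0)
    meta <- list()
    for (p in plates) {
      pm <- plateMatrix(wells, layout, p, rep_, design@plateRows,
                        design@plateCols)
      bs <- bscorePlate(pm$values, pm$libraryMask, maxIter = maxIter,
                        tol = tol)
      if (bs$degenerate)
        flags <- c(flags, sprintf("DEGENERATE_MAD plate=%s replicate=%d",
                                  p, rep_))
      lay <- layout[layout$plate_id == p, , drop = FALSE]
      prc <- parseWellName(lay$well)
      idx <- cbind(prc$row, prc$col)
      meta[[p]] <- data.frame(
        plate_id = p, well = lay$well, replicate = rep_,
        content_class = lay$content_class,
        sirna_id = lay$sirna_id, gene_id = lay$gene_id,
        b = bs$bscore[idx], stringsAsFactors = FALSE
      )
      libB <- bs$bscore
      libB[!pm$libraryMask] <- NA
      qc[[paste(p, rep_)]] <- data.frame(
        plate_id = p, replicate = rep_,
        scale = bs$scale, degenerate = bs$degenerate,
        max_abs_row_median = max(abs(apply(libB, 1, stats::median,
                                           na.rm = TRUE)), na.rm = TRUE),
        max_abs_col_median = max(abs(apply(libB, 2, stats::median,
                                           na.rm = TRUE)), na.rm = TRUE)
      )
    }
    repTab <- do.call(rbind, meta)
    zres <- zscoreReplicate(repTab$b, repTab$content_class == "library",
                            method = zMethod)
    if (zres$degenerate)
      flags <- c(flags, sprintf("DEGENERATE_Z replicate=%d", rep_))
    repTab$z <- zres$z
    wellScores[[as.character(rep_)]] <- repTab
  }
  wellScores <- do.call(rbind, wellScores)
  rownames(wellScores) <- NULL

  libScores <- wellScores[wellScores$content_class == "library", ,
                          drop = FALSE]
  sirnaTable <- sirnaScores(libScores)
  geneTable <- geneScores(sirnaTable)
  hits <- callHits(geneTable, zThreshold)

  qc <- do.call(rbind, qc)
  rownames(qc) <- NULL
  ctrl <- wellScores[wellScores$content_class %in%
                       c("neg_control", "pos_control"), , drop = FALSE]
  ctrlSep <- if (nrow(ctrl)) {
    negZ <- ctrl$z[ctrl$content_class == "neg_control"]
    posZ <- ctrl$z[ctrl$content_class == "pos_control"]
    data.frame(neg_median_z = stats::median(negZ, na.rm = TRUE),
               pos_median_z = stats::median(posZ, na.rm = TRUE))
  } else {
    data.frame(neg_median_z = NA_real_, pos_median_z = NA_real_)
  }

  list(wellScores = wellScores, sirnaTable = sirnaTable,
       geneTable = geneTable, hits = hits, qc = qc,
       controlSeparation = ctrlSep, flags = flags)
}
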