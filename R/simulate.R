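#' Construct a truth model wired to a screen layout
#'
#' Convenience constructor for \code{\linkS4class{TruthModel}}: draws a
#' potency for every library siRNA from Uniform(0.5, 1), initializes every
#' gene effect and per-siRNA off-target effect to zero, then spikes the
#' requested hit genes (all sibling siRNAs fully potent, a shared additive
#' gene effect) and decoy siRNAs (a single siRNA of an otherwise inactive
#' gene carrying its own large effect, emulating an off-target artifact
#' that the gene-level median is designed to suppress).
#'
#' @param layout plate layout table from \code{\link{buildScreenLayout}}.
#' @param hitGenes character vector of gene ids to spike as true hits.
#' @param hitEffect additive intensity effect given to every sibling siRNA
#'   of a hit gene.
#' @param decoyGenes character vector of gene ids to spike as decoys.
#' @param decoyEffect additive effect given to exactly one siRNA of each
#'   decoy gene.
#' @param seed integer seed for the potency draw.
#' @param ... further slots passed to \code{TruthModel()}
#'   (e.g. \code{noiseSd}, \code{rowEffectRange}, \code{baseline}).
#' @return a validated \code{\linkS4class{TruthModel}}.
#' @examples
#' lay <- buildScreenLayout(ScreenDesign(nGenes = 8))
#' tm <- newTruthModel(lay, hitGenes = "GENE001", hitEffect = 50, seed = 1)
#' tm
#' @export
newTruthModel <- function(layout, hitGenes = character(), hitEffect = 0,
                          decoyGenes = character(), decoyEffect = 0,
                          seed = 1L, ...) {
  lib <- layout[layout$content_class == "library", , drop = FALSE]
  sirnas <- unique(lib$sirna_id)
  genes <- unique(lib$gene_id)
  unknown <- setdiff(c(hitGenes, decoyGenes), genes)
  if (length(unknown))
    stop("gene id(s) absent from the layout: ",
         paste(unknown, collapse = ", "))
  set.seed(as.integer(seed))
  potency <- stats::runif(length(sirnas), 0.5, 1)
  names(potency) <- sirnas
  geneEffect <- stats::setNames(numeric(length(genes)), genes)
  sirnaEffect <- stats::setNames(numeric(length(sirnas)), sirnas)
  sirnaGene <- lib$gene_id[match(sirnas, lib$sirna_id)]
  if (length(hitGenes)) {
    geneEffect[hitGenes] <- hitEffect
    potency[sirnaGene %in% hitGenes] <- 1
  }
  for (g in decoyGenes) {
    s <- sirnas[sirnaGene == g][1]
    sirnaEffect[s] <- decoyEffect
  }
  TruthModel(geneEffect = geneEffect, sirnaPotency = potency,
             sirnaEffect = sirnaEffect, ...)
}

#' Simulate raw per-well screen readouts
#'
#' Draws one raw readout per non-empty well, replicate by replicate, from
#' the additive generative model: baseline, gene effect scaled by siRNA
#' potency plus any per-siRNA off-target effect (library wells), positive
#' control effect (positive controls), per-plate additive row and column
#' artifacts (drawn independently for every plate x replicate unless
#' pinned via \code{fixedEffects}), and Gaussian measurement noise. A
#' nuclei count is drawn per well as
#' Poisson(\code{cellsPerWellMean * attrition}). Empty wells yield a
#' missing value with zero nuclei. Identical seeds give bit-identical
#' tables.
#'
#' @param layout plate layout from \code{\link{buildScreenLayout}}.
#' @param truth a \code{\linkS4class{TruthModel}}; every library siRNA or
#'   gene in the layout without an entry contributes no effect (potency
#'   defaults to 1 for such siRNAs).
#' @param design a \code{\linkS4class{ScreenDesign}} (for replicate count
#'   and plate geometry).
#' @param seed integer seed.
#' @return well table \code{data.frame}: \code{plate_id}, \code{well},
#'   \code{replicate}, \code{raw_value}, \code{n_nuclei}, \code{source}
#'   (\code{"simulated"}).
#' @export
simulateWellValues <- function(layout, truth, design, seed = 1L) {
  stopifnot(is(truth, "TruthModel"), is(design, "ScreenDesign"))
  validObject(truth)
  validatePlateLayout(layout, design@plateRows, design@plateCols)
  set.seed(as.integer(seed))
  nr <- design@plateRows
  nc <- design@plateCols
  rc <- parseWellName(layout$well)
  plates <- unique(layout$plate_id)

  ge <- function(g) {
    v <- truth@geneEffect[g]
    ifelse(is.na(v), 0, v)
  }
  pot <- function(s) {
    v <- truth@sirnaPotency[s]
    ifelse(is.na(v), 1, v)
  }
  se <- function(s) {
    v <- truth@sirnaEffect[s]
    ifelse(is.na(v), 0, v)
  }

  # expected value per well before plate artifacts and noise
  base <- rep(NA_real_, nrow(layout))
  isLib <- layout$content_class == "library"
  base[isLib] <- truth@baseline +
    ge(layout$gene_id[isLib]) * pot(layout$sirna_id[isLib]) +
    se(layout$sirna_id[isLib])
  base[layout$content_class == "neg_control"] <- truth@baseline
  base[layout$content_class == "pos_control"] <-
    truth@baseline + truth@posControlEffect

  out <- vector("list", design@nReplicates)
  for (rep_ in seq_len(design@nReplicates)) {
    value <- base
    for (p in plates) {
      key <- paste0(rep_, ":", p)
      fx <- truth@fixedEffects[[key]]
      if (is.null(fx)) {
        rowEff <- stats::runif(nr, truth@rowEffectRange[1],
                               truth@rowEffectRange[2])
        colEff <- stats::runif(nc, truth@colEffectRange[1],
                               truth@colEffectRange[2])
      } else {
        rowEff <- fx$row
        colEff <- fx$col
        stopifnot(length(rowEff) == nr, length(colEff) == nc)
      }
      i <- layout$plate_id == p
      value[i] <- value[i] + rowEff[rc$row[i]] + colEff[rc$col[i]]
    }
    notEmpty <- !is.na(base)
    if (truth@noiseSd > 0)
      value[notEmpty] <- value[notEmpty] +
        stats::rnorm(sum(notEmpty), 0, truth@noiseSd)
    nNuclei <- integer(nrow(layout))
    nNuclei[notEmpty] <- stats::rpois(
      sum(notEmpty), truth@cellsPerWellMean * truth@attrition)
    out[[rep_]] <- data.frame(
      plate_id = layout$plate_id,
      well = layout$well,
      replicate = rep_,
      raw_value = value,
      n_nuclei = nNuclei,
      source = "simulated",
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
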