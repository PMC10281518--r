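#' @import methods
NULL

#' Screen design parameters
#'
#' An S4 parameter object describing the geometry of an arrayed siRNA
#' screen: the library size, the number of sibling siRNAs per gene (one
#' siRNA per well), the number of biological replicates, and the plate
#' geometry. The default control scheme (\code{"columns_23_24"}) places
#' scrambled negative-control siRNAs in the odd rows of the second-to-last
#' plate column and two alternating positive-control siRNAs (odd/even rows)
#' in the last column, mirroring the layout used for imaging screens on
#' 384-well plates.
#'
#' @slot nGenes number of library genes (default 521).
#' @slot sirnasPerGene number of independent siRNAs per gene (default 3).
#' @slot nReplicates number of biological replicates (default 2).
#' @slot plateRows,plateCols plate geometry (default 16 x 24, a 384-well
#'   plate with rows A--P and columns 1--24).
#' @slot controlScheme control placement scheme; only
#'   \code{"columns_23_24"} is implemented.
#'
#' @examples
#' des <- ScreenDesign(nGenes = 10)
#' des
#' @export ScreenDesign
#' @exportClass ScreenDesign
ScreenDesign <- setClass("ScreenDesign",
  representation(
    nGenes = "integer",
    sirnasPerGene = "integer",
    nReplicates = "integer",
    plateRows = "integer",
    plateCols = "integer",
    controlScheme = "character"
  ),
  prototype(
    nGenes = 521L,
    sirnasPerGene = 3L,
    nReplicates = 2L,
    plateRows = 16L,
    plateCols = 24L,
    controlScheme = "columns_23_24"
  )
)

setValidity("ScreenDesign", function(object) {
  msg <- character()
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@sirnasPerGene < 1L) msg <- c(msg, "sirnasPerGene must be >= 1")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@plateRows < 1L) msg <- c(msg, "plateRows must be >= 1")
  if (!identical(object@controlScheme, "columns_23_24"))
    msg <- c(msg, "unknown controlScheme")
  # control scheme reserves the last two columns; at least one library column
  if (object@plateCols < 3L)
    msg <- c(msg, "plateCols leaves no room for the two control columns")
  if (length(msg)) msg else TRUE
})

setMethod("initialize", "ScreenDesign", function(.Object, ...) {
  args <- list(...)
  for (nm in c("nGenes", "sirnasPerGene", "nReplicates", "plateRows",
               "plateCols")) {
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  }
  .Object <- do.call(callNextMethod, c(list(.Object), args))
  validObject(.Object)
  .Object
})

setMethod("show", "ScreenDesign", function(object) {
  cat("ScreenDesign:", object@nGenes, "genes x", object@sirnasPerGene,
      "siRNAs/gene,", object@nReplicates, "replicate(s)\n")
  cat("  plate geometry:", object@plateRows, "x", object@plateCols,
      " control scheme:", object@controlScheme, "\n")
  cat("  library siRNAs:", object@nGenes * object@sirnasPerGene,
      "over", nPlatesNeeded(object), "plate(s) per replicate\n")
})

#' Number of library wells on one plate
#'
#' Library siRNAs occupy all columns except the two control columns.
#' @param design a \code{\linkS4class{ScreenDesign}}.
#' @return integer count of library positions per plate.
#' @export
libraryWellsPerPlate <- function(design) {
  design@plateRows * (design@plateCols - 2L)
}

#' Number of plates needed for one replicate
#' @param design a \code{\linkS4class{ScreenDesign}}.
#' @return integer plate count.
#' @export
nPlatesNeeded <- function(design) {
  as.integer(ceiling(design@nGenes * design@sirnasPerGene /
                       libraryWellsPerPlate(design)))
}

#' Generative truth model for simulated well values
#'
#' Parameters of the additive generative model used to simulate per-well
#' raw readouts with known ground truth. A library well's expected value is
#' \deqn{baseline + geneEffect[g] \cdot sirnaPotency[s] + sirnaEffect[s]}
#' plus a plate row effect, a plate column effect and Gaussian measurement
#' noise. The screen analysis itself stays on this additive scale (no log
#' transform), so the generator is additive as well. Positive-control wells
#' get \code{posControlEffect} instead of a gene effect; negative controls
#' and empty fitted cells get none. Row/column artifact vectors are drawn
#' uniformly from the stated ranges, independently per plate and per
#' replicate, unless explicit vectors are supplied via \code{fixedEffects}.
#'
#' The per-siRNA \code{sirnaEffect} term models single-oligonucleotide
#' off-target activity (an effect not shared by the gene's sibling
#' siRNAs); it defaults to zero for every siRNA.
#'
#' @slot baseline baseline intensity, arbitrary units (default 1000).
#' @slot geneEffect named numeric, additive intensity shift per gene.
#' @slot sirnaPotency named numeric in [0, 1], multiplier applied to the
#'   gene effect of the siRNA's target gene.
#' @slot sirnaEffect named numeric, additive per-siRNA off-target shift.
#' @slot rowEffectRange,colEffectRange numeric(2) uniform ranges for the
#'   per-plate additive row/column artifacts (defaults [-200, 200] and
#'   [-100, 100]).
#' @slot noiseSd Gaussian measurement noise sd (default 10).
#' @slot posControlEffect additive shift for positive-control wells
#'   (default +300, an increased-signal control).
#' @slot cellsPerWellMean mean number of cells seeded per well
#'   (default 1500).
#' @slot attrition fraction of seeded cells that end up imaged and counted
#'   (default 0.4).
#' @slot fixedEffects optional named list keyed by
#'   \code{"<replicate>:<plate_id>"} with components \code{row} and
#'   \code{col} (numeric vectors matching the plate geometry) overriding
#'   the random artifact draw for that plate.
#'
#' @seealso \code{\link{newTruthModel}} for the usual constructor that
#'   wires a model to a layout, draws potencies and spikes hits/decoys.
#' @export TruthModel
#' @exportClass TruthModel
TruthModel <- setClass("TruthModel",
  representation(
    baseline = "numeric",
    geneEffect = "numeric",
    sirnaPotency = "numeric",
    sirnaEffect = "numeric",
    rowEffectRange = "numeric",
    colEffectRange = "numeric",
    noiseSd = "numeric",
    posControlEffect = "numeric",
    cellsPerWellMean = "numeric",
    attrition = "numeric",
    fixedEffects = "list"
  ),
  prototype(
    baseline = 1000,
    geneEffect = numeric(),
    sirnaPotency = numeric(),
    sirnaEffect = numeric(),
    rowEffectRange = c(-200, 200),
    colEffectRange = c(-100, 100),
    noiseSd = 10,
    posControlEffect = 300,
    cellsPerWellMean = 1500,
    attrition = 0.4,
    fixedEffects = list()
  )
)

setValidity("TruthModel", function(object) {
  msg <- character()
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@sirnaPotency) &&
      (any(object@sirnaPotency < 0) || any(object@sirnaPotency > 1)))
    msg <- c(msg, "sirnaPotency values must lie in [0, 1]")
  if (length(object@rowEffectRange) != 2L ||
      length(object@colEffectRange) != 2L)
    msg <- c(msg, "effect ranges must have length 2")
  if (object@attrition < 0 || object@attrition > 1)
    msg <- c(msg, "attrition must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TruthModel", function(object) {
  cat("TruthModel: baseline", object@baseline, " noise sd", object@noiseSd,
      "\n  row artifacts U[", object@rowEffectRange[1], ",",
      object@rowEffectRange[2], "]  col artifacts U[",
      object@colEffectRange[1], ",", object@colEffectRange[2], "]\n")
  nz <- sum(object@geneEffect != 0)
  cat("  genes with non-zero effect:", nz,
      " siRNAs with off-target effect:", sum(object@sirnaEffect != 0), "\n")
})

#' Rendering parameters for synthetic well images
#'
#' Parameters of the synthetic two-channel (DAPI + YFP) well image
#' renderer. Nuclei are smoothed, optionally boundary-perturbed ellipses
#' placed without mutual contact; a ground-truth label mask and per-nucleus
#' truth table are always emitted alongside the images.
#'
#' @slot imageShape integer(2), image size in pixels (default 256 x 256;
#'   a camera-geometry-sized image can be requested instead).
#' @slot nNuclei number of nuclei to place.
#' @slot radiusRange numeric(2), nucleus radius range in pixels.
#' @slot eccentricity maximal ellipse axis ratio deviation (default 0.25;
#'   axes are scaled by 1 +/- a uniform draw up to this value).
#' @slot irregularity fraction in [0, 1] controlling low-frequency radial
#'   boundary perturbation; 0 renders smooth ellipses.
#' @slot dapiLevel DAPI intensity inside nuclei (default 20000).
#' @slot dapiBackground DAPI background level (default 400).
#' @slot focusBlurSigma Gaussian blur sigma in pixels applied to both
#'   channels (default 0.5).
#' @slot noiseGaussianSd additive Gaussian noise sd (default 100).
#' @slot noisePoisson logical; apply Poisson resampling of pixel counts
#'   before the Gaussian term (default FALSE).
#' @slot fociPerNucleus number of bright centromeric foci per nucleus in
#'   the YFP channel (default 0).
#' @slot fociAmplitude intensity added at each focus (default 4000).
#' @export RenderParams
#' @exportClass RenderParams
RenderParams <- setClass("RenderParams",
  representation(
    imageShape = "integer",
    nNuclei = "integer",
    radiusRange = "numeric",
    eccentricity = "numeric",
    irregularity = "numeric",
    dapiLevel = "numeric",
    dapiBackground = "numeric",
    focusBlurSigma = "numeric",
    noiseGaussianSd = "numeric",
    noisePoisson = "logical",
    fociPerNucleus = "integer",
    fociAmplitude = "numeric"
  ),
  prototype(
    imageShape = c(256L, 256L),
    nNuclei = 40L,
    radiusRange = c(6, 10),
    eccentricity = 0.25,
    irregularity = 0,
    dapiLevel = 20000,
    dapiBackground = 400,
    focusBlurSigma = 0.5,
    noiseGaussianSd = 100,
    noisePoisson = FALSE,
    fociPerNucleus = 0L,
    fociAmplitude = 4000
  )
)

setValidity("RenderParams", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
    msg <- c(msg, "imageShape must be two dimensions >= 16")
  if (object@nNuclei < 0L) msg <- c(msg, "nNuclei must be >= 0")
  if (length(object@radiusRange) != 2L || any(object@radiusRange <= 0) ||
      diff(object@radiusRange) < 0)
    msg <- c(msg, "radiusRange must be a positive non-decreasing pair")
  if (object@irregularity < 0 || object@irregularity > 1)
    msg <- c(msg, "irregularity must lie in [0, 1]")
  if (object@noiseGaussianSd < 0) msg <- c(msg, "noiseGaussianSd must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("initialize", "RenderParams", function(.Object, ...) {
  args <- list(...)
  for (nm in c("imageShape", "nNuclei", "fociPerNucleus")) {
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  }
  .Object <- do.call(callNextMethod, c(list(.Object), args))
  validObject(.Object)
  .Object
})

setMethod("show", "RenderParams", function(object) {
  cat("RenderParams:", paste(object@imageShape, collapse = " x "),
      "px,", object@nNuclei, "nuclei, radius [",
      paste(object@radiusRange, collapse = ", "), "], irregularity",
      object@irregularity, "\n")
})

#' Two-way median-polish fit
#'
#' Result of the iterative alternating row/column median decomposition
#' \code{value = overall + rowEffects[r] + colEffects[c] + residuals[r, c]}
#' at fitted cells. Missing cells are ignored in the medians and stay
#' missing in the residuals.
#'
#' @slot overall fitted grand term.
#' @slot rowEffects,colEffects fitted additive effects.
#' @slot residuals matrix of residuals (NA at missing cells).
#' @slot nIter number of sweeps performed.
#' @slot converged logical convergence flag.
#' @export
#' @exportClass MedianPolishFit
setClass("MedianPolishFit",
  representation(
    overall = "numeric",
    rowEffects = "numeric",
    colEffects = "numeric",
    residuals = "matrix",
    nIter = "integer",
    converged = "logical"
  )
)

setMethod("show", "MedianPolishFit", function(object) {
  cat("MedianPolishFit on a", nrow(object@residuals), "x",
      ncol(object@residuals), "grid:", object@nIter, "sweep(s),",
      if (object@converged) "converged" else "not converged", "\n")
  cat("  overall:", format(object@overall), "\n")
})

#' Fitted additive surface of a median-polish fit
#'
#' @param fit a \code{\linkS4class{MedianPolishFit}}.
#' @return matrix \code{overall + rowEffects + colEffects} over the full
#'   grid (defined for every cell, including cells that were missing in
#'   the fit).
#' @export
polishFitted <- function(fit) {
  stopifnot(is(fit, "MedianPolishFit"))
  fit@overall + outer(fit@rowEffects, fit@colEffects, "+")
}
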