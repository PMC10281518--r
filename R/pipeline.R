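# End-to-end pipeline: simulate -> (optionally render + quantify) ->
# score -> report, with one global seed governing every stochastic stage
# through documented sub-seeding.

#' Derive a per-stage seed from the global seed
#'
#' Stage seeds are a fixed affine hash of the global seed and a stage
#' offset, reduced modulo 2^31 - 1:
#' \code{((seed mod 1000003) * 1009 + offset * 97) mod 2147483647}.
#' This lets individual stages be rerun in isolation with exactly the
#' RNG stream the full pipeline would have used.
#'
#' @param seed global integer seed.
#' @param stage one of \code{"truth"}, \code{"simulate"}, \code{"render"},
#'   \code{"spots"}, or an integer offset.
#' @return integer stage seed in [1, 2^31 - 1).
#' @export
stageSeed <- function(seed, stage) {
  offsets <- c(truth = 1L, simulate = 2L, render = 3L, spots = 4L)
  off <- if (is.character(stage)) {
    if (is.na(offsets[stage])) stop("unknown stage: ", stage)
    offsets[[stage]]
  } else as.integer(stage)
  as.integer(((as.numeric(seed) %% 1000003) * 1009 + off * 97) %%
               2147483647) + 1L
}

#' Default pipeline configuration
#'
#' Returns the fully resolved nested configuration list consumed by
#' \code{\link{runPipeline}}. The defaults describe the reference screen:
#' 521 genes x 3 siRNAs (one per well) across 384-well plates, controls
#' in the last two columns, two biological replicates, additive plate
#' artifacts and Gaussian noise. The \code{images} block switches the
#' measurement path from directly simulated well values to rendered and
#' re-quantified well images.
#'
#' @param seed global seed stored in the configuration.
#' @return named list with blocks \code{design}, \code{truth},
#'   \code{images}, \code{scoring}, \code{report}.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(n_genes = 521L, sirnas_per_gene = 3L,
                  n_replicates = 2L, plate_rows = 16L, plate_cols = 24L),
    truth = list(baseline = 1000, noise_sd = 10,
                 row_effect_range = c(-200, 200),
                 col_effect_range = c(-100, 100),
                 pos_control_effect = 300,
                 # empty sequences as lists so the YAML round trip is exact
                 hit_genes = list(), hit_effect = 0,
                 decoy_genes = list(), decoy_effect = 0),
    images = list(enabled = FALSE, image_shape = c(128L, 128L),
                  n_nuclei = 10L, radius_range = c(6, 10),
                  blur_sigma = 0, noise_sd = 0, write_images = FALSE,
                  min_roundness = 0.775),
    scoring = list(z_method = "robust", z_threshold = 3,
                   max_iter = 100L, tol = 1e-9),
    report = list(top_n = 20L)
  )
}

# fill missing entries of a user config with defaults, recursively
mergeConfig <- function(config, defaults) {
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) {
      config[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(config[[nm]])) {
      config[[nm]] <- mergeConfig(config[[nm]], defaults[[nm]])
    }
  }
  config
}

stageError <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage:", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the simulated-screen pipeline
#'
#' Executes simulate -> (optional render + quantify) -> score -> report
#' under one global seed and writes all tables, the resolved
#' configuration and a run log to \code{outDir}. Reruns with the same
#' configuration and seed produce bit-identical CSV outputs.
#'
#' Files written: \code{platemap.csv}, \code{wells_simulated.csv},
#' \code{wells_imaged.csv} (image path only), \code{well_scores.csv}
#' (per-well B- and Z-scores; plate heat-map data), \code{sirna_scores.csv},
#' \code{gene_scores.csv}, \code{hits.csv}, \code{qc.csv},
#' \code{report.txt}, \code{config.yaml}, \code{log.txt}.
#'
#' @param config configuration list (missing entries take
#'   \code{\link{defaultRunConfig}} values).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with \code{layout}, \code{wells},
#'   \code{scores} and \code{paths}.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir) {
  config <- mergeConfig(config, defaultRunConfig())
  seed <- as.integer(config$seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log <- c(sprintf("hcscreen %s", as.character(utils::packageVersion("hcscreen"))),
           sprintf("seed: %d", seed))

  design <- stageError("design", ScreenDesign(
    nGenes = config$design$n_genes,
    sirnasPerGene = config$design$sirnas_per_gene,
    nReplicates = config$design$n_replicates,
    plateRows = config$design$plate_rows,
    plateCols = config$design$plate_cols))
  layout <- stageError("layout", buildScreenLayout(design))
  writePlateMap(layout, file.path(outDir, "platemap.csv"))

  truth <- stageError("truth", newTruthModel(
    layout,
    hitGenes = as.character(config$truth$hit_genes),
    hitEffect = config$truth$hit_effect,
    decoyGenes = as.character(config$truth$decoy_genes),
    decoyEffect = config$truth$decoy_effect,
    seed = stageSeed(seed, "truth"),
    baseline = config$truth$baseline,
    noiseSd = config$truth$noise_sd,
    rowEffectRange = config$truth$row_effect_range,
    colEffectRange = config$truth$col_effect_range,
    posControlEffect = config$truth$pos_control_effect))

  wellsSim <- stageError("simulate", simulateWellValues(
    layout, truth, design, seed = stageSeed(seed, "simulate")))
  writeWellTable(wellsSim, file.path(outDir, "wells_simulated.csv"))
  log <- c(log, sprintf("simulated %d well values", nrow(wellsSim)))

  wells <- wellsSim
  if (isTRUE(config$images$enabled)) {
    wells <- stageError("render", quantifySimulatedImages(
      wellsSim, config, seed, outDir))
    writeWellTable(wells, file.path(outDir, "wells_imaged.csv"))
    log <- c(log, sprintf("quantified %d rendered wells",
                          sum(!is.na(wells$raw_value))))
  }

  scores <- stageError("score", scoreScreen(
    wells, layout, design,
    zMethod = config$scoring$z_method,
    zThreshold = config$scoring$z_threshold,
    maxIter = config$scoring$max_iter,
    tol = config$scoring$tol))
  writeCsv(scores$wellScores, file.path(outDir, "well_scores.csv"))
  writeCsv(scores$sirnaTable, file.path(outDir, "sirna_scores.csv"))
  writeCsv(scores$geneTable, file.path(outDir, "gene_scores.csv"))
  writeCsv(scores$hits, file.path(outDir, "hits.csv"))
  writeCsv(scores$qc, file.path(outDir, "qc.csv"))
  for (f in scores$flags) log <- c(log, paste("WARN", f))

  writeReport(scores, file.path(outDir, "report.txt"),
              topN = config$report$top_n)
  writeRunConfig(config, file.path(outDir, "config.yaml"))
  log <- c(log, sprintf("elapsed: %.2f s",
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log, file.path(outDir, "log.txt"))

  invisible(list(layout = layout, wells = wells, scores = scores,
                 paths = normalizePath(outDir)))
}

# image path of the pipeline: render every measured well at the simulated
# value and re-quantify it; deterministic per-well sub-seeds
quantifySimulatedImages <- function(wellsSim, config, seed, outDir) {
  ic <- config$images
  renderSeed <- stageSeed(seed, "render")
  imgDir <- file.path(outDir, "images")
  if (isTRUE(ic$write_images))
    dir.create(imgDir, showWarnings = FALSE)
  out <- wellsSim
  out$source <- "imaged"
  measured <- which(!is.na(wellsSim$raw_value))
  params <- RenderParams(imageShape = as.integer(ic$image_shape),
                         nNuclei = ic$n_nuclei,
                         radiusRange = ic$radius_range,
                         focusBlurSigma = ic$blur_sigma,
                         noiseGaussianSd = ic$noise_sd)
  for (i in measured) {
    w <- renderWellImage(params, wellsSim$raw_value[i],
                         seed = (renderSeed + i) %% 2147483647L)
    if (isTRUE(ic$write_images)) {
      stem <- sprintf("%s_%s_r%d", wellsSim$plate_id[i], wellsSim$well[i],
                      wellsSim$replicate[i])
      writeChannelTiff(w$dapi, file.path(imgDir, paste0(stem, "_dapi.tif")))
      writeChannelTiff(w$yfp, file.path(imgDir, paste0(stem, "_yfp.tif")))
    }
    # match the segmentation smoothing to the simulated optical blur so
    # a blur-free render is recovered pixel-exactly
    q <- quantifyWell(w$dapi, w$yfp, minRoundness = ic$min_roundness,
                      blurSigma = ic$blur_sigma)
    out$raw_value[i] <- q$well$well_mean_of_means
    out$n_nuclei[i] <- q$well$n_nuclei_kept
  }
  out
}

#' Write a human-readable screen report
#'
#' Plain-text summary: library size, degeneracy flags, negative/positive
#' control separation, and the top-N gene table (the full table if N
#' exceeds the gene count). Regenerating the report from the same score
#' tables reproduces it byte for byte.
#'
#' @param scores result list of \code{\link{scoreScreen}}.
#' @param path output file.
#' @param topN number of top-ranked genes to print.
#' @return the path, invisibly.
#' @export
writeReport <- function(scores, path, topN = 20L) {
  g <- scores$geneTable
  lines <- c(
    "== screen report ==",
    sprintf("genes scored: %d   siRNAs scored: %d", nrow(g),
            nrow(scores$sirnaTable)),
    sprintf("hits called: %d", nrow(scores$hits)),
    if (length(scores$flags)) paste("flag:", scores$flags) else
      "flags: none",
    sprintf("control separation (robust z): neg %.3f  pos %.3f",
            scores$controlSeparation$neg_median_z,
            scores$controlSeparation$pos_median_z),
    ""
  )
  if (nrow(scores$hits) == 0L)
    lines <- c(lines, "zero hits at the configured threshold", "")
  n <- min(topN, nrow(g))
  top <- g[seq_len(n), c("rank", "gene_id", "gene_median_z", "n_sirnas")]
  lines <- c(lines, sprintf("top %d genes by gene-level median Z:", n),
             utils::capture.output(print(top, row.names = FALSE)))
  writeLines(lines, path)
  invisible(path)
}
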