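#' Build the plate layouts of an arrayed siRNA screen
#'
#' Arrays the library one siRNA per well across as many plates as needed.
#' Library siRNAs fill the non-control columns (1 to \code{plateCols - 2})
#' in row-major order, a gene's sibling siRNAs landing in consecutive
#' wells; unfilled library positions on the last plate stay empty. Under
#' the \code{"columns_23_24"} control scheme the second-to-last column
#' carries the scrambled negative control in odd rows (even rows empty)
#' and the last column carries two alternating positive-control siRNA ids,
#' one in odd and one in even rows.
#'
#' The same physical plate set serves every biological replicate, so one
#' layout table describes the whole screen.
#'
#' @param design a \code{\linkS4class{ScreenDesign}}.
#' @param genePrefix,negControlId,posControlIds identifier cosmetics: gene
#'   ids are \code{<genePrefix><number>}, siRNA ids append \code{_<k>};
#'   the two \code{posControlIds} alternate by row parity.
#' @return A plate layout \code{data.frame} with one row per plate well:
#'   columns \code{plate_id}, \code{well}, \code{row}, \code{col},
#'   \code{content_class} (one of \code{"library"}, \code{"neg_control"},
#'   \code{"pos_control"}, \code{"empty"}), \code{sirna_id},
#'   \code{gene_id} (\code{NA} unless library or positive control).
#' @examples
#' lay <- buildScreenLayout(ScreenDesign(nGenes = 1))
#' subset(lay, content_class != "empty")
#' @export
buildScreenLayout <- function(design,
                              genePrefix = "GENE",
                              negControlId = "siNeg.1",
                              posControlIds = c("siPOS.odd", "siPOS.even")) {
  stopifnot(is(design, "ScreenDesign"))
  validObject(design)
  nr <- design@plateRows
  nc <- design@plateCols
  negCol <- nc - 1L
  posCol <- nc
  nLib <- design@nGenes * design@sirnasPerGene
  perPlate <- libraryWellsPerPlate(design)
  nPlates <- nPlatesNeeded(design)

  width <- max(3L, nchar(as.character(design@nGenes)))
  geneIds <- paste0(genePrefix, formatC(seq_len(design@nGenes),
                                        width = width, flag = "0"))
  sirnaGene <- rep(geneIds, each = design@sirnasPerGene)
  sirnaIds <- paste0(sirnaGene, "_",
                     rep(seq_len(design@sirnasPerGene), design@nGenes))

  out <- vector("list", nPlates)
  for (p in seq_len(nPlates)) {
    plateId <- sprintf("P%02d", p)
    row <- rep(seq_len(nr), each = nc)
    col <- rep(seq_len(nc), nr)
    contentClass <- rep("empty", nr * nc)
    sirna <- rep(NA_character_, nr * nc)
    gene <- rep(NA_character_, nr * nc)

    isLib <- col <= nc - 2L
    # row-major index of the library positions on this plate
    libPos <- (row[isLib] - 1L) * (nc - 2L) + col[isLib]
    libIdx <- (p - 1L) * perPlate + libPos
    filled <- libIdx <= nLib
    libSlots <- which(isLib)[filled]
    contentClass[libSlots] <- "library"
    sirna[libSlots] <- sirnaIds[libIdx[filled]]
    gene[libSlots] <- sirnaGene[libIdx[filled]]

    negSlots <- which(col == negCol & row %% 2L == 1L)
    contentClass[negSlots] <- "neg_control"
    sirna[negSlots] <- negControlId

    posSlots <- which(col == posCol)
    contentClass[posSlots] <- "pos_control"
    sirna[posSlots] <- ifelse(row[posSlots] %% 2L == 1L,
                              posControlIds[1], posControlIds[2])
    gene[posSlots] <- "POS_CONTROL"

    out[[p]] <- data.frame(
      plate_id = plateId,
      well = wellName(row, col),
      row = row, col = col,
      content_class = contentClass,
      sirna_id = sirna,
      gene_id = gene,
      stringsAsFactors = FALSE
    )
  }
  layout <- do.call(rbind, out)
  rownames(layout) <- NULL
  layout
}

#' Validate a plate layout table
#'
#' Checks the structural invariants of a layout: required columns, known
#' content classes, well names covering each plate's geometry exactly
#' once, each library siRNA id appearing at most once per plate, and
#' controls confined to the two control columns.
#'
#' @param layout a layout \code{data.frame} (see
#'   \code{\link{buildScreenLayout}}).
#' @param plateRows,plateCols expected plate geometry.
#' @return the layout, invisibly; stops with an informative message on
#'   violation.
#' @export
validatePlateLayout <- function(layout, plateRows = 16L, plateCols = 24L) {
  need <- c("plate_id", "well", "content_class", "sirna_id", "gene_id")
  missing <- setdiff(need, names(layout))
  if (length(missing))
    stop("layout lacks column(s): ", paste(missing, collapse = ", "))
  badClass <- setdiff(unique(layout$content_class),
                      c("library", "neg_control", "pos_control", "empty"))
  if (length(badClass))
    stop("unknown content_class: ", paste(badClass, collapse = ", "))
  rc <- checkWellsInPlate(layout$well, plateRows, plateCols)
  key <- paste(layout$plate_id, layout$well)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate well in layout: plate ", sub(" .*", "", d),
         " well ", sub(".* ", "", d))
  }
  ctrl <- layout$content_class %in% c("neg_control", "pos_control")
  if (any(ctrl & rc$col < plateCols - 1L))
    stop("control wells outside the control columns")
  lib <- layout$content_class == "library"
  if (any(lib & rc$col > plateCols - 2L))
    stop("library wells inside the control columns")
  perPlate <- split(layout$sirna_id[lib], layout$plate_id[lib])
  for (p in names(perPlate)) {
    if (anyDuplicated(perPlate[[p]]))
      stop("library siRNA duplicated on plate ", p, ": ",
           perPlate[[p]][duplicated(perPlate[[p]])][1])
  }
  invisible(layout)
}
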