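# Well-name handling for multiwell plates: canonical form is a row letter
# (A, B, ... borrowing AA-style extension beyond 26 rows is not needed at
# 384-well scale) followed by a zero-padded two-digit column, e.g. "A01".

#' Format plate well names
#'
#' @param row,col integer row and column indices (1-based; row 1 = "A").
#' @return character well names like \code{"A01"}.
#' @examples
#' wellName(1, 1)    # "A01"
#' wellName(16, 24)  # "P24"
#' @export
wellName <- function(row, col) {
  stopifnot(all(row >= 1L), all(row <= 26L), all(col >= 1L), all(col <= 99L))
  paste0(LETTERS[row], formatC(col, width = 2, flag = "0"))
}

#' Parse plate well names
#'
#' @param x character vector of well names (\code{"A01"} style).
#' @return data.frame with integer columns \code{row} and \code{col}.
#' @examples
#' parseWellName(c("A01", "P24"))
#' @export
parseWellName <- function(x) {
  ok <- grepl("^[A-Z][0-9]{2}$", x)
  if (!all(ok))
    stop("malformed well name(s): ", paste(unique(x[!ok]), collapse = ", "))
  row <- match(substr(x, 1, 1), LETTERS)
  col <- as.integer(substr(x, 2, 3))
  if (any(col < 1L))
    stop("well column out of range in: ",
         paste(unique(x[col < 1L]), collapse = ", "))
  data.frame(row = row, col = col)
}

# validate well names against a plate geometry, stopping with offenders
checkWellsInPlate <- function(wells, plateRows, plateCols) {
  rc <- parseWellName(wells)
  bad <- rc$row > plateRows | rc$col > plateCols
  if (any(bad))
    stop("well name(s) outside the ", plateRows, "x", plateCols,
         " plate: ", paste(unique(wells[bad]), collapse = ", "))
  rc
}
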