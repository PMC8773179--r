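#' 384-well plate well-label utilities
#'
#' Wells are labelled by row letter A--P and column number 1--24. The
#' canonical dialect has no zero padding ("A1"); a zero-padded dialect
#' ("A01") is accepted on input and available on output for instruments
#' that require it.
#'
#' @name wells
NULL

PLATE_ROWS <- LETTERS[1:16]
PLATE_COLS <- 1:24
PLATE_WELLS <- 384L

#' All well labels of a 384-well plate in row-major order
#'
#' @param zero_pad pad column numbers to two digits ("A01" instead of "A1")
#' @return character vector of length 384, A1..A24, B1..B24, ..., P24
#' @export
well_labels <- function(zero_pad = FALSE) {
  cols <- if (zero_pad) sprintf("%02d", PLATE_COLS) else as.character(PLATE_COLS)
  as.vector(t(outer(PLATE_ROWS, cols, paste0)))
}

#' Parse well labels into row/column indices
#'
#' Accepts both "A1" and zero-padded "A01" forms.
#'
#' @param wells character vector of well labels
#' @return data.frame with columns `row` (1--16), `col` (1--24), `well`
#'   (normalized, unpadded label)
#' @export
parse_well <- function(wells) {
  wells <- as.character(wells)
  m <- regmatches(wells, regexec("^([A-P])0?([1-9]|1[0-9]|2[0-4])$", wells))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed well label(s): ", paste(unique(wells[bad]), collapse = ", "),
         call. = FALSE)
  }
  row <- match(vapply(m, `[`, "", 2L), PLATE_ROWS)
  col <- as.integer(vapply(m, `[`, "", 3L))
  data.frame(row = row, col = col,
             well = paste0(PLATE_ROWS[row], col),
             stringsAsFactors = FALSE)
}

#' @keywords internal
is_valid_well <- function(wells) {
  grepl("^([A-P])0?([1-9]|1[0-9]|2[0-4])$", as.character(wells))
}

# row-major sort key for well labels (A1=1 .. P24=384)
well_order_key <- function(wells) {
  p <- parse_well(wells)
  (p$row - 1L) * 24L + p$col
}

# condition label -> barcode-safe slug ("20mM+IBMX" -> "20mMIBMX")
condition_slug <- function(condition) {
  gsub("[^A-Za-z0-9]", "", condition)
}
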