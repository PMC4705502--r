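#' Read a labelled square judgment matrix from CSV
#'
#' Judgment matrices (pairwise-comparison matrices on the Saaty scale and
#' influence matrices on the 0--4 scale) are exchanged as square CSV tables
#' with a header row and a leading label column. Cells may use a decimal
#' point or a decimal comma (`"0,5"`), and comparison matrices may contain
#' vulgar fractions such as `"1/9"`.
#'
#' @param path path to a CSV file.
#' @return a square numeric matrix with row and column names.
#' @export
#' @examples
#' f <- system.file("extdata", "cost_comparison.csv", package = "danpselect")
#' read_matrix_csv(f)
read_matrix_csv <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (ncol(raw) < 2) stopf("'%s' is not a labelled matrix CSV", path)
  labels <- trimws(raw[[1]])
  cols <- trimws(names(raw)[-1])
  if (length(labels) != length(cols) || !all(labels == cols)) {
    stopf("'%s': row labels and column labels disagree", path)
  }
  m <- vapply(raw[-1], function(col) vapply(col, parse_cell, numeric(1)),
              numeric(length(labels)))
  m <- matrix(m, nrow = length(labels), dimnames = list(labels, labels))
  m
}

# "3", "0,5", ".5", "1/9" -> numeric; empty/NA -> 0 (DEMATEL blank diagonal).
parse_cell <- function(x) {
  x <- gsub(",", ".", trimws(x), fixed = TRUE)
  if (is.na(x) || x == "") return(0)
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stopf("cannot parse matrix cell '%s'", x)
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num) || num[2] == 0) stopf("cannot parse matrix cell '%s'", x)
    return(num[1] / num[2])
  }
  val <- suppressWarnings(as.numeric(x))
  if (is.na(val)) stopf("cannot parse matrix cell '%s'", x)
  val
}

#' Write a labelled square matrix to CSV
#'
#' Inverse of [read_matrix_csv()]: writes the matrix with a header row and a
#' leading label column, decimal points, full precision (17 significant
#' digits, so a write/read round trip is exact).
#'
#' @param m square numeric matrix with dimnames.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  if (!is_square(m)) stopf("'m' must be a square matrix")
  m <- label_matrix(m)
  df <- data.frame(format(rownames(m)), format(m, digits = 17, trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("", colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
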