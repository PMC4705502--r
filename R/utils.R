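#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate arrange filter select left_join bind_rows group_by
#'   summarise ungroup across desc row_number
NULL

# Round half away from zero at `digits` decimals (base round() is banker's).
round_half_up <- function(x, digits = 5) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

stopf <- function(fmt, ..., class = "danpselect_error") {
  abort(sprintf(fmt, ...), class = class)
}

warnf <- function(fmt, ...) warn(sprintf(fmt, ...))

# Attach row/column labels, recycling from existing dimnames if absent.
label_matrix <- function(m, labels = NULL) {
  if (is.null(labels)) labels <- rownames(m) %||% colnames(m)
  if (is.null(labels)) labels <- paste0("E", seq_len(nrow(m)))
  if (length(labels) != nrow(m)) {
    stopf("labels length (%d) does not match matrix dimension (%d)",
          length(labels), nrow(m))
  }
  dimnames(m) <- list(labels, labels)
  m
}
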