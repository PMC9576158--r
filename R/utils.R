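#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.00005 -> 0.0001), the convention of
#' the printed diversity tables; base `round()` rounds ties to even.
#'
#' @param x numeric.
#' @param digits number of decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## resolve an accession subset ("all", character ids, or logical/integer index)
## to column indices of x, erroring usefully
.resolveSubset <- function(x, subset) {
  ids <- colnames(x)
  if (is.null(subset) || identical(subset, "all")) return(seq_along(ids))
  if (is.logical(subset)) subset <- which(subset)
  if (is.numeric(subset)) {
    if (length(subset) == 0L) stop("empty accession subset")
    stopifnot(all(subset >= 1L), all(subset <= length(ids)))
    return(as.integer(subset))
  }
  idx <- match(subset, ids)
  if (length(idx) == 0L) stop("empty accession subset")
  if (anyNA(idx))
    stop("unknown accession id(s): ",
         paste(head(subset[is.na(idx)], 5), collapse = ", "))
  idx
}
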