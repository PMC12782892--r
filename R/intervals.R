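# Genomic coordinates are 1-based throughout. Interval length for QTL
# window reporting defaults to the difference convention (end - start),
# which matches how narrowed QTL windows are conventionally quoted in kb;
# the inclusive convention (end - start + 1) is what a deletion's size in
# bp requires.

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Length of a genomic interval in kilobases
#'
#' Computes `(end - start) / 1000` under the default difference convention,
#' rounded half-up to one decimal; the inclusive convention adds 1 bp
#' before dividing. Vectorized over `start`/`end`.
#'
#' @param start,end 1-based integer coordinates, `end >= start`.
#' @param convention `"difference"` (default) or `"inclusive"`.
#' @return Numeric vector of lengths in kb, one decimal.
#' @examples
#' interval_length_kb(28907974, 29398499) # 490.5
#' @export
interval_length_kb <- function(start, end, convention = c("difference", "inclusive")) {
  convention <- match.arg(convention)
  if (any(end < start)) {
    abort("Interval end must be >= start.", class = "markergap_ordering_error")
  }
  bp <- end - start + if (convention == "inclusive") 1 else 0
  round_half_up(bp / 1000, 1)
}

#' Length of a deletion in base pairs
#'
#' Deletion coordinates are inclusive of both endpoints, so the length is
#' `end - start + 1`.
#'
#' @param start,end 1-based inclusive coordinates, `end >= start`.
#' @return Integer vector of lengths in bp.
#' @examples
#' deletion_length_bp(9126219, 9126434) # 216
#' @export
deletion_length_bp <- function(start, end) {
  if (any(end < start)) {
    abort("Deletion end must be >= start.", class = "markergap_ordering_error")
  }
  as.integer(end - start + 1)
}
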