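#' Convert between 1-based point and 0-based half-open interval coordinates
#'
#' All interval data in this package (BED tracks, windows, masks) use 0-based
#' half-open coordinates; variant positions mirror VCF and stay 1-based. These
#' two functions are the only crossing point between the conventions: a 1-based
#' point `p` corresponds to the half-open interval `[p - 1, p)`.
#'
#' @param pos Integer vector of 1-based positions.
#' @return `point_to_interval()` returns a two-column matrix (`start`, `end`)
#'   of 0-based half-open intervals; `interval_start_to_point()` returns the
#'   1-based position of the first base covered by an interval start.
#' @examples
#' point_to_interval(1)              # [0, 1)
#' interval_start_to_point(0)        # 1
#' @export
point_to_interval <- function(pos) {
  stopifnot(is.numeric(pos), all(pos >= 1))
  cbind(start = as.integer(pos) - 1L, end = as.integer(pos))
}

#' @rdname point_to_interval
#' @param start Integer vector of 0-based interval start coordinates.
#' @export
interval_start_to_point <- function(start) {
  stopifnot(is.numeric(start), all(start >= 0))
  as.integer(start) + 1L
}
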