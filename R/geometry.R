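#' Circular distance between positions
#'
#' The array of neurons is treated as a ring to avoid border effects, so the
#' distance between two positions is measured along the shorter arc.
#'
#' @param a,b positions in degrees, in \code{[0, period)}. Vectorized.
#' @param period extent of the circular space in degrees (default 180).
#' @return Nonnegative distance in degrees, at most \code{period/2}.
#' @examples
#' circular_distance(100, 120)  # 20
#' circular_distance(1, 179)    # 2, wraps around
#' @export
circular_distance <- function(a, b, period = 180) {
  d <- abs(a - b)
  pmin(d, period - d)
}

#' Signed circular difference
#'
#' Wraps \code{a - b} into \code{(-period/2, period/2]}; positive values point
#' toward increasing degrees. Used to express a perceived position as a shift
#' relative to the true stimulus position.
#'
#' @inheritParams circular_distance
#' @return Signed difference in degrees in \code{(-period/2, period/2]}.
#' @examples
#' perceived_shift(108.6, 100)  # +8.6
#' perceived_shift(1, 179)      # +2
#' @export
perceived_shift <- function(a, b, period = 180) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}
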