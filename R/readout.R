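#' Decode a perceived position from population activity
#'
#' Three metrics turn an activity profile over the ring into a single
#' perceived position in degrees. Because the 180-degree space is circular,
#' unit labels are doubled onto the full circle (unit k maps to angle 2k
#' degrees), so every metric is well defined across the wrap.
#'
#' \describe{
#'   \item{vector}{Population vector: each unit contributes a planar vector
#'     of length equal to its activity and phase twice its preferred
#'     position; the decoded position is half the phase of the resultant.}
#'   \item{barycenter}{Activity-weighted mean position. The window of
#'     positions is first re-centered on the circular mean (the vector-metric
#'     estimate) so the weighted average is taken on an unwrapped axis; for
#'     profiles with reflective symmetry about their circular mean it equals
#'     the vector metric exactly.}
#'   \item{wta}{Winner-takes-all: the preferred position of the most active
#'     unit; ties are broken by the circular midpoint (doubled-angle circular
#'     mean) of the tied set.}
#' }
#'
#' @param y activity vector (one entry per unit); must contain at least one
#'   strictly positive value.
#' @param metric \code{"vector"}, \code{"barycenter"} or \code{"wta"}.
#' @param params an \code{\link{av_params}} set (supplies unit positions and
#'   the period of the space).
#' @return Perceived position in degrees, in \code{[0, 180)}.
#' @examples
#' p <- av_params()
#' y <- exp(-circular_distance(unit_positions(p), 120)^2 / 50)
#' decode_position(y, "vector", p)  # 120
#' @export
decode_position <- function(y, metric = c("vector", "barycenter", "wta"),
                            params = av_params()) {
  metric <- match.arg(metric)
  n <- params$n_units
  if (length(y) != n) stop("activity vector must have length n_units")
  if (all(y <= 0)) stop("undefined percept: no unit has positive activity")
  switch(metric,
         vector = population_vector(y, params),
         barycenter = barycenter(y, params),
         wta = winner_takes_all(y, params))
}

#' @rdname decode_position
#' @export
population_vector <- function(y, params = av_params()) {
  if (all(y <= 0)) stop("undefined percept: no unit has positive activity")
  circular_mean(unit_positions(params), y, space_period(params))
}

#' @rdname decode_position
#' @export
barycenter <- function(y, params = av_params()) {
  if (all(y <= 0)) stop("undefined percept: no unit has positive activity")
  period <- space_period(params)
  center <- circular_mean(unit_positions(params), y, period)
  # re-center positions into (center - period/2, center + period/2] and take
  # the plain weighted mean on the unwrapped axis; a unit exactly antipodal
  # to the center is equidistant both ways, so its offset contribution is
  # split evenly (i.e. cancels) rather than landing on one branch
  rel <- perceived_shift(unit_positions(params), center, period)
  rel[abs(abs(rel) - period / 2) < 1e-9] <- 0
  canonical_deg((center + sum(rel * y) / sum(y)) %% period, period)
}

#' @rdname decode_position
#' @export
winner_takes_all <- function(y, params = av_params()) {
  if (all(y <= 0)) stop("undefined percept: no unit has positive activity")
  period <- space_period(params)
  tied <- which(y >= max(y) - 1e-12)
  pos <- unit_positions(params)[tied]
  if (length(tied) == 1L) return(pos %% period)
  # circular midpoint of the tied set via the doubled-angle mean; a fully
  # symmetric tie (zero resultant) degenerates to the smallest tied position
  ang <- pos * 2 * pi / period
  re <- sum(cos(ang)); im <- sum(sin(ang))
  if (sqrt(re^2 + im^2) < 1e-9) return(min(pos))
  canonical_deg((atan2(im, re) * period / (2 * pi)) %% period, period)
}

# weighted circular mean on a space of the given period, via angle doubling
# onto the full circle
circular_mean <- function(pos, w, period) {
  ang <- pos * 2 * pi / period
  re <- sum(w * cos(ang))
  im <- sum(w * sin(ang))
  if (re == 0 && im == 0) stop("undefined percept: zero resultant vector")
  canonical_deg((atan2(im, re) * period / (2 * pi)) %% period, period)
}

# fold floating-point results within 1e-9 of the period back onto 0 (the
# same point on the ring), so decoders never report e.g. 180 for 0
canonical_deg <- function(x, period) {
  x[x > period - 1e-9] <- 0
  x
}
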