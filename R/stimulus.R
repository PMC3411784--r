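#' Define an external stimulus
#'
#' A punctate stimulus of one modality, characterised by its position on the
#' ring, its strength and (optionally) the width of the Gaussian input it
#' produces once filtered by the neurons' receptive fields. When \code{width}
#' is \code{NULL} the modality's default width (\code{sigma_a} or
#' \code{sigma_v}) is taken from the parameter set at evaluation time.
#'
#' @param modality \code{"auditory"} or \code{"visual"}.
#' @param position stimulus position in degrees, in \code{[0, 180)}.
#' @param strength input amplitude (dimensionless, nonnegative).
#' @param width optional Gaussian width override in degrees.
#' @return An object of class \code{av_stimulus}.
#' @examples
#' av_stimulus("auditory", position = 100, strength = 15)
#' @export
av_stimulus <- function(modality = c("auditory", "visual"),
                        position, strength, width = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(position), length(position) == 1L,
            is.numeric(strength), length(strength) == 1L)
  if (strength < 0) stop("stimulus strength must be nonnegative")
  if (!is.null(width)) {
    stopifnot(is.numeric(width), length(width) == 1L)
    if (width <= 0) stop("stimulus width must be positive")
  }
  structure(list(modality = modality, position = position,
                 strength = strength, width = width),
            class = "av_stimulus")
}

#' @export
print.av_stimulus <- function(x, ...) {
  cat(sprintf("%s stimulus at %g deg, strength %g%s\n", x$modality,
              x$position, x$strength,
              if (is.null(x$width)) "" else sprintf(", width %g deg", x$width)))
  invisible(x)
}

#' External input profile of a stimulus
#'
#' The input delivered to each neuron of the stimulated layer: a Gaussian of
#' the circular distance between the neuron's preferred position and the
#' stimulus position, peaking at exactly the stimulus strength.
#'
#' @param stim an \code{\link{av_stimulus}}.
#' @param params an \code{\link{av_params}} set.
#' @return Numeric vector of length \code{params$n_units}.
#' @examples
#' e <- external_input(av_stimulus("visual", 120, 15), av_params())
#' e[121]  # unit at 120 deg receives the full strength 15
#' @export
external_input <- function(stim, params) {
  stopifnot(inherits(stim, "av_stimulus"))
  period <- space_period(params)
  if (stim$position < 0 || stim$position >= period)
    stop("stimulus position must lie in [0, ", period, ")")
  sigma <- if (!is.null(stim$width)) stim$width else
    switch(stim$modality, auditory = params$sigma_a, visual = params$sigma_v)
  d <- circular_distance(unit_positions(params), stim$position, period)
  stim$strength * exp(-d^2 / (2 * sigma^2))
}

# Sum the input profiles of a list of stimuli into per-layer input vectors.
stimulus_fields <- function(stimuli, params) {
  if (inherits(stimuli, "av_stimulus")) stimuli <- list(stimuli)
  E_a <- numeric(params$n_units)
  E_v <- numeric(params$n_units)
  for (stim in stimuli) {
    if (is.null(stim)) next
    prof <- external_input(stim, params)
    if (stim$modality == "auditory") E_a <- E_a + prof else E_v <- E_v + prof
  }
  list(E_a = E_a, E_v = E_v)
}
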