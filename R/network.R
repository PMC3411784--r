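#' Initial lateral weight matrices
#'
#' Before training, the lateral synapses of each layer follow a Mexican-hat
#' profile built as the difference of two Gaussians of the circular distance
#' between the pre- and post-synaptic units: strong narrow excitation minus
#' weaker broad inhibition. Self-loops are excluded (zero diagonal). The same
#' profile is used for both layers and every post-synaptic neuron, so the
#' initial matrices are symmetric and translation-invariant on the ring.
#'
#' @param params an \code{\link{av_params}} set.
#' @return List with matrices \code{L_ex} and \code{L_in}, both
#'   \code{[post x pre]}, nonnegative, zero on the diagonal.
#' @examples
#' w <- lateral_weights(av_params())
#' w$L_ex[1, 2] - w$L_in[1, 2]  # net excitation at 1 deg: ~0.719
#' @export
lateral_weights <- function(params) {
  pos <- unit_positions(params)
  period <- space_period(params)
  d <- outer(pos, pos, circular_distance, period = period)
  L_ex <- params$L_ex0 * exp(-d^2 / (2 * params$sigma_ex^2))
  L_in <- params$L_in0 * exp(-d^2 / (2 * params$sigma_in^2))
  diag(L_ex) <- 0
  diag(L_in) <- 0
  list(L_ex = L_ex, L_in = L_in)
}

#' Build a network
#'
#' Assembles the two-layer network: one auditory and one visual ring of
#' neurons, each with its own excitatory and inhibitory lateral weight
#' matrices (identical before training), coupled by one-to-one excitatory
#' inter-area synapses of strength \code{W}. The pre-training row sums of the
#' weight matrices are stored as the normalization targets used during
#' Hebbian training.
#'
#' @param params an \code{\link{av_params}} set.
#' @return An object of class \code{av_network}.
#' @examples
#' net <- av_network(av_params())
#' net
#' @export
av_network <- function(params = av_params()) {
  stopifnot(inherits(params, "av_params"))
  w <- lateral_weights(params)
  net <- list(
    params = params,
    auditory = list(L_ex = w$L_ex, L_in = w$L_in),
    visual = list(L_ex = w$L_ex, L_in = w$L_in),
    target_ex = rowSums(w$L_ex),
    target_in = rowSums(w$L_in),
    trained = FALSE
  )
  class(net) <- "av_network"
  net
}

#' @export
print.av_network <- function(x, ...) {
  p <- x$params
  cat(sprintf("Two-layer audio-visual ring network (%d units/layer, W=%g)\n",
              p$n_units, p$W))
  cat(sprintf("  lateral synapses: %s\n",
              if (x$trained) "trained" else "pre-training Mexican hat"))
  net_w <- x$auditory$L_ex[1, 2] - x$auditory$L_in[1, 2]
  cat(sprintf("  auditory net lateral weight at 1 deg: %.4f\n", net_w))
  invisible(x)
}

#' Sigmoidal activation function
#'
#' Static input-output relationship of each neuron:
#' \code{F(u) = 1 / (1 + exp(-s * (u - theta)))}. Activity saturates at 1
#' (all activities are normalized to the maximum) and is negligible at zero
#' input under basal \code{theta} and \code{s}.
#'
#' @param u net input (vectorized).
#' @param params an \code{\link{av_params}} set.
#' @return Activation in (0, 1).
#' @export
activation <- function(u, params) {
  1 / (1 + exp(-params$s * (u - params$theta)))
}

#' Net input to each neuron
#'
#' The input to a neuron is the sum of three contributions: the external
#' input, the lateral input from its own layer (net weights
#' \code{L_ex - L_in} times the layer activity) and the cross-modal input
#' \code{W} times the activity of the unit at the same position in the other
#' layer.
#'
#' @param net an \code{\link{av_network}}.
#' @param y_a,y_v activity vectors of the auditory and visual layer.
#' @param E_a,E_v external input vectors.
#' @return List with input vectors \code{u_a} and \code{u_v}.
#' @export
net_input <- function(net, y_a, y_v, E_a, E_v) {
  n <- net$params$n_units
  if (length(y_a) != n || length(y_v) != n ||
      length(E_a) != n || length(E_v) != n)
    stop("activity/input vectors must have length n_units")
  W <- net$params$W
  u_a <- E_a + drop((net$auditory$L_ex - net$auditory$L_in) %*% y_a) + W * y_v
  u_v <- E_v + drop((net$visual$L_ex - net$visual$L_in) %*% y_v) + W * y_a
  list(u_a = u_a, u_v = u_v)
}

# One explicit Euler step of the rate dynamics (no plasticity).
# Returns updated activities; errors out if activities leave [0,1] by more
# than a small floating-point guard (instability), as drift is never silently
# clipped.
euler_step <- function(net, y_a, y_v, E_a, E_v) {
  p <- net$params
  u <- net_input(net, y_a, y_v, E_a, E_v)
  r <- p$dt / p$tau_y
  y_a2 <- y_a + r * (-y_a + activation(u$u_a, p))
  y_v2 <- y_v + r * (-y_v + activation(u$u_v, p))
  guard <- 1e-9
  if (any(y_a2 < -guard | y_a2 > 1 + guard | y_v2 < -guard | y_v2 > 1 + guard))
    stop("integration instability: activity left [0,1] (max |y| = ",
         format(max(abs(c(y_a2, y_v2)))), "); reduce dt")
  list(y_a = y_a2, y_v = y_v2)
}

#' Simulate the network to steady state
#'
#' Integrates the rate equations with the explicit Euler method from rest
#' (all activities zero) with the given stimuli switched on at t = 0 and held
#' constant. Integration stops when the maximum rate of change of any unit
#' falls below \code{params$tol} (per ms) or when \code{params$max_t} is
#' reached; in the latter case the result carries \code{converged = FALSE}
#' and the residual.
#'
#' @param net an \code{\link{av_network}}.
#' @param stimuli an \code{\link{av_stimulus}} or list of them (possibly one
#'   per modality); \code{NULL} entries are ignored.
#' @param snapshot_times optional numeric vector of times (ms) at which to
#'   record the full activity profiles.
#' @return An object of class \code{av_state}: list with activity vectors
#'   \code{y_a}, \code{y_v}, final time \code{t} (ms), \code{converged},
#'   \code{residual} (max |dy/dt| at the final step) and, if requested,
#'   \code{snapshots} (a data frame with columns \code{time_ms},
#'   \code{modality}, \code{unit_deg}, \code{activity}).
#' @examples
#' net <- av_network(av_params())
#' st <- simulate_network(net, av_stimulus("auditory", 120, 15))
#' which.max(st$y_a) - 1  # peak at 120 deg
#' @export
simulate_network <- function(net, stimuli, snapshot_times = NULL) {
  stopifnot(inherits(net, "av_network"))
  p <- net$params
  f <- stimulus_fields(stimuli, p)
  n_steps <- ceiling(p$max_t / p$dt)
  y_a <- numeric(p$n_units)
  y_v <- numeric(p$n_units)
  snaps <- list()
  snap_steps <- if (!is.null(snapshot_times))
    pmax(1L, round(snapshot_times / p$dt)) else integer()
  converged <- FALSE
  residual <- NA_real_
  t <- 0
  for (k in seq_len(n_steps)) {
    yy <- euler_step(net, y_a, y_v, f$E_a, f$E_v)
    residual <- max(abs(c(yy$y_a - y_a, yy$y_v - y_v))) / p$dt
    y_a <- yy$y_a
    y_v <- yy$y_v
    t <- k * p$dt
    if (k %in% snap_steps)
      snaps[[length(snaps) + 1L]] <- snapshot_frame(t, y_a, y_v, p)
    if (residual < p$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("no steady state within ", p$max_t, " ms (residual ",
            format(residual), " /ms)")
  out <- list(y_a = y_a, y_v = y_v, t = t, converged = converged,
              residual = residual,
              snapshots = if (length(snaps)) do.call(rbind, snaps) else NULL)
  class(out) <- "av_state"
  out
}

snapshot_frame <- function(t, y_a, y_v, p) {
  deg <- unit_positions(p)
  data.frame(
    time_ms = t,
    modality = rep(c("auditory", "visual"), each = p$n_units),
    unit_deg = c(deg, deg),
    activity = c(y_a, y_v)
  )
}

#' @export
print.av_state <- function(x, ...) {
  cat(sprintf("Network state at t = %g ms (%s, residual %.3g /ms)\n", x$t,
              if (x$converged) "converged" else "NOT converged", x$residual))
  cat(sprintf("  auditory: max activity %.3f at %d deg\n",
              max(x$y_a), which.max(x$y_a) - 1L))
  cat(sprintf("  visual:   max activity %.3f at %d deg\n",
              max(x$y_v), which.max(x$y_v) - 1L))
  invisible(x)
}
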