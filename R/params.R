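#' Model parameters
#'
#' Builds the full parameter set of the two-layer ring network. Defaults are
#' the basal values of the model: two chains of 180 neurons, 1 degree apart,
#' covering a circular 180-degree space; Gaussian external inputs whose width
#' encodes cue reliability (narrow visual, broad auditory); a common sigmoidal
#' activation and membrane time constant; Mexican-hat lateral connectivity
#' (narrow strong excitation, broad weaker inhibition); one-to-one excitatory
#' inter-area coupling \code{W}; and Hebbian-rule constants for training the
#' lateral synapses.
#'
#' @param E0_a,E0_v external input strength (dimensionless) for the auditory
#'   and visual stimulus.
#' @param sigma_a,sigma_v standard deviation (degrees) of the Gaussian input;
#'   the auditory receptive field is much broader than the visual one.
#' @param theta center of the sigmoidal activation (input units).
#' @param s slope of the sigmoidal activation.
#' @param tau_y membrane time constant (ms).
#' @param L_ex0,L_in0 peak strength of lateral excitatory/inhibitory weights.
#' @param sigma_ex,sigma_in Gaussian widths (degrees) of the lateral
#'   excitatory/inhibitory weight profiles; a Mexican hat needs
#'   \code{L_ex0 > L_in0} and \code{sigma_ex < sigma_in}.
#' @param W strength of the one-to-one excitatory inter-area synapses.
#' @param alpha_ex0 maximum learning factor of excitatory lateral synapses
#'   (the factor at zero synapse strength).
#' @param alpha_in0 maximum learning factor of inhibitory lateral synapses.
#' @param theta_post post-synaptic activity threshold gating plasticity,
#'   in (0, 1).
#' @param L_max saturation value of each excitatory lateral synapse.
#' @param tau_L learning time constant (ms) scaling the per-step Hebbian
#'   update.
#' @param n_units number of neurons per layer.
#' @param spacing degrees between adjacent neurons.
#' @param dt Euler integration step (ms).
#' @param max_t hard cap on simulated time when seeking a steady state (ms).
#' @param tol steady-state criterion: maximum |dy/dt| (1/ms) below which the
#'   network is declared converged.
#'
#' @return An object of class \code{av_params}: a validated named list.
#' @examples
#' p <- av_params()
#' p$sigma_a / p$sigma_v  # auditory/visual reliability ratio
#' @export
av_params <- function(E0_a = 15, E0_v = 15,
                      sigma_a = 32, sigma_v = 4,
                      theta = 12, s = 0.6, tau_y = 3,
                      L_ex0 = 2.4, sigma_ex = 2,
                      L_in0 = 1.4, sigma_in = 24,
                      W = 5,
                      alpha_ex0 = 0.015, alpha_in0 = 0.025,
                      theta_post = 0.5, L_max = 2.4, tau_L = 0.5,
                      n_units = 180, spacing = 1,
                      dt = 0.1, max_t = 500, tol = 1e-6) {
  p <- list(E0_a = E0_a, E0_v = E0_v, sigma_a = sigma_a, sigma_v = sigma_v,
            theta = theta, s = s, tau_y = tau_y,
            L_ex0 = L_ex0, sigma_ex = sigma_ex,
            L_in0 = L_in0, sigma_in = sigma_in, W = W,
            alpha_ex0 = alpha_ex0, alpha_in0 = alpha_in0,
            theta_post = theta_post, L_max = L_max, tau_L = tau_L,
            n_units = n_units, spacing = spacing,
            dt = dt, max_t = max_t, tol = tol)
  class(p) <- "av_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (k in names(p)) {
    if (!num1(p[[k]])) stop("parameter '", k, "' must be a finite scalar")
  }
  if (p$n_units <= 0 || p$n_units != round(p$n_units))
    stop("n_units must be a positive integer")
  pos <- c("sigma_a", "sigma_v", "tau_y", "s", "spacing", "dt", "max_t",
           "tol", "L_max", "tau_L")
  for (k in pos) if (p[[k]] <= 0) stop("parameter '", k, "' must be > 0")
  nonneg <- c("E0_a", "E0_v", "L_ex0", "L_in0", "W", "alpha_ex0", "alpha_in0")
  for (k in nonneg) if (p[[k]] < 0) stop("parameter '", k, "' must be >= 0")
  if (p$theta_post <= 0 || p$theta_post >= 1)
    stop("theta_post must lie strictly between 0 and 1")
  if (p$dt >= p$tau_y)
    stop("integration step dt must be well below tau_y")
  # Mexican-hat shape is the intended regime but sensitivity sweeps may leave
  # it; warn instead of failing.
  if (!(p$L_ex0 > p$L_in0 && p$sigma_ex < p$sigma_in))
    warning("lateral weights do not form a Mexican hat ",
            "(need L_ex0 > L_in0 and sigma_ex < sigma_in)")
  invisible(p)
}

#' @export
print.av_params <- function(x, ...) {
  cat("Audio-visual ring network parameters\n")
  cat(sprintf("  space: %d units x %g deg (period %g deg)\n",
              x$n_units, x$spacing, x$n_units * x$spacing))
  cat(sprintf("  inputs: E0_a=%g E0_v=%g sigma_a=%g sigma_v=%g\n",
              x$E0_a, x$E0_v, x$sigma_a, x$sigma_v))
  cat(sprintf("  neuron: theta=%g s=%g tau_y=%g ms\n", x$theta, x$s, x$tau_y))
  cat(sprintf("  lateral: L_ex0=%g sigma_ex=%g L_in0=%g sigma_in=%g\n",
              x$L_ex0, x$sigma_ex, x$L_in0, x$sigma_in))
  cat(sprintf("  cross-modal: W=%g\n", x$W))
  cat(sprintf("  plasticity: alpha_ex0=%g alpha_in0=%g theta_post=%g L_max=%g tau_L=%g ms\n",
              x$alpha_ex0, x$alpha_in0, x$theta_post, x$L_max, x$tau_L))
  cat(sprintf("  integration: dt=%g ms, max_t=%g ms, tol=%g /ms\n",
              x$dt, x$max_t, x$tol))
  invisible(x)
}

# period of the circular space in degrees
space_period <- function(p) p$n_units * p$spacing

#' Preferred positions of the units
#'
#' Degrees of each unit on the ring; unit i (1-based index) prefers
#' \code{(i - 1) * spacing} degrees.
#'
#' @param p an \code{\link{av_params}} set.
#' @return Numeric vector of length \code{n_units}.
#' @export
unit_positions <- function(p) (seq_len(p$n_units) - 1) * p$spacing
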