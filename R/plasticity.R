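#' Saturation-dependent learning factors
#'
#' The learning factor of each lateral synapse depends on its current
#' strength, so that excitatory synapses cannot exceed the saturation value
#' \code{L_max} and inhibitory synapses cannot fall below zero.
#'
#' \code{learning_rate_ex} tapers linearly from \code{alpha_ex0} at zero
#' strength to 0 at \code{L_max}. \code{learning_rate_in} grows linearly with
#' the synapse value and is capped at \code{alpha_in0} (reached at the
#' pre-training peak \code{L_in0}), so depression smoothly halts as a synapse
#' approaches zero.
#'
#' @param L current synapse strength (matrix or vector).
#' @param params an \code{\link{av_params}} set.
#' @return Learning factor of the same shape as \code{L}.
#' @export
learning_rate_ex <- function(L, params) {
  params$alpha_ex0 * pmax(params$L_max - L, 0) / params$L_max
}

#' @rdname learning_rate_ex
#' @export
learning_rate_in <- function(L, params) {
  params$alpha_in0 * pmin(pmax(L, 0) / params$L_in0, 1)
}

#' One-step Hebbian weight changes
#'
#' Threshold-gated Hebbian rule: a lateral synapse from pre-synaptic unit k
#' to post-synaptic unit j changes only when the post-synaptic activity
#' exceeds \code{theta_post}; the change is proportional to the product of
#' the supra-threshold post-synaptic activity and the pre-synaptic activity,
#' scaled by \code{dt / tau_L} and by the saturation-dependent learning
#' factor. Excitatory synapses potentiate and inhibitory synapses depress
#' under correlated activity; the diagonal (self-loops) never changes.
#'
#' @param y_pre,y_post pre- and post-synaptic activity vectors in [0, 1]
#'   (for lateral synapses both come from the same layer).
#' @param L_ex,L_in current weight matrices \code{[post x pre]}.
#' @param params an \code{\link{av_params}} set.
#' @return List with matrices \code{dL_ex} (\eqn{\ge 0}) and \code{dL_in}
#'   (\eqn{\le 0}).
#' @export
hebbian_deltas <- function(y_pre, y_post, L_ex, L_in, params) {
  g <- pmax(y_post - params$theta_post, 0)
  f <- params$dt / params$tau_L
  dL_ex <- f * learning_rate_ex(L_ex, params) * outer(g, y_pre)
  dL_in <- -f * learning_rate_in(L_in, params) * outer(g, y_pre)
  diag(dL_ex) <- 0
  diag(dL_in) <- 0
  list(dL_ex = dL_ex, dL_in = dL_in)
}

#' Normalize incoming synapses
#'
#' Multiplicative normalization keeping the total excitatory and the total
#' inhibitory synaptic input to every neuron constant: each row (the incoming
#' set of a post-synaptic neuron) is rescaled so its sum equals its
#' pre-training target, separately for excitatory and inhibitory matrices.
#' Excitatory entries are then clipped to \code{L_max}; if clipping removed
#' weight, the row is rescaled once more and clipped again.
#'
#' @param L_ex,L_in weight matrices \code{[post x pre]} after a Hebbian
#'   update.
#' @param target_ex,target_in per-row target sums (the pre-training sums).
#' @param params an \code{\link{av_params}} set.
#' @param rows optional indices of the rows to normalize (all by default).
#' @return List with the normalized \code{L_ex} and \code{L_in}.
#' @export
normalize_incoming <- function(L_ex, L_in, target_ex, target_in, params,
                               rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(L_ex))
  s_ex <- rowSums(L_ex[rows, , drop = FALSE])
  s_in <- rowSums(L_in[rows, , drop = FALSE])
  if (any(s_ex <= 0) || any(s_in <= 0))
    stop("degenerate normalization: a neuron's incoming synapses sum to zero")
  L_ex[rows, ] <- L_ex[rows, , drop = FALSE] * (target_ex[rows] / s_ex)
  L_in[rows, ] <- L_in[rows, , drop = FALSE] * (target_in[rows] / s_in)
  over <- L_ex[rows, , drop = FALSE] > params$L_max
  if (any(over)) {
    block <- pmin(L_ex[rows, , drop = FALSE], params$L_max)
    s2 <- rowSums(block)
    block <- block * (target_ex[rows] / s2)
    L_ex[rows, ] <- pmin(block, params$L_max)
  }
  list(L_ex = L_ex, L_in = L_in)
}

#' Run one training trial
#'
#' Integrates the network from rest for \code{duration} ms with the stimuli
#' held constant, applying plasticity to the lateral synapses of both layers
#' at every integration step: Hebbian changes, saturation, then multiplicative
#' normalization of the rows that changed. The inter-area gain \code{W} is
#' never modified. Activity does not persist beyond the trial (the next trial
#' starts from rest again).
#'
#' @param net an \code{\link{av_network}}.
#' @param stimuli stimulus or list of stimuli presented during the trial.
#' @param duration trial length in ms.
#' @return The network with updated lateral weight matrices and
#'   \code{trained = TRUE}.
#' @export
run_training_trial <- function(net, stimuli, duration = 200) {
  stopifnot(inherits(net, "av_network"), duration > 0)
  p <- net$params
  f <- stimulus_fields(stimuli, p)
  n_steps <- round(duration / p$dt)
  y_a <- numeric(p$n_units)
  y_v <- numeric(p$n_units)
  # local copies; the net lateral matrix L_ex - L_in is maintained
  # incrementally (only supra-threshold rows change per step)
  La_ex <- net$auditory$L_ex; La_in <- net$auditory$L_in
  Lv_ex <- net$visual$L_ex;   Lv_in <- net$visual$L_in
  La_net <- La_ex - La_in
  Lv_net <- Lv_ex - Lv_in
  t_ex <- net$target_ex; t_in <- net$target_in
  r <- p$dt / p$tau_y
  W <- p$W
  guard <- 1e-9
  for (k in seq_len(n_steps)) {
    u_a <- f$E_a + drop(La_net %*% y_a) + W * y_v
    u_v <- f$E_v + drop(Lv_net %*% y_v) + W * y_a
    y_a2 <- y_a + r * (-y_a + activation(u_a, p))
    y_v2 <- y_v + r * (-y_v + activation(u_v, p))
    if (any(y_a2 < -guard | y_a2 > 1 + guard |
            y_v2 < -guard | y_v2 > 1 + guard))
      stop("integration instability during training; reduce dt")
    rows_a <- which(y_a > p$theta_post)
    if (length(rows_a)) {
      up <- plastic_rows(La_ex, La_in, y_a, rows_a, p, t_ex, t_in)
      La_ex[rows_a, ] <- up$ex
      La_in[rows_a, ] <- up$in_
      La_net[rows_a, ] <- up$ex - up$in_
    }
    rows_v <- which(y_v > p$theta_post)
    if (length(rows_v)) {
      up <- plastic_rows(Lv_ex, Lv_in, y_v, rows_v, p, t_ex, t_in)
      Lv_ex[rows_v, ] <- up$ex
      Lv_in[rows_v, ] <- up$in_
      Lv_net[rows_v, ] <- up$ex - up$in_
    }
    y_a <- y_a2
    y_v <- y_v2
  }
  net$auditory$L_ex <- La_ex; net$auditory$L_in <- La_in
  net$visual$L_ex <- Lv_ex;   net$visual$L_in <- Lv_in
  net$trained <- TRUE
  net
}

# Hebbian + saturation + normalization for the supra-threshold rows of one
# layer at one step (rows below threshold are untouched by construction of
# the rule). Pre- and post-synaptic activities are those at the current step.
plastic_rows <- function(L_ex, L_in, y, rows, p, target_ex, target_in) {
  g <- y[rows] - p$theta_post
  f <- p$dt / p$tau_L
  ex <- L_ex[rows, , drop = FALSE]
  in_ <- L_in[rows, , drop = FALSE]
  gy <- g %o% y
  ex <- ex + f * (p$alpha_ex0 / p$L_max) * pmax(p$L_max - ex, 0) * gy
  in_ <- in_ - f * (p$alpha_in0 / p$L_in0) * pmin(in_, p$L_in0) * gy
  idx <- cbind(seq_along(rows), rows)
  ex[idx] <- 0
  in_[idx] <- 0
  ex[ex > p$L_max] <- p$L_max
  in_[in_ < 0] <- 0
  # multiplicative normalization of each incoming set to its pre-training
  # sum, separately for excitatory and inhibitory synapses
  ex <- ex * (target_ex[rows] / .rowSums(ex, length(rows), ncol(ex)))
  in_ <- in_ * (target_in[rows] / .rowSums(in_, length(rows), ncol(in_)))
  if (any(ex > p$L_max)) {
    ex[ex > p$L_max] <- p$L_max
    ex <- ex * (target_ex[rows] / .rowSums(ex, length(rows), ncol(ex)))
    ex[ex > p$L_max] <- p$L_max
  }
  list(ex = ex, in_ = in_)
}

#' Generate a training schedule
#'
#' The four cross-modal adaptation paradigms, each presenting an auditory and
#' a visual stimulus simultaneously for 200 ms per exposure:
#' \describe{
#'   \item{1a}{10 identical trials with disparate stimuli in fixed positions
#'     (auditory 100, visual 120 degrees).}
#'   \item{1b}{10 identical trials with coincident stimuli at 100 degrees.}
#'   \item{2a}{10 blocks; in each block the nine auditory positions 20, 40,
#'     ..., 180 degrees are each trained once in random order, with the
#'     visual stimulus always 20 degrees to the right.}
#'   \item{2b}{as 2a but with coincident stimuli (visual at the auditory
#'     position).}
#' }
#'
#' @param paradigm \code{"1a"}, \code{"1b"}, \code{"2a"} or \code{"2b"}.
#' @param seed integer seed controlling the random block orderings of
#'   paradigms 2a/2b (ignored by 1a/1b).
#' @param duration exposure length in ms (default 200).
#' @return An object of class \code{av_schedule}: a data frame with columns
#'   \code{trial}, \code{p_a}, \code{p_v}, \code{duration_ms}, plus
#'   attributes \code{paradigm} and \code{seed}.
#' @examples
#' sch <- make_schedule("2a", seed = 1)
#' nrow(sch)  # 90 exposures, each position trained ten times
#' @export
make_schedule <- function(paradigm = c("1a", "1b", "2a", "2b"), seed = 1,
                          duration = 200) {
  paradigm <- match.arg(paradigm)
  if (paradigm %in% c("1a", "1b")) {
    p_a <- rep(100, 10)
    p_v <- if (paradigm == "1a") rep(120, 10) else rep(100, 10)
  } else {
    positions <- seq(20, 180, by = 20) %% 180  # nine positions; 180 == 0 on the ring
    p_a <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      unlist(lapply(1:10, function(b) sample(positions)))
    })
    p_v <- if (paradigm == "2a") (p_a + 20) %% 180 else p_a
  }
  sch <- data.frame(trial = seq_along(p_a), p_a = p_a, p_v = p_v,
                    duration_ms = duration)
  attr(sch, "paradigm") <- paradigm
  attr(sch, "seed") <- seed
  class(sch) <- c("av_schedule", "data.frame")
  sch
}

#' Train a network on a schedule
#'
#' Runs every exposure of the schedule in order via
#' \code{\link{run_training_trial}}; synapses persist across trials, activity
#' does not.
#'
#' @param net an \code{\link{av_network}}.
#' @param schedule an \code{\link{make_schedule}} result or any data frame
#'   with columns \code{p_a}, \code{p_v}, \code{duration_ms} (either position
#'   may be \code{NA} for a unimodal exposure).
#' @param strength_a,strength_v stimulus strengths used during training.
#' @param verbose print a per-trial summary line.
#' @return The trained network.
#' @export
train_network <- function(net, schedule, strength_a = net$params$E0_a,
                          strength_v = net$params$E0_v, verbose = FALSE) {
  stopifnot(inherits(net, "av_network"), is.data.frame(schedule))
  for (i in seq_len(nrow(schedule))) {
    stims <- list()
    if (!is.na(schedule$p_a[i]))
      stims <- c(stims, list(av_stimulus("auditory", schedule$p_a[i],
                                         strength_a)))
    if (!is.na(schedule$p_v[i]))
      stims <- c(stims, list(av_stimulus("visual", schedule$p_v[i],
                                         strength_v)))
    before <- net$auditory$L_ex
    net <- run_training_trial(net, stims, schedule$duration_ms[i])
    if (verbose) {
      resid <- max(abs(rowSums(net$auditory$L_ex) - net$target_ex) /
                     net$target_ex)
      message(sprintf(
        "trial %d: |dL_ex|=%.4f, conservation residual %.2e",
        i, max(abs(net$auditory$L_ex - before)), resid))
    }
  }
  net
}
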