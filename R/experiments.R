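#' Unimodal controls: no phantom activation
#'
#' Presents a single stimulus of each modality and verifies that the
#' stimulated layer develops a bump of activity peaked at the stimulus
#' position while the other layer stays everywhere below the activation
#' threshold (no phantom activity through the inter-area synapses).
#'
#' @param params an \code{\link{av_params}} set.
#' @param position stimulus position (degrees).
#' @param active_threshold activity above which a unit counts as active
#'   (used only for the phantom check, not in the dynamics).
#' @return List with the two steady states (\code{auditory_run},
#'   \code{visual_run}), the maximum off-modality activity per run, and
#'   \code{phantom_free}.
#' @export
run_unimodal_controls <- function(params = av_params(), position = 120,
                                  active_threshold = 0.05) {
  net <- av_network(params)
  st_a <- simulate_network(net, av_stimulus("auditory", position, params$E0_a))
  st_v <- simulate_network(net, av_stimulus("visual", position, params$E0_v))
  out <- list(
    auditory_run = st_a,
    visual_run = st_v,
    max_phantom_visual = max(st_a$y_v),
    max_phantom_auditory = max(st_v$y_a),
    phantom_free = max(st_a$y_v) < active_threshold &&
      max(st_v$y_a) < active_threshold
  )
  if (!out$phantom_free)
    warning(sprintf("phantom activity detected (max %.3f)",
                    max(out$max_phantom_visual, out$max_phantom_auditory)))
  out
}

#' Bias of perceived location versus audio-visual disparity
#'
#' For a fixed visual stimulus and a sweep of auditory positions, simulates
#' each audio-visual pair to steady state and decodes both layers, recording
#' the shift (perceived minus true position) of each modality as a function
#' of the disparity \code{p_v - p_a}. This is the ventriloquism-effect curve:
#' under basal parameters the sound is captured by the visual stimulus at
#' moderate disparities while the visual percept barely moves.
#'
#' @param net an \code{\link{av_network}} (pre-trained networks allowed).
#' @param auditory_positions degrees of the auditory stimulus per run.
#' @param visual_position fixed visual stimulus position (degrees).
#' @param metric decoding metric (see \code{\link{decode_position}}).
#' @param strength_a,strength_v stimulus strengths.
#' @param width_a,width_v optional input-width overrides (degrees).
#' @return A data frame of class \code{av_bias_curve} with columns
#'   \code{p_a}, \code{p_v}, \code{separation} (\code{p_v - p_a}, wrapped),
#'   \code{auditory_perceived}, \code{visual_perceived},
#'   \code{auditory_shift}, \code{visual_shift}.
#' @examples
#' \donttest{
#' bc <- run_bias_sweep(av_network(), auditory_positions = c(100, 160))
#' bc$auditory_shift  # ~8.6 at 20 deg separation, ~0 at 40+
#' }
#' @export
run_bias_sweep <- function(net = av_network(),
                           auditory_positions = seq(60, 180, by = 10) %% 180,
                           visual_position = 120,
                           metric = "vector",
                           strength_a = net$params$E0_a,
                           strength_v = net$params$E0_v,
                           width_a = NULL, width_v = NULL) {
  p <- net$params
  period <- space_period(p)
  rows <- lapply(auditory_positions, function(pa) {
    st <- simulate_network(net, list(
      av_stimulus("auditory", pa %% period, strength_a, width_a),
      av_stimulus("visual", visual_position, strength_v, width_v)))
    za <- decode_position(st$y_a, metric, p)
    zv <- decode_position(st$y_v, metric, p)
    data.frame(
      p_a = pa, p_v = visual_position,
      separation = perceived_shift(visual_position, pa, period),
      auditory_perceived = za, visual_perceived = zv,
      auditory_shift = perceived_shift(za, pa %% period, period),
      visual_shift = perceived_shift(zv, visual_position, period))
  })
  out <- do.call(rbind, rows)
  attr(out, "metric") <- metric
  class(out) <- c("av_bias_curve", "data.frame")
  out
}

#' Sensitivity analysis over one parameter
#'
#' Recomputes the bias-versus-disparity curve while one aspect of the model
#' is changed and everything else stays basal. Panels:
#' \describe{
#'   \item{remove_W}{inter-area synapses eliminated (W = 0).}
#'   \item{remove_lateral}{lateral synapses eliminated.}
#'   \item{vary_W, vary_sigma_in, vary_sigma_ex, vary_E0a, vary_E0v,
#'     vary_sigma_a, vary_sigma_v}{the named parameter set to each entry of
#'     \code{values}.}
#' }
#'
#' @param panel which manipulation to run.
#' @param values parameter values for the \code{vary_*} panels.
#' @param params basal parameter set.
#' @param auditory_positions,visual_position,metric as in
#'   \code{\link{run_bias_sweep}}.
#' @return Named list of \code{av_bias_curve} data frames, one per value (or
#'   a single-element list for the removal panels).
#' @export
run_sensitivity <- function(panel = c("remove_W", "remove_lateral", "vary_W",
                                      "vary_sigma_in", "vary_sigma_ex",
                                      "vary_E0a", "vary_E0v", "vary_sigma_a",
                                      "vary_sigma_v"),
                            values = NULL, params = av_params(),
                            auditory_positions = seq(60, 180, by = 10) %% 180,
                            visual_position = 120, metric = "vector") {
  panel <- match.arg(panel)
  key <- switch(panel, vary_W = "W", vary_sigma_in = "sigma_in",
                vary_sigma_ex = "sigma_ex", vary_E0a = "E0_a",
                vary_E0v = "E0_v", vary_sigma_a = "sigma_a",
                vary_sigma_v = "sigma_v", NULL)
  make_net <- function(p) av_network(p)
  if (panel == "remove_W") {
    p <- modify_params(params, list(W = 0))
    curves <- list(`W=0` = run_bias_sweep(make_net(p), auditory_positions,
                                          visual_position, metric))
  } else if (panel == "remove_lateral") {
    p <- suppressWarnings(modify_params(params, list(L_ex0 = 0, L_in0 = 0)))
    net <- av_network(p)
    curves <- list(`lateral=0` = run_bias_sweep(net, auditory_positions,
                                                visual_position, metric))
  } else {
    if (is.null(values)) stop("panel '", panel, "' needs explicit values")
    curves <- lapply(values, function(v) {
      ov <- list(v); names(ov) <- key
      run_bias_sweep(make_net(modify_params(params, ov)), auditory_positions,
                     visual_position, metric)
    })
    names(curves) <- paste0(key, "=", values)
  }
  curves
}

#' Derive a modified parameter set
#'
#' Rebuilds an \code{\link{av_params}} object with some fields replaced,
#' re-running validation (parameter sets that leave the Mexican-hat regime
#' warn, as during sensitivity sweeps).
#'
#' @param params an \code{\link{av_params}} set.
#' @param overrides named list of fields to replace.
#' @return A validated \code{av_params} object.
#' @examples
#' p <- modify_params(av_params(), list(W = 0))
#' @export
modify_params <- function(params, overrides) {
  stopifnot(inherits(params, "av_params"))
  p <- unclass(params)
  for (k in names(overrides)) {
    if (!k %in% names(p)) stop("unknown parameter '", k, "'")
    p[[k]] <- overrides[[k]]
  }
  do.call(av_params, p[names(formals(av_params))])
}

#' Gain-coded reliability variant
#'
#' Alternative coding in which cue reliability lives in the input strength
#' rather than its width: both inputs share the same Gaussian width (35
#' degrees) but the visual input is stronger (16 versus 12). Runs the two
#' unimodal controls and the disparate cross-modal case (visual 120, auditory
#' 100 degrees) and decodes both layers with the vector metric.
#'
#' With equal input widths the two activity bumps are evenly matched, which
#' opens an extremely slow competitive drift mode (activities keep creeping
#' at ~1e-4 per ms long after the transient). The protocol therefore defines
#' its steady state as the end of the fast transient and decodes at
#' \code{eval_time} (100 ms by default), where the profiles have settled for
#' all practical purposes.
#'
#' @param params basal parameter set (widths/strengths are overridden).
#' @param sigma shared input width (degrees).
#' @param strength_v,strength_a input strengths.
#' @param p_v,p_a stimulus positions for the cross-modal run.
#' @param eval_time time (ms) at which percepts are decoded.
#' @return List with \code{controls} (phantom check), \code{state} (the
#'   cross-modal state at \code{eval_time}), \code{auditory_perceived},
#'   \code{visual_perceived} and the corresponding shifts.
#' @export
run_gain_coding_variant <- function(params = av_params(), sigma = 35,
                                    strength_v = 16, strength_a = 12,
                                    p_v = 120, p_a = 100, eval_time = 100) {
  p <- modify_params(params, list(sigma_a = sigma, sigma_v = sigma,
                                  E0_a = strength_a, E0_v = strength_v))
  net <- av_network(p)
  controls <- list(
    auditory_run = suppressWarnings(
      simulate_network(net, av_stimulus("auditory", p_a, strength_a))),
    visual_run = suppressWarnings(
      simulate_network(net, av_stimulus("visual", p_v, strength_v)))
  )
  p_eval <- modify_params(p, list(max_t = eval_time, tol = 1e-15))
  net_eval <- av_network(p_eval)
  st <- suppressWarnings(
    simulate_network(net_eval, list(av_stimulus("auditory", p_a, strength_a),
                                    av_stimulus("visual", p_v, strength_v))))
  za <- decode_position(st$y_a, "vector", p)
  zv <- decode_position(st$y_v, "vector", p)
  list(controls = controls, state = st,
       auditory_perceived = za, visual_perceived = zv,
       auditory_shift = perceived_shift(za, p_a),
       visual_shift = perceived_shift(zv, p_v))
}

#' Aftereffect of cross-modal adaptation
#'
#' Trains the lateral synapses under one of the adaptation paradigms, then
#' probes the trained network with unimodal auditory stimuli across space and
#' reports the shift of the perceived position at every test location (the
#' ventriloquism aftereffect). For the variable-position paradigms (2a/2b) a
#' straight line perceived-versus-actual is also fitted by ordinary least
#' squares.
#'
#' @param paradigm \code{"1a"}, \code{"1b"}, \code{"2a"} or \code{"2b"}.
#' @param seed seed for the randomized block orderings (paradigm 2).
#' @param test_positions degrees of the unimodal test stimuli; defaults to
#'   the paradigm's grid (40-160 by 10 for paradigm 1, 0-180 by 10 for
#'   paradigm 2).
#' @param params basal parameter set.
#' @param metric decoding metric.
#' @return List of class \code{av_aftereffect} with the trained \code{net},
#'   the \code{schedule}, a \code{curve} data frame (\code{position},
#'   \code{perceived}, \code{shift}), \code{mean_shift} and, for paradigm 2,
#'   \code{regression} (slope, offset, r.squared).
#' @export
run_aftereffect <- function(paradigm = c("1a", "1b", "2a", "2b"), seed = 1,
                            test_positions = NULL, params = av_params(),
                            metric = "vector") {
  paradigm <- match.arg(paradigm)
  if (is.null(test_positions))
    test_positions <- if (paradigm %in% c("1a", "1b"))
      seq(40, 160, by = 10) else seq(0, 180, by = 10)
  sch <- make_schedule(paradigm, seed = seed)
  net <- train_network(av_network(params), sch)
  curve <- unimodal_test_curve(net, test_positions, metric)
  out <- list(net = net, schedule = sch, curve = curve,
              mean_shift = mean(curve$shift), paradigm = paradigm,
              seed = seed)
  if (paradigm %in% c("2a", "2b")) {
    # unwrap the perceived position so the OLS line is fitted on a linear
    # axis: perceived = position + shift
    fit <- stats::lm(I(position + shift) ~ position, data = curve)
    out$regression <- list(slope = unname(stats::coef(fit)[2]),
                           offset = unname(stats::coef(fit)[1]),
                           r.squared = summary(fit)$r.squared)
  }
  class(out) <- "av_aftereffect"
  out
}

# decode unimodal auditory tests on a (possibly trained) network
unimodal_test_curve <- function(net, test_positions, metric = "vector") {
  p <- net$params
  period <- space_period(p)
  rows <- lapply(test_positions, function(pos) {
    st <- simulate_network(net, av_stimulus("auditory", pos %% period,
                                            p$E0_a))
    z <- decode_position(st$y_a, metric, p)
    data.frame(position = pos, perceived = z,
               shift = perceived_shift(z, pos %% period, period))
  })
  do.call(rbind, rows)
}

#' @export
print.av_aftereffect <- function(x, ...) {
  cat(sprintf("Aftereffect after paradigm %s (seed %d)\n", x$paradigm,
              x$seed))
  cat(sprintf("  mean shift over %d test positions: %.2f deg\n",
              nrow(x$curve), x$mean_shift))
  if (!is.null(x$regression))
    cat(sprintf("  perceived ~ actual: slope %.3f, offset %.2f deg, r^2 %.4f\n",
                x$regression$slope, x$regression$offset,
                x$regression$r.squared))
  invisible(x)
}

#' Cross-modal stimulation after training
#'
#' Probes a trained network with an auditory stimulus at a fixed position
#' joined with a visual stimulus at each of a sweep of positions, and
#' compares the resulting sound-location shifts with the same sweep on the
#' untrained network. Near the trained disparity the online visual capture
#' and the synaptic aftereffect combine; far from the sound the shift reduces
#' to the pure aftereffect.
#'
#' @param trained_net a network trained by \code{\link{train_network}}.
#' @param p_a fixed auditory stimulus position (degrees).
#' @param visual_positions sweep of visual stimulus positions (degrees).
#' @param metric decoding metric.
#' @return Data frame with columns \code{p_v}, \code{separation},
#'   \code{shift_post}, \code{shift_pre}.
#' @export
run_posttraining_crossmodal <- function(trained_net, p_a = 100,
                                        visual_positions = seq(40, 160, 10),
                                        metric = "vector") {
  stopifnot(inherits(trained_net, "av_network"))
  p <- trained_net$params
  pre_net <- av_network(p)
  period <- space_period(p)
  run_one <- function(net, pv) {
    st <- simulate_network(net, list(av_stimulus("auditory", p_a, p$E0_a),
                                     av_stimulus("visual", pv %% period,
                                                 p$E0_v)))
    perceived_shift(decode_position(st$y_a, metric, p), p_a, period)
  }
  data.frame(
    p_v = visual_positions,
    separation = perceived_shift(visual_positions, p_a, period),
    shift_post = vapply(visual_positions, function(pv)
      run_one(trained_net, pv), numeric(1)),
    shift_pre = vapply(visual_positions, function(pv)
      run_one(pre_net, pv), numeric(1))
  )
}
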