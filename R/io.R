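#' Load a configuration file
#'
#' Reads a structured-text (YAML key/value) configuration whose keys follow
#' the model's parameter names (\code{E0_a}, \code{E0_v}, \code{sigma_a},
#' \code{sigma_v}, \code{theta}, \code{s}, \code{tau_y}, \code{L_ex0},
#' \code{sigma_ex}, \code{L_in0}, \code{sigma_in}, \code{W},
#' \code{alpha_ex0}, \code{alpha_in0}, \code{theta_post}, \code{L_max},
#' \code{tau_L}, \code{dt}, \code{max_t}, \code{tol}, ...). Missing keys keep
#' their basal defaults; unknown keys are an error; out-of-range values fail
#' validation, and parameter sets that break the Mexican-hat arrangement
#' produce a warning.
#'
#' @param path path to the YAML file; an empty or missing body yields the
#'   full basal parameter set.
#' @return An \code{\link{av_params}} object.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a key/value mapping")
  known <- names(formals(av_params))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(av_params, raw)
}

#' Run manifest
#'
#' A flat record of everything needed to reproduce a run: the full parameter
#' set, the seed, an optional schedule digest, and the package version.
#'
#' @param params an \code{\link{av_params}} set.
#' @param seed integer seed used for any randomized schedule (or \code{NA}).
#' @param schedule optional \code{\link{make_schedule}} result; its trial
#'   list is hashed into the manifest.
#' @param extra named list of additional fields to record.
#' @return Named list of class \code{av_manifest}.
#' @export
run_manifest <- function(params, seed = NA_integer_, schedule = NULL,
                         extra = list()) {
  m <- c(unclass(params), list(seed = seed))
  if (!is.null(schedule)) {
    m$paradigm <- attr(schedule, "paradigm")
    m$schedule_digest <- sum(schedule$trial * (schedule$p_a + 1) +
                               schedule$p_v %% 1e6)
    m$n_trials <- nrow(schedule)
  }
  m$package_version <- as.character(utils::packageVersion("avring"))
  m <- c(m, extra)
  class(m) <- "av_manifest"
  m
}

#' Write experiment results
#'
#' Serializes a set of result tables as tab-delimited text plus the manifest
#' as YAML, with deterministic file names, creating the output directory if
#' needed. Tables round-trip losslessly through \code{\link{read_result}}.
#'
#' @param tables named list of data frames.
#' @param manifest a \code{\link{run_manifest}} (optional).
#' @param out_dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, manifest = NULL, out_dir) {
  stopifnot(is.list(tables), all(nzchar(names(tables))))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, path)
  }
  if (!is.null(manifest)) {
    path <- file.path(out_dir, "manifest.yaml")
    yaml::write_yaml(lapply(unclass(manifest), function(x)
      if (is.numeric(x)) unname(x) else x), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' @rdname write_results
#' @param path path to a table written by \code{write_results}.
#' @export
read_result <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Activity profiles as a tidy table
#'
#' Long-format view of a simulated state: one row per unit and modality,
#' suitable for serialization or plotting.
#'
#' @param state an \code{av_state} from \code{\link{simulate_network}}.
#' @param params the \code{\link{av_params}} used for the simulation.
#' @return Data frame with columns \code{time_ms}, \code{modality},
#'   \code{unit_deg}, \code{activity}.
#' @export
state_table <- function(state, params) {
  snapshot_frame(state$t, state$y_a, state$y_v, params)
}

#' Incoming synapse profile of one neuron
#'
#' Extracts the lateral synapses entering a given post-synaptic neuron as a
#' function of the (signed) circular offset of the pre-synaptic neuron, the
#' standard view for inspecting what training did to the weight pattern.
#'
#' @param net an \code{\link{av_network}}.
#' @param layer \code{"auditory"} or \code{"visual"}.
#' @param position preferred position (degrees) of the post-synaptic neuron.
#' @return Data frame with columns \code{offset_deg} (pre minus post,
#'   wrapped), \code{L_ex}, \code{L_in}, \code{net} (= L_ex - L_in), sorted
#'   by offset.
#' @export
synapse_profile <- function(net, layer = c("auditory", "visual"), position) {
  layer <- match.arg(layer)
  p <- net$params
  period <- space_period(p)
  j <- which(unit_positions(p) == position %% period)
  if (!length(j)) stop("no unit at position ", position)
  offs <- perceived_shift(unit_positions(p), position %% period, period)
  out <- data.frame(offset_deg = offs,
                    L_ex = net[[layer]]$L_ex[j, ],
                    L_in = net[[layer]]$L_in[j, ])
  out$net <- out$L_ex - out$L_in
  out[order(out$offset_deg), ]
}
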