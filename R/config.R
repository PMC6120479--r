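#' Build a run configuration
#'
#' Collects every parameter of an end-to-end run (simulate -> quantify ->
#' matrix -> network) in one serialisable list. Unspecified parameters
#' take the study defaults (31 z-slices 0.2 um apart, 3 um measurement
#' ROIs, alpha = 0.05, 100-cell arms).
#'
#' @param ... Named configuration fields, see [validate_config()].
#' @return A validated `poldep_config`.
#' @export
run_config <- function(...) {
  validate_config(list(...))
}

#' Validate and normalise a run configuration
#'
#' Fills defaults, coerces sub-configurations (design, truth preset, noise
#' model, simulation profile, quantification parameters) and reports every
#' contradiction found, naming the offending field; nothing is partially
#' defaulted on error.
#'
#' @param config A named list. Recognised fields: `design` (a
#'   [study_design()] or a list of its arguments), `truth` (preset name,
#'   effect data frame, or [truth_table()]), `noise` ([noise_model()] or
#'   argument list), `prior` ([cell_prior()] or argument list), `profile`
#'   ([sim_profile()], `"default"`, `"scaled"`, or argument list),
#'   `quantify` ([quantify_params()] or argument list), `statistic`
#'   (`"mean"`/`"max"`), `alpha`, `min_effect`, `min_cells`,
#'   `bipolar_threshold`, `edge_rule`, `seed`, `out_dir` (optional; tables
#'   are written there), `write_images` (simulate to TIFF instead of
#'   in-memory).
#' @return A `poldep_config` list with all defaults filled.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  errors <- character()
  note <- function(msg) errors <<- c(errors, msg)

  known <- c("design", "truth", "noise", "prior", "profile", "quantify",
             "statistic", "alpha", "min_effect", "min_cells",
             "bipolar_threshold", "edge_rule", "seed", "out_dir",
             "write_images")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) note(paste0("unknown field(s): ",
                                   paste(unknown, collapse = ", ")))

  design <- config$design
  if (is.null(design)) design <- study_design()
  if (!inherits(design, "poldep_design")) {
    design <- tryCatch(do.call(study_design, as.list(design)),
                       error = function(e) {
                         note(paste0("design: ", conditionMessage(e)))
                         NULL
                       })
  }
  coerce <- function(obj, cls, builder, field) {
    if (is.null(obj)) return(builder())
    if (inherits(obj, cls)) return(obj)
    tryCatch(do.call(builder, as.list(obj)), error = function(e) {
      note(paste0(field, ": ", conditionMessage(e)))
      NULL
    })
  }
  noise <- coerce(config$noise, "poldep_noise", noise_model, "noise")
  prior <- coerce(config$prior, "poldep_cell_prior", cell_prior, "prior")
  profile <- config$profile
  if (is.null(profile)) profile <- sim_profile()
  else if (identical(profile, "default")) profile <- sim_profile()
  else if (identical(profile, "scaled")) profile <- sim_profile_scaled()
  else if (!inherits(profile, "poldep_sim_profile")) {
    profile <- tryCatch(do.call(sim_profile, as.list(profile)),
                        error = function(e) {
                          note(paste0("profile: ", conditionMessage(e)))
                          NULL
                        })
  }
  quantify <- coerce(config$quantify, "poldep_quantify_params",
                     quantify_params, "quantify")

  statistic <- config$statistic %||% "mean"
  if (!statistic %in% c("mean", "max")) note("statistic: must be mean or max")
  alpha <- config$alpha %||% 0.05
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    note("alpha: must be in (0, 1)")
  } else if (alpha > 0.1) {
    warn(paste0("alpha = ", alpha, " is unusually permissive"))
  }
  min_effect <- config$min_effect %||% 0.10
  if (!is.numeric(min_effect) || min_effect < 0) note("min_effect: must be >= 0")
  min_cells <- config$min_cells %||% 100L
  if (!is.numeric(min_cells) || min_cells < 1) note("min_cells: must be >= 1")
  bipolar_threshold <- config$bipolar_threshold %||% 0.5
  edge_rule <- config$edge_rule %||% "either"
  if (!edge_rule %in% c("either", "end1", "end2")) {
    note("edge_rule: must be either/end1/end2")
  }
  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L) note("seed: must be one number")

  truth <- config$truth %||% "null"
  truth_label <- if (is.character(truth)) truth else "custom"
  if (!is.data.frame(truth) || !all(c("mult_end1", "mult_end2", "mult_cyto",
                                      "bipolarity_shift") %in% names(truth))) {
    if (!is.null(design)) {
      truth <- tryCatch(truth_table(design, truth),
                        error = function(e) {
                          note(paste0("truth: ", conditionMessage(e)))
                          NULL
                        })
    }
  }

  if (length(errors)) {
    poldep_abort(paste0("invalid configuration:\n  ",
                        paste(errors, collapse = "\n  ")),
                 "poldep_config_error")
  }
  structure(
    list(design = design, truth = truth, truth_label = truth_label,
         noise = noise, prior = prior,
         profile = profile, quantify = quantify, statistic = statistic,
         alpha = alpha, min_effect = min_effect,
         min_cells = as.integer(min_cells),
         bipolar_threshold = bipolar_threshold, edge_rule = edge_rule,
         seed = as.integer(seed), out_dir = config$out_dir,
         write_images = isTRUE(config$write_images)),
    class = "poldep_config"
  )
}

#' Read / write a run configuration as YAML
#'
#' Only plainly serialisable fields are stored (design arguments, preset
#' names, parameter lists); [validate_config()] rebuilds the full objects
#' on read.
#'
#' @param path YAML file path.
#' @param config A `poldep_config`.
#' @return `read_config()`: a validated `poldep_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "poldep_config"))
  plain <- list(
    design = list(markers = config$design$markers,
                  deletions = config$design$deletions,
                  cells_per_arm = config$design$cells_per_arm,
                  fields_per_combination =
                    config$design$fields_per_combination),
    noise = unclass(config$noise),
    profile = unclass(config$profile)[c("pixel_size_xy", "field_px", "n_z",
                                        "z_step", "cells_per_field")],
    truth = config$truth_label,
    statistic = config$statistic, alpha = config$alpha,
    min_effect = config$min_effect, min_cells = config$min_cells,
    bipolar_threshold = config$bipolar_threshold,
    edge_rule = config$edge_rule, seed = config$seed
  )
  yaml::write_yaml(plain, path)
  invisible(path)
}
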