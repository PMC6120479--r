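#' Run the full dependency analysis end to end
#'
#' Orchestrates simulate -> quantify -> normalise -> matrix -> NETO ->
#' network as one reproducible run. Fields are simulated and quantified
#' one at a time (full stacks are written to disk only when
#' `write_images = TRUE`), every random draw derives from the single
#' config seed through documented per-stage sub-seeds, and identical
#' config + seed gives identical outputs.
#'
#' @param config A `poldep_config` (see [run_config()] /
#'   [validate_config()]).
#' @return A `poldep_run`: `$cells` (per-cell measurements joined to
#'   ground truth), `$normalized`, `$matrix` (`poldep_matrix`), `$neto`,
#'   `$edges`, `$network` (`poldep_network`), `$report` (bookkeeping
#'   summary), `$annotations`, `$field_counts` and the config. When
#'   `config$out_dir` is set, `cells.csv`, `matrix.csv`, `neto.csv`,
#'   `net.tsv` and `report.yaml` are also written there.
#' @examples
#' \donttest{
#' cfg <- run_config(
#'   design = study_design(markers = c("Tea1", "Tip1"),
#'                         deletions = c("tea2", "myo52"),
#'                         cells_per_arm = 6),
#'   truth = "literature", profile = "scaled", min_cells = 5, seed = 7)
#' run <- run_study(cfg)
#' run$report$n_cells_analysed
#' }
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "poldep_config"))
  plan <- field_plan(config$design, config$profile)
  if (anyDuplicated(plan$field_id)) {
    poldep_abort("duplicate field_id in study plan", "poldep_integrity_error")
  }
  truth_key <- paste(config$truth$marker, config$truth$deletion)

  cells <- vector("list", nrow(plan))
  annotations <- vector("list", nrow(plan))
  counts <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    row <- plan[i, ]
    tr <- config$truth[match(paste(row$marker, row$deletion), truth_key), ]
    fs <- render_planned_field(row, tr, config$noise, config$prior,
                               config$profile, config$seed,
                               keep_stack = config$write_images)
    if (config$write_images) {
      if (is.null(config$out_dir)) {
        poldep_abort("write_images = TRUE requires out_dir",
                     "poldep_config_error")
      }
      dir.create(file.path(config$out_dir, "images"),
                 showWarnings = FALSE, recursive = TRUE)
      sh <- min(min(fs$gfp), min(fs$red), 0)
      sc <- (max(max(fs$gfp), max(fs$red)) - sh + 1) * (1 + 1e-6)
      pages <- c(lapply(seq_len(fs$n_z),
                        function(k) (fs$gfp[, , k] - sh) / sc),
                 lapply(seq_len(fs$n_z),
                        function(k) (fs$red[, , k] - sh) / sc))
      tiff::writeTIFF(pages,
                      file.path(config$out_dir, "images",
                                paste0(row$field_id, ".tif")),
                      bits.per.sample = 32L, compression = "deflate")
    }
    meas <- quantify_field(fs, config$quantify)
    meas <- join_truth(meas, fs$cells)
    cells[[i]] <- meas
    annotations[[i]] <- fs$cells
    counts[[i]] <- tibble(
      field_id = row$field_id, marker = row$marker, deletion = row$deletion,
      n_planned = row$n_control + row$n_deletion,
      n_segmented = nrow(meas),
      n_analysed = sum(meas$analysed),
      n_excluded = sum(!meas$analysed)
    )
  }
  cells <- bind_rows(cells)
  annotations <- bind_rows(annotations)
  field_counts <- bind_rows(counts)

  normalized <- normalize_to_controls(cells, statistic = config$statistic)
  mx <- dependency_matrix(normalized, alpha = config$alpha,
                          min_effect = config$min_effect,
                          min_cells = config$min_cells)
  neto <- neto_shift_test(normalized, alpha = config$alpha,
                          bipolar_threshold = config$bipolar_threshold)
  edges <- matrix_to_edges(mx, neto, edge_rule = config$edge_rule)
  network <- dependency_network(edges)

  arm_counts <- summarise(
    group_by(filter(cells, .data$analysed),
             .data$marker, .data$deletion, .data$genotype),
    n = dplyr::n(), .groups = "drop"
  )
  report <- list(
    package_version = as.character(utils::packageVersion("poldep")),
    seed = config$seed,
    truth = config$truth_label,
    n_combinations = nrow(config$design$combinations),
    n_fields = nrow(field_counts),
    n_cells_segmented = sum(field_counts$n_segmented),
    n_cells_analysed = sum(field_counts$n_analysed),
    n_cells_excluded = sum(field_counts$n_excluded),
    min_arm_count = if (nrow(arm_counts)) min(arm_counts$n) else 0L,
    calls = as.list(table(mx$entries$call)),
    n_neto_shifted = sum(neto$shifted),
    loops = as.list(table(network$loops$class))
  )

  out <- structure(
    list(cells = cells, normalized = normalized, matrix = mx, neto = neto,
         edges = edges, network = network, annotations = annotations,
         field_counts = field_counts, arm_counts = arm_counts,
         report = report, config = config),
    class = "poldep_run"
  )
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(run$cells, file.path(out_dir, "cells.csv"))
  readr::write_csv(run$matrix$entries, file.path(out_dir, "matrix.csv"))
  readr::write_csv(run$neto, file.path(out_dir, "neto.csv"))
  export_network(run$network, file.path(out_dir, "net.tsv"), "tsv")
  export_network(run$network, file.path(out_dir, "net.dot"), "dot")
  yaml::write_yaml(run$report, file.path(out_dir, "report.yaml"))
  invisible(out_dir)
}

#' @export
print.poldep_run <- function(x, ...) {
  r <- x$report
  cat("<poldep_run> ", r$n_combinations, " combinations, ", r$n_fields,
      " fields\n  cells: ", r$n_cells_analysed, " analysed / ",
      r$n_cells_segmented, " segmented (", r$n_cells_excluded,
      " excluded)\n  calls: ", sep = "")
  cat(paste(names(r$calls), unlist(r$calls), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}
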