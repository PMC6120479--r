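#' Summarise one marker x deletion combination for one compartment
#'
#' Computes the relative difference of a deletion arm against its co-imaged
#' wild-type controls, `rel_diff = mean(deletion) / mean(control) - 1`, on
#' field-normalised values, and a two-sided Welch t-test on log-transformed
#' normalised values (intensity ratios are heavily right-skewed, so the
#' location test runs on the log scale). Non-positive normalised values
#' cannot be log-transformed and are excluded from the test (they are rare
#' for genuinely polar markers and counted in `n_dropped`).
#'
#' @param records Normalised records of one (marker, deletion) combination
#'   (see [normalize_to_controls()]).
#' @param compartment `"end1"`, `"end2"` or `"cyto"`.
#' @param min_cells Arms below this analysed-cell count are flagged
#'   `underpowered` (reported, never silently dropped).
#' @return One-row tibble: `marker`, `deletion`, `compartment`, `n_del`,
#'   `n_ctrl`, `n_dropped`, `rel_diff`, `p_value`, `underpowered`.
#' @export
summarize_combination <- function(records,
                                  compartment = c("end1", "end2", "cyto"),
                                  min_cells = 100L) {
  compartment <- match.arg(compartment)
  stopifnot(length(unique(records$marker)) == 1L,
            length(unique(records$deletion)) == 1L)
  v <- records[[paste0("norm_", compartment)]]
  del <- v[records$genotype == "deletion"]
  ctl <- v[records$genotype == "control"]
  if (!length(del) || !length(ctl)) {
    poldep_abort(paste0("combination ", records$marker[1], " x ",
                        records$deletion[1], " is missing an arm"),
                 "poldep_missing_arm")
  }
  rel_diff <- mean(del) / mean(ctl) - 1
  ld <- log(del[del > 0]); lc <- log(ctl[ctl > 0])
  p <- if (length(ld) >= 2L && length(lc) >= 2L &&
           (sd(ld) > 0 || sd(lc) > 0)) {
    t.test(ld, lc, var.equal = FALSE)$p.value
  } else {
    1
  }
  tibble(
    marker = records$marker[1], deletion = records$deletion[1],
    compartment = compartment,
    n_del = length(del), n_ctrl = length(ctl),
    n_dropped = (length(del) - length(ld)) + (length(ctl) - length(lc)),
    rel_diff = rel_diff, p_value = p,
    underpowered = length(del) < min_cells || length(ctl) < min_cells
  )
}

#' Adjust and call a table of matrix entries
#'
#' Benjamini-Hochberg adjustment across *all* entries jointly, then a call
#' per entry: `increase` / `decrease` when `q_value <= alpha` **and**
#' `|rel_diff| >= min_effect` (sign from `rel_diff`), otherwise `ns`.
#'
#' @param entries Tibble of [summarize_combination()] rows, one per
#'   (marker, deletion, compartment).
#' @param alpha Matrix-wide FDR level.
#' @param min_effect Minimum absolute relative difference for a call.
#' @return A `poldep_matrix` object.
#' @export
build_matrix <- function(entries, alpha = 0.05, min_effect = 0.10) {
  key <- paste(entries$marker, entries$deletion, entries$compartment)
  if (anyDuplicated(key)) {
    poldep_abort("duplicate (marker, deletion, compartment) entry",
                 "poldep_integrity_error")
  }
  entries <- mutate(entries,
    q_value = p.adjust(.data$p_value, method = "BH"),
    call = case_when(
      .data$q_value <= alpha & .data$rel_diff >= min_effect ~ "increase",
      .data$q_value <= alpha & .data$rel_diff <= -min_effect ~ "decrease",
      TRUE ~ "ns"
    )
  )
  structure(
    list(entries = entries, alpha = alpha, min_effect = min_effect),
    class = "poldep_matrix"
  )
}

#' Build the dependency matrix from normalised records
#'
#' Summarises every (marker, deletion) combination in all three
#' compartments (both cell ends and the cytosol) and applies matrix-wide
#' multiple-testing adjustment and calling - the quantitative equivalent of
#' the colour-coded dependency matrix figure of the assay.
#'
#' @param normalized Output of [normalize_to_controls()].
#' @param alpha Matrix-wide FDR level.
#' @param min_effect Minimum |rel_diff| for a call.
#' @param min_cells Underpowered-arm threshold (see
#'   [summarize_combination()]).
#' @return A `poldep_matrix`: `$entries` holds the long-form matrix
#'   (marker, deletion, compartment, n, rel_diff, p, q, call).
#' @examples
#' \donttest{
#' d <- study_design(markers = c("Tea1", "Tip1"),
#'                   deletions = c("tea2", "myo52"), cells_per_arm = 6)
#' cfg <- validate_config(list(design = d, truth = "literature", seed = 2))
#' run <- run_study(cfg)
#' tidy(run$matrix)
#' }
#' @export
dependency_matrix <- function(normalized, alpha = 0.05, min_effect = 0.10,
                              min_cells = 100L) {
  groups <- distinct(normalized, .data$marker, .data$deletion)
  entries <- bind_rows(pmap(groups, function(marker, deletion) {
    rec <- filter(normalized, .data$marker == !!marker,
                  .data$deletion == !!deletion)
    bind_rows(map(c("end1", "end2", "cyto"), function(cp) {
      summarize_combination(rec, cp, min_cells = min_cells)
    }))
  }))
  build_matrix(entries, alpha = alpha, min_effect = min_effect)
}

#' @export
print.poldep_matrix <- function(x, ...) {
  e <- x$entries
  cat("<poldep_matrix> ", length(unique(e$marker)), " markers x ",
      length(unique(e$deletion)), " deletions, ", nrow(e), " entries\n",
      "  calls: ", sum(e$call == "increase"), " increase, ",
      sum(e$call == "decrease"), " decrease, ",
      sum(e$call == "ns"), " ns  (alpha = ", x$alpha,
      ", min effect = ", x$min_effect, ")\n", sep = "")
  invisible(x)
}

#' @rdname poldep-tidiers
#' @export
tidy.poldep_matrix <- function(x, ...) x$entries

#' Broom-style accessors for poldep result objects
#'
#' `tidy()` returns the long-form entry/edge tables; `glance()` returns a
#' one-row summary.
#'
#' @param x A `poldep_matrix` or `poldep_network`.
#' @param ... Unused.
#' @name poldep-tidiers
#' @export
glance.poldep_matrix <- function(x, ...) {
  e <- x$entries
  tibble(
    n_entries = nrow(e),
    n_increase = sum(e$call == "increase"),
    n_decrease = sum(e$call == "decrease"),
    n_ns = sum(e$call == "ns"),
    n_underpowered = sum(e$underpowered),
    alpha = x$alpha, min_effect = x$min_effect
  )
}

#' Cast the long-form matrix to a wide marker x deletion table
#'
#' @param x A `poldep_matrix`.
#' @param compartment Which compartment to pivot.
#' @param value Which column to spread (`"rel_diff"` or `"call"`).
#' @return Tibble with one row per marker and one column per deletion;
#'   combinations absent from the design (a marker against its own gene)
#'   are NA.
#' @export
matrix_wide <- function(x, compartment = "end1", value = "rel_diff") {
  stopifnot(inherits(x, "poldep_matrix"))
  e <- filter(x$entries, .data$compartment == !!compartment)
  tidyr::pivot_wider(select(e, "marker", "deletion",
                            dplyr::all_of(value)),
                     names_from = "deletion", values_from = dplyr::all_of(value))
}
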