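#' Default polarity marker and deletion sets
#'
#' Nine GFP-tagged polarity markers are scored against deletions of the ten
#' polarity genes (the nine marker genes plus *mal3*). A marker is never
#' scored in the strain deleted for its own gene, so the default design has
#' 81 informative marker x deletion combinations arranged as a 9 x 10 grid
#' with an empty diagonal.
#'
#' @return Character vector of protein / gene names.
#' @export
polarity_markers <- function() {
  c("Bud6", "For3", "Mod5", "Myo52", "Tea1", "Tea2", "Tea3", "Tip1", "Tea4")
}

#' @rdname polarity_markers
#' @export
polarity_deletions <- function() {
  c(tolower(polarity_markers()), "mal3")
}

#' Define a marker x deletion study design
#'
#' A design fixes which GFP markers are imaged in which deletion backgrounds,
#' how many analysed cells are planned per arm (deletion cells and co-imaged
#' wild-type controls count as separate arms of equal size) and across how
#' many fields of view each combination is spread.
#'
#' @param markers Character vector of GFP-tagged marker proteins.
#' @param deletions Character vector of deleted genes (lower case by
#'   convention).
#' @param cells_per_arm Planned cells per (marker, deletion) combination for
#'   each genotype arm. A full-scale analysis uses >= 100 analysed cells
#'   per strain, so plan a small excess to survive QC exclusions.
#' @param fields_per_combination Number of fields of view per combination;
#'   `NULL` lets the simulator choose from the field capacity.
#' @return A `poldep_design` object: a list with the parameters and a
#'   `combinations` tibble (one row per informative marker x deletion pair).
#' @examples
#' d <- study_design(cells_per_arm = 5)
#' nrow(d$combinations)
#' @export
study_design <- function(markers = polarity_markers(),
                         deletions = polarity_deletions(),
                         cells_per_arm = 100L,
                         fields_per_combination = NULL) {
  stopifnot(length(markers) >= 1L, length(deletions) >= 1L)
  if (anyDuplicated(markers) || anyDuplicated(deletions)) {
    poldep_abort("markers and deletions must be unique", "poldep_design_error")
  }
  if (!is.numeric(cells_per_arm) || cells_per_arm < 1) {
    poldep_abort("cells_per_arm must be >= 1", "poldep_design_error")
  }
  combos <- tidyr::expand_grid(marker = markers, deletion = deletions)
  combos <- filter(combos, tolower(.data$marker) != tolower(.data$deletion))
  structure(
    list(
      markers = markers,
      deletions = deletions,
      cells_per_arm = as.integer(cells_per_arm),
      fields_per_combination = fields_per_combination,
      combinations = combos
    ),
    class = "poldep_design"
  )
}

#' @export
print.poldep_design <- function(x, ...) {
  cat("<poldep_design> ", length(x$markers), " markers x ",
      length(x$deletions), " deletions (", nrow(x$combinations),
      " combinations), ", x$cells_per_arm, " cells/arm\n", sep = "")
  invisible(x)
}

#' Total planned cell count of a design
#'
#' Both genotype arms are counted: `cells_per_arm * 2 * n_combinations`.
#'
#' @param design A [study_design()].
#' @return Integer.
#' @export
planned_cells <- function(design) {
  stopifnot(inherits(design, "poldep_design"))
  design$cells_per_arm * 2L * nrow(design$combinations)
}
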