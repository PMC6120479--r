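#' Ground-truth effect table for a synthetic study
#'
#' Every (marker, deletion) combination of the design is assigned
#' phenomenological effect multipliers on the baseline compartment
#' intensities of deletion cells (1.0 = no effect) plus an additive shift of
#' the baseline bipolarity parameter. Effects are deliberately
#' phenomenological: they encode *what* a deletion does to the marker's
#' distribution, not *how* (no microtubule or motor mechanics are
#' simulated).
#'
#' @param design A [study_design()].
#' @param effects Either a preset name (`"null"`, `"literature"`,
#'   `"planted"`) or a data frame with columns `marker`, `deletion` and any
#'   of `mult_end1`, `mult_end2`, `mult_cyto`, `bipolarity_shift`;
#'   combinations not listed default to no effect.
#'   * `"null"`: all multipliers 1, all shifts 0.
#'   * `"literature"`: qualitative encoding of the headline dependencies
#'     (e.g. more polar Tip1 without Myo52; loss of polar Tea1 without the
#'     Tea2 kinesin; tea1-deletion shifts in bipolar redistribution).
#'   * `"planted"`: a fixed recovery benchmark with 20 affected matrix
#'     entries (eight marker-deletion pairs with both polar ends scaled by
#'     0.5 or 1.5, four cytosolic effects) and three bipolarity shifts.
#' @param seed Unused by the deterministic presets; accepted so callers can
#'   pass one uniformly.
#' @return Tibble with one row per combination: `marker`, `deletion`,
#'   `mult_end1`, `mult_end2`, `mult_cyto`, `bipolarity_shift`.
#' @examples
#' tt <- truth_table(study_design(), "literature")
#' tt[tt$marker == "Tip1" & tt$deletion == "myo52", ]
#' @export
truth_table <- function(design, effects = "null", seed = NULL) {
  stopifnot(inherits(design, "poldep_design"))
  base <- mutate(design$combinations,
                 mult_end1 = 1, mult_end2 = 1, mult_cyto = 1,
                 bipolarity_shift = 0)
  eff_tbl <- if (is.character(effects)) {
    switch(effects,
      null = base[0, ],
      literature = truth_preset_literature(),
      planted = truth_preset_planted(),
      poldep_abort(paste0("unknown effect preset: ", effects),
                   "poldep_name_error")
    )
  } else {
    as_tibble(effects)
  }
  if (nrow(eff_tbl)) {
    stopifnot(all(c("marker", "deletion") %in% names(eff_tbl)))
    known <- paste(base$marker, base$deletion)
    bad <- setdiff(paste(eff_tbl$marker, eff_tbl$deletion), known)
    # presets cover the full default grid; a reduced design just uses less
    if (!is.character(effects) && length(bad)) {
      poldep_abort(paste0("unknown (marker, deletion) in effects: ",
                          paste(bad, collapse = ", ")),
                   "poldep_name_error")
    }
    eff_tbl <- eff_tbl[paste(eff_tbl$marker, eff_tbl$deletion) %in% known, ]
    for (col in c("mult_end1", "mult_end2", "mult_cyto", "bipolarity_shift")) {
      if (!col %in% names(eff_tbl)) eff_tbl[[col]] <- NA_real_
    }
    idx <- match(paste(eff_tbl$marker, eff_tbl$deletion), known)
    for (col in c("mult_end1", "mult_end2", "mult_cyto")) {
      val <- eff_tbl[[col]]
      if (any(!is.na(val) & val <= 0)) {
        poldep_abort("effect multipliers must be > 0", "poldep_design_error")
      }
      base[[col]][idx] <- ifelse(is.na(val), base[[col]][idx], val)
    }
    sh <- eff_tbl$bipolarity_shift
    if (any(!is.na(sh) & abs(sh) > 1)) {
      poldep_abort("bipolarity_shift must lie in [-1, 1]",
                   "poldep_design_error")
    }
    base$bipolarity_shift[idx] <-
      ifelse(is.na(sh), base$bipolarity_shift[idx], sh)
  }
  base
}

# Qualitative encoding of the headline dependency calls: polar gain of Tip1
# and of the Myo52-degraded microtubule markers in myo52, polar loss of the
# microtubule-delivered markers without Tea2/Tip1/Mal3, Mod5 anchoring
# effects, For3 competition effects, and tea1-deletion bipolarity shifts.
truth_preset_literature <- function() {
  e <- function(marker, deletion, ends = NA, cyto = NA, shift = NA) {
    tibble(marker = marker, deletion = deletion,
           mult_end1 = ends, mult_end2 = ends,
           mult_cyto = cyto, bipolarity_shift = shift)
  }
  bind_rows(
    e("Tip1", "myo52", ends = 1.6),
    e("Tea1", "tea2",  ends = 0.4),
    e("Tea1", "tea3",  ends = 0.5, cyto = 0.7),
    e("Tea1", "tea4",  ends = 0.5),
    e("Tea1", "tip1",  ends = 0.4),
    e("Tea1", "mod5",  ends = 0.6),
    e("Tea1", "mal3",  ends = 0.4),
    e("Tea1", "myo52", ends = 0.6),
    e("Tea2", "mal3",  ends = 0.4),
    e("Tea2", "tip1",  ends = 0.4),
    e("Tea4", "mal3",  ends = 0.4),
    e("Tea4", "tip1",  ends = 0.4),
    e("Tea2", "myo52", ends = 1.5, cyto = 1.3),
    e("Tea3", "myo52", ends = 1.5, cyto = 1.3),
    e("Tea4", "myo52", ends = 1.5, cyto = 1.3),
    e("Bud6", "for3",  ends = 1.5),
    e("Mod5", "for3",  ends = 1.5),
    e("Tea2", "for3",  ends = 1.5),
    e("Mod5", "bud6",  ends = 0.6),
    e("Mod5", "tea3",  ends = 0.6),
    e("Mod5", "tip1",  ends = 0.6),
    e("Tea4", "for3",  cyto = 0.6),
    e("Tea4", "tea1",  cyto = 0.6),
    e("Bud6", "tea1",  ends = 0.6),
    e("Myo52", "tea4", ends = 0.6),
    e("For3", "tea1",  shift = -0.4),
    e("Myo52", "tea1", shift = -0.4),
    e("Tea2", "tea1",  shift = -0.4)
  )
}

# Fixed benchmark for effect-recovery studies: 20 affected matrix entries
# with |multiplier - 1| = 0.5, spread over the grid, plus three bipolarity
# shifts on otherwise untouched combinations.
truth_preset_planted <- function() {
  pol <- tibble(
    marker   = c("Tea1", "Tip1", "Tea2", "Myo52", "Mod5", "Tea3", "Bud6",
                 "Tea4"),
    deletion = c("tea2", "myo52", "mal3", "tea4", "bud6", "myo52", "for3",
                 "tip1"),
    m        = c(0.5, 1.5, 0.5, 0.5, 0.5, 1.5, 1.5, 0.5)
  )
  cyt <- tibble(
    marker   = c("Tea4", "Tea1", "For3", "Mod5"),
    deletion = c("tea1", "tea3", "tip1", "for3"),
    m        = c(1.5, 0.5, 0.5, 1.5)
  )
  bind_rows(
    tibble(marker = pol$marker, deletion = pol$deletion,
           mult_end1 = pol$m, mult_end2 = pol$m),
    tibble(marker = cyt$marker, deletion = cyt$deletion, mult_cyto = cyt$m),
    tibble(marker = c("For3", "Myo52", "Tea2"), deletion = "tea1",
           bipolarity_shift = -0.4)
  )
}

#' Entries of a truth table that constitute real planted effects
#'
#' Helper for recovery benchmarks: returns the (marker, deletion,
#' compartment) entries whose multiplier differs from 1, with the expected
#' call sign.
#'
#' @param truth A [truth_table()].
#' @return Tibble with `marker`, `deletion`, `compartment`,
#'   `expected_call`.
#' @export
planted_entries <- function(truth) {
  long <- tidyr::pivot_longer(
    select(truth, "marker", "deletion", "mult_end1", "mult_end2",
           "mult_cyto"),
    cols = dplyr::starts_with("mult_"),
    names_to = "compartment", values_to = "mult",
    names_prefix = "mult_"
  )
  long <- filter(long, .data$mult != 1)
  mutate(long,
         expected_call = ifelse(.data$mult > 1, "increase", "decrease"),
         mult = NULL)
}
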