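#' Test for shifts in monopolar/bipolar marker distribution
#'
#' NETO (New End Take Off) is the switch from monopolar to bipolar tip
#' growth; a deletion that blocks the bipolar redistribution of a marker
#' shifts the population's bipolarity index (corrected End2/End1 ratio)
#' downwards. Each (marker, deletion) pair is compared against its
#' co-imaged controls with a rank-based two-sample (Wilcoxon) test on the
#' per-cell bipolarity index, adjusted across all pairs (BH); the
#' proportion of cells classified bipolar (index >= `bipolar_threshold`)
#' is reported per arm as a descriptive dichotomy, but the distribution
#' test drives the `shifted` call.
#'
#' @param normalized Output of [normalize_to_controls()].
#' @param alpha FDR level for the `shifted` call.
#' @param bipolar_threshold Bipolarity-index cut-off for the descriptive
#'   bipolar/monopolar dichotomy.
#' @return Tibble with one row per (marker, deletion):
#'   `delta_bipolarity` (median deletion - median control), bipolar
#'   proportions, `p_value`, `q_value`, `shifted`.
#' @export
neto_shift_test <- function(normalized, alpha = 0.05,
                            bipolar_threshold = 0.5) {
  groups <- distinct(normalized, .data$marker, .data$deletion)
  out <- bind_rows(pmap(groups, function(marker, deletion) {
    rec <- filter(normalized, .data$marker == !!marker,
                  .data$deletion == !!deletion)
    del <- rec$bipolarity_index[rec$genotype == "deletion"]
    ctl <- rec$bipolarity_index[rec$genotype == "control"]
    if (!length(del) || !length(ctl)) {
      poldep_abort(paste0("combination ", marker, " x ", deletion,
                          " is missing an arm"), "poldep_missing_arm")
    }
    p <- if (all(del == del[1]) && all(ctl == ctl[1]) && del[1] == ctl[1]) {
      1   # both arms constant and identical: no evidence of any shift
    } else {
      suppressWarnings(wilcox.test(del, ctl, exact = FALSE)$p.value)
    }
    tibble(
      marker = marker, deletion = deletion,
      n_del = length(del), n_ctrl = length(ctl),
      delta_bipolarity = median(del) - median(ctl),
      prop_bipolar_del = mean(del >= bipolar_threshold),
      prop_bipolar_ctrl = mean(ctl >= bipolar_threshold),
      p_value = p
    )
  }))
  mutate(out,
         q_value = p.adjust(.data$p_value, method = "BH"),
         shifted = .data$q_value <= alpha)
}
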