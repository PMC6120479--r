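#' Normalise measurements to same-field wild-type controls
#'
#' The heart of the internally controlled design: every cell's
#' background-corrected compartment values are divided by the mean of the
#' wild-type (control) cells from the *same field of view*, cancelling any
#' field-to-field variation in illumination, mounting or camera settings.
#' Control cells are normalised by their own field mean too, so control
#' normalised values average exactly 1 within every field. Fields without
#' a usable control arm (none present, or a non-positive control mean) are
#' dropped with a warning.
#'
#' @param cells Measurement tibble from [quantify_study()] /
#'   [quantify_field()].
#' @param statistic Which ROI statistic to normalise: the disc `"mean"`
#'   (default) or disc `"max"`.
#' @return Tibble of analysed cells with `norm_end1`, `norm_end2`,
#'   `norm_cyto` columns (dimensionless, control mean = 1 per field) plus
#'   the identifying and bipolarity columns.
#' @export
normalize_to_controls <- function(cells, statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  suffix <- if (statistic == "mean") "_mean" else "_max"
  use <- filter(cells, .data$analysed)
  if (nrow(use) == 0L) {
    poldep_abort("no analysed cells to normalise", "poldep_missing_arm")
  }
  cols <- paste0(c("end1", "end2", "cyto"), suffix)
  use$..e1 <- use[[cols[1]]]
  use$..e2 <- use[[cols[2]]]
  use$..cy <- use[[cols[3]]]
  grp <- group_by(use, .data$marker, .data$deletion, .data$field_id)
  grp <- mutate(grp,
    ..n_ctrl = sum(.data$genotype == "control"),
    ..m1 = mean(.data$..e1[.data$genotype == "control"]),
    ..m2 = mean(.data$..e2[.data$genotype == "control"]),
    ..mc = mean(.data$..cy[.data$genotype == "control"])
  )
  grp <- ungroup(grp)
  bad <- grp$..n_ctrl == 0L | grp$..m1 <= 0 | grp$..m2 <= 0 | grp$..mc <= 0
  if (any(bad)) {
    dropped <- unique(grp$field_id[bad])
    warn(paste0("dropping ", length(dropped),
                " field(s) without usable controls: ",
                paste(head(dropped, 5), collapse = ", "),
                if (length(dropped) > 5) ", ..." else ""))
    grp <- grp[!bad, ]
  }
  out <- mutate(grp,
    norm_end1 = .data$..e1 / .data$..m1,
    norm_end2 = .data$..e2 / .data$..m2,
    norm_cyto = .data$..cy / .data$..mc
  )
  select(out, "field_id", "cell_id", "marker", "deletion", "genotype",
         "norm_end1", "norm_end2", "norm_cyto", "bipolarity_index")
}
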