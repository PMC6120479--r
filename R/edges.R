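#' Convert the called matrix into signed dependency edges
#'
#' An edge runs from the deleted protein to the measured marker. A
#' *positive* regulation (`+`) means the upstream protein is required for
#' the marker's polar localisation: the marker's polar signal *decreases*
#' in the deletion. A *negative* regulation (`-`) means the upstream
#' protein limits polar accumulation: the signal *increases* in the
#' deletion. Polar calls come from the end compartments (`edge_rule`
#' selects which); when the two ends disagree, the entry with the larger
#' `|rel_diff|` wins, and both underlying calls are kept in the `basis`
#' column.
#'
#' @param x A `poldep_matrix` (or its long-form entries tibble).
#' @param neto Optional [neto_shift_test()] table; its `shifted` flag is
#'   attached to the matching edges.
#' @param edge_rule `"either"` (default: a call at either end makes an
#'   edge), `"end1"` or `"end2"`.
#' @return Tibble of signed edges: `source`, `target`, `sign`, `basis`,
#'   `rel_diff`, `neto`.
#' @export
matrix_to_edges <- function(x, neto = NULL,
                            edge_rule = c("either", "end1", "end2")) {
  edge_rule <- match.arg(edge_rule)
  entries <- if (inherits(x, "poldep_matrix")) x$entries else as_tibble(x)
  ends <- switch(edge_rule, either = c("end1", "end2"),
                 end1 = "end1", end2 = "end2")
  polar <- filter(entries, .data$compartment %in% ends, .data$call != "ns")
  if (nrow(polar) == 0L) return(empty_edges())
  grouped <- group_by(polar, .data$marker, .data$deletion)
  edges <- summarise(grouped,
    basis = paste(.data$compartment, collapse = ","),
    rel_diff = .data$rel_diff[which.max(abs(.data$rel_diff))],
    .groups = "drop"
  )
  edges <- mutate(edges,
    source = protein_name(.data$deletion),
    target = .data$marker,
    sign = ifelse(.data$rel_diff < 0, "+", "-")
  )
  if (any(edges$source == edges$target)) {
    poldep_abort("self-edge produced; marker measured in its own deletion",
                 "poldep_integrity_error")
  }
  edges$neto <- FALSE
  if (!is.null(neto)) {
    key <- paste(protein_name(neto$deletion), neto$marker)
    idx <- match(paste(edges$source, edges$target), key)
    edges$neto <- !is.na(idx) & neto$shifted[idx]
  }
  select(edges, "source", "target", "sign", "basis", "rel_diff", "neto")
}

# gene name -> protein display name (tea2 -> Tea2)
protein_name <- function(gene) {
  paste0(toupper(substr(gene, 1, 1)), substring(gene, 2))
}

empty_edges <- function() {
  tibble(source = character(), target = character(), sign = character(),
         basis = character(), rel_diff = double(), neto = logical())
}

#' Signed dependency relations reported for the fission yeast polarity
#' network
#'
#' A small curated edge set transcribed from published descriptions of the
#' polarity-protein dependency network: the two-protein feedback pair
#' examples (`context = "pair_example"`), the nine edges of the three
#' larger all-positive loops (`"positive_loop"`) and the five edges of the
#' larger negative loop (`"negative_loop"`; the two edge signs that are
#' not individually reported are inferred from the loop's overall negative
#' sign, as noted in the `evidence` column). The set is deliberately
#' partial - it covers what the prose states, not the full figure.
#'
#' @param contexts Which contexts to include (default all).
#' @param dedupe Drop duplicate (source, target, sign) rows that appear in
#'   several contexts.
#' @return Edge tibble with `source`, `target`, `sign`, `neto`, `context`,
#'   `evidence`.
#' @examples
#' ref <- reference_edges("positive_loop")
#' enumerate_cycles(ref)
#' @export
reference_edges <- function(contexts = NULL, dedupe = TRUE) {
  path <- system.file("extdata", "polarity_reference_edges.tsv",
                      package = "poldep")
  ed <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = "ccclcc")
  if (!is.null(contexts)) ed <- filter(ed, .data$context %in% contexts)
  if (dedupe) ed <- distinct(ed, .data$source, .data$target, .data$sign,
                             .keep_all = TRUE)
  ed
}
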