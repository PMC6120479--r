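edge_table_for_export <- function(x) {
  if (inherits(x, "poldep_network")) {
    edges <- x$edges
    loops <- x$loops
  } else {
    edges <- as_tibble(x)
    loops <- empty_loops()
  }
  for (col in c("basis", "rel_diff", "neto")) {
    if (!col %in% names(edges)) {
      edges[[col]] <- if (col == "rel_diff") NA_real_
                      else if (col == "neto") FALSE else NA_character_
    }
  }
  # an edge table read back from TSV already carries loop memberships;
  # recompute only when a network object provides its loop table
  membership <- if ("loops" %in% names(edges)) {
    ifelse(is.na(edges$loops), "", edges$loops)
  } else {
    rep("", nrow(edges))
  }
  if (nrow(loops)) {
    membership <- rep("", nrow(edges))
    key <- paste(edges$source, edges$target)
    for (i in seq_len(nrow(loops))) {
      nds <- loops$nodes[[i]]
      pairs <- paste(nds, c(nds[-1], nds[1]))
      if (loops$length[i] == 2L) pairs <- c(pairs, paste(nds[2], nds[1]))
      hit <- key %in% pairs
      membership[hit] <- ifelse(membership[hit] == "",
                                loops$nodes_chr[i],
                                paste(membership[hit], loops$nodes_chr[i],
                                      sep = ";"))
    }
  }
  edges$loops <- membership
  select(edges, "source", "target", "sign", "basis", "rel_diff", "neto",
         "loops")
}

#' Export a dependency network
#'
#' Writes the signed edge list with its attributes (call basis, relative
#' difference, NETO flag, loop memberships) as a tab-separated edge list,
#' GraphML, or Graphviz DOT. DOT output follows the figure conventions of
#' the assay: green arrows for positive regulations, red for negative,
#' blue for NETO-shift edges. The TSV form round-trips losslessly through
#' [read_network_tsv()].
#'
#' @param x A `poldep_network` or an edge tibble.
#' @param path Output file path.
#' @param format `"tsv"`, `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("tsv", "graphml", "dot")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) poldep_abort(
                       paste0("unsupported network format: ", format[1]),
                       "poldep_format_error"))
  edges <- edge_table_for_export(x)
  if (format == "tsv") {
    readr::write_tsv(edges, path)
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- c("digraph poldep {", "  rankdir=LR;")
    for (i in seq_len(nrow(edges))) {
      colour <- if (isTRUE(edges$neto[i])) "blue"
                else if (edges$sign[i] == "+") "green" else "red"
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [color=%s];",
                                edges$source[i], edges$target[i], colour))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a network edge list written by [export_network()]
#'
#' @param path TSV file path.
#' @return Edge tibble with the documented columns and types.
#' @export
read_network_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    source = readr::col_character(), target = readr::col_character(),
    sign = readr::col_character(), basis = readr::col_character(),
    rel_diff = readr::col_double(), neto = readr::col_logical(),
    loops = readr::col_character()
  ), na = "NA")
}
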