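#' Classify two-protein feedback loops
#'
#' Every unordered protein pair connected by edges in both directions forms
#' one two-node loop, classified by its sign pair:
#' * `(+, +)` - positive amplification loop: A and B promote each other's
#'   recruitment;
#' * `(-, -)` - negative reduction loop: A and B inhibit each other's
#'   accumulation;
#' * `(+, -)` - direct unidirectional loop: A promotes the recruitment of
#'   B, which in turn prevents excess accumulation of A.
#'
#' @param edges Edge tibble with `source`, `target`, `sign` (deduplicated;
#'   at most one edge per ordered pair).
#' @return Tibble of length-2 loops: `nodes` (list column, smaller name
#'   first), `nodes_chr`, `length`, `edge_signs`, `class`, `overall_sign`,
#'   `all_positive`.
#' @export
classify_two_node_loops <- function(edges) {
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key)) {
    poldep_abort("edges must be deduplicated (one per ordered pair)",
                 "poldep_integrity_error")
  }
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$source[i]; b <- edges$target[i]
    if (a >= b) next   # visit each unordered pair once, smaller name first
    j <- match(paste(b, a), key)
    if (is.na(j)) next
    s_ab <- edges$sign[i]; s_ba <- edges$sign[j]
    cls <- if (s_ab == "+" && s_ba == "+") "positive_2"
           else if (s_ab == "-" && s_ba == "-") "negative_2"
           else "unidirectional_2"
    rows[[length(rows) + 1L]] <- make_loop(c(a, b), c(s_ab, s_ba), cls)
  }
  if (!length(rows)) return(empty_loops())
  bind_rows(rows)
}

make_loop <- function(nodes, signs, class) {
  chr <- paste(nodes, collapse = "-")
  len <- length(nodes)
  sgn <- if (sum(signs == "-") %% 2 == 1) "-" else "+"
  pos <- all(signs == "+")
  tibble(
    nodes = list(nodes),
    nodes_chr = chr,
    length = len,
    edge_signs = paste(signs, collapse = ""),
    class = class,
    overall_sign = sgn,
    all_positive = pos
  )
}

empty_loops <- function() {
  tibble(nodes = list(), nodes_chr = character(), length = integer(),
         edge_signs = character(), class = character(),
         overall_sign = character(), all_positive = logical())
}

#' Enumerate simple directed cycles with their feedback signs
#'
#' Finds every simple cycle of length in `[min_len, max_len]` in the
#' signed directed dependency graph by rooted depth-first search: each
#' cycle is explored only from its lexicographically smallest node, so it
#' is reported exactly once, in canonical rotation, regardless of edge
#' order. The overall feedback sign is the product of the edge signs
#' (negative iff the cycle carries an odd number of negative edges); loops
#' whose edges are all positive are additionally flagged, matching the
#' convention that a "positive loop" is an all-positive-edge cycle.
#'
#' @param edges Edge tibble (`source`, `target`, `sign`), at most one edge
#'   per ordered pair.
#' @param min_len Minimum cycle length (default 3; use
#'   [classify_two_node_loops()] for length 2).
#' @param max_len Maximum cycle length; default = number of nodes.
#' @return Tibble of loops in the format of [classify_two_node_loops()],
#'   with `class = "cycle_n"`.
#' @examples
#' enumerate_cycles(reference_edges("positive_loop"))
#' @export
enumerate_cycles <- function(edges, min_len = 3L, max_len = NULL) {
  key <- paste(edges$source, edges$target)
  if (anyDuplicated(key)) {
    poldep_abort("edges must be deduplicated (one per ordered pair)",
                 "poldep_integrity_error")
  }
  nodes <- sort(unique(c(edges$source, edges$target)))
  max_len <- max_len %||% length(nodes)
  if (!nrow(edges) || max_len < min_len) return(empty_loops())
  adj <- map(setNames(nodes, nodes), function(nd) {
    ord <- edges$target[edges$source == nd]
    sort(ord)
  })
  sign_of <- setNames(edges$sign, key)
  loops <- list()
  path <- character(max_len)
  on_path <- setNames(rep(FALSE, length(nodes)), nodes)

  dfs <- function(root, node, depth) {
    for (nb in adj[[node]]) {
      if (nb == root) {
        if (depth >= min_len) {
          nds <- path[seq_len(depth)]
          signs <- sign_of[paste(nds, c(nds[-1], nds[1]))]
          loops[[length(loops) + 1L]] <<- make_loop(nds, unname(signs),
                                                    "cycle_n")
        }
      } else if (nb > root && !on_path[[nb]] && depth < max_len) {
        path[depth + 1L] <<- nb
        on_path[[nb]] <<- TRUE
        dfs(root, nb, depth + 1L)
        on_path[[nb]] <<- FALSE
      }
    }
  }
  for (root in nodes) {
    path[1L] <- root
    on_path[[root]] <- TRUE
    dfs(root, root, 1L)
    on_path[[root]] <- FALSE
  }
  if (!length(loops)) return(empty_loops())
  arrange(bind_rows(loops), .data$length, .data$nodes_chr)
}

#' Assemble the signed dependency network with its loop taxonomy
#'
#' @param edges Edge tibble from [matrix_to_edges()] or
#'   [reference_edges()].
#' @param min_len,max_len Cycle length range passed to
#'   [enumerate_cycles()].
#' @return A `poldep_network`: list with `$edges`, `$loops` (two-node
#'   classes and longer cycles combined) and `$nodes`.
#' @export
dependency_network <- function(edges, min_len = 3L, max_len = NULL) {
  edges <- distinct(as_tibble(edges), .data$source, .data$target,
                    .keep_all = TRUE)
  if (!"neto" %in% names(edges)) edges$neto <- FALSE
  loops <- bind_rows(classify_two_node_loops(edges),
                     enumerate_cycles(edges, min_len, max_len))
  structure(
    list(edges = edges, loops = loops,
         nodes = sort(unique(c(edges$source, edges$target)))),
    class = "poldep_network"
  )
}

#' @export
print.poldep_network <- function(x, ...) {
  cat("<poldep_network> ", length(x$nodes), " proteins, ", nrow(x$edges),
      " signed edges\n  loops: ", sep = "")
  if (nrow(x$loops)) {
    tb <- table(x$loops$class)
    cat(paste(names(tb), tb, sep = " = ", collapse = ", "), "\n")
  } else cat("none\n")
  invisible(x)
}

#' @rdname poldep-tidiers
#' @export
tidy.poldep_network <- function(x, ...) x$edges

#' @rdname poldep-tidiers
#' @export
glance.poldep_network <- function(x, ...) {
  lp <- x$loops
  tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_positive_edges = sum(x$edges$sign == "+"),
    n_negative_edges = sum(x$edges$sign == "-"),
    n_neto_edges = sum(x$edges$neto),
    n_unidirectional_2 = sum(lp$class == "unidirectional_2"),
    n_positive_2 = sum(lp$class == "positive_2"),
    n_negative_2 = sum(lp$class == "negative_2"),
    n_cycles = sum(lp$class == "cycle_n"),
    n_all_positive_cycles = sum(lp$class == "cycle_n" & lp$all_positive)
  )
}
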