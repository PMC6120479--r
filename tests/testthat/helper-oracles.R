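# independent oracles used by the unit and acceptance tests

# per-pixel maximum over z by explicit triple loop
brute_force_max_project <- function(arr) {
  d <- dim(arr)
  out <- arr[, , 1]
  for (y in seq_len(d[1])) {
    for (x in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        if (arr[y, x, k] > out[y, x]) out[y, x] <- arr[y, x, k]
      }
    }
  }
  out
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# enumerate simple directed cycles by exhaustive search over node subsets
# and permutations, each cycle rooted at its lexicographically smallest node
brute_force_cycles <- function(edges, min_len = 3L, max_len = NULL) {
  key <- paste(edges$source, edges$target)
  nodes <- sort(unique(c(edges$source, edges$target)))
  max_len <- if (is.null(max_len)) length(nodes) else max_len
  found <- character()
  if (length(nodes) < min_len) return(found)
  for (k in seq(min_len, min(max_len, length(nodes)))) {
    subsets <- utils::combn(nodes, k, simplify = FALSE)
    for (s in subsets) {
      root <- s[1]   # nodes sorted, so s[1] is smallest
      for (perm in all_permutations(s[-1])) {
        path <- c(root, perm)
        nxt <- c(path[-1], root)
        if (all(paste(path, nxt) %in% key)) {
          found <- c(found, paste(path, collapse = "-"))
        }
      }
    }
  }
  sort(found)
}

random_signed_graph <- function(n_nodes, p_edge = 0.35, seed = 1) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n_nodes)]
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < p_edge
  ed <- pairs[keep, ]
  ed$sign <- sample(c("+", "-"), nrow(ed), replace = TRUE)
  tibble::as_tibble(ed)
}
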