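#' Maximum intensity projection of a z-stack
#'
#' Collapses a multi-slice stack to a single 2-D image by taking the
#' per-pixel maximum over z, the standard way of presenting 3-D widefield
#' data of rod-shaped yeast cells as a single analysable plane.
#'
#' @param stack A finalized [field_stack()] or a plain 3-D array indexed
#'   `[y, x, z]`.
#' @param channel For a `field_stack`: `"gfp"` or `"red"`.
#' @return A 2-D matrix of the same (y, x) shape.
#' @examples
#' a <- array(runif(4 * 4 * 3), c(4, 4, 3))
#' max_project(a)
#' @export
max_project <- function(stack, channel = c("gfp", "red")) {
  if (inherits(stack, "field_stack")) {
    channel <- match.arg(channel)
    arr <- stack[[channel]]
    if (is.null(arr)) {
      proj <- stack[[paste0(channel, "_proj")]]
      if (is.null(proj)) {
        poldep_abort("field_stack holds neither slices nor a projection",
                     "poldep_empty_stack")
      }
      return(proj)
    }
    stack <- arr
  }
  if (!is.array(stack) || length(dim(stack)) != 3L || dim(stack)[3] < 1L) {
    poldep_abort("stack must be a non-empty [y, x, z] array",
                 "poldep_empty_stack")
  }
  nz <- dim(stack)[3]
  proj <- stack[, , 1]
  for (k in seq_len(nz - 1L) + 1L) proj <- pmax(proj, stack[, , k])
  proj
}
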