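#' Time slices of a dated tree
#'
#' The distinct internal-node ages, together with the present (0), cut the
#' interval from the present back to the root age into time slices.  A species
#' branch belongs to a slice when its age interval spans the whole slice; two
#' branches can exchange genes by horizontal transfer only when they co-occur
#' in the slice where the transfer happens.
#'
#' @param tree A [dated_tree].
#' @return A `slice_index`: a tibble with one row per slice (`slice`, youngest
#'   first; `lower`, `upper` in Ga; `branches`, a list-column of branch ids
#'   alive throughout the slice) carrying the boundary vector as attribute
#'   `boundaries`.
#' @examples
#' tr <- parse_dated_newick("((A:1,B:1):2,C:3);")
#' compute_time_slices(tr)
#' @export
compute_time_slices <- function(tree) {
  stopifnot(is_dated_tree(tree))
  br <- branches(tree)
  n <- n_tips(tree)
  internal_ages <- tree$ages[(n + 1L):length(tree$ages)]
  bounds <- sort(unique(c(0, internal_ages)))
  k <- length(bounds) - 1L
  tol <- 1e-12 * max(1, root_age(tree))
  alive <- lapply(seq_len(k), function(s) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    sort(br$branch[br$t_child <= lo + tol & br$t_parent >= hi - tol])
  })
  out <- tibble(
    slice = seq_len(k),
    lower = bounds[seq_len(k)],
    upper = bounds[-1L],
    branches = alive
  )
  attr(out, "boundaries") <- bounds
  class(out) <- c("slice_index", class(out))
  out
}

#' @rdname compute_time_slices
#' @param slices A `slice_index`.
#' @param age Age in Ga.
#' @return `slice_at()` returns the slice number whose interval contains `age`
#'   (boundary ages resolve to the younger slice; the present belongs to
#'   slice 1).
#' @export
slice_at <- function(slices, age) {
  bounds <- attr(slices, "boundaries")
  if (age < 0 || age > bounds[length(bounds)]) {
    abort(sprintf("Age %.6g Ga is outside [0, root age].", age))
  }
  if (age == 0) return(1L)
  findInterval(age, bounds, left.open = TRUE)
}
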