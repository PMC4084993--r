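#' Enumerate the DEC range state space
#'
#' Builds the ordered set of allowed geographic ranges (subsets of areas)
#' for a DEC model: the empty range, all singletons, and every subset of
#' size at most `max_range_size` that is connected under the adjacency
#' matrix.  States are ordered deterministically by size, then
#' lexicographically by area index; the empty range is always state 1.
#'
#' @param areas Character vector of area labels (length N >= 1).
#' @param max_range_size Maximum number of areas in a range (1..N).
#' @param adjacency Symmetric 0/1 matrix (N x N); a multi-area range is a
#'   state only if it induces a connected subgraph.  Default: complete.
#' @return An object of class `range_state_space`: a list with `areas`,
#'   `max_range_size`, `adjacency`, `states` (list of integer index
#'   vectors; `integer(0)` is the empty range), `labels`, and `n_states`.
#' @examples
#' sp <- build_state_space(c("A", "B", "C"), max_range_size = 2)
#' sp$n_states  # 7: empty + 3 singletons + 3 pairs
#' @export
build_state_space <- function(areas, max_range_size,
                              adjacency = NULL) {
  n <- length(areas)
  if (n < 1) stop("at least one area is required", call. = FALSE)
  if (anyDuplicated(areas)) stop("area labels must be unique", call. = FALSE)
  if (max_range_size < 1 || max_range_size > n) {
    stop("max_range_size must be between 1 and the number of areas",
         call. = FALSE)
  }
  if (is.null(adjacency)) {
    adjacency <- matrix(1, n, n)
  }
  adjacency <- as.matrix(adjacency)
  if (!all(dim(adjacency) == c(n, n))) {
    stop("adjacency must be N x N", call. = FALSE)
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  adjacency <- (adjacency != 0) * 1
  diag(adjacency) <- 1

  states <- list(integer(0))
  for (k in seq_len(max_range_size)) {
    sets <- utils::combn(n, k, simplify = FALSE)
    if (k > 1) {
      sets <- Filter(function(s) is_connected_subset(s, adjacency), sets)
    }
    # combn already emits sets in lexicographic order within each size
    states <- c(states, sets)
  }
  labels <- vapply(states, function(s) {
    if (!length(s)) "0" else paste(areas[s], collapse = "+")
  }, character(1))
  structure(
    list(areas = areas, max_range_size = max_range_size,
         adjacency = adjacency, states = states, labels = labels,
         n_states = length(states)),
    class = "range_state_space"
  )
}

is_connected_subset <- function(s, adjacency) {
  seen <- s[1]
  repeat {
    nb <- s[colSums(adjacency[seen, s, drop = FALSE] > 0) > 0]
    nb <- union(seen, nb)
    if (length(nb) == length(seen)) break
    seen <- nb
  }
  length(seen) == length(s)
}

#' @export
print.range_state_space <- function(x, ...) {
  cat(sprintf(
    "DEC range state space: %d areas, max range size %d, %d states\n",
    length(x$areas), x$max_range_size, x$n_states))
  invisible(x)
}

# index of the state equal to the integer set `s` (sorted), or NA
state_index <- function(space, s) {
  s <- sort(as.integer(s))
  for (i in seq_along(space$states)) {
    if (length(space$states[[i]]) == length(s) &&
        all(space$states[[i]] == s)) {
      return(i)
    }
  }
  NA_integer_
}

# translate a character vector of area labels to a state index
range_to_state <- function(space, areas) {
  idx <- match(areas, space$areas)
  if (anyNA(idx)) {
    stop("unknown area label(s): ",
         paste(areas[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  st <- state_index(space, idx)
  if (is.na(st)) {
    stop("range {", paste(areas, collapse = ","),
         "} is not a state of the space (size or connectivity constraint)",
         call. = FALSE)
  }
  st
}

# canonical lookup key for an integer area set ("-" for the empty range,
# since empty-string names never match in named indexing)
set_key <- function(s) {
  if (!length(s)) "-" else paste(s, collapse = ",")
}
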