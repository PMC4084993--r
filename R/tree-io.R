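#' Read a dated ultrametric tree from a Newick file
#'
#' Parses a Newick tree (branch lengths required, interpreted as Ma),
#' computes node ages from branch lengths, and validates that the tree is
#' strictly bifurcating and ultrametric: all root-to-tip path lengths must
#' agree within `age_tolerance`.
#'
#' @param path Path to a Newick file, or a Newick string (must end in ";").
#' @param age_tolerance Maximum allowed deviation among root-to-tip path
#'   lengths, in Ma.  Default `1e-6`.
#' @return An object of class `phylo` (see [ape::read.tree()]) carrying a
#'   `node_age` attribute: a numeric vector of ages (Ma, tips ~ 0) indexed
#'   by node number.
#' @seealso [write_newick()], [node_ages()]
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' max(node_ages(tr))  # root age 2
#' @export
read_newick <- function(path, age_tolerance = 1e-6) {
  txt <- grepl(";\\s*$", path[1]) && !file.exists(path[1])
  if (!txt && !file.exists(path[1])) {
    stop("no such file, and not a Newick string: ", path[1], call. = FALSE)
  }
  tree <- tryCatch(
    if (txt) ape::read.tree(text = path) else ape::read.tree(path),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("failed to parse Newick input: ", path[1], call. = FALSE)
  }
  validate_dated_tree(tree, age_tolerance = age_tolerance)
}

#' Validate a phylo object as a dated ultrametric tree
#'
#' @param tree A `phylo` object with branch lengths in Ma.
#' @inheritParams read_newick
#' @return The tree, with a `node_age` attribute attached.
#' @export
validate_dated_tree <- function(tree, age_tolerance = 1e-6) {
  if (!inherits(tree, "phylo")) {
    stop("`tree` must be a phylo object", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; a dated tree is required", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("tree has negative branch lengths", call. = FALSE)
  }
  if (ape::Ntip(tree) >= 2 &&
      (!ape::is.rooted(tree) || !ape::is.binary(tree))) {
    stop("tree is not rooted and strictly bifurcating; ",
         "resolve polytomies first", call. = FALSE)
  }
  depth <- ape::node.depth.edgelength(tree)  # root-to-node path lengths
  ntip <- ape::Ntip(tree)
  tip_depth <- depth[seq_len(ntip)]
  height <- max(tip_depth)
  dev <- abs(tip_depth - height)
  if (any(dev > age_tolerance)) {
    worst <- which.max(dev)
    stop(sprintf(
      "tree is not ultrametric: tip '%s' has root-to-tip length %.9g vs tree height %.9g (tolerance %g)",
      tree$tip.label[worst], tip_depth[worst], height, age_tolerance
    ), call. = FALSE)
  }
  age <- height - depth
  age[seq_len(ntip)] <- 0  # tips are the present, by definition
  attr(tree, "node_age") <- age
  tree
}

#' Node ages of a dated tree
#'
#' @param tree A `phylo` object (validated trees carry cached ages).
#' @return Numeric vector of node ages in Ma, indexed by node number
#'   (tips `1..Ntip`, then internal nodes).
#' @export
node_ages <- function(tree) {
  age <- attr(tree, "node_age")
  if (!is.null(age)) {
    return(age)
  }
  depth <- ape::node.depth.edgelength(tree)
  height <- max(depth[seq_len(ape::Ntip(tree))])
  age <- height - depth
  age[seq_len(ape::Ntip(tree))] <- 0
  age
}

#' Write a dated tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

root_node <- function(tree) ape::Ntip(tree) + 1L

# children of each internal node as a list indexed by node number
child_list <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2])
  }
  kids
}

# internal nodes in postorder (children before parents)
postorder_nodes <- function(tree) {
  ord <- ape::reorder.phylo(tree, "postorder")
  unique(ord$edge[, 1])
}
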