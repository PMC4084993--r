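#' LCA-mapping reconciliation of a tanglegram
#'
#' Maps every parasite node to the least common ancestor (LCA) of the
#' host tips of its descendant parasites.  A parasite node *tracks a host
#' divergence* when its two children map into subtrees rooted at two
#' distinct children of the node's own host image.  The congruence
#' statistic is the number of distinct host nodes tracked this way, so a
#' host speciation is counted once however many parasite nodes echo it;
#' it ranges from 0 to the number of internal parasite nodes.
#'
#' @param host,parasite Strictly bifurcating `phylo` trees (polytomies
#'   are rejected; resolve or prune first).
#' @param assoc Named character vector: parasite tip label -> host tip
#'   label (many parasites may share one host).
#' @return List with `cospeciations` (the statistic), `node_map` (host
#'   node image per parasite node), and `cospeciating_nodes` (parasite
#'   nodes that track a host divergence).
#' @examples
#' h <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
#' p <- ape::read.tree(text = "((pa:1,pb:1):1,(pc:1,pd:1):1);")
#' lca_reconcile(h, p, c(pa = "a", pb = "b", pc = "c", pd = "d"))$cospeciations
#' @export
lca_reconcile <- function(host, parasite, assoc) {
  for (tr in list(host, parasite)) {
    if (ape::Ntip(tr) >= 2 &&
        (!ape::is.rooted(tr) || !ape::is.binary(tr))) {
      stop("trees must be rooted and strictly bifurcating", call. = FALSE)
    }
  }
  unmapped <- setdiff(parasite$tip.label, names(assoc))
  if (length(unmapped)) {
    stop("unmapped parasite tip(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  bad <- !assoc[parasite$tip.label] %in% host$tip.label
  if (any(bad)) {
    stop("association points to unknown host tip(s): ",
         paste(unique(assoc[parasite$tip.label][bad]), collapse = ", "),
         call. = FALSE)
  }
  hp <- host_parents(host)
  hdepth <- host_depths(host, hp)
  host_tip_idx <- stats::setNames(seq_along(host$tip.label), host$tip.label)

  lca2 <- function(a, b) {
    while (a != b) {
      if (hdepth[a] >= hdepth[b]) a <- hp[a] else b <- hp[b]
    }
    a
  }
  ntip_p <- ape::Ntip(parasite)
  n_node_p <- ntip_p + parasite$Nnode
  m <- integer(n_node_p)
  m[seq_len(ntip_p)] <- host_tip_idx[assoc[parasite$tip.label]]
  kids <- child_list(parasite)
  cosp_nodes <- integer(0)
  host_hits <- integer(0)
  for (v in postorder_nodes(parasite)) {
    c1 <- kids[[v]][1]
    c2 <- kids[[v]][2]
    m[v] <- lca2(m[c1], m[c2])
    if (m[c1] != m[v] && m[c2] != m[v]) {
      # the host-children subtrees containing the two images are
      # necessarily distinct when neither image equals the LCA itself
      cosp_nodes <- c(cosp_nodes, v)
      host_hits <- c(host_hits, m[v])
    }
  }
  list(cospeciations = length(unique(host_hits)),
       node_map = m, cospeciating_nodes = cosp_nodes)
}

host_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p[root_node(tree)] <- root_node(tree)
  p
}

host_depths <- function(tree, parents = host_parents(tree)) {
  n <- length(parents)
  d <- rep(NA_integer_, n)
  d[root_node(tree)] <- 0L
  # edges in preorder: parents appear before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    d[ord$edge[i, 2]] <- d[ord$edge[i, 1]] + 1L
  }
  d
}

#' Permutation test of host-parasite tree congruence
#'
#' Tests the null hypothesis that the parasite phylogeny is independent
#' of the host phylogeny.  The observed statistic is the
#' [lca_reconcile()] cospeciation count; the null distribution is
#' generated by uniformly permuting the parasite-tip-to-host assignment
#' as a multiset (host multiplicities preserved).
#'
#' Because the statistic is integer-valued, the standard permutation
#' p-value `(1 + #(null >= obs)) / (n_perm + 1)` is conservative under
#' ties; `p_randomized` breaks ties uniformly and is exactly uniform
#' under the null, which makes it the appropriate quantity for
#' calibration studies.
#'
#' @inheritParams lca_reconcile
#' @param n_perm Number of permutations (>= 99).
#' @param seed Optional integer seed for the permutation stream.
#' @return List with `observed`, `null` (integer vector of permuted
#'   statistics), `p_value`, `p_mid`, `p_randomized`, and `null_ci` (the
#'   2.5% and 97.5% quantiles of the null counts).
#' @export
permutation_congruence_test <- function(host, parasite, assoc,
                                        n_perm = 999, seed = NULL) {
  if (ape::Ntip(parasite) < 3) {
    stop("congruence test undefined for fewer than 3 parasite tips",
         call. = FALSE)
  }
  if (n_perm < 99) stop("use at least 99 permutations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  observed <- lca_reconcile(host, parasite, assoc)$cospeciations
  tips <- parasite$tip.label
  hosts <- unname(assoc[tips])
  null <- integer(n_perm)
  for (i in seq_len(n_perm)) {
    perm <- stats::setNames(sample(hosts), tips)
    null[i] <- lca_reconcile(host, parasite, perm)$cospeciations
  }
  n_ge <- sum(null >= observed)
  n_gt <- sum(null > observed)
  u <- stats::runif(1)
  list(
    observed = observed,
    null = null,
    p_value = (1 + n_ge) / (n_perm + 1),
    p_mid = (n_gt + 0.5 * (1 + n_ge - n_gt)) / (n_perm + 1),
    p_randomized = (n_gt + u * (1 + n_ge - n_gt)) / (n_perm + 1),
    null_ci = stats::quantile(null, c(0.025, 0.975), names = FALSE)
  )
}
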