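# Cladogenetic scenario enumeration, Lagrange-style.
#
# For an ancestral range S:
#   |S| = 1  sympatric-copy:     both daughters inherit S.
#   |S| >= 2 vicariance:         one daughter a singleton {i} of S, the
#                                other S \ {i} (when that set is a state);
#            peripheral-isolate: one daughter a singleton {i} of S, the
#                                other retains S.
# Left/right daughter assignments count as distinct scenarios; all
# scenarios of a given ancestral range share equal weight 1/n(S).
scenario_table <- function(space) {
  lookup <- stats::setNames(seq_len(space$n_states),
                            vapply(space$states, set_key, character(1)))
  anc <- left <- right <- integer(0)
  type <- character(0)
  for (si in seq_len(space$n_states)) {
    S <- space$states[[si]]
    if (!length(S)) next
    if (length(S) == 1) {
      anc <- c(anc, si); left <- c(left, si); right <- c(right, si)
      type <- c(type, "sympatric-copy")
      next
    }
    seen <- character(0)
    for (i in S) {
      ii <- lookup[set_key(i)]
      rest <- lookup[set_key(setdiff(S, i))]
      if (!is.na(rest)) {
        for (pair in list(c(ii, rest), c(rest, ii))) {
          key <- paste(pair, collapse = "|")
          if (!key %in% seen) {
            seen <- c(seen, key)
            anc <- c(anc, si); left <- c(left, pair[1]); right <- c(right, pair[2])
            type <- c(type, "vicariance")
          }
        }
      }
      for (pair in list(c(ii, si), c(si, ii))) {
        anc <- c(anc, si); left <- c(left, pair[1]); right <- c(right, pair[2])
        type <- c(type, "peripheral-isolate")
      }
    }
  }
  tab <- data.frame(anc = anc, left = left, right = right, type = type,
                    stringsAsFactors = FALSE)
  n_per_anc <- table(tab$anc)
  tab$weight <- 1 / as.numeric(n_per_anc[as.character(tab$anc)])
  tab
}

# Resolve user-facing tip ranges (named list/vector of area labels) to
# state indices; errors name the offending tip.
resolve_tip_states <- function(tree, tip_ranges, space) {
  tips <- tree$tip.label
  states <- integer(length(tips))
  for (i in seq_along(tips)) {
    r <- if (is.list(tip_ranges)) tip_ranges[[tips[i]]]
         else unname(tip_ranges[tips[i]])
    if (is.null(r) || (length(r) == 1 && is.na(r))) {
      stop("no observed range for tip '", tips[i], "'", call. = FALSE)
    }
    if (length(r) == 1 && grepl("[,+]", r)) {
      r <- strsplit(r, "[,+]")[[1]]
    }
    r <- trimws(r)
    if (!length(r)) {
      stop("tip '", tips[i], "' has an empty range", call. = FALSE)
    }
    states[i] <- tryCatch(range_to_state(space, r), error = function(err) {
      stop("tip '", tips[i], "': ", conditionMessage(err), call. = FALSE)
    })
  }
  states
}

# Precompute everything that does not depend on (d, e): traversal order,
# epoch segmentation per branch, scenario table, tip states.
prepare_likelihood <- function(tree, tip_ranges, space, epochs = NULL) {
  tree <- validate_dated_tree(tree)
  if (is.null(epochs)) {
    epochs <- epoch_config(0, n_areas = length(space$areas))
  }
  age <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  edge <- tree$edge
  segments <- vector("list", nrow(edge))
  for (i in seq_len(nrow(edge))) {
    segments[[i]] <- epoch_segments(epochs, age[edge[i, 1]], age[edge[i, 2]])
  }
  list(
    tree = tree, space = space, epochs = epochs,
    ntip = ntip, edge = edge, age = age,
    edge_of_child = stats::setNames(seq_len(nrow(edge)), edge[, 2]),
    kids = child_list(tree),
    postorder = postorder_nodes(tree),
    segments = segments,
    scen = scenario_table(space),
    tip_states = resolve_tip_states(tree, tip_ranges, space),
    nonempty = which(vapply(space$states, length, integer(1)) > 0)
  )
}

# per-epoch generator decompositions for given rates
epoch_decs <- function(ctx, d, e) {
  params <- dec_params(d, e, epochs = ctx$epochs)
  lapply(seq_len(ctx$epochs$n_epochs), function(k) {
    q_eigen(build_rate_matrix(ctx$space, params, k))
  })
}

# transition matrix along one branch: product of epoch-segment matrices,
# oldest segment first
branch_p <- function(ctx, decs, edge_i) {
  seg <- ctx$segments[[edge_i]]
  P <- NULL
  for (r in seq_len(nrow(seg))) {
    Pk <- p_matrix(decs[[seg$epoch[r]]], seg$dt[r])
    P <- if (is.null(P)) Pk else P %*% Pk
  }
  if (is.null(P)) P <- diag(ctx$space$n_states)
  P
}

# Felsenstein pruning over the DEC chain.  Returns log-likelihood and,
# when keep = TRUE, the per-node conditional likelihood vectors and
# per-branch (child-indexed) P matrices and D vectors for reuse by the
# ancestral-scenario pass.
prune_loglik <- function(ctx, d, e, keep = FALSE) {
  ns <- ctx$space$n_states
  n_node <- ctx$ntip + ctx$tree$Nnode
  decs <- epoch_decs(ctx, d, e)
  L <- matrix(0, n_node, ns)
  for (i in seq_len(ctx$ntip)) L[i, ctx$tip_states[i]] <- 1
  Pmats <- if (keep) vector("list", n_node) else NULL
  Dvecs <- if (keep) vector("list", n_node) else NULL
  scen <- ctx$scen
  log_scale <- 0
  get_D <- function(child) {
    P <- branch_p(ctx, decs, ctx$edge_of_child[[as.character(child)]])
    D <- as.numeric(P %*% L[child, ])
    if (keep) {
      Pmats[[child]] <<- P
      Dvecs[[child]] <<- D
    }
    D
  }
  for (v in ctx$postorder) {
    ch <- ctx$kids[[v]]
    D1 <- get_D(ch[1])
    D2 <- get_D(ch[2])
    contrib <- scen$weight * D1[scen$left] * D2[scen$right]
    Lv <- numeric(ns)
    agg <- rowsum(contrib, scen$anc)
    Lv[as.integer(rownames(agg))] <- agg
    m <- max(Lv)
    if (m <= 0) {
      return(list(loglik = -Inf, L = L, Pmats = Pmats, Dvecs = Dvecs,
                  decs = decs))
    }
    L[v, ] <- Lv / m
    log_scale <- log_scale + log(m)
  }
  root <- root_node(ctx$tree)
  root_avg <- sum(L[root, ctx$nonempty]) / length(ctx$nonempty)
  loglik <- log(root_avg) + log_scale
  list(loglik = loglik, L = L, Pmats = Pmats, Dvecs = Dvecs, decs = decs)
}

#' DEC log-likelihood of tip ranges on a dated tree
#'
#' Computes the likelihood of observed tip ranges under the DEC model by
#' postorder pruning: along each branch the anagenetic CTMC transition
#' matrix `exp(Q t)` is applied per epoch segment (branches crossing
#' epoch boundaries are split and the segment matrices chained in time
#' order); at each internal node the allowed cladogenetic scenarios of
#' every ancestral range are summed with equal weights; at the root the
#' likelihood is averaged over all non-empty ranges with equal weights.
#'
#' @param tree Dated ultrametric `phylo` (see [read_newick()]).
#' @param tip_ranges Named list or character vector mapping every tip
#'   label to its observed range: a character vector of area labels, or a
#'   single string with areas separated by `,` or `+`.
#' @param space A [build_state_space()] object.
#' @param params A [dec_params()] object (rates and epoch configuration).
#' @return The log-likelihood (a single number, `<= 0`).
#' @examples
#' tr <- read_newick("(t1:1,t2:1);")
#' sp <- build_state_space("A", 1)
#' tree_likelihood(tr, c(t1 = "A", t2 = "A"), sp,
#'                 dec_params(0, 0.1, n_areas = 1))  # log exp(-0.2)
#' @export
tree_likelihood <- function(tree, tip_ranges, space, params) {
  ctx <- prepare_likelihood(tree, tip_ranges, space, params$epochs)
  prune_loglik(ctx, params$d, params$e)$loglik
}
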