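# Independent brute-force DEC likelihood oracle.
#
# Everything here is computed from first principles, separately from the
# package's pruning implementation: the generator is rebuilt entry by
# entry from the rate definitions, matrix exponentials come from
# Matrix::expm, cladogenetic scenarios are re-enumerated, and the
# likelihood is an explicit sum over every joint assignment of a
# scenario to every internal node.  Feasible for <= 4 tips / <= 3 areas.

oracle_rate_matrix <- function(space, d, e, mult = NULL) {
  n_areas <- length(space$areas)
  if (is.null(mult)) mult <- matrix(1, n_areas, n_areas)
  ns <- space$n_states
  Q <- matrix(0, ns, ns)
  for (a in seq_len(ns)) {
    Sa <- space$states[[a]]
    if (!length(Sa)) next
    for (b in seq_len(ns)) {
      if (a == b) next
      Sb <- space$states[[b]]
      if (length(Sb) == length(Sa) + 1 && all(Sa %in% Sb)) {
        j <- setdiff(Sb, Sa)
        Q[a, b] <- sum(d * mult[Sa, j] * space$adjacency[Sa, j])
      } else if (length(Sb) == length(Sa) - 1 && all(Sb %in% Sa)) {
        Q[a, b] <- e
      }
    }
    Q[a, a] <- -sum(Q[a, -a])
  }
  Q
}

oracle_scenarios <- function(space) {
  find_state <- function(s) {
    s <- sort(s)
    for (i in seq_along(space$states)) {
      if (identical(space$states[[i]], as.integer(s))) return(i)
    }
    NA_integer_
  }
  out <- list()
  for (si in seq_along(space$states)) {
    S <- space$states[[si]]
    if (!length(S)) next
    if (length(S) == 1) {
      out[[length(out) + 1]] <- c(anc = si, left = si, right = si)
      next
    }
    pairs <- list()
    for (i in S) {
      ii <- find_state(i)
      rest <- find_state(setdiff(S, i))
      if (!is.na(rest)) {
        pairs <- c(pairs, list(c(ii, rest)), list(c(rest, ii)))
      }
      pairs <- c(pairs, list(c(ii, si)), list(c(si, ii)))
    }
    pairs <- unique(pairs)
    for (p in pairs) {
      out[[length(out) + 1]] <- c(anc = si, left = p[1], right = p[2])
    }
  }
  tab <- do.call(rbind, out)
  w <- 1 / table(tab[, "anc"])
  cbind(tab, weight = as.numeric(w[as.character(tab[, "anc"])]))
}

# explicit enumeration over all joint scenario assignments
oracle_loglik <- function(tree, tip_states, space, d, e, epochs = NULL) {
  age <- decophy::node_ages(tree)
  ntip <- ape::Ntip(tree)
  if (is.null(epochs)) {
    epochs <- decophy::epoch_config(0, n_areas = length(space$areas))
  }
  Qk <- lapply(epochs$multipliers, function(m) {
    oracle_rate_matrix(space, d, e, m)
  })
  edge_P <- vector("list", nrow(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    a_hi <- age[tree$edge[i, 1]]
    a_lo <- age[tree$edge[i, 2]]
    cuts <- epochs$boundaries[epochs$boundaries < a_hi &
                                epochs$boundaries > a_lo]
    pts <- c(a_hi, cuts, a_lo)
    P <- diag(space$n_states)
    for (r in seq_len(length(pts) - 1)) {
      k <- which(epochs$boundaries < pts[r])[1]
      if (is.na(k)) k <- epochs$n_epochs
      P <- P %*% as.matrix(Matrix::expm(Qk[[k]] * (pts[r] - pts[r + 1])))
    }
    edge_P[[i]] <- P
  }
  parent_edge <- integer(ntip + tree$Nnode)
  parent_edge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  kids <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  }
  internal <- (ntip + 1):(ntip + tree$Nnode)
  scen <- oracle_scenarios(space)
  root <- ntip + 1L
  nonempty <- sum(vapply(space$states, length, integer(1)) > 0)

  combos <- expand.grid(rep(list(seq_len(nrow(scen))), length(internal)))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    choice <- as.integer(combos[r, ])
    names(choice) <- internal
    term <- scen[choice[as.character(root)], "weight"] / nonempty
    for (v in internal) {
      s_v <- scen[choice[as.character(v)], ]
      if (v != root) {
        term <- term * scen[choice[as.character(v)], "weight"]
      }
      for (j in 1:2) {
        child <- kids[[v]][j]
        from <- s_v[[if (j == 1) "left" else "right"]]
        to <- if (child <= ntip) tip_states[child]
              else scen[choice[as.character(child)], "anc"]
        term <- term * edge_P[[parent_edge[child]]][from, to]
      }
      if (term == 0) break
    }
    total <- total + term
  }
  log(as.numeric(total))
}

# random small instances for the oracle sweep
random_instance <- function(seed) {
  set.seed(seed)
  n_tip <- sample(2:4, 1)
  n_area <- sample(2:3, 1)
  tree <- decophy::simulate_host_tree(1, n_tip)
  space <- decophy::build_state_space(LETTERS[seq_len(n_area)],
                                      max_range_size = min(2, n_area))
  nonempty <- which(vapply(space$states, length, integer(1)) > 0)
  tip_states <- sample(nonempty, n_tip, replace = TRUE)
  tip_ranges <- stats::setNames(
    lapply(tip_states, function(s) space$areas[space$states[[s]]]),
    tree$tip.label)
  d <- stats::runif(1, 0.01, 0.5)
  e <- stats::runif(1, 0.01, 0.5)
  list(tree = tree, space = space, tip_states = tip_states,
       tip_ranges = tip_ranges, d = d, e = e)
}
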