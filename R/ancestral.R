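#' Ancestral cladogenetic scenarios with relative probabilities
#'
#' For each internal node and each allowed cladogenetic scenario
#' (ancestral range and ordered daughter ranges), computes the fraction
#' of the total likelihood obtained when the node's split is fixed to
#' that scenario.  Per node the relative probabilities sum to one.
#' Implemented by a single inside (pruning) pass plus an outside pass, so
#' no per-scenario re-evaluation of the tree is needed.
#'
#' @inheritParams tree_likelihood
#' @return A data frame of class `node_scenarios`, one row per (node,
#'   scenario): columns `node`, `child_left`, `child_right`, `anc`,
#'   `left`, `right` (range labels), `type` (`sympatric-copy`,
#'   `vicariance`, `peripheral-isolate`), `rel_prob`.  Rows are sorted by
#'   node, then by decreasing `rel_prob` (ties broken by state-space
#'   order).  The overall log-likelihood is attached as attribute
#'   `loglik`, the state space as `space`.
#' @export
ancestral_scenarios <- function(tree, tip_ranges, space, params) {
  ctx <- prepare_likelihood(tree, tip_ranges, space, params$epochs)
  down <- prune_loglik(ctx, params$d, params$e, keep = TRUE)
  if (!is.finite(down$loglik)) {
    stop("data have zero likelihood under the supplied parameters",
         call. = FALSE)
  }
  ns <- ctx$space$n_states
  n_node <- ctx$ntip + ctx$tree$Nnode
  root <- root_node(ctx$tree)
  scen <- ctx$scen

  # outside pass: up[v, S] is proportional to the likelihood of all data
  # outside the clade of v given range S at v just before its split.
  # Relative probabilities only need per-node normalisation, so each up
  # vector is rescaled freely for numerical stability.
  up <- matrix(0, n_node, ns)
  up[root, ctx$nonempty] <- 1
  preorder <- rev(ctx$postorder)
  for (v in preorder) {
    ch <- ctx$kids[[v]]
    for (j in 1:2) {
      child <- ch[j]
      if (child <= ctx$ntip) next
      sib <- ch[3 - j]
      Dsib <- down$Dvecs[[sib]]
      side <- if (j == 1) scen$left else scen$right
      other <- if (j == 1) scen$right else scen$left
      contrib <- up[v, scen$anc] * scen$weight * Dsib[other]
      top <- numeric(ns)
      agg <- rowsum(contrib, side)
      top[as.integer(rownames(agg))] <- agg
      u <- as.numeric(top %*% down$Pmats[[child]])
      m <- max(u)
      up[child, ] <- if (m > 0) u / m else u
    }
  }

  out <- NULL
  for (v in ctx$postorder) {
    ch <- ctx$kids[[v]]
    D1 <- down$Dvecs[[ch[1]]]
    D2 <- down$Dvecs[[ch[2]]]
    contrib <- up[v, scen$anc] * scen$weight * D1[scen$left] * D2[scen$right]
    total <- sum(contrib)
    rel <- if (total > 0) contrib / total else rep(0, length(contrib))
    block <- data.frame(
      node = v, child_left = ch[1], child_right = ch[2],
      anc = ctx$space$labels[scen$anc],
      left = ctx$space$labels[scen$left],
      right = ctx$space$labels[scen$right],
      type = scen$type, rel_prob = rel,
      scen_index = seq_along(rel),
      stringsAsFactors = FALSE
    )
    block <- block[order(-block$rel_prob, block$scen_index), ]
    out <- rbind(out, block)
  }
  out <- out[order(out$node, -out$rel_prob, out$scen_index), ]
  out$scen_index <- NULL
  rownames(out) <- NULL
  attr(out, "loglik") <- down$loglik
  attr(out, "space") <- space
  class(out) <- c("node_scenarios", "data.frame")
  out
}

#' Combine ancestral reconstructions across model runs
#'
#' Applies a consensus rule over several DEC runs on the same tree (e.g.
#' different maximum range sizes or dispersal constraints).  Within each
#' run, the support for an area at a node is the summed relative
#' probability of all scenarios whose ancestral range contains that area.
#' An area is *accepted* at a node when the mean support across runs
#' exceeds `threshold` AND the area is the top-ranked area in every run;
#' a *moderate* tier applies the same agreement rule at
#' `moderate_threshold`.  Nodes with no accepted or moderate area are
#' labelled equivocal.
#'
#' @param scenario_sets List (length >= 2) of [ancestral_scenarios()]
#'   results computed on the same tree.
#' @param threshold Acceptance threshold on mean support (default 0.7).
#' @param moderate_threshold Moderate-support threshold (default 0.5).
#' @return List with `areas`: data frame (node, area, mean_support,
#'   top_in_all, tier in accepted/moderate/none) and `nodes`: one row per
#'   node with its best area and node-level call (accepted / moderate /
#'   equivocal).
#' @export
combine_runs <- function(scenario_sets, threshold = 0.7,
                         moderate_threshold = 0.5) {
  if (length(scenario_sets) < 2) {
    stop("need at least two runs to combine", call. = FALSE)
  }
  key <- function(s) {
    u <- unique(s[, c("node", "child_left", "child_right")])
    u <- u[order(u$node), ]
    paste(u$node, u$child_left, u$child_right, collapse = ";")
  }
  keys <- vapply(scenario_sets, key, character(1))
  if (length(unique(keys)) != 1) {
    stop("runs were computed on different trees", call. = FALSE)
  }
  if (threshold <= 0 || threshold > 1 || moderate_threshold <= 0 ||
      moderate_threshold > 1) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }

  # per-run per-node area support
  support_one <- function(s) {
    rows <- NULL
    for (v in unique(s$node)) {
      block <- s[s$node == v, ]
      areas_per_row <- strsplit(block$anc, "+", fixed = TRUE)
      all_areas <- unique(unlist(areas_per_row))
      all_areas <- all_areas[all_areas != "0"]
      supp <- vapply(all_areas, function(a) {
        sum(block$rel_prob[vapply(areas_per_row, function(x) a %in% x,
                                  logical(1))])
      }, numeric(1))
      rows <- rbind(rows, data.frame(node = v, area = all_areas,
                                     support = supp,
                                     stringsAsFactors = FALSE))
    }
    rows
  }
  supports <- lapply(scenario_sets, support_one)
  space <- attr(scenario_sets[[1]], "space")
  area_order <- if (!is.null(space)) space$areas else {
    sort(unique(unlist(lapply(supports, function(s) s$area))))
  }

  nodes <- sort(unique(supports[[1]]$node))
  area_rows <- NULL
  node_rows <- NULL
  for (v in nodes) {
    per_run <- lapply(supports, function(s) s[s$node == v, ])
    areas <- sort(unique(unlist(lapply(per_run, function(s) s$area))))
    areas <- areas[order(match(areas, area_order))]
    mean_supp <- vapply(areas, function(a) {
      mean(vapply(per_run, function(s) {
        x <- s$support[s$area == a]
        if (length(x)) x else 0
      }, numeric(1)))
    }, numeric(1))
    top_per_run <- vapply(per_run, function(s) {
      s <- s[order(-s$support, match(s$area, area_order)), ]
      s$area[1]
    }, character(1))
    top_in_all <- vapply(areas, function(a) all(top_per_run == a),
                         logical(1))
    tier <- ifelse(mean_supp > threshold & top_in_all, "accepted",
                   ifelse(mean_supp > moderate_threshold & top_in_all,
                          "moderate", "none"))
    area_rows <- rbind(area_rows, data.frame(
      node = v, area = areas, mean_support = mean_supp,
      top_in_all = top_in_all, tier = tier, stringsAsFactors = FALSE,
      row.names = NULL))
    call_v <- if (any(tier == "accepted")) "accepted"
              else if (any(tier == "moderate")) "moderate"
              else "equivocal"
    best <- if (call_v == "equivocal") NA_character_
            else areas[tier != "none"][1]
    node_rows <- rbind(node_rows, data.frame(
      node = v, call = call_v, area = best,
      mean_support = if (is.na(best)) NA_real_
                     else mean_supp[areas == best],
      stringsAsFactors = FALSE, row.names = NULL))
  }
  list(areas = area_rows, nodes = node_rows)
}
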