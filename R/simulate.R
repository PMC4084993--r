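#' Simulate a dated Yule (pure-birth) host tree
#'
#' Grows a Yule tree forward in time: starting from the root split, each
#' of the `k` extant lineages speciates at rate `lambda`, until `n_tips`
#' lineages exist; the tree is then cut one further exponential waiting
#' time `Exp(n_tips * lambda)` later, so the expected root age is
#' `sum_{k=2..n_tips} 1/(k*lambda)`.
#'
#' @param lambda Speciation rate per lineage per Ma (> 0).
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @return A dated ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_host_tree <- function(lambda, n_tips, seed = NULL) {
  if (n_tips < 2) stop("need at least 2 tips", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  # forward time from the root split at 0
  birth <- c(0, 0)            # birth time per lineage
  parent <- c(0L, 0L)
  children <- list()
  active <- c(1L, 2L)
  t <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + stats::rexp(1, k * lambda)
    who <- active[sample.int(k, 1)]
    id1 <- length(birth) + 1L
    id2 <- id1 + 1L
    birth <- c(birth, t, t)
    parent <- c(parent, who, who)
    children[[who]] <- c(id1, id2)
    active <- c(setdiff(active, who), id1, id2)
  }
  t_end <- t + stats::rexp(1, n_tips * lambda)
  tip_no <- 0L
  build <- function(id) {
    if (id <= length(children) && !is.null(children[[id]])) {
      ch <- children[[id]]
      s1 <- build(ch[1])
      s2 <- build(ch[2])
      len <- birth[ch[1]] - birth[id]
      sprintf("(%s,%s):%.12g", s1, s2, len)
    } else {
      tip_no <<- tip_no + 1L
      sprintf("t%d:%.12g", tip_no, t_end - birth[id])
    }
  }
  left <- build(1L)
  right <- build(2L)
  nwk <- sprintf("(%s,%s);", left, right)
  read_newick(nwk)
}

host_label <- function(tree, v) {
  if (v <= ape::Ntip(tree)) tree$tip.label[v] else paste0("n", v)
}

#' Simulate host-parasite codiversification on a host tree
#'
#' A single parasite lineage starts on the host root lineage.  At each
#' host speciation, every parasite on the splitting host cospeciates
#' with probability `p_c` (one daughter on each host daughter) and
#' otherwise follows one uniformly chosen host daughter.  Along host
#' branches each parasite lineage experiences host-switches (rate
#' `lambda_s`; the lineage leaves its host and colonises a uniformly
#' chosen other co-extant host lineage, the analogue of dispersal),
#' duplications (rate `lambda_d`; the lineage splits on its current
#' host) and losses (rate `mu`) as independent Poisson processes.  All
#' events are logged with type and age; lineages surviving to the
#' present define the parasite tree.
#'
#' @param host Dated ultrametric `phylo`.
#' @param p_c Cospeciation probability at host speciations, in `[0, 1]`.
#' @param lambda_s,lambda_d,mu Switch, duplication and loss rates per
#'   parasite lineage per Ma (>= 0).
#' @param seed Optional integer seed.
#' @return List of class `codiv_sim`: `host`, `parasite` (dated `phylo`,
#'   or `NULL` if fewer than 2 survivors), `association` (named vector
#'   parasite tip -> host tip), `events` (true [event_history()];
#'   `node` is the internal parasite-lineage id), `event_detail` (the
#'   same log with host/donor/recipient labels), `empty` (`TRUE` if all
#'   parasite lineages were lost), `n_parasites`, and the simulation
#'   parameters.
#' @export
simulate_cophylo <- function(host, p_c, lambda_s = 0, lambda_d = 0,
                             mu = 0, seed = NULL) {
  stopifnot(p_c >= 0, p_c <= 1, lambda_s >= 0, lambda_d >= 0, mu >= 0)
  if (!is.null(seed)) set.seed(seed)
  host <- validate_dated_tree(host)
  age <- node_ages(host)
  ntip <- ape::Ntip(host)
  root <- root_node(host)
  kids <- child_list(host)
  hparent <- host_parents(host)
  edge_start <- function(v) if (v == root) Inf else age[hparent[v]]

  # parasite lineage segments (grown incrementally)
  seg_host <- integer(0); seg_birth <- numeric(0); seg_end <- numeric(0)
  seg_fate <- character(0); seg_child <- list(); seg_event <- integer(0)
  new_seg <- function(hostv, birth) {
    seg_host[length(seg_host) + 1L] <<- hostv
    seg_birth[length(seg_birth) + 1L] <<- birth
    seg_end[length(seg_end) + 1L] <<- NA_real_
    seg_fate[length(seg_fate) + 1L] <<- "active"
    seg_child[[length(seg_host)]] <<- integer(0)
    seg_event[length(seg_event) + 1L] <<- NA_integer_
    length(seg_host)
  }
  ev <- list()
  log_event <- function(type, seg, c1 = NA, c2 = NA, gained = NA,
                        lost = NA, age_ev = NA, h_left = NA, h_right = NA) {
    ev[[length(ev) + 1L]] <<- data.frame(
      type = type, node = seg, child_left = as.integer(c1),
      child_right = as.integer(c2), gained = as.character(gained),
      lost = as.character(lost), age = age_ev,
      host_left = as.character(h_left), host_right = as.character(h_right),
      stringsAsFactors = FALSE)
    length(ev)
  }

  rate_total <- lambda_s + lambda_d + mu
  extant_hosts <- function(t) {
    which(vapply(seq_len(ntip + host$Nnode), function(v) {
      v != root && edge_start(v) > t && age[v] <= t
    }, logical(1)))
  }
  evolve <- function(active, t_hi, t_lo) {
    if (rate_total == 0) return(active)
    stack <- lapply(active, function(s) list(seg = s, t = t_hi))
    out <- integer(0)
    while (length(stack)) {
      it <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      s <- it$seg; t <- it$t
      repeat {
        t <- t - stats::rexp(1, rate_total)
        if (t <= t_lo) { out <- c(out, s); break }
        u <- stats::runif(1) * rate_total
        if (u < mu) {
          seg_fate[s] <<- "loss"; seg_end[s] <<- t
          log_event("lineage-loss", s, lost = host_label(host, seg_host[s]),
                    age_ev = t)
          break
        } else if (u < mu + lambda_d) {
          a <- new_seg(seg_host[s], t)
          b <- new_seg(seg_host[s], t)
          seg_fate[s] <<- "split"; seg_end[s] <<- t
          seg_child[[s]] <<- c(a, b)
          seg_event[s] <<- log_event("duplication", s, a, b, age_ev = t,
                                     h_left = host_label(host, seg_host[s]),
                                     h_right = host_label(host, seg_host[s]))
          stack[[length(stack) + 1L]] <- list(seg = a, t = t)
          stack[[length(stack) + 1L]] <- list(seg = b, t = t)
          break
        } else {
          cand <- setdiff(extant_hosts(t), seg_host[s])
          if (!length(cand)) next  # no other host to switch to
          recip <- cand[sample.int(length(cand), 1)]
          log_event("host-switch", s,
                    gained = host_label(host, recip),
                    lost = host_label(host, seg_host[s]),
                    age_ev = t)
          seg_host[s] <<- recip  # the lineage colonises the recipient
        }
      }
    }
    out
  }

  active <- new_seg(root, age[root])
  internal <- (ntip + 1L):(ntip + host$Nnode)
  sched <- internal[order(-age[internal])]
  t_prev <- age[root]
  for (v in sched) {
    active <- evolve(active, t_prev, age[v])
    c1 <- kids[[v]][1]; c2 <- kids[[v]][2]
    for (s in active[seg_host[active] == v]) {
      if (stats::runif(1) <= p_c) {
        a <- new_seg(c1, age[v])
        b <- new_seg(c2, age[v])
        seg_fate[s] <- "split"; seg_end[s] <- age[v]
        seg_child[[s]] <- c(a, b)
        seg_event[s] <- log_event("cospeciation", s, a, b, age_ev = age[v],
                                  h_left = host_label(host, c1),
                                  h_right = host_label(host, c2))
        active <- c(setdiff(active, s), a, b)
      } else {
        seg_host[s] <- if (stats::runif(1) < 0.5) c1 else c2
      }
    }
    t_prev <- age[v]
  }
  active <- evolve(active, t_prev, 0)
  for (s in active) {
    seg_fate[s] <- "tip"; seg_end[s] <- 0
  }

  resolve <- function(s) {
    if (seg_fate[s] == "loss") return(NULL)
    if (seg_fate[s] == "tip") {
      return(list(str = paste0("p", s), age = 0))
    }
    ch <- seg_child[[s]]
    r1 <- resolve(ch[1]); r2 <- resolve(ch[2])
    if (is.null(r1) && is.null(r2)) return(NULL)
    if (is.null(r1)) return(r2)
    if (is.null(r2)) return(r1)
    a <- seg_end[s]
    list(str = sprintf("(%s:%.12g,%s:%.12g)e%d",
                       r1$str, a - r1$age, r2$str, a - r2$age, seg_event[s]),
         age = a)
  }
  survivors <- which(seg_fate == "tip")
  parasite <- NULL
  assoc <- stats::setNames(character(0), character(0))
  if (length(survivors) >= 1) {
    assoc <- stats::setNames(host$tip.label[seg_host[survivors]],
                             paste0("p", survivors))
  }
  if (length(survivors) >= 2) {
    r <- resolve(1L)
    parasite <- read_newick(paste0(r$str, ";"))
  }
  detail <- if (length(ev)) do.call(rbind, ev) else
    data.frame(type = character(), node = integer(),
               child_left = integer(), child_right = integer(),
               gained = character(), lost = character(), age = numeric(),
               host_left = character(), host_right = character(),
               stringsAsFactors = FALSE)
  events <- validate_event_history(
    detail[, c("type", "node", "child_left", "child_right",
               "gained", "lost", "age")])
  structure(
    list(host = host, parasite = parasite, association = assoc,
         events = events, event_detail = detail,
         empty = length(survivors) == 0, n_parasites = length(survivors),
         params = list(p_c = p_c, lambda_s = lambda_s,
                       lambda_d = lambda_d, mu = mu, seed = seed)),
    class = "codiv_sim")
}

#' Read the true per-node scenarios off a codiversification history
#'
#' Translates the logged divergence events of a [simulate_cophylo()]
#' result into the DEC-analogy scenario table for the surviving parasite
#' tree: cospeciations read as vicariance of the two daughter hosts and
#' duplications as sympatric-copy on the shared host (host-switches are
#' anagenetic branch events, not divergences).  Daughter order follows
#' the order in which subtrees were written, matching the parasite
#' tree's child order.
#'
#' @param sim A `codiv_sim` with at least two surviving parasites.
#' @return Data frame with columns `node`, `child_left`, `child_right`,
#'   `anc`, `left`, `right`, `type`, suitable for
#'   [classify_node_events()].
#' @export
history_to_scenarios <- function(sim) {
  if (is.null(sim$parasite)) {
    stop("simulation has no surviving parasite tree", call. = FALSE)
  }
  tree <- sim$parasite
  labs <- tree$node.label
  ntip <- ape::Ntip(tree)
  kids <- child_list(tree)
  out <- NULL
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    lab <- labs[v - ntip]
    row <- sim$event_detail[as.integer(sub("^e", "", lab)), ]
    hl <- row$host_left; hr <- row$host_right
    if (row$type == "duplication") {
      anc <- hl; left <- hl; right <- hr; type <- "sympatric-copy"
    } else {  # cospeciation or host-switch: repertoire partitioned
      anc <- paste(sort(c(hl, hr)), collapse = "+")
      left <- hl; right <- hr; type <- "vicariance"
    }
    out <- rbind(out, data.frame(
      node = v, child_left = kids[[v]][1], child_right = kids[[v]][2],
      anc = anc, left = left, right = right, type = type,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Simulate a DEC range history forward along a tree
#'
#' Runs the anagenetic CTMC (Gillespie algorithm, epoch-aware rates)
#' along every branch and draws a cladogenetic scenario uniformly among
#' the allowed scenarios at every internal node.  Lineages whose range
#' hits the empty set are extinct; their tips are flagged and reported
#' with an empty range.
#'
#' @inheritParams tree_likelihood
#' @param root_range Character vector of area labels: the range at the
#'   root (non-empty, must be a state of the space).
#' @param seed Optional integer seed.
#' @return List with `tip_ranges` (named list, character vectors of area
#'   labels; `character(0)` for extinct tips), `extinct` (named logical),
#'   `scenarios` (true scenario per internal node, as in
#'   [ancestral_scenarios()] minus probabilities), and `events` (true
#'   [event_history()] of dispersal/extinction along branches and
#'   cladogenetic node events).
#' @export
simulate_dec_history <- function(tree, space, params, root_range,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- validate_dated_tree(tree)
  root_state <- range_to_state(space, root_range)
  if (root_state == 1) stop("root range must be non-empty", call. = FALSE)
  age <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  kids <- child_list(tree)
  scen <- scenario_table(space)
  Qs <- lapply(seq_len(params$epochs$n_epochs), function(k) {
    build_rate_matrix(space, params, k)
  })
  b <- params$epochs$boundaries
  ev <- list()
  log_event <- function(type, node, c1 = NA, c2 = NA, gained = NA,
                        lost = NA, age_ev = NA) {
    ev[[length(ev) + 1L]] <<- data.frame(
      type = type, node = node, child_left = as.integer(c1),
      child_right = as.integer(c2), gained = as.character(gained),
      lost = as.character(lost), age = age_ev, stringsAsFactors = FALSE)
  }

  # anagenetic evolution from age t_hi down to t_lo, starting in state s
  evolve_branch <- function(s, t_hi, t_lo, node) {
    t <- t_hi
    repeat {
      if (s == 1L || t <= t_lo) return(s)
      k <- epoch_of_age(params$epochs, t)
      # stay in epoch k while age >= b[k]
      edge_of_epoch <- max(b[k], t_lo)
      rate <- -Qs[[k]][s, s]
      if (rate <= 0) {
        t <- edge_of_epoch
        if (t <= t_lo) return(s)
        t <- t - 1e-12  # step across the boundary
        next
      }
      t_new <- t - stats::rexp(1, rate)
      if (t_new < edge_of_epoch) {
        t <- if (edge_of_epoch == t_lo) t_lo else edge_of_epoch - 1e-12
        next
      }
      t <- t_new
      row <- Qs[[k]][s, ]
      row[s] <- 0
      s_new <- sample.int(length(row), 1, prob = row)
      old <- space$states[[s]]
      new <- space$states[[s_new]]
      if (length(new) > length(old)) {
        log_event("dispersal/host-switch", node,
                  gained = space$areas[setdiff(new, old)], age_ev = t)
      } else {
        log_event("extinction/loss", node,
                  lost = space$areas[setdiff(old, new)], age_ev = t)
      }
      s <- s_new
    }
  }

  n_node <- ntip + tree$Nnode
  state_at <- integer(n_node)  # state at the node itself (before split)
  tip_state <- integer(ntip)
  scen_rows <- NULL
  recurse <- function(v, s_top) {
    # s_top: state at the top of the branch leading to v (at v for root)
    if (v <= ntip) {
      tip_state[v] <<- s_top
      return(invisible())
    }
    state_at[v] <<- s_top
    if (s_top == 1L) {
      # extinct: empty range propagates to all descendants
      for (ch in kids[[v]]) recurse(ch, 1L)
      return(invisible())
    }
    rows <- which(scen$anc == s_top)
    pick <- scen[rows[sample.int(length(rows), 1)], ]
    scen_rows <<- rbind(scen_rows, data.frame(
      node = v, child_left = kids[[v]][1], child_right = kids[[v]][2],
      anc = space$labels[pick$anc], left = space$labels[pick$left],
      right = space$labels[pick$right], type = pick$type,
      stringsAsFactors = FALSE))
    log_event(if (pick$type == "vicariance") "vicariance/cospeciation"
              else "duplication",
              v, kids[[v]][1], kids[[v]][2], age_ev = age[v])
    starts <- c(pick$left, pick$right)
    for (j in 1:2) {
      ch <- kids[[v]][j]
      s_end <- evolve_branch(starts[j], age[v], age[ch], ch)
      recurse(ch, s_end)
    }
    invisible()
  }
  root <- root_node(tree)
  recurse(root, root_state)

  tip_ranges <- stats::setNames(
    lapply(seq_len(ntip), function(i) space$areas[space$states[[tip_state[i]]]]),
    tree$tip.label)
  extinct <- vapply(tip_ranges, function(r) length(r) == 0, logical(1))
  events <- if (length(ev)) validate_event_history(do.call(rbind, ev))
            else event_history()
  list(tip_ranges = tip_ranges, extinct = extinct,
       scenarios = scen_rows, events = events)
}
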