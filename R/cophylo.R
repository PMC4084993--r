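#' Encode host repertoires as DEC ranges
#'
#' Applies the area-equals-host analogy: every parasite terminal (one
#' parasite lineage in one area, mirroring per-area tree tips) gets as
#' its DEC "range" the set of host species it parasitises there, capped
#' at `max_repertoire` hosts.  The host space plays the role of the area
#' set; host "adjacency" defaults to complete (any switch possible) and
#' can optionally be gated by shared-area co-occurrence.
#'
#' @param table A validated [read_association_table()] table.
#' @param max_repertoire Maximum hosts per ancestral repertoire
#'   (default 2).
#' @param cooccurrence_gate If `TRUE`, two hosts are "adjacent" only when
#'   they share at least one area in the table; otherwise the adjacency
#'   is complete.
#' @return List with `space` (a [build_state_space()] over host codes,
#'   carrying `host_species` and `tribes` attributes) and `tip_ranges`
#'   (named list: terminal label `"<lineage>@<area_code>"` -> character
#'   vector of host codes), directly consumable by [tree_likelihood()]
#'   and [fit_dec()].
#' @examples
#' enc <- encode_hosts_as_areas(margotrema_associations())
#' enc$tip_ranges[["Margotrema bravoae Lineage II@B"]]  # "i"
#' @export
encode_hosts_as_areas <- function(table, max_repertoire = 2,
                                  cooccurrence_gate = FALSE) {
  if (!nrow(table)) stop("association table is empty", call. = FALSE)
  hosts <- sort(unique(table$host_code))
  tribes <- stats::setNames(
    table$host_tribe[!duplicated(table$host_code)],
    table$host_code[!duplicated(table$host_code)])[hosts]
  n <- length(hosts)
  adjacency <- matrix(1, n, n, dimnames = list(hosts, hosts))
  if (cooccurrence_gate) {
    adjacency <- matrix(0, n, n, dimnames = list(hosts, hosts))
    diag(adjacency) <- 1
    for (area in unique(table$area_code)) {
      h <- unique(table$host_code[table$area_code == area])
      adjacency[h, h] <- 1
    }
  }
  space <- build_state_space(hosts, max_range_size = max_repertoire,
                             adjacency = adjacency)
  attr(space, "host_species") <- stats::setNames(
    table$host_species[!duplicated(table$host_code)],
    table$host_code[!duplicated(table$host_code)])[hosts]
  attr(space, "tribes") <- tribes

  key <- paste0(table$parasite_lineage, "@", table$area_code)
  tip_ranges <- lapply(split(table$host_code, key), unique)
  too_many <- vapply(tip_ranges, length, integer(1)) > max_repertoire
  if (any(too_many)) {
    stop("terminal(s) with more than ", max_repertoire,
         " hosts in one area: ", paste(names(tip_ranges)[too_many],
                                       collapse = ", "),
         "; split these terminals before encoding", call. = FALSE)
  }
  list(space = space, tip_ranges = tip_ranges)
}

#' Translate cladogenetic scenarios into cophylogenetic node events
#'
#' Under the area-equals-host analogy, a vicariance scenario is a
#' cospeciation (the ancestral repertoire is partitioned between daughter
#' parasites as the hosts diverge); a sympatric-copy on a single host is
#' a duplication (parasite speciation within one host); a
#' peripheral-isolate split is reported as a duplication plus a sharing
#' event (one daughter keeps the full repertoire).
#'
#' @param scenarios Data frame with one chosen scenario per internal
#'   node: columns `node`, `child_left`, `child_right`, `anc`, `left`,
#'   `right`, `type` — e.g. the top row per node of
#'   [ancestral_scenarios()], or the truth from [simulate_dec_history()].
#' @param ages Optional numeric vector of node ages (Ma) indexed by node.
#' @return An [event_history()] with one `cospeciation` or `duplication`
#'   row per node (plus `sharing` rows for peripheral-isolate splits).
#' @export
classify_node_events <- function(scenarios, ages = NULL) {
  known <- c("sympatric-copy", "vicariance", "peripheral-isolate")
  bad <- !scenarios$type %in% known
  if (any(bad)) {
    stop("unknown scenario type(s): ",
         paste(unique(scenarios$type[bad]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(scenarios$node)) {
    stop("expected one scenario per node; reduce to the accepted/top ",
         "scenario first", call. = FALSE)
  }
  rows <- NULL
  for (r in seq_len(nrow(scenarios))) {
    s <- scenarios[r, ]
    age <- if (is.null(ages)) NA_real_ else ages[s$node]
    type <- switch(s$type,
                   "vicariance" = "cospeciation",
                   "sympatric-copy" = "duplication",
                   "peripheral-isolate" = "duplication")
    rows <- rbind(rows, data.frame(
      type = type, node = s$node, child_left = s$child_left,
      child_right = s$child_right, gained = NA_character_,
      lost = NA_character_, age = age, stringsAsFactors = FALSE))
    if (s$type == "peripheral-isolate") {
      # the daughter retaining the full repertoire shares its hosts
      rows <- rbind(rows, data.frame(
        type = "sharing", node = s$node, child_left = s$child_left,
        child_right = s$child_right, gained = NA_character_,
        lost = NA_character_, age = age, stringsAsFactors = FALSE))
    }
  }
  validate_event_history(rows)
}

#' Translate branch range changes into host-switch and loss events
#'
#' Compares the repertoire at the top of each branch (the daughter range
#' assigned by the parent's scenario) with the repertoire at its bottom
#' (the child's ancestral range, or the observed tip range).  Every host
#' gained is one host-switch (recipient = gained host, donor = the first
#' retained host in host order, or the first lost host under complete
#' turnover within one branch); every host lost is one lineage-loss.
#' Events carry the branch age interval and are ordered by age (oldest
#' first).
#'
#' @param tree Dated `phylo`.
#' @param scenarios One chosen scenario per internal node (see
#'   [classify_node_events()]).
#' @param tip_ranges Named list/vector of tip repertoires (host codes).
#' @return An [event_history()]; for switches `gained` holds the
#'   recipient and `lost` the donor (`donor->recipient` reading), `age`
#'   is the upper end of the branch interval.
#' @export
classify_branch_events <- function(tree, scenarios, tip_ranges) {
  age <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  split_label <- function(lab) {
    if (lab == "0") character(0) else strsplit(lab, "+", fixed = TRUE)[[1]]
  }
  state_at_node <- function(v) {
    if (v <= ntip) {
      r <- tip_ranges[[tree$tip.label[v]]]
      if (length(r) == 1 && grepl("[,+]", r)) r <- strsplit(r, "[,+]")[[1]]
      trimws(r)
    } else {
      split_label(scenarios$anc[scenarios$node == v])
    }
  }
  rows <- NULL
  for (r in seq_len(nrow(scenarios))) {
    s <- scenarios[r, ]
    for (side in c("left", "right")) {
      child <- if (side == "left") s$child_left else s$child_right
      start <- split_label(s[[side]])
      end <- state_at_node(child)
      if (setequal(start, end)) next
      gained <- sort(setdiff(end, start))
      lost <- sort(setdiff(start, end))
      retained <- sort(intersect(start, end))
      if (!length(start)) {
        stop("inconsistent states on branch to node ", child,
             ": gain from an empty repertoire", call. = FALSE)
      }
      # donor: a retained host when one exists; under complete turnover
      # (e.g. {a} -> {a,b} -> {b} within one branch) the lost host is
      # the only possible source
      donor <- if (length(retained)) retained[1] else lost[1]
      for (g in gained) {
        rows <- rbind(rows, data.frame(
          type = "host-switch", node = child, child_left = NA_integer_,
          child_right = NA_integer_, gained = g, lost = donor,
          age = age[s$node], stringsAsFactors = FALSE))
      }
      for (l in lost) {
        rows <- rbind(rows, data.frame(
          type = "lineage-loss", node = child, child_left = NA_integer_,
          child_right = NA_integer_, gained = NA_character_, lost = l,
          age = age[s$node], stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(rows)) {
    return(event_history())
  }
  rows <- rows[order(-rows$age, rows$node), ]
  rownames(rows) <- NULL
  validate_event_history(rows)
}

#' Classify host-parasite associations into codivergence levels
#'
#' Assigns each parasite lineage one of three hierarchical levels of
#' historical association:
#' * **Species-Species** — the lineage is a full species restricted to a
#'   single host species (strict cospeciation);
#' * **Species-Lineage** — an intraspecific parasite lineage restricted
#'   to a single host species;
#' * **Tribe-Lineage** — the lineage parasitises several host species;
#'   its focal tribes are the goodeine tribes carrying either a
#'   plurality of its hosts or at least two of them, all other hosts
#'   (including any non-goodeid) being listed as exceptions.
#'
#' @param table A validated association table.
#' @param tribes Optional named vector host_code -> tribe overriding the
#'   table's `host_tribe` column.
#' @return Data frame with one row per parasite lineage: `parasite_lineage`,
#'   `level`, `hosts` (codes, comma-separated), `tribes` (focal),
#'   `exceptions` (out-of-focal-tribe host codes, or "").
#' @examples
#' assign_codivergence_levels(margotrema_associations())
#' @export
assign_codivergence_levels <- function(table, tribes = NULL) {
  if (is.null(tribes)) {
    tribes <- stats::setNames(
      table$host_tribe[!duplicated(table$host_code)],
      table$host_code[!duplicated(table$host_code)])
  }
  missing_tribe <- setdiff(unique(table$host_code), names(tribes))
  if (length(missing_tribe)) {
    stop("no tribe for host(s): ", paste(missing_tribe, collapse = ", "),
         call. = FALSE)
  }
  out <- NULL
  for (lin in unique(table$parasite_lineage)) {
    sub <- table[table$parasite_lineage == lin, ]
    hosts <- sort(unique(sub$host_code))
    rank <- unique(sub$parasite_rank)
    if (length(rank) != 1) {
      stop("inconsistent parasite_rank for ", lin, call. = FALSE)
    }
    host_tribes <- tribes[hosts]
    if (length(hosts) == 1) {
      level <- if (rank == "species") "Species-Species" else "Species-Lineage"
      focal <- unname(host_tribes)
      exceptions <- character(0)
    } else {
      level <- "Tribe-Lineage"
      goodeine <- host_tribes[host_tribes %in% goodeine_tribes]
      counts <- sort(base::table(goodeine), decreasing = TRUE)
      focal <- names(counts)[counts >= 2 | counts == max(counts)]
      exceptions <- hosts[!(host_tribes %in% focal)]
    }
    out <- rbind(out, data.frame(
      parasite_lineage = lin, level = level,
      hosts = paste(hosts, collapse = ","),
      tribes = paste(focal, collapse = ","),
      exceptions = paste(exceptions, collapse = ","),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
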