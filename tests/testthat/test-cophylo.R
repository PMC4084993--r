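test_that("host repertoires encode as DEC ranges per (lineage, area) terminal", {
  enc <- encode_hosts_as_areas(margotrema_associations())
  expect_equal(length(enc$space$areas), 15)
  expect_equal(enc$space$max_range_size, 2)
  expect_equal(enc$tip_ranges[["Margotrema bravoae Lineage II@B"]], "i")
  expect_setequal(enc$tip_ranges[["Margotrema bravoae Lineage III@D"]],
                  c("f", "n"))
  expect_setequal(enc$tip_ranges[["Margotrema bravoae Lineage III@E"]],
                  c("e", "n"))
  # every terminal respects the repertoire cap
  expect_true(all(lengths(enc$tip_ranges) <= 2))
  expect_error(encode_hosts_as_areas(margotrema_associations()[0, ]),
               "empty")
})

test_that("terminals with too many hosts per area are rejected with advice", {
  tab <- as.data.frame(margotrema_associations())
  extra <- tab[tab$area_code == "D", ][1, ]
  extra$host_code <- "c"
  extra$host_species <- "Allotoca meeki"
  tab2 <- validate_association_table(rbind(tab, extra))
  expect_error(encode_hosts_as_areas(tab2), "split")
})

test_that("co-occurrence gating restricts the host adjacency", {
  enc <- encode_hosts_as_areas(margotrema_associations(),
                               cooccurrence_gate = TRUE)
  adj <- enc$space$adjacency
  # f and n share Zacapu Lake; f and i share no area
  expect_equal(adj["f", "n"], 1)
  expect_equal(adj["f", "i"], 0)
  # gated space drops disconnected pairs
  full <- encode_hosts_as_areas(margotrema_associations())
  expect_lt(enc$space$n_states, full$space$n_states)
})

test_that("node scenarios translate to the cophylogenetic event vocabulary", {
  scen <- data.frame(
    node = c(4, 5, 6),
    child_left = c(5, 1, 2), child_right = c(6, 2, 3),
    anc = c("i+n", "g", "g+i"),
    left = c("i", "g", "g"), right = c("n", "g", "g+i"),
    type = c("vicariance", "sympatric-copy", "peripheral-isolate"),
    stringsAsFactors = FALSE)
  ev <- classify_node_events(scen)
  expect_equal(ev$type[ev$node == 4], "cospeciation")
  expect_equal(ev$type[ev$node == 5], "duplication")
  expect_setequal(ev$type[ev$node == 6], c("duplication", "sharing"))
  bad <- scen
  bad$type[1] <- "budding"
  expect_error(classify_node_events(bad), "unknown scenario")
  expect_error(classify_node_events(rbind(scen, scen[1, ])), "one scenario")
})

test_that("branch events are the set differences between branch ends", {
  # 3-tip tree: root 4 -> (node 5 -> t1,t2), t3
  tr <- read_newick("((t1:1,t2:1):1,t3:2);")
  scen <- data.frame(
    node = c(4, 5), child_left = c(5, 1), child_right = c(3, 2),
    anc = c("n", "n+d"), left = c("n", "n"), right = c("n", "d"),
    type = c("sympatric-copy", "vicariance"), stringsAsFactors = FALSE)
  # branch 4->5 runs from {n} to {n,d}: one switch n -> d
  ev <- classify_branch_events(tr, scen,
                               c(t1 = "n", t2 = "d", t3 = "n"))
  sw <- ev[ev$type == "host-switch", ]
  expect_equal(nrow(sw), 1)
  expect_equal(sw$gained, "d")
  expect_equal(sw$lost, "n")
  expect_equal(sw$node, 5)

  # loss: branch top {i,h} -> tip {h}
  scen2 <- data.frame(
    node = 4, child_left = 5, child_right = 3,
    anc = "h+i", left = "h+i", right = "h",
    type = "peripheral-isolate", stringsAsFactors = FALSE)
  scen2 <- rbind(scen2, data.frame(
    node = 5, child_left = 1, child_right = 2,
    anc = "h", left = "h", right = "h",
    type = "sympatric-copy", stringsAsFactors = FALSE))
  ev2 <- classify_branch_events(tr, scen2,
                                c(t1 = "h", t2 = "h", t3 = "h"))
  loss <- ev2[ev2$type == "lineage-loss", ]
  expect_equal(nrow(loss), 1)
  expect_equal(loss$lost, "i")
  expect_equal(loss$node, 5)

  # identical branch ends produce no events
  scen3 <- data.frame(
    node = c(4, 5), child_left = c(5, 1), child_right = c(3, 2),
    anc = c("h", "h"), left = c("h", "h"), right = c("h", "h"),
    type = c("sympatric-copy", "sympatric-copy"), stringsAsFactors = FALSE)
  ev3 <- classify_branch_events(tr, scen3,
                                c(t1 = "h", t2 = "h", t3 = "h"))
  expect_equal(nrow(ev3), 0)
})

test_that("gains and losses are conserved along simulated histories", {
  # find a fully extant realisation (the truth only assigns scenarios to
  # surviving lineages) whose branches show net losses as well as gains
  sp <- build_state_space(letters[1:4], 2)
  tr <- simulate_host_tree(1, 20, seed = 8)
  net_changes <- function(hist) {
    split_lab <- function(x) if (x == "0") character(0)
                             else strsplit(x, "+", fixed = TRUE)[[1]]
    n_gain <- 0L
    n_loss <- 0L
    for (r in seq_len(nrow(hist$scenarios))) {
      s <- hist$scenarios[r, ]
      for (side in c("left", "right")) {
        child <- if (side == "left") s$child_left else s$child_right
        start <- split_lab(s[[side]])
        end <- if (child <= ape::Ntip(tr)) {
          hist$tip_ranges[[tr$tip.label[child]]]
        } else {
          split_lab(hist$scenarios$anc[hist$scenarios$node == child])
        }
        n_gain <- n_gain + length(setdiff(end, start))
        n_loss <- n_loss + length(setdiff(start, end))
      }
    }
    c(gain = n_gain, loss = n_loss)
  }
  hist <- NULL
  for (s in 1:30) {
    cand <- simulate_dec_history(tr, sp, dec_params(0.4, 0.1, n_areas = 4),
                                 root_range = "a", seed = s)
    if (any(cand$extinct)) next
    nc <- net_changes(cand)
    if (nc["gain"] > 0 && nc["loss"] > 0) {
      hist <- cand
      break
    }
  }
  expect_false(is.null(hist))
  nc <- net_changes(hist)
  ev <- classify_branch_events(tr, hist$scenarios, hist$tip_ranges)
  expect_equal(sum(ev$type == "host-switch"), unname(nc["gain"]))
  expect_equal(sum(ev$type == "lineage-loss"), unname(nc["loss"]))
})

test_that("codivergence levels match the known host-specificity structure", {
  lev <- assign_codivergence_levels(margotrema_associations())
  expect_equal(nrow(lev), 4)
  expect_setequal(unique(lev$level),
                  c("Species-Species", "Species-Lineage", "Tribe-Lineage"))
  get <- function(lin) lev[lev$parasite_lineage == lin, ]
  expect_equal(get("Margotrema resolanae")$level, "Species-Species")
  expect_equal(get("Margotrema bravoae Lineage II")$level, "Species-Lineage")
  expect_equal(get("Margotrema bravoae Lineage I")$level, "Tribe-Lineage")
  expect_equal(get("Margotrema bravoae Lineage III")$level, "Tribe-Lineage")
  # the cyprinid C. ornata (h) never defines the focal tribe of Lineage I
  l1 <- get("Margotrema bravoae Lineage I")
  expect_equal(l1$tribes, "Ilyodontini")
  expect_true(grepl("h", l1$exceptions))
  l3 <- get("Margotrema bravoae Lineage III")
  expect_setequal(strsplit(l3$tribes, ",")[[1]],
                  c("Girardinichthyini", "Chapalichthyini"))
  expect_error(
    assign_codivergence_levels(margotrema_associations(),
                               tribes = c(a = "Girardinichthyini")),
    "no tribe")
})

test_that("event classification commutes with relabelling hosts", {
  scen <- data.frame(
    node = c(4, 5), child_left = c(5, 1), child_right = c(3, 2),
    anc = c("a+b", "a"), left = c("a", "a"), right = c("b", "a"),
    type = c("vicariance", "sympatric-copy"), stringsAsFactors = FALSE)
  tr <- read_newick("((t1:1,t2:1):1,t3:2);")
  ev <- classify_branch_events(tr, scen,
                               list(t1 = "a", t2 = c("a", "c"), t3 = "b"))
  # relabel a->x, b->y, c->z everywhere
  relab <- function(s) chartr("abc", "xyz", s)
  scen2 <- scen
  for (col in c("anc", "left", "right")) scen2[[col]] <- relab(scen2[[col]])
  ev2 <- classify_branch_events(tr, scen2,
                                list(t1 = "x", t2 = c("x", "z"), t3 = "y"))
  expect_equal(ev2$type, ev$type)
  expect_equal(ev2$gained, relab(ev$gained))
  expect_equal(ev2$lost, relab(ev$lost))
})
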