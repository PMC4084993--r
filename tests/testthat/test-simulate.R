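test_that("Yule simulation yields valid, reproducible dated trees", {
  tr <- simulate_host_tree(1, 2, seed = 1)
  expect_equal(ape::Ntip(tr), 2)
  expect_no_error(validate_dated_tree(tr))
  t1 <- simulate_host_tree(0.7, 9, seed = 123)
  t2 <- simulate_host_tree(0.7, 9, seed = 123)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_no_error(validate_dated_tree(t1))
})

test_that("Yule root ages match the closed-form expectation", {
  lambda <- 1
  n <- 8
  ages <- vapply(1:1000, function(i) {
    max(node_ages(simulate_host_tree(lambda, n, seed = 50000 + i)))
  }, numeric(1))
  expected <- sum(1 / (lambda * (2:n)))
  se <- stats::sd(ages) / sqrt(length(ages))
  expect_lt(abs(mean(ages) - expected), 3 * se)
})

test_that("pure cospeciation reproduces the host tree exactly", {
  h <- simulate_host_tree(1, 10, seed = 31)
  s <- simulate_cophylo(h, p_c = 1, seed = 32)
  expect_false(s$empty)
  expect_equal(s$n_parasites, 10)
  expect_equal(sum(s$events$type == "cospeciation"), 9)
  expect_equal(nrow(s$events), 9)  # nothing but cospeciations
  p <- s$parasite
  p$tip.label <- unname(s$association[p$tip.label])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(h), ape::unroot(p))), 0)
  # parasite node ages coincide with host node ages
  expect_equal(sort(node_ages(p)), sort(node_ages(h)), tolerance = 1e-9)
})

test_that("overwhelming loss flags an empty result instead of erroring", {
  h <- simulate_host_tree(1, 6, seed = 77)
  s <- simulate_cophylo(h, p_c = 1, mu = 200, seed = 78)
  expect_true(s$empty)
  expect_null(s$parasite)
  expect_equal(s$n_parasites, 0)
})

test_that("switch counts scale linearly with the switch rate", {
  count_switches <- function(rate, seed_base) {
    total <- 0
    for (i in 1:500) {
      h <- simulate_host_tree(1, 8, seed = seed_base + i)
      s <- simulate_cophylo(h, p_c = 1, lambda_s = rate,
                            seed = seed_base + 10000 + i)
      total <- total + sum(s$events$type == "host-switch")
    }
    total
  }
  n_half <- count_switches(0.5, 100000)
  n_full <- count_switches(1.0, 200000)
  expect_gt(n_half, 50)  # enough events for the ratio to be meaningful
  ratio <- n_full / n_half
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("degenerate DEC histories stay at the root range", {
  sp <- build_state_space(c("A", "B"), 2)
  tr <- simulate_host_tree(1, 10, seed = 5)
  hist <- simulate_dec_history(tr, sp, dec_params(0, 0, n_areas = 2),
                               root_range = "A", seed = 6)
  expect_true(all(vapply(hist$tip_ranges, identical, logical(1), "A")))
  expect_true(all(hist$events$type %in% c("duplication",
                                          "vicariance/cospeciation")))
  expect_equal(sum(!hist$events$type %in%
                     c("duplication", "vicariance/cospeciation")), 0)
  expect_false(any(hist$extinct))
  h1 <- simulate_dec_history(tr, sp, dec_params(0.2, 0.1, n_areas = 2),
                             root_range = "A", seed = 42)
  h2 <- simulate_dec_history(tr, sp, dec_params(0.2, 0.1, n_areas = 2),
                             root_range = "A", seed = 42)
  expect_identical(h1$tip_ranges, h2$tip_ranges)
  expect_identical(as.data.frame(h1$events), as.data.frame(h2$events))
  expect_error(simulate_dec_history(tr, sp,
                                    dec_params(0.1, 0.1, n_areas = 2),
                                    root_range = character(0)))
})

test_that("branch-end state frequencies follow the CTMC law", {
  # two tips hanging from the root by branches of length 1: the root's
  # singleton range copies itself, so each tip state is an independent
  # draw from the exp(Qt) row of the root range
  sp <- build_state_space(c("A", "B"), 2)
  params <- dec_params(0.3, 0.2, n_areas = 2)
  tr <- read_newick("(t1:1,t2:1);")
  set.seed(90)
  n_rep <- 5000
  counts <- numeric(sp$n_states)
  for (i in 1:n_rep) {
    hist <- simulate_dec_history(tr, sp, params, root_range = "A")
    r <- hist$tip_ranges[["t1"]]
    s <- if (!length(r)) 1L else which(sp$labels == paste(r, collapse = "+"))
    counts[s] <- counts[s] + 1
  }
  emp <- counts / n_rep
  Q <- build_rate_matrix(sp, params)
  theo <- transition_matrix(Q, 1)["A", ]
  expect_lt(0.5 * sum(abs(emp - theo)), 0.02)
})

test_that("simulated histories translate into classifiable scenarios", {
  h <- simulate_host_tree(1, 7, seed = 61)
  s <- simulate_cophylo(h, p_c = 1, seed = 62)
  scen <- history_to_scenarios(s)
  expect_equal(nrow(scen), 6)
  expect_true(all(scen$type == "vicariance"))
  ev <- classify_node_events(scen)
  expect_equal(sum(ev$type == "cospeciation"), 6)
  expect_equal(sum(ev$type %in% c("host-switch", "duplication")), 0)
})
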