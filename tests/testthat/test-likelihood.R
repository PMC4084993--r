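test_that("two-tip single-area likelihood has its closed form", {
  tr <- read_newick("(t1:1,t2:1);")
  sp <- build_state_space("A", 1)
  ll <- tree_likelihood(tr, c(t1 = "A", t2 = "A"), sp,
                        dec_params(0, 0.1, n_areas = 1))
  # sympatric copy at the root, survival (no loss) on both branches
  expect_equal(ll, log(exp(-0.2)), tolerance = 1e-12)
  # general branch lengths: L = exp(-e * total length)
  tr2 <- read_newick("(t1:2.5,t2:2.5);")
  ll2 <- tree_likelihood(tr2, c(t1 = "A", t2 = "A"), sp,
                         dec_params(0, 0.07, n_areas = 1))
  expect_equal(ll2, -0.07 * 5, tolerance = 1e-12)
})

test_that("pruning equals the brute-force enumeration oracle", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    o <- oracle_loglik(inst$tree, inst$tip_states, inst$space,
                       inst$d, inst$e)
    p <- tree_likelihood(
      inst$tree, inst$tip_ranges, inst$space,
      dec_params(inst$d, inst$e, n_areas = length(inst$space$areas)))
    expect_equal(p, o, tolerance = 1e-10)
  }
})

test_that("time stratification with unit multipliers is a no-op", {
  inst <- random_instance(101)
  n <- length(inst$space$areas)
  flat <- dec_params(inst$d, inst$e, n_areas = n)
  root_age <- max(node_ages(inst$tree))
  strat <- dec_params(inst$d, inst$e,
                      epochs = epoch_config(c(root_age / 2, 0),
                                            n_areas = n))
  ll_flat <- tree_likelihood(inst$tree, inst$tip_ranges, inst$space, flat)
  ll_strat <- tree_likelihood(inst$tree, inst$tip_ranges, inst$space, strat)
  expect_equal(ll_strat, ll_flat, tolerance = 1e-9)
})

test_that("stratified likelihood matches the oracle when multipliers differ", {
  inst <- random_instance(7)
  n <- length(inst$space$areas)
  root_age <- max(node_ages(inst$tree))
  mult_old <- matrix(1, n, n)
  mult_new <- matrix(5, n, n)
  ep <- epoch_config(c(root_age * 0.4, 0), list(mult_old, mult_new))
  params <- dec_params(inst$d, inst$e, epochs = ep)
  ll <- tree_likelihood(inst$tree, inst$tip_ranges, inst$space, params)
  o <- oracle_loglik(inst$tree, inst$tip_states, inst$space,
                     inst$d, inst$e, epochs = ep)
  expect_equal(ll, o, tolerance = 1e-10)
})

test_that("likelihood is invariant to a consistent permutation of areas", {
  inst <- random_instance(55)
  n <- length(inst$space$areas)
  perm <- rev(seq_len(n))
  areas2 <- inst$space$areas[perm]
  sp2 <- build_state_space(areas2, inst$space$max_range_size,
                           inst$space$adjacency[perm, perm])
  ll1 <- tree_likelihood(inst$tree, inst$tip_ranges, inst$space,
                         dec_params(inst$d, inst$e, n_areas = n))
  ll2 <- tree_likelihood(inst$tree, inst$tip_ranges, sp2,
                         dec_params(inst$d, inst$e, n_areas = n))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("raising e cannot improve data where every tip keeps the full range", {
  tr <- read_newick("((t1:1,t2:1):1,t3:2);")
  sp <- build_state_space(c("A", "B"), 2)
  ranges <- c(t1 = "A,B", t2 = "A,B", t3 = "A,B")
  ll <- vapply(c(0.01, 0.05, 0.2, 0.5, 1),
               function(e) tree_likelihood(tr, ranges, sp,
                                           dec_params(0.1, e, n_areas = 2)),
               numeric(1))
  expect_true(all(diff(ll) < 0))
})

test_that("unknown tip ranges produce errors naming the tip", {
  tr <- read_newick("(t1:1,t2:1);")
  sp <- build_state_space(c("A", "B"), 1)  # pairs not in the space
  expect_error(
    tree_likelihood(tr, c(t1 = "A", t2 = "A,B"), sp,
                    dec_params(0.1, 0.1, n_areas = 2)),
    "t2")
  expect_error(
    tree_likelihood(tr, c(t1 = "A"), sp,
                    dec_params(0.1, 0.1, n_areas = 2)),
    "t2")
})
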