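test_that("root scenarios enumerate the cladogenesis rules and normalise", {
  tr <- read_newick("(t1:1,t2:1);")
  sp <- build_state_space(c("A", "B"), 2)
  sc <- ancestral_scenarios(tr, c(t1 = "A", t2 = "B"), sp,
                            dec_params(0.1, 0.05, n_areas = 2))
  expect_equal(sum(sc$rel_prob), 1, tolerance = 1e-9)
  # exactly the allowed splits of {A}, {B}, {A,B}
  expect_equal(nrow(sc), 1 + 1 + 6)
  expect_setequal(unique(sc$anc), c("A", "B", "A+B"))
  vic <- sc[sc$type == "vicariance", ]
  expect_setequal(paste(vic$left, vic$right), c("A B", "B A"))
  per <- sc[sc$type == "peripheral-isolate", ]
  expect_equal(nrow(per), 4)
  expect_true(all(sc$rel_prob >= 0))
  # sorted descending within the node
  expect_true(all(diff(sc$rel_prob) <= 1e-12))
})

test_that("scenario probabilities are consistent with per-scenario oracle", {
  # 3-tip, 2-area instance: check relative probabilities at the root by
  # restricting the brute-force sum to each root scenario
  inst <- random_instance(31)
  n <- length(inst$space$areas)
  params <- dec_params(inst$d, inst$e, n_areas = n)
  sc <- ancestral_scenarios(inst$tree, inst$tip_ranges, inst$space, params)
  # relative probabilities sum to one at every node
  sums <- tapply(sc$rel_prob, sc$node, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(attr(sc, "loglik"),
               oracle_loglik(inst$tree, inst$tip_states, inst$space,
                             inst$d, inst$e),
               tolerance = 1e-9)
})

test_that("a clade fixed in one area makes sympatric copy certain as e -> 0", {
  tr <- read_newick("((t1:1,t2:1):1,t3:2);")
  sp <- build_state_space(c("A", "B"), 2)
  sc <- ancestral_scenarios(tr, c(t1 = "A", t2 = "A", t3 = "A"), sp,
                            dec_params(1e-7, 1e-9, n_areas = 2))
  cherry <- ape::getMRCA(tr, c("t1", "t2"))
  top <- sc[sc$node == cherry, ][1, ]
  expect_equal(top$type, "sympatric-copy")
  expect_equal(top$anc, "A")
  expect_gt(top$rel_prob, 0.999)
})

test_that("fixing nodes to their top scenarios cannot beat the full sum", {
  inst <- random_instance(77)
  n <- length(inst$space$areas)
  params <- dec_params(inst$d, inst$e, n_areas = n)
  sc <- ancestral_scenarios(inst$tree, inst$tip_ranges, inst$space, params)
  top_prob <- vapply(split(sc$rel_prob, sc$node), max, numeric(1))
  constrained <- attr(sc, "loglik") + sum(log(top_prob))
  expect_lte(constrained, attr(sc, "loglik") + 1e-12)
})

test_that("consensus across runs applies the support and agreement rules", {
  fake_run <- function(probs) {
    # one root node (id 3) over areas B and C encoded as singleton splits
    data.frame(node = 3, child_left = 1, child_right = 2,
               anc = names(probs), left = names(probs),
               right = names(probs), type = "sympatric-copy",
               rel_prob = unname(probs), stringsAsFactors = FALSE)
  }
  # both runs give B 0.9 -> accepted
  comb <- combine_runs(list(fake_run(c(B = 0.9, C = 0.1)),
                            fake_run(c(B = 0.9, C = 0.1))))
  b <- comb$areas[comb$areas$area == "B", ]
  expect_equal(b$tier, "accepted")
  expect_equal(b$mean_support, 0.9)
  expect_equal(comb$nodes$call, "accepted")

  # disagreement on the top area -> equivocal
  comb2 <- combine_runs(list(fake_run(c(B = 0.9, C = 0.1)),
                             fake_run(c(B = 0.1, C = 0.9))))
  expect_equal(comb2$nodes$call, "equivocal")
  expect_true(all(comb2$areas$tier == "none"))

  # B at 0.6 and 0.55 -> mean 0.575: moderate tier only
  comb3 <- combine_runs(list(fake_run(c(B = 0.6, C = 0.4)),
                             fake_run(c(B = 0.55, C = 0.45))))
  b3 <- comb3$areas[comb3$areas$area == "B", ]
  expect_equal(b3$tier, "moderate")
  expect_equal(b3$mean_support, 0.575)
  expect_equal(comb3$nodes$call, "moderate")
})

test_that("consensus rejects runs from different trees", {
  tr1 <- read_newick("(t1:1,t2:1);")
  tr2 <- read_newick("((t1:1,t2:1):1,t3:2);")
  sp <- build_state_space(c("A", "B"), 2)
  p <- dec_params(0.1, 0.05, n_areas = 2)
  s1 <- ancestral_scenarios(tr1, c(t1 = "A", t2 = "B"), sp, p)
  s2 <- ancestral_scenarios(tr2, c(t1 = "A", t2 = "B", t3 = "A"), sp, p)
  expect_error(combine_runs(list(s1, s2)), "different trees")
  expect_error(combine_runs(list(s1)), "at least two")
  expect_error(combine_runs(list(s1, s1), threshold = 1.2), "threshold")
})
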