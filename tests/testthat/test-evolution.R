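test_that("goal functions validate their greedy node sets", {
  expect_s3_class(goal_function("tst"), "goal_function")
  expect_error(goal_function("TST", greedy_nodes = 1), "no `greedy_nodes`")
  expect_error(goal_function("ABS_FLOW"), "non-empty")
  expect_error(goal_function("POWER"), "unknown goal")
})

test_that("goal evaluation matches the toy steady state and Finn values", {
  cyc <- toy_cycle()
  expect_equal(evaluate_goal(cyc, "TST"), 1.0)
  expect_equal(evaluate_goal(cyc, goal_function("ABS_FLOW", 1)), 4 / 3)
  expect_equal(evaluate_goal(cyc, goal_function("PROP_FLOW", 1)), 2 / 3)
  expect_equal(evaluate_goal(cyc, goal_function("ABS_FINN", 2)), 1 / 6)
  expect_equal(evaluate_goal(cyc, goal_function("PROP_FINN", 2)), 2 / 3)
  bd <- index_bundle(cyc)
  expect_equal(evaluate_goal(cyc, "AMI"), bd$ami)
  expect_equal(evaluate_goal(cyc, "ASC"), bd$asc)
  expect_equal(evaluate_goal(cyc, "EDIFF"), bd$ediff)
  expect_error(evaluate_goal(cyc, goal_function("ABS_FLOW", 99)),
               "out of core-node range")
})

test_that("short mutations preserve the arc set and renormalize the row", {
  cyc <- toy_cycle()
  set.seed(21)
  for (i in 1:50) {
    mut <- mutate_short(cyc, mutation_policy("short"))
    expect_identical(as.matrix(mut) > 0, as.matrix(cyc) > 0)
    expect_equal(rowSums(as.matrix(mut))[1:3], c(1, 1, 1),
                 ignore_attr = TRUE)
    expect_true(validate_fcdn(mut)$is_valid)
  }
  # a +10% tweak of n1->n2 renormalizes n1's row to (0.5238..., 0.4762...)
  A <- as.matrix(cyc)
  A[1, 2] <- A[1, 2] * 1.1
  A[1, ] <- A[1, ] / sum(A[1, ])
  expect_equal(A[1, c(2, 4)], c(0.55, 0.5) / 1.05, ignore_attr = TRUE)
  # zero vicinity leaves the network unchanged
  mut0 <- mutate_short(cyc, mutation_policy("short", vicinity = 0), seed = 1)
  expect_equal(as.matrix(mut0), as.matrix(cyc))
})

test_that("large mutations always yield valid networks and never touch input arcs", {
  net <- random_fcdn(12, 0.25, seed = 31)
  in_row <- as.matrix(net)[13, ]
  set.seed(32)
  for (i in 1:120) {
    net2 <- mutate_large(net, mutation_policy("large"))
    expect_true(validate_fcdn(net2)$is_valid)
    expect_equal(as.matrix(net2)[13, ], in_row)
    net <- net2
  }
})

test_that("add mutations fall back to reweight on a saturated core", {
  net <- random_fcdn(3, 1.0, seed = 33)
  pol <- mutation_policy("large", p_add = 1, p_delete = 0, p_reweight = 0)
  set.seed(34)
  for (i in 1:20) {
    mut <- mutate_large(net, pol)
    expect_identical(core_matrix(mut) > 0, core_matrix(net) > 0)
    expect_true(validate_fcdn(mut)$is_valid)
  }
})

test_that("deleting the cycle-closing arc removes all cycling", {
  cyc <- toy_cycle()
  pol <- mutation_policy("large", p_add = 0, p_delete = 1, p_reweight = 0)
  set.seed(35)
  seen_acyclic <- FALSE
  for (i in 1:20) {
    mut <- mutate_large(cyc, pol)
    expect_true(validate_fcdn(mut)$is_valid)
    if (as.matrix(mut)[2, 1] == 0) {
      seen_acyclic <- TRUE
      expect_equal(finn(mut, flux_matrix(mut))$finn_total, 0)
    }
  }
  expect_true(seen_acyclic)
})

test_that("hill climbing is monotone, rejects harmful mutations, and reproduces", {
  net <- random_fcdn(10, 0.25, seed = 41)
  ev <- evolve(net, "TST", mutation_policy("large"), n_iter = 300,
               seed = 42)
  expect_true(all(diff(ev$trace$goal_value) >= 0))
  # accepted events strictly increase the goal
  acc_vals <- ev$trace$goal_value[ev$trace$accepted]
  expect_true(all(diff(c(ev$trace$goal_value[1], acc_vals)) >= 0))
  expect_true(all(diff(acc_vals) > 0))
  expect_true(validate_fcdn(ev$net)$is_valid)
  expect_true(all(is.finite(ev$trace$b)))
  # bit-for-bit reproducibility under the same seed
  ev2 <- evolve(net, "TST", mutation_policy("large"), n_iter = 300,
                seed = 42)
  expect_identical(ev$trace, ev2$trace)
  expect_identical(as.matrix(ev$net), as.matrix(ev2$net))
  # a rejected proposal leaves the network unchanged
  ev3 <- evolve(net, "TST", mutation_policy("short", vicinity = 0),
                n_iter = 1, seed = 43)
  expect_false(ev3$trace$accepted[1])
  expect_equal(as.matrix(ev3$net), as.matrix(net))
})

test_that("short-scale evolution keeps the arc set constant over the whole run", {
  net <- random_fcdn(15, 0.2, seed = 51)
  ev <- evolve(net, "TST", mutation_policy("short"), n_iter = 500,
               seed = 52, record_b = FALSE)
  expect_identical(as.matrix(ev$net) > 0, as.matrix(net) > 0)
  expect_true(all(diff(ev$trace$goal_value) >= 0))
})

test_that("every systemic and greedy goal can drive an evolution run", {
  net <- random_fcdn(12, 0.25, seed = 61)
  gn <- select_greedy_nodes(net, 0.3, seed = 62)
  goals <- list("TST", "AMI", "ASC", "EDIFF",
                goal_function("ABS_FLOW", gn),
                goal_function("PROP_FLOW", gn),
                goal_function("ABS_FINN", gn),
                goal_function("PROP_FINN", gn))
  for (g in goals) {
    ev <- evolve(net, g, mutation_policy("short"), n_iter = 50,
                 seed = 63, record_b = FALSE)
    expect_true(all(diff(ev$trace$goal_value) >= 0))
    expect_true(validate_fcdn(ev$net)$is_valid)
  }
})

test_that("greedy node selection rounds half up with a floor of one node", {
  net <- random_fcdn(30, 0.2, seed = 71)
  expect_length(select_greedy_nodes(net, 0.5, seed = 1), 15)
  expect_length(select_greedy_nodes(net, 0.10, seed = 1), 3)
  expect_length(select_greedy_nodes(net, 0.01, seed = 1), 1)
  expect_identical(select_greedy_nodes(net, 0.3, seed = 2),
                   select_greedy_nodes(net, 0.3, seed = 2))
  expect_error(select_greedy_nodes(net, 0), "fraction")
  expect_error(select_greedy_nodes(net, 1.5), "fraction")
})
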