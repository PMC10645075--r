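test_that("Leontief inverse matches hand inversion on the toys", {
  expect_equal(unname(leontief(toy_chain())),
               rbind(c(1, 0.5), c(0, 1)))
  expect_equal(unname(leontief(toy_cycle())),
               rbind(c(4, 2), c(2, 4)) / 3)
  # empty core: L is the identity
  A <- matrix(0, 4, 4)
  A[3, 1:2] <- 0.5; A[1, 4] <- 1; A[2, 4] <- 1
  expect_true(validate_fcdn(fcdn(A))$is_valid)
  expect_equal(unname(leontief(fcdn(A))), diag(2))
})

test_that("steady states match the fixed-point oracle on the toys", {
  expect_equal(unname(steady_state(toy_chain())), c(1, 0.5))
  expect_equal(unname(steady_state(toy_chain())),
               fp_steady(toy_chain(), steps = 50), tolerance = 1e-8)
  expect_equal(unname(steady_state(toy_cycle())), c(4, 2) / 3)
  x <- steady_state(toy_cycle())
  expect_equal(unname(x[1]), 1 + 0.5 * unname(x[2]))  # node balance
  expect_equal(unname(steady_state(toy_cycle(), input_rate = 0)), c(0, 0))
})

test_that("linear solve agrees with long fixed-point iteration on random networks", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(2:50, 1)
    net <- random_net(n)
    expect_equal(unname(steady_state(net)), fp_steady(net, steps = 2000),
                 tolerance = 1e-6)
  }
})

test_that("steady-state conservation and linearity hold", {
  set.seed(6)
  for (i in 1:25) {
    net <- random_net(sample(2:40, 1))
    n <- n_core(net)
    fl <- flux_matrix(net)
    # all input eventually reaches the output
    expect_equal(sum(fl[seq_len(n), n + 2]), 1, tolerance = 1e-9)
    # node balance at steady state
    inflow <- colSums(fl[, seq_len(n), drop = FALSE])
    outflow <- rowSums(fl[seq_len(n), , drop = FALSE])
    expect_equal(inflow, outflow, tolerance = 1e-9, ignore_attr = TRUE)
    # scaling the input scales states and fluxes linearly
    expect_equal(unname(steady_state(net, input_rate = 3)),
                 3 * unname(steady_state(net)), tolerance = 1e-9)
    expect_equal(unname(flux_matrix(net, input_rate = 3)),
                 3 * unname(fl), tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("realized fluxes on the toys match hand multiplication", {
  fl <- flux_matrix(toy_chain())
  expect_equal(fl["n1", "n2"], 0.5)
  expect_equal(fl["n1", "out"], 0.5)
  expect_equal(fl["n2", "out"], 0.5)
  fl2 <- flux_matrix(toy_cycle())
  expect_equal(fl2["n1", "n2"], 2 / 3)
  expect_equal(fl2["n2", "n1"], 1 / 3)
  expect_equal(fl2["n1", "out"], 2 / 3)
  expect_equal(fl2["n2", "out"], 1 / 3)
  expect_equal(sum(fl2[1:2, "out"]), 1)
  # zero state gives zero core flows
  expect_true(all(flux_matrix(toy_cycle(), state = c(0, 0))[1:2, ] == 0))
})

test_that("simulation converges to the steady state under constant input", {
  tr <- simulate_flows(toy_cycle(), input_schedule(rate = 1),
                       t_max = 200)
  expect_equal(tr$states[201, ], steady_state(toy_cycle()),
               tolerance = 1e-6)
  net <- random_net(20)
  tr2 <- simulate_flows(net, input_schedule(rate = 1), t_max = 3000)
  expect_equal(tr2$states[3001, ], steady_state(net), tolerance = 1e-6)
})

test_that("cutting the input at steady state decays energy as the toys predict", {
  # cycle: total energy halves each iteration (|b| = 0.5)
  tr <- simulate_flows(toy_cycle(), input_schedule(rate = 0),
                       x0 = steady_state(toy_cycle()), t_max = 3)
  expect_equal(tr$total_energy, c(2, 1, 0.5, 0.25))
  # chain: nilpotent core flushes in two steps
  tr2 <- simulate_flows(toy_chain(), input_schedule(rate = 0),
                        x0 = steady_state(toy_chain()), t_max = 3)
  expect_equal(tr2$total_energy, c(1.5, 0.5, 0, 0))
  # with the input off, total energy never increases
  expect_true(all(diff(tr$total_energy) <= 0))
})

test_that("pulsed input fires on the scheduled iterations", {
  # period 1: the input misses one iteration between firings
  sched <- input_schedule(rate = 1, period = 1)
  tr <- simulate_flows(toy_chain(), sched, t_max = 6)
  # manual iteration of the same map
  A <- as.matrix(toy_chain())
  x <- c(0, 0)
  manual <- x
  for (t in 0:5) {
    x <- drop(x %*% A[1:2, 1:2])
    if (t %% 2 == 0) x <- x + A[3, 1:2]
    manual <- rbind(manual, x)
  }
  expect_equal(unname(tr$states), unname(manual))
  expect_true(is.data.frame(as.data.frame(tr)))
})

test_that("decay rate equals the dominant core eigenvalue minus one", {
  expect_equal(decay_rate(toy_chain()), -1)
  expect_equal(decay_rate(toy_cycle()), -0.5)
  # fully dissipative star: every core node feeds the output only
  A <- matrix(0, 5, 5)
  A[4, 1:3] <- 1 / 3
  A[1:3, 5] <- 1
  expect_equal(decay_rate(fcdn(A)), -1)
})

test_that("no-input energy decay follows log(1 + b) asymptotically", {
  set.seed(8)
  checked <- 0
  for (i in 1:30) {
    net <- random_net(sample(3:40, 1))
    b <- decay_rate(net)
    if (1 + b < 1e-8) next
    tr <- simulate_flows(net, input_schedule(rate = 0),
                         x0 = steady_state(net), t_max = 400)
    e <- tr$total_energy
    keep <- which(e > 1e-250)
    keep <- keep[keep > max(keep) - 100]
    if (length(keep) < 10) next
    slope <- unname(coef(stats::lm(log(e[keep]) ~ keep))[2])
    expect_equal(slope, log(1 + b), tolerance = 1e-4)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
})
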