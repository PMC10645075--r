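small_config <- function(...) {
  experiment_config(sizes = 8, replicates = 3, natural_iters = 60,
                    short_iters = 60, goals = "TST",
                    greedy_scenarios = c("ABS_FLOW", "PROP_FLOW"),
                    greedy_fractions = c(0.25, 0.5), master_seed = 7,
                    ...)
}

test_that("experiment configurations validate and round-trip through YAML", {
  cfg <- small_config()
  expect_s3_class(cfg, "experiment_config")
  expect_error(experiment_config(replicates = 0), "replicates")
  expect_error(experiment_config(greedy_fractions = 1.5))
  expect_error(experiment_config(goals = "ABS_FLOW"))
  expect_error(experiment_config(greedy_scenarios = "TST"))

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("sizes: [8]", "replicates: 3", "natural_iters: 60",
               "short_iters: 60", "goals: [TST]",
               "greedy_scenarios: [ABS_FLOW, PROP_FLOW]",
               "greedy_fractions: [0.25, 0.5]", "master_seed: 7"), path)
  cfg2 <- read_experiment_config(path)
  expect_equal(cfg2, cfg)
  writeLines("bogus_key: 1", path)
  expect_error(read_experiment_config(path), "unknown configuration key")
})

test_that("natural history produces valid ensembles with monotone traces", {
  cfg <- small_config()
  nh <- run_natural_history(cfg, size = 8, goal = "TST")
  expect_length(nh$nets, 3)
  for (i in seq_along(nh$nets)) {
    expect_true(validate_fcdn(nh$nets[[i]])$is_valid)
    expect_true(all(diff(nh$traces[[i]]$goal_value) >= 0))
  }
  nh2 <- run_natural_history(cfg, size = 8, goal = "TST")
  expect_equal(as.matrix(nh2$nets[[2]]), as.matrix(nh$nets[[2]]))
})

test_that("branch pairs report antisymmetric normalized differences", {
  nd <- fcdnet:::.norm_diff
  expect_equal(nd(0, 0), 0)
  expect_equal(nd(-0.5, -0.25), -1 / 3)  # greedy decays faster: control wins
  expect_equal(nd(-0.25, -0.5), 1 / 3)
  expect_equal(nd(3, 1), -nd(1, 3))

  cfg <- small_config()
  nh <- run_natural_history(cfg, size = 8, goal = "TST")
  rec <- run_branch_pair(nh$nets[[1]], "TST", "ABS_FLOW", 0.5, cfg,
                         seed = 99)
  expect_identical(nrow(rec), 1L)
  expect_true(all(c("b_diff", "goal_diff", "greedy_out_links") %in%
                    names(rec)))
  expect_gt(rec$b_diff, -1); expect_lt(rec$b_diff, 1)
  expect_gt(rec$goal_diff, -1); expect_lt(rec$goal_diff, 1)
  expect_equal(rec$b_diff,
               nd(rec$b_control, rec$b_greedy))
  expect_equal(rec$goal_diff,
               nd(rec$goal_control, rec$goal_greedy))
  rec2 <- run_branch_pair(nh$nets[[1]], "TST", "ABS_FLOW", 0.5, cfg,
                          seed = 99)
  expect_equal(rec, rec2)
})

test_that("surpass percentages count negative differences per cell", {
  rec <- data.frame(goal = "TST", scenario = "ABS_FLOW", size = 30,
                    fraction = 0.5,
                    b_diff = c(-0.1, -0.2, -0.3, 0.1, 0.2, 0.3, 0.4,
                               0.5, 0.6, 0.7),
                    goal_diff = c(-0.1, 0.2, -0.3, 0.1, -0.2, 0.3, 0.4,
                                  0.5, 0.6, 0.7),
                    greedy_out_links = 1:10)
  st <- surpass_percentages(rec)
  expect_equal(st$pct_b_surpass, 30)
  expect_equal(st$pct_goal_surpass, 30)
  expect_equal(st$pct_both_surpass, 20)
  expect_lte(st$pct_both_surpass,
             min(st$pct_b_surpass, st$pct_goal_surpass))
  # all positive differences: nothing surpasses
  rec$b_diff <- abs(rec$b_diff)
  rec$goal_diff <- abs(rec$goal_diff)
  expect_equal(surpass_percentages(rec)$pct_b_surpass, 0)
})

test_that("scatter statistics recover known linear relations", {
  d <- data.frame(b_diff = -seq(0.05, 0.5, length.out = 10))
  d$goal_diff <- d$b_diff
  st <- diff_scatter_stats(d)
  expect_true(st$computable)
  expect_equal(st$slope, 1, tolerance = 1e-12)
  expect_equal(st$r, 1, tolerance = 1e-12)
  set.seed(1)
  d2 <- data.frame(b_diff = -runif(200, 0.01, 0.9))
  d2$goal_diff <- 0.5 * d2$b_diff - 1e-6 * runif(200)
  st2 <- diff_scatter_stats(d2)
  expect_equal(st2$slope, 0.5, tolerance = 1e-3)
  # no record in the negative quadrant: not computable
  st3 <- diff_scatter_stats(data.frame(b_diff = c(1, 2),
                                       goal_diff = c(1, 2)))
  expect_false(st3$computable)
})

test_that("output-link analysis detects monotone and null relations", {
  d <- data.frame(greedy_out_links = 1:12, b_diff = seq(-0.5, 0.6, 0.1))
  la <- link_vs_diff_analysis(d)
  expect_true(la$computable)
  expect_equal(la$spearman_rho, 1)
  expect_equal(nrow(la$by_out_links), 12)
  # shuffled pairings should show little correlation on average
  set.seed(2)
  rhos <- replicate(200, {
    d2 <- d
    d2$b_diff <- sample(d2$b_diff)
    link_vs_diff_analysis(d2)$spearman_rho
  })
  expect_lt(abs(mean(rhos)), 0.1)
  expect_false(link_vs_diff_analysis(d[1:2, ])$computable)
  d3 <- d; d3$greedy_out_links <- 3
  expect_false(link_vs_diff_analysis(d3)$computable)
})

test_that("index correlation matrices are symmetric with unit diagonal", {
  set.seed(3)
  nets <- lapply(1:12, function(i) random_net(10))
  cm <- goal_correlation_matrix(nets)
  expect_equal(dim(cm), c(6, 6))
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, 6))
  expect_true(all(abs(cm[is.finite(cm)]) <= 1 + 1e-12))
  # an ensemble of copies has no variance to correlate
  cm2 <- goal_correlation_matrix(rep(list(nets[[1]]), 5))
  expect_true(all(is.na(cm2)))
})

test_that("a small experiment grid runs end to end and writes result tables", {
  cfg <- small_config()
  out <- withr::local_tempdir()
  res <- run_experiment(cfg, out_dir = out)
  expect_identical(nrow(res$records), 3L * 2L * 2L)
  expect_true(all(res$records$b_diff > -1 & res$records$b_diff < 1))
  expect_true(all(res$summary$pct_both_surpass <=
                    pmin(res$summary$pct_b_surpass,
                         res$summary$pct_goal_surpass)))
  expect_true(file.exists(file.path(out, "records.csv")))
  expect_true(file.exists(file.path(out, "summary.csv")))
  back <- utils::read.csv(file.path(out, "records.csv"))
  expect_identical(nrow(back), nrow(res$records))
  # resumable determinism: the same master seed reproduces the records
  res2 <- run_experiment(cfg)
  expect_equal(res2$records, res$records)
})
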