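#' Configuration of a control-versus-greedy evolution experiment
#'
#' Bundles and validates the parameters of the full experimental grid:
#' network ensembles of several sizes are first evolved at the large
#' time-scale under each systemic goal ("natural history"), then each
#' evolved network is branched into a paired control (same systemic
#' goal) and greedy (greedy goal over a random node subset) short
#' time-scale evolution.
#'
#' @param sizes Core-node counts of the ensembles.
#' @param replicates Networks per ensemble.
#' @param connectance Target core-to-core arc density.
#' @param natural_iters Large time-scale iterations of the natural
#'   history phase.
#' @param short_iters Short time-scale iterations of each branch.
#' @param goals Systemic goal functions driving natural history and the
#'   control branches.
#' @param greedy_scenarios Greedy goal names for the greedy branches.
#' @param greedy_fractions Fractions of core nodes converted to greedy.
#' @param input_rate Energy per iteration delivered by the input node.
#' @param master_seed Master seed; every replicate stream is derived
#'   from it, so runs are reproducible end to end.
#' @return A validated list of class `"experiment_config"`.
#' @export
experiment_config <- function(sizes = c(30L, 50L, 70L, 100L),
                              replicates = 100L,
                              connectance = 0.20,
                              natural_iters = 500L,
                              short_iters = 5000L,
                              goals = c("TST", "AMI", "ASC", "EDIFF"),
                              greedy_scenarios = c("ABS_FLOW", "PROP_FLOW",
                                                   "ABS_FINN", "PROP_FINN"),
                              greedy_fractions = c(0.10, 0.30, 0.50),
                              input_rate = 1,
                              master_seed = 1L) {
  sizes <- as.integer(sizes)
  stopifnot(length(sizes) >= 1, all(sizes >= 2),
            replicates >= 1, natural_iters >= 1, short_iters >= 1,
            connectance > 0, connectance <= 1, input_rate > 0,
            all(greedy_fractions > 0), all(greedy_fractions <= 1))
  goals <- toupper(goals)
  greedy_scenarios <- toupper(greedy_scenarios)
  for (g in goals) stopifnot(!goal_function(g)$is_greedy)
  for (g in greedy_scenarios)
    stopifnot(goal_function(g, greedy_nodes = 1L)$is_greedy)
  structure(list(sizes = sizes, replicates = as.integer(replicates),
                 connectance = connectance,
                 natural_iters = as.integer(natural_iters),
                 short_iters = as.integer(short_iters),
                 goals = goals, greedy_scenarios = greedy_scenarios,
                 greedy_fractions = greedy_fractions,
                 input_rate = input_rate,
                 master_seed = as.integer(master_seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()]; missing keys
#' fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return An `"experiment_config"`.
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(experiment_config, vals)
}

# Derive n child seeds from a parent seed.  One documented splitting
# scheme everywhere: seed the generator, draw integers below 2^31 - 1.
.spawn_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

# normalized difference (a - b) / (|a| + |b|); 0 when both are 0
.norm_diff <- function(a, b) {
  if (a == 0 && b == 0) return(0)
  (a - b) / (abs(a) + abs(b))
}

#' Natural-history evolution of a network ensemble
#'
#' Generates `config$replicates` random FCDNs of the given size and
#' evolves each for `config$natural_iters` large time-scale iterations
#' maximizing the systemic goal, emulating the system's adaptation at
#' evolutionary time-scales.  Replicates whose evolution fails are
#' dropped with a warning.
#'
#' @param config An [experiment_config()].
#' @param size Core-node count of this ensemble.
#' @param goal Systemic goal name.
#' @param seed Seed for this ensemble (default: the config's master
#'   seed).
#' @return List with `nets` (evolved [fcdn] objects) and `traces`
#'   (their evolution traces).
#' @export
run_natural_history <- function(config, size, goal,
                                seed = config$master_seed) {
  stopifnot(inherits(config, "experiment_config"))
  reps <- config$replicates
  seeds <- .spawn_seeds(seed, 2L * reps)
  nets <- vector("list", reps)
  traces <- vector("list", reps)
  ok <- logical(reps)
  for (r in seq_len(reps)) {
    res <- tryCatch({
      net0 <- random_fcdn(size, config$connectance, seed = seeds[r])
      evolve(net0, goal, mutation_policy("large"),
             n_iter = config$natural_iters, seed = seeds[reps + r],
             input_rate = config$input_rate, record_b = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("replicate ", r, " failed and was excluded: ",
              conditionMessage(res), call. = FALSE)
    } else {
      nets[[r]] <- res$net
      traces[[r]] <- res$trace
      ok[r] <- TRUE
    }
  }
  list(nets = nets[ok], traces = traces[ok])
}

# one short-scale branch; returns the endpoint network
.short_branch <- function(net, goal, iters, seed, rate) {
  evolve(net, goal, mutation_policy("short"), n_iter = iters,
         seed = seed, input_rate = rate, record_b = FALSE)$net
}

# assemble a comparison record from the two endpoints
.compare_endpoints <- function(control_net, greedy_net, sys_goal,
                               greedy_nodes, rate) {
  b_c <- decay_rate(control_net)
  b_g <- decay_rate(greedy_net)
  g_c <- evaluate_goal(control_net, sys_goal, rate)
  g_g <- evaluate_goal(greedy_net, sys_goal, rate)
  out_links <- sum(greedy_net$adjacency[greedy_nodes,
                                        greedy_net$output] > 0)
  data.frame(b_control = b_c, b_greedy = b_g,
             goal_control = g_c, goal_greedy = g_g,
             b_diff = .norm_diff(b_c, b_g),
             goal_diff = .norm_diff(g_c, g_g),
             greedy_out_links = out_links)
}

#' Paired control and greedy branch from one evolved network
#'
#' Runs two short time-scale evolutions of `config$short_iters`
#' iterations from the same starting network: a control branch that
#' keeps maximizing the systemic goal, and a greedy branch that
#' maximizes the greedy scenario over a freshly sampled random set of
#' `fraction * n_core` greedy nodes.  Both endpoints are scored on the
#' decay rate `b` and on the systemic goal, and the normalized
#' differences `b_diff = (b_control - b_greedy) / (|b_control| +
#' |b_greedy|)` and `goal_diff` (same form) are reported; negative
#' values mean the greedy branch surpassed the control.
#'
#' @param evolved An [fcdn] from the natural-history phase.
#' @param goal Systemic goal name (the orientor of the control branch
#'   and the performance yardstick for both endpoints).
#' @param scenario Greedy goal name.
#' @param fraction Fraction of core nodes converted to greedy.
#' @param config An [experiment_config()] (iteration counts and input
#'   rate).
#' @param seed Seed for this pair.
#' @return One-row data frame: `goal`, `scenario`, `size`, `fraction`,
#'   `b_control`, `b_greedy`, `goal_control`, `goal_greedy`, `b_diff`,
#'   `goal_diff`, `greedy_out_links`.
#' @export
run_branch_pair <- function(evolved, goal, scenario, fraction, config,
                            seed) {
  stopifnot(inherits(evolved, "fcdn"),
            inherits(config, "experiment_config"))
  seeds <- .spawn_seeds(seed, 3L)
  rate <- config$input_rate
  control <- .short_branch(evolved, goal_function(goal),
                           config$short_iters, seeds[1L], rate)
  gnodes <- select_greedy_nodes(evolved, fraction, seed = seeds[2L])
  greedy <- .short_branch(evolved, goal_function(scenario, gnodes),
                          config$short_iters, seeds[3L], rate)
  rec <- .compare_endpoints(control, greedy, goal, gnodes, rate)
  cbind(data.frame(goal = goal, scenario = scenario,
                   size = evolved$n_core, fraction = fraction),
        rec)
}

#' Run the full control-versus-greedy experimental grid
#'
#' For every ensemble size and systemic goal: evolve the ensemble at
#' the large time-scale (natural history), then branch every evolved
#' network into one control short-scale evolution and one greedy
#' short-scale evolution per (scenario, fraction) cell.  The control
#' branch is computed once per replicate and shared across cells, since
#' it does not depend on the greedy scenario.  Greedy node sets are
#' drawn independently per replicate and cell.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory; when given, `records.csv`,
#'   `summary.csv` and the final greedy/control networks (edge-list
#'   TSVs under `networks/`) are written there.
#' @param progress Print per-cell progress to stderr?
#' @return List with `records` (one [run_branch_pair()]-style row per
#'   replicate and cell, plus a `replicate` column) and `summary` (the
#'   [surpass_percentages()] table).
#' @export
run_experiment <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  combos <- expand.grid(size = config$sizes, goal = config$goals,
                        stringsAsFactors = FALSE)
  combo_seeds <- .spawn_seeds(config$master_seed, nrow(combos))
  all_records <- list()
  for (ci in seq_len(nrow(combos))) {
    size <- combos$size[ci]
    goal <- combos$goal[ci]
    if (progress)
      message(sprintf("ensemble: size %d, goal %s", size, goal))
    seeds <- .spawn_seeds(combo_seeds[ci], 2L)
    nh <- run_natural_history(config, size, goal, seed = seeds[1L])
    reps <- length(nh$nets)
    n_cells <- length(config$greedy_scenarios) *
      length(config$greedy_fractions)
    branch_seeds <- matrix(.spawn_seeds(seeds[2L],
                                        reps * (1L + 2L * n_cells)),
                           nrow = reps)
    for (r in seq_len(reps)) {
      evolved <- nh$nets[[r]]
      control <- .short_branch(evolved, goal_function(goal),
                               config$short_iters, branch_seeds[r, 1L],
                               config$input_rate)
      cell <- 0L
      for (scen in config$greedy_scenarios) {
        for (frac in config$greedy_fractions) {
          cell <- cell + 1L
          gnodes <- select_greedy_nodes(evolved, frac,
                                        seed = branch_seeds[r, 2L * cell])
          greedy <- .short_branch(evolved,
                                  goal_function(scen, gnodes),
                                  config$short_iters,
                                  branch_seeds[r, 2L * cell + 1L],
                                  config$input_rate)
          rec <- .compare_endpoints(control, greedy, goal, gnodes,
                                    config$input_rate)
          all_records[[length(all_records) + 1L]] <-
            cbind(data.frame(replicate = r, goal = goal,
                             scenario = scen, size = size,
                             fraction = frac),
                  rec)
        }
      }
      if (progress && r %% 10L == 0L)
        message(sprintf("  replicate %d/%d done", r, reps))
    }
  }
  records <- do.call(rbind, all_records)
  rownames(records) <- NULL
  summary <- surpass_percentages(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  list(records = records, summary = summary)
}

#' Surpass percentages per experimental cell
#'
#' For every (goal, scenario, size, fraction) cell: the percentage of
#' replicates whose greedy branch surpassed the control in scarcity
#' tolerance (`b_diff < 0`), in systemic-goal performance (`goal_diff <
#' 0`), and in both at once, together with quartiles of the two
#' normalized differences.
#'
#' @param records Record table from [run_experiment()] or stacked
#'   [run_branch_pair()] rows.
#' @return Data frame, one row per cell.
#' @export
surpass_percentages <- function(records) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  grp <- interaction(records$goal, records$scenario, records$size,
                     records$fraction, drop = TRUE)
  rows <- lapply(split(records, grp), function(d) {
    qb <- stats::quantile(d$b_diff, c(0.25, 0.5, 0.75), names = FALSE)
    qg <- stats::quantile(d$goal_diff, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(goal = d$goal[1L], scenario = d$scenario[1L],
               size = d$size[1L], fraction = d$fraction[1L],
               n = nrow(d),
               pct_b_surpass = 100 * mean(d$b_diff < 0),
               pct_goal_surpass = 100 * mean(d$goal_diff < 0),
               pct_both_surpass = 100 * mean(d$b_diff < 0 &
                                               d$goal_diff < 0),
               b_diff_q25 = qb[1L], b_diff_median = qb[2L],
               b_diff_q75 = qb[3L],
               goal_diff_q25 = qg[1L], goal_diff_median = qg[2L],
               goal_diff_q75 = qg[3L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$goal, out$scenario, out$size, out$fraction), ]
}

#' Tolerance-performance relation among "better greedy" networks
#'
#' Ordinary least-squares fit of `goal_diff` on `b_diff` restricted to
#' the records where the greedy branch surpassed the control in both
#' scarcity tolerance and performance (both differences negative).  A
#' positive slope with strong correlation indicates that greedy
#' branches gaining tolerance gain performance in proportion.
#'
#' @param records Record table with `b_diff` and `goal_diff` columns.
#' @return List with `computable`, `n`, and (when computable) `slope`,
#'   `intercept`, `r` (Pearson).
#' @export
diff_scatter_stats <- function(records) {
  d <- records[records$b_diff < 0 & records$goal_diff < 0, , drop = FALSE]
  if (nrow(d) < 3L)
    return(list(computable = FALSE, n = nrow(d)))
  fit <- stats::lm(goal_diff ~ b_diff, data = d)
  list(computable = TRUE, n = nrow(d),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r = stats::cor(d$b_diff, d$goal_diff))
}

#' Greedy output links versus scarcity tolerance
#'
#' Tests whether greedy branches whose greedy nodes hold fewer direct
#' arcs to the output node tend to tolerate scarcity better, via the
#' Spearman rank correlation between the per-record count of greedy
#' node-to-output links and `b_diff`, plus a binned summary (mean
#' `b_diff` per out-link count).  A positive correlation means more
#' output links go with larger (worse for greedy) `b_diff`.
#'
#' @param records Record table with `greedy_out_links` and `b_diff`.
#' @return List with `computable`, `n`, and (when computable)
#'   `spearman_rho` and `by_out_links` (data frame: `out_links`,
#'   `mean_b_diff`, `n`).
#' @export
link_vs_diff_analysis <- function(records) {
  n <- nrow(records)
  if (n < 3L || length(unique(records$greedy_out_links)) < 2L)
    return(list(computable = FALSE, n = n))
  rho <- stats::cor(records$greedy_out_links, records$b_diff,
                    method = "spearman")
  bins <- lapply(split(records, records$greedy_out_links), function(d)
    data.frame(out_links = d$greedy_out_links[1L],
               mean_b_diff = mean(d$b_diff), n = nrow(d)))
  by_links <- do.call(rbind, bins)
  rownames(by_links) <- NULL
  list(computable = TRUE, n = n, spearman_rho = rho,
       by_out_links = by_links[order(by_links$out_links), ])
}

#' Pairwise correlations among systemic indexes across an ensemble
#'
#' Computes the index bundle of every network and returns the Pearson
#' correlation matrix of TST, AMI, ascendency, EDiff, the Finn total
#' and the decay rate `b`.  Indexes with zero variance across the
#' ensemble get `NA` rows/columns.
#'
#' @param nets List of [fcdn] objects (at least 3).
#' @param input_rate Energy per iteration delivered by the input node.
#' @return Symmetric 6 x 6 correlation matrix.
#' @export
goal_correlation_matrix <- function(nets, input_rate = 1) {
  stopifnot(length(nets) >= 3L)
  vals <- t(vapply(nets, function(nt) {
    bd <- index_bundle(nt, input_rate)
    c(tst = bd$tst, ami = bd$ami, asc = bd$asc, ediff = bd$ediff,
      finn = bd$finn_total, b = bd$b)
  }, numeric(6L)))
  sds <- apply(vals, 2L, stats::sd)
  cm <- suppressWarnings(stats::cor(vals))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  diag(cm) <- ifelse(sds == 0, NA_real_, 1)
  cm
}
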