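#' Goal functions (orientors) for network evolution
#'
#' A goal function is the scalar objective that selection maximizes.
#' Systemic goals evaluate the whole network: `"TST"` (total system
#' throughflow), `"AMI"` (average mutual information), `"ASC"`
#' (ascendency) and `"EDIFF"` (output-minus-input flow entropy).
#' Greedy goals evaluate a designated subset of core nodes, emulating a
#' consumer strategy that drives the system toward its own demands:
#' `"ABS_FLOW"` (summed steady-state throughflow of the greedy nodes),
#' `"PROP_FLOW"` (their share of total core throughflow), `"ABS_FINN"`
#' (summed per-node Finn cycling of the greedy nodes) and `"PROP_FINN"`
#' (their share of total cycling).  The absolute variants permit
#' synergies with whole-system growth; the proportional variants select
#' only changes that sequester flow relative to the rest of the
#' network.
#'
#' @param name One of `"TST"`, `"AMI"`, `"ASC"`, `"EDIFF"`,
#'   `"ABS_FLOW"`, `"PROP_FLOW"`, `"ABS_FINN"`, `"PROP_FINN"`
#'   (case-insensitive).
#' @param greedy_nodes Integer vector of core-node indices; required
#'   and non-empty for greedy goals, forbidden for systemic goals.
#' @return An object of class `"goal_function"`.
#' @examples
#' goal_function("TST")
#' goal_function("ABS_FLOW", greedy_nodes = c(1, 4, 9))
#' @export
goal_function <- function(name, greedy_nodes = NULL) {
  name <- toupper(name)
  systemic <- c("TST", "AMI", "ASC", "EDIFF")
  greedy <- c("ABS_FLOW", "PROP_FLOW", "ABS_FINN", "PROP_FINN")
  if (!name %in% c(systemic, greedy))
    stop("unknown goal function: ", name, call. = FALSE)
  is_greedy <- name %in% greedy
  if (is_greedy) {
    if (is.null(greedy_nodes) || !length(greedy_nodes))
      stop("greedy goal ", name, " requires a non-empty `greedy_nodes` set",
           call. = FALSE)
    greedy_nodes <- sort(unique(as.integer(greedy_nodes)))
  } else if (!is.null(greedy_nodes)) {
    stop("systemic goal ", name, " takes no `greedy_nodes`", call. = FALSE)
  }
  structure(list(name = name, greedy_nodes = greedy_nodes,
                 is_greedy = is_greedy),
            class = "goal_function")
}

#' @export
print.goal_function <- function(x, ...) {
  if (x$is_greedy) {
    cat(sprintf("greedy goal %s over %d node(s): %s\n", x$name,
                length(x$greedy_nodes),
                paste(x$greedy_nodes, collapse = ", ")))
  } else {
    cat(sprintf("systemic goal %s\n", x$name))
  }
  invisible(x)
}

# Fast scalar goal evaluation on the raw weight matrix.  `IN` is the
# cached N x N identity (hot loop avoids re-allocating it).
.goal_value <- function(A, n, name, greedy = NULL, rate = 1,
                        IN = diag(n)) {
  core <- seq_len(n)
  Ac <- A[core, core, drop = FALSE]
  u <- rate * A[n + 1L, core]
  x <- solve(IN - t(Ac), u)
  if (name == "ABS_FLOW") return(sum(x[greedy]))
  if (name == "PROP_FLOW") return(sum(x[greedy]) / sum(x))
  out_flow <- rowSums(Ac)  # core share of each node's unit outflow
  total <- sum(x * out_flow)
  if (name == "TST") return(total)
  if (total <= 0)
    stop("undefined index: total core throughflow is zero", call. = FALSE)
  if (name %in% c("AMI", "ASC")) {
    Tc <- x * Ac
    ri <- rowSums(Tc)
    cj <- colSums(Tc)
    pos <- which(Tc > 0, arr.ind = TRUE)
    Tij <- Tc[pos]
    a <- sum((Tij / total) *
               log2(Tij * total / (ri[pos[, 1L]] * cj[pos[, 2L]])))
    return(if (name == "AMI") a else a * total)
  }
  if (name == "EDIFF") {
    in_adj <- core[A[n + 1L, core] > 0]
    t_out <- x * A[core, n + 2L]
    t_out <- t_out[t_out > 0]
    return(.entropy2(t_out / sum(t_out)) -
             .entropy2(x[in_adj] / sum(x[in_adj])))
  }
  # Finn-based greedy goals
  L <- solve(IN - Ac)
  dL <- diag(L)
  per <- (colSums(x * Ac) / total) * (dL - 1) / dL
  g <- sum(per[greedy])
  if (name == "ABS_FINN") return(g)
  ft <- sum(per)
  if (ft <= 0) return(0)
  g / ft
}

#' Evaluate a goal function on a network
#'
#' @param net A valid [fcdn] object.
#' @param goal A [goal_function()] (or a goal name, for systemic
#'   goals).
#' @param input_rate Energy per iteration delivered by the input node.
#' @return Scalar goal value.
#' @examples
#' net <- random_fcdn(30, 0.2, seed = 1)
#' evaluate_goal(net, "TST")
#' evaluate_goal(net, goal_function("ABS_FLOW", greedy_nodes = 1:3))
#' @export
evaluate_goal <- function(net, goal, input_rate = 1) {
  stopifnot(inherits(net, "fcdn"))
  if (!inherits(goal, "goal_function")) goal <- goal_function(goal)
  if (goal$is_greedy &&
      (min(goal$greedy_nodes) < 1L || max(goal$greedy_nodes) > net$n_core))
    stop("`greedy_nodes` out of core-node range", call. = FALSE)
  .goal_value(net$adjacency, net$n_core, goal$name, goal$greedy_nodes,
              input_rate)
}

#' Mutation policies for the two evolutionary time-scales
#'
#' Large time-scale mutations model evolutionary change: a single arc
#' among core nodes may be added, deleted or reweighted (output-arc
#' weights may also change, input arcs never do).  Reweighting is
#' either a local tweak around the current value or a fresh U(0,1)
#' draw.  Equal add and delete probabilities keep connectance roughly
#' constant over an evolutionary run.  Short time-scale mutations model
#' ecological change: the arc set is frozen and a single existing
#' weight is nudged multiplicatively within `vicinity` (default 10%) of
#' its value.
#'
#' @param scale `"large"` or `"short"`.
#' @param p_add,p_delete,p_reweight Mutation-type probabilities (large
#'   scale; must sum to 1).
#' @param vicinity Relative half-width of local weight tweaks.
#' @param p_vicinity_large Probability that a large-scale reweight is a
#'   local tweak rather than a fresh U(0,1) draw.
#' @return An object of class `"mutation_policy"`.
#' @export
mutation_policy <- function(scale = c("large", "short"), p_add = 0.25,
                            p_delete = 0.25, p_reweight = 0.5,
                            vicinity = 0.10, p_vicinity_large = 0.5) {
  scale <- match.arg(scale)
  p <- c(p_add, p_delete, p_reweight)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("mutation-type probabilities must be nonnegative and sum to 1",
         call. = FALSE)
  if (vicinity < 0 || p_vicinity_large < 0 || p_vicinity_large > 1)
    stop("invalid vicinity parameters", call. = FALSE)
  structure(list(scale = scale, p_add = p_add, p_delete = p_delete,
                 p_reweight = p_reweight, vicinity = vicinity,
                 p_vicinity_large = p_vicinity_large),
            class = "mutation_policy")
}

# pick one existing mutable arc (core-core or core->out; never input
# arcs); returns c(row, col) into the full matrix
.pick_mutable_arc <- function(A, n) {
  out <- n + 2L
  sub <- A[seq_len(n), c(seq_len(n), out), drop = FALSE]
  arcs <- which(sub > 0)
  k <- arcs[sample.int(length(arcs), 1L)]
  i <- ((k - 1L) %% n) + 1L
  j <- ((k - 1L) %/% n) + 1L
  if (j > n) j <- out
  c(i, j)
}

.mutate_short_A <- function(A, n, vicinity) {
  ij <- .pick_mutable_arc(A, n)
  A[ij[1L], ij[2L]] <- A[ij[1L], ij[2L]] *
    stats::runif(1, 1 - vicinity, 1 + vicinity)
  A[ij[1L], ] <- A[ij[1L], ] / sum(A[ij[1L], ])
  A
}

# `ref_density` anchors structural mutations: when the current core
# density sits below the reference a structural move becomes an add,
# above it a delete; at the reference the drawn type stands.  The total
# structural probability stays p_add + p_delete, so links are lost and
# created with the same probability around the reference, and realized
# connectance cannot drift even though selection filters the two move
# types asymmetrically.  NULL anchors at the current density.
.mutate_large_A <- function(A, n, policy, ref_density = NULL) {
  core <- seq_len(n)
  out <- n + 2L
  type <- sample.int(3L, 1L, prob = c(policy$p_add, policy$p_delete,
                                      policy$p_reweight))
  if (type != 3L && !is.null(ref_density)) {
    dens <- sum(A[core, core] > 0) / (n * (n - 1L))
    if (dens < ref_density) type <- 1L
    else if (dens > ref_density) type <- 2L
  }
  if (type == 1L) {  # add a core-core arc
    Acc <- A[core, core, drop = FALSE]
    absent <- which(Acc == 0)
    absent <- absent[((absent - 1L) %% n) != ((absent - 1L) %/% n)]
    if (!length(absent)) {
      type <- 3L  # saturated core: fall back to reweight
    } else {
      k <- absent[sample.int(length(absent), 1L)]
      i <- ((k - 1L) %% n) + 1L
      j <- ((k - 1L) %/% n) + 1L
      A[i, j] <- stats::runif(1)
      A[i, ] <- A[i, ] / sum(A[i, ])
      return(A)
    }
  }
  if (type == 2L) {  # delete a core-core arc (repair restores validity)
    Acc <- A[core, core, drop = FALSE]
    present <- which(Acc > 0)
    if (!length(present)) {
      type <- 3L
    } else {
      for (try in 1:3) {
        k <- present[sample.int(length(present), 1L)]
        i <- ((k - 1L) %% n) + 1L
        j <- ((k - 1L) %/% n) + 1L
        B <- A
        B[i, j] <- 0
        if (sum(B[i, ]) <= 0) B[i, out] <- 1 else
          B[i, ] <- B[i, ] / sum(B[i, ])
        B <- .repair_A(B, n)
        if (B[i, j] == 0) return(B)  # repair did not re-add the arc
      }
      return(A)  # retries exhausted: skip this mutation
    }
  }
  # reweight an existing mutable arc
  ij <- .pick_mutable_arc(A, n)
  A[ij[1L], ij[2L]] <-
    if (stats::runif(1) < policy$p_vicinity_large)
      A[ij[1L], ij[2L]] * stats::runif(1, 1 - policy$vicinity,
                                       1 + policy$vicinity)
    else stats::runif(1)
  A[ij[1L], ] <- A[ij[1L], ] / sum(A[ij[1L], ])
  A
}

#' Propose one large time-scale mutation
#'
#' Applies a single structural mutation — add, delete or reweight of a
#' core-core arc, or reweight of a core-to-output arc — according to
#' the policy probabilities, renormalizes the affected row, and repairs
#' reachability where a deletion broke it.  Input arcs are never
#' touched.  The result is always a valid FCDN.
#'
#' When `ref_density` is given, structural moves are anchored to it:
#' below the reference density the move is an add, above it a delete.
#' [evolve()] anchors at the starting network's density, which holds
#' connectance roughly constant over an evolutionary run even though
#' selection accepts adds and deletes at different rates.
#'
#' @param net A valid [fcdn] object.
#' @param policy A large-scale [mutation_policy()].
#' @param seed Optional integer seed.
#' @param ref_density Optional reference core-arc density in \[0, 1\].
#' @return A mutated, valid [fcdn].
#' @export
mutate_large <- function(net, policy = mutation_policy("large"),
                         seed = NULL, ref_density = NULL) {
  stopifnot(inherits(net, "fcdn"), inherits(policy, "mutation_policy"))
  if (!is.null(seed)) set.seed(seed)
  fcdn(.mutate_large_A(unname(net$adjacency), net$n_core, policy,
                       ref_density),
       labels = net$labels)
}

#' Propose one short time-scale mutation
#'
#' Multiplies the weight of one existing mutable arc (core-core or
#' core-to-output, never an input arc) by a factor drawn uniformly from
#' `(1 - vicinity, 1 + vicinity)` and renormalizes the row.  The arc
#' set is exactly preserved: no arc is created or destroyed.
#'
#' @inheritParams mutate_large
#' @param policy A short-scale [mutation_policy()] (its `vicinity` is
#'   used).
#' @return A mutated, valid [fcdn] with the same arc set as `net`.
#' @export
mutate_short <- function(net, policy = mutation_policy("short"),
                         seed = NULL) {
  stopifnot(inherits(net, "fcdn"), inherits(policy, "mutation_policy"))
  if (!is.null(seed)) set.seed(seed)
  fcdn(.mutate_short_A(unname(net$adjacency), net$n_core,
                       policy$vicinity),
       labels = net$labels)
}

#' Randomly designate greedy core nodes
#'
#' Samples `round(fraction * n_core)` core nodes uniformly without
#' replacement (round half up, never fewer than one node).
#'
#' @param net An [fcdn] object.
#' @param fraction Fraction of core nodes to convert, in (0, 1].
#' @param seed Optional integer seed.
#' @return Sorted integer vector of core-node indices.
#' @export
select_greedy_nodes <- function(net, fraction, seed = NULL) {
  stopifnot(inherits(net, "fcdn"))
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must lie in (0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  k <- max(1L, as.integer(floor(fraction * net$n_core + 0.5)))
  sort(sample.int(net$n_core, k))
}

#' Evolve an FCDN by mutation and selection
#'
#' Hill-climbing over networks: each iteration proposes one mutation
#' (large or short time-scale, per the policy) and accepts it if and
#' only if the goal function strictly increases; accepted mutations
#' become fixed events in the network's evolutionary history.  The
#' sequence of goal values is therefore non-decreasing.  The run is
#' deterministic given `seed`.
#'
#' @param net A valid starting [fcdn].
#' @param goal A [goal_function()] or systemic goal name.
#' @param policy A [mutation_policy()] selecting the time-scale.
#' @param n_iter Number of mutation proposals (>= 1).
#' @param seed Optional integer seed.
#' @param input_rate Energy per iteration delivered by the input node.
#' @param record_b Record the decay rate `b` at every iteration?
#'   Recording costs one eigendecomposition per iteration; experiment
#'   drivers switch it off and compute `b` at the endpoints only.
#' @return An object of class `"evolution_trace"`: list with `trace`
#'   (data frame: `iteration`, `accepted`, `goal_value`, and `b` when
#'   recorded), `net` (the final [fcdn]), `goal`, `policy`, and
#'   `acceptance_rate`.
#' @examples
#' net <- random_fcdn(10, 0.25, seed = 5)
#' ev <- evolve(net, "TST", mutation_policy("large"), n_iter = 100,
#'              seed = 99)
#' ev$trace$goal_value[100] >= ev$trace$goal_value[1]
#' @export
evolve <- function(net, goal, policy = mutation_policy("large"),
                   n_iter = 500L, seed = NULL, input_rate = 1,
                   record_b = TRUE) {
  stopifnot(inherits(net, "fcdn"), inherits(policy, "mutation_policy"))
  if (!inherits(goal, "goal_function")) goal <- goal_function(goal)
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("`n_iter` must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- net$n_core
  A <- unname(net$adjacency)
  IN <- diag(n)
  short <- policy$scale == "short"
  ref_density <- if (n > 1) sum(A[seq_len(n), seq_len(n)] > 0) /
    (n * (n - 1L)) else 0
  gname <- goal$name
  gnodes <- goal$greedy_nodes
  cur <- .goal_value(A, n, gname, gnodes, input_rate, IN)
  accepted <- logical(n_iter)
  goal_value <- numeric(n_iter)
  b_trace <- if (record_b) numeric(n_iter) else NULL
  for (it in seq_len(n_iter)) {
    cand <- if (short) .mutate_short_A(A, n, policy$vicinity)
            else .mutate_large_A(A, n, policy, ref_density)
    val <- tryCatch(.goal_value(cand, n, gname, gnodes, input_rate, IN),
                    error = function(e) -Inf)
    if (is.finite(val) && val > cur) {
      A <- cand
      cur <- val
      accepted[it] <- TRUE
    }
    goal_value[it] <- cur
    if (record_b) b_trace[it] <- .decay_b(A, n)
  }
  trace <- data.frame(iteration = seq_len(n_iter), accepted = accepted,
                      goal_value = goal_value)
  if (record_b) trace$b <- b_trace
  structure(list(trace = trace, net = fcdn(A, labels = net$labels),
                 goal = goal, policy = policy,
                 acceptance_rate = mean(accepted)),
            class = "evolution_trace")
}

#' @export
print.evolution_trace <- function(x, ...) {
  n_iter <- nrow(x$trace)
  cat(sprintf("evolution trace: %d iterations (%s scale), goal %s\n",
              n_iter, x$policy$scale, x$goal$name))
  cat(sprintf("  goal: %.6g -> %.6g; acceptance rate %.3f\n",
              x$trace$goal_value[1L], x$trace$goal_value[n_iter],
              x$acceptance_rate))
  invisible(x)
}
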