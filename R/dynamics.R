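#' Leontief inverse of an FCDN core
#'
#' Computes `L = (I - A)^-1` for the core adjacency matrix `A`.  Entry
#' `L[i, j]` accumulates the direct and indirect flow contributions of
#' node `i` to node `j` over paths of every length; the diagonal
#' `L[i, i] >= 1` counts the flow returning to `i` and underpins the
#' Finn cycling index (see [finn()]).  The inverse exists for every
#' valid FCDN because dissipation keeps the core spectral radius below
#' one.
#'
#' @param net An [fcdn] object.
#' @return Numeric `N x N` matrix with unit-or-larger diagonal.
#' @export
leontief <- function(net) {
  stopifnot(inherits(net, "fcdn"))
  Ac <- core_matrix(net)
  L <- tryCatch(solve(diag(nrow(Ac)) - Ac),
                error = function(e)
                  stop("non-dissipative core: (I - A) is singular",
                       call. = FALSE))
  L
}

# steady-state throughflow vector on the raw matrix; x solves
# x = x A_core + u  with u the input delivery scaled by `rate`
.steady_x <- function(A, n, rate = 1) {
  core <- seq_len(n)
  u <- rate * A[n + 1L, core]
  if (rate == 0) return(numeric(n))
  solve(diag(n) - t(A[core, core, drop = FALSE]), u)
}

#' Steady-state throughflows
#'
#' Under a constant energy input the discrete-time flow map
#' `x(t+1) = x(t) A_core + u` converges to the unique fixed point
#' `x* = u (I - A_core)^-1`, the vector of node throughflows (energy
#' passing through each core node per iteration).  `u` is the input
#' node's delivery vector scaled by `input_rate`.  At the fixed point
#' the total inflow equals the total flow delivered to the output node
#' (conservation).
#'
#' @param net A valid [fcdn] object.
#' @param input_rate Energy per iteration delivered by the input node.
#' @return Named numeric vector of length `n_core(net)`.
#' @examples
#' net <- random_fcdn(10, 0.3, seed = 2)
#' x <- steady_state(net)
#' sum(x * as.matrix(net)[seq_len(10), 12])  # flow to output = input rate
#' @export
steady_state <- function(net, input_rate = 1) {
  stopifnot(inherits(net, "fcdn"))
  if (input_rate < 0) stop("`input_rate` must be nonnegative", call. = FALSE)
  x <- .steady_x(net$adjacency, net$n_core, input_rate)
  stats::setNames(x, net$labels)
}

#' Realized flux matrix
#'
#' Expands a throughflow vector into per-edge fluxes `T[i, j] = x[i] *
#' A[i, j]` for every core node `i`, with the input row equal to
#' `input_rate` times the input shares.  At steady state every core
#' node is balanced: its total inflow equals its total outflow.
#'
#' @param net An [fcdn] object.
#' @param state Throughflow vector over core nodes; defaults to the
#'   steady state at `input_rate`.
#' @param input_rate Energy per iteration delivered by the input node.
#' @return `(N+2) x (N+2)` matrix of class `"flow_matrix"` (attribute
#'   `n_core` records the core block size).
#' @export
flux_matrix <- function(net, state = NULL, input_rate = 1) {
  stopifnot(inherits(net, "fcdn"))
  n <- net$n_core
  if (is.null(state)) state <- .steady_x(net$adjacency, n, input_rate)
  if (length(state) != n)
    stop("`state` must have length n_core = ", n, call. = FALSE)
  A <- net$adjacency
  Tm <- matrix(0, n + 2L, n + 2L, dimnames = dimnames(A))
  Tm[seq_len(n), ] <- state * A[seq_len(n), , drop = FALSE]
  Tm[net$input, ] <- input_rate * A[net$input, ]
  structure(Tm, n_core = n, class = c("flow_matrix", "matrix"))
}

#' Input schedule for flow simulations
#'
#' Describes when and how strongly the input node fires.  With period
#' `p` above zero the input operates only every `p + 1` iterations (it
#' "misses" `p` iterations between firings); `phase` shifts the firing
#' pattern.  `t_off` cuts the input from that iteration onward, which is
#' the scarcity scenario used to measure energy decay.
#'
#' @param rate Energy delivered per active iteration (nonnegative).
#' @param period Number of missed iterations between firings
#'   (nonnegative integer; 0 means constant input).
#' @param phase Offset of the firing pattern (integer >= 0).
#' @param t_off First iteration (0-based) at which the input stops;
#'   `Inf` for never.
#' @return An object of class `"input_schedule"`.
#' @export
input_schedule <- function(rate = 1, period = 0L, phase = 0L, t_off = Inf) {
  stopifnot(rate >= 0, period >= 0, phase >= 0)
  structure(list(rate = rate, period = as.integer(period),
                 phase = as.integer(phase), t_off = t_off),
            class = "input_schedule")
}

# is the input active at (0-based) iteration t?
.schedule_on <- function(sched, t) {
  t < sched$t_off & ((t - sched$phase) %% (sched$period + 1L)) == 0L
}

#' Simulate flow dynamics
#'
#' Iterates the synchronous flow map `x(t+1) = x(t) A_core + u(t)`,
#' where `u(t)` is the input delivery vector on iterations where the
#' schedule fires and zero otherwise.  With constant input the
#' trajectory converges geometrically to [steady_state()]; with the
#' input off, total energy decays at the asymptotic rate given by
#' [decay_rate()].
#'
#' @param net A valid [fcdn] object.
#' @param schedule An [input_schedule()].
#' @param x0 Initial throughflow vector (default: all zero).
#' @param t_max Number of iterations (>= 1).
#' @return A list of class `"flow_trajectory"`: `states` is a
#'   `(t_max + 1) x N` matrix of throughflows (row `t + 1` holds
#'   iteration `t`), `total_energy` the per-iteration energy sums, and
#'   `schedule` the input schedule used.
#' @examples
#' net <- random_fcdn(5, 0.5, seed = 3)
#' tr <- simulate_flows(net, input_schedule(rate = 1), t_max = 100)
#' max(abs(tr$states[101, ] - steady_state(net)))
#' @export
simulate_flows <- function(net, schedule = input_schedule(), x0 = NULL,
                           t_max = 100L) {
  stopifnot(inherits(net, "fcdn"), inherits(schedule, "input_schedule"))
  t_max <- as.integer(t_max)
  if (t_max < 1L) stop("`t_max` must be at least 1", call. = FALSE)
  n <- net$n_core
  core <- seq_len(n)
  Ac <- net$adjacency[core, core, drop = FALSE]
  u <- schedule$rate * net$adjacency[net$input, core]
  if (is.null(x0)) x0 <- numeric(n)
  if (length(x0) != n)
    stop("`x0` must have length n_core = ", n, call. = FALSE)
  states <- matrix(0, t_max + 1L, n)
  colnames(states) <- net$labels
  states[1L, ] <- x0
  x <- as.numeric(x0)
  for (t in seq_len(t_max)) {
    x <- drop(x %*% Ac)
    if (.schedule_on(schedule, t - 1L)) x <- x + u
    states[t + 1L, ] <- x
  }
  structure(list(states = states, total_energy = rowSums(states),
                 schedule = schedule),
            class = "flow_trajectory")
}

#' @export
print.flow_trajectory <- function(x, ...) {
  n_t <- nrow(x$states) - 1L
  cat(sprintf("flow trajectory: %d iterations, %d core nodes\n",
              n_t, ncol(x$states)))
  cat(sprintf("  total energy: %.6g (start) -> %.6g (end)\n",
              x$total_energy[1L], x$total_energy[n_t + 1L]))
  invisible(x)
}

#' Export a trajectory as a tidy data frame
#'
#' @param x A `"flow_trajectory"` from [simulate_flows()].
#' @param ... Unused.
#' @return Data frame with columns `iteration`, `node`, `throughflow`,
#'   `total_energy`.
#' @export
as.data.frame.flow_trajectory <- function(x, ...) {
  n_t <- nrow(x$states)
  nodes <- colnames(x$states)
  data.frame(
    iteration = rep(seq_len(n_t) - 1L, times = length(nodes)),
    node = rep(nodes, each = n_t),
    throughflow = as.vector(x$states),
    total_energy = rep(x$total_energy, times = length(nodes))
  )
}

#' Energy-flux decay rate (scarcity tolerance)
#'
#' When the input is cut, the accumulated energy of a valid FCDN decays
#' geometrically; the asymptotic per-iteration rate is governed by the
#' dominant eigenvalue of the core adjacency matrix:
#' `b = E_max(A_core) - 1`.  Since the core matrix is nonnegative with
#' spectral radius below one, `b` lies in `[-1, 0)`; values closer to 0
#' mean the network holds its energy longer under scarcity (more
#' tolerant), values near -1 mean almost immediate dissipation.
#'
#' @param net A valid [fcdn] object.
#' @return Scalar `b` in `[-1, 0)`.
#' @examples
#' decay_rate(random_fcdn(20, 0.2, seed = 4))
#' @export
decay_rate <- function(net) {
  stopifnot(inherits(net, "fcdn"))
  .decay_b(net$adjacency, net$n_core)
}

.decay_b <- function(A, n) {
  ev <- eigen(A[seq_len(n), seq_len(n), drop = FALSE],
              only.values = TRUE)$values
  # among eigenvalues attaining the spectral radius (imprimitive cores
  # tie in modulus, e.g. a damped 2-cycle has +/-r), take the one with
  # the largest real part
  r <- max(Mod(ev))
  cand <- ev[Mod(ev) >= r - 1e-12]
  lead <- cand[which.max(Re(cand))]
  # Perron-Frobenius: the spectral radius of a nonnegative matrix is
  # attained by a real nonnegative eigenvalue
  if (abs(Im(lead)) > 1e-9)
    stop("dominant core eigenvalue is not real (|Im| = ",
         format(abs(Im(lead))), ")", call. = FALSE)
  Re(lead) - 1
}
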