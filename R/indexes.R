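#' Total system throughflow (TST)
#'
#' Sum of the realized fluxes among core nodes, `sum(T[i, j])` for
#' `i, j` core.  Boundary flows (input to core, core to output) are
#' excluded by default, following the core-restricted double sum used
#' to define the index here; set `include_boundary = TRUE` for the
#' conventional whole-network total used elsewhere in ecological
#' network analysis.  TST measures the "power" the system processes per
#' iteration.
#'
#' @param flows A `"flow_matrix"` from [flux_matrix()].
#' @param include_boundary Also count input and output flows?
#' @return Nonnegative scalar (energy per iteration).
#' @export
tst <- function(flows, include_boundary = FALSE) {
  n <- attr(flows, "n_core")
  stopifnot(!is.null(n))
  core <- seq_len(n)
  total <- sum(flows[core, core])
  if (include_boundary)
    total <- total + sum(flows[n + 1L, ]) + sum(flows[core, n + 2L])
  total
}

# entropy helper with 0 log 0 := 0, base 2
.entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Average mutual information (AMI) of the flow distribution
#'
#' Information-theoretic organization of the core flow pattern: with
#' joint flow probabilities `T[i, j] / TST` and their row/column
#' marginals, `AMI = sum (T_ij/TST) * log2(T_ij * TST / (T_i. * T_.j))`.
#' Zero flows contribute nothing.  AMI is nonnegative, invariant to a
#' uniform rescaling of all flows, and grows as the flow pattern
#' becomes more articulated (fewer, more determinate routes); it is the
#' classical "development" index of ecological network analysis.
#' Marginals are taken over core-core flows only, consistently with
#' [tst()].
#'
#' @param flows A `"flow_matrix"` from [flux_matrix()].
#' @return Nonnegative scalar, in bits.
#' @export
ami <- function(flows) {
  n <- attr(flows, "n_core")
  stopifnot(!is.null(n))
  core <- seq_len(n)
  Tc <- flows[core, core, drop = FALSE]
  total <- sum(Tc)
  if (total <= 0)
    stop("undefined index: total core throughflow is zero", call. = FALSE)
  ri <- rowSums(Tc)
  cj <- colSums(Tc)
  pos <- which(Tc > 0, arr.ind = TRUE)
  Tij <- Tc[pos]
  sum((Tij / total) * log2(Tij * total / (ri[pos[, 1L]] * cj[pos[, 2L]])))
}

#' Ascendency (ASC)
#'
#' The average mutual information of the flow pattern scaled by the
#' total system throughflow, `ASC = AMI * TST` — a joint
#' growth-and-development index: it increases when the system processes
#' more energy, organizes its flows more determinately, or both.
#'
#' @param flows A `"flow_matrix"` from [flux_matrix()].
#' @return Nonnegative scalar (bits x energy / iteration).
#' @export
ascendency <- function(flows) {
  ami(flows) * tst(flows)
}

#' Entropy difference between output and input flows (EDiff)
#'
#' Living systems are held to keep internal entropy low by exporting
#' entropy to their surroundings.  This index compares the Shannon
#' entropy of the flow distribution leaving the system with that
#' entering it: `s_in` is the entropy (base 2) of the normalized
#' throughflows of the core nodes fed directly by the input node, and
#' `s_out` the entropy of the normalized core-to-output flows.  The
#' index is `ediff = s_out - s_in`, positive when the exported flow
#' distribution carries more entropy than the imported one.  Both
#' entropies are invariant to the input rate.
#'
#' @param net The [fcdn] the flows were computed on.
#' @param flows A `"flow_matrix"` from [flux_matrix()] at steady state.
#' @return List with elements `s_in`, `s_out` (bits) and `ediff = s_out
#'   - s_in`.
#' @export
ediff <- function(net, flows) {
  stopifnot(inherits(net, "fcdn"))
  n <- net$n_core
  core <- seq_len(n)
  in_adj <- core[net$adjacency[net$input, core] > 0]
  if (!length(in_adj))
    stop("no core node receives the input", call. = FALSE)
  # throughflow of an input-adjacent node = its total outflow
  x_in <- rowSums(flows[in_adj, , drop = FALSE])
  t_out <- flows[core, net$output]
  t_out <- t_out[t_out > 0]
  if (!length(t_out))
    stop("no core node sends flow to the output", call. = FALSE)
  s_in <- .entropy2(x_in / sum(x_in))
  s_out <- .entropy2(t_out / sum(t_out))
  list(s_in = s_in, s_out = s_out, ediff = s_out - s_in)
}

#' Finn cycling index
#'
#' Fraction of the total system throughflow that cycles, i.e. returns
#' to a node it already passed.  From the Leontief inverse `L = (I -
#' A_core)^-1`, the fraction of node `i`'s throughflow that returns to
#' `i` is `(L[i,i] - 1) / L[i,i]`; weighting it by node `i`'s share of
#' core inflow gives the per-node index
#' `finn_i = (sum_j T[j, i] / TST) * (L[i,i] - 1) / L[i,i]`, and the
#' total index is the sum over nodes.  Acyclic cores give exactly zero.
#'
#' @param net The [fcdn] the flows were computed on.
#' @param flows A `"flow_matrix"` from [flux_matrix()] at steady state.
#' @return List with `finn_total` (fraction in `[0, 1)`) and
#'   `finn_per_node` (named vector summing to `finn_total`).
#' @export
finn <- function(net, flows) {
  stopifnot(inherits(net, "fcdn"))
  n <- net$n_core
  core <- seq_len(n)
  total <- sum(flows[core, core])
  if (total <= 0)
    stop("undefined index: total core throughflow is zero", call. = FALSE)
  L <- leontief(net)
  dL <- diag(L)
  inflow <- colSums(flows[core, core, drop = FALSE])
  per_node <- stats::setNames((inflow / total) * (dL - 1) / dL, net$labels)
  list(finn_total = sum(per_node), finn_per_node = per_node)
}

#' All systemic indexes of an FCDN in one call
#'
#' Convenience wrapper: computes the steady state, the realized flux
#' matrix and every systemic index — TST, AMI, ascendency, input/output
#' entropies and their difference, the Finn cycling index (total and
#' per node) and the energy-flux decay rate `b`.
#'
#' @param net A valid [fcdn] object.
#' @param input_rate Energy per iteration delivered by the input node.
#' @return List of class `"index_bundle"` with fields `tst`, `ami`,
#'   `asc`, `s_in`, `s_out`, `ediff`, `finn_total`, `finn_per_node`,
#'   `b`.
#' @examples
#' index_bundle(random_fcdn(30, 0.2, seed = 7))
#' @export
index_bundle <- function(net, input_rate = 1) {
  stopifnot(inherits(net, "fcdn"))
  fl <- flux_matrix(net, input_rate = input_rate)
  tst_v <- tst(fl)
  ami_v <- ami(fl)
  ed <- ediff(net, fl)
  fn <- finn(net, fl)
  structure(
    list(tst = tst_v, ami = ami_v, asc = ami_v * tst_v,
         s_in = ed$s_in, s_out = ed$s_out, ediff = ed$ediff,
         finn_total = fn$finn_total, finn_per_node = fn$finn_per_node,
         b = decay_rate(net)),
    class = "index_bundle"
  )
}

#' @export
print.index_bundle <- function(x, ...) {
  cat("systemic indexes\n")
  cat(sprintf("  TST   %.6g energy/iter\n", x$tst))
  cat(sprintf("  AMI   %.6g bits\n", x$ami))
  cat(sprintf("  ASC   %.6g bits*energy/iter\n", x$asc))
  cat(sprintf("  EDiff %.6g bits (S_out %.6g - S_in %.6g)\n",
              x$ediff, x$s_out, x$s_in))
  cat(sprintf("  Finn  %.6g (cycled fraction)\n", x$finn_total))
  cat(sprintf("  b     %.6g (scarcity tolerance)\n", x$b))
  invisible(x)
}

#' Flatten an index bundle to a one-row data frame
#'
#' Scalar fields only (the per-node Finn vector is dropped), suitable
#' for stacking into per-network CSV result tables.
#'
#' @param x An `"index_bundle"`.
#' @param ... Unused.
#' @return One-row data frame.
#' @export
as.data.frame.index_bundle <- function(x, ...) {
  data.frame(tst = x$tst, ami = x$ami, asc = x$asc, s_in = x$s_in,
             s_out = x$s_out, ediff = x$ediff,
             finn_total = x$finn_total, b = x$b)
}

#' Count directed simple cycles
#'
#' Enumerates (by counting) the directed simple cycles of length >= 2
#' among the core nodes, using a Johnson-style blocked backtracking
#' search implemented in C++.  Self-loops are ignored.  The number of
#' cycles explodes combinatorially — the complete digraph on `n` nodes
#' holds `sum_{k=2}^{n} choose(n, k) (k-1)!` of them, over a million
#' already at `n = 10` — so exhaustive counting is guarded by
#' `max_nodes`.
#'
#' @param net An [fcdn] (its core block is used) or a square adjacency
#'   matrix of an arbitrary digraph (nonzero = arc).
#' @param max_nodes Guard on the node count for exhaustive enumeration.
#' @return Cycle count (numeric, exact for counts below 2^53).
#' @examples
#' count_cycles(matrix(1, 3, 3) - diag(3))  # 5 cycles in complete K3
#' @export
count_cycles <- function(net, max_nodes = 12L) {
  M <- if (inherits(net, "fcdn")) core_matrix(net) else net
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  n <- nrow(M)
  if (n > max_nodes)
    stop("exhaustive cycle enumeration guarded at ", max_nodes,
         " nodes (got ", n, "); counts grow super-exponentially",
         call. = FALSE)
  if (n < 2L) return(0)
  adj <- M != 0
  diag(adj) <- FALSE
  count_cycles_cpp(adj)
}
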