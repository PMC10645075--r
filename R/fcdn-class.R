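#' Flowing connected directed networks (FCDN)
#'
#' An FCDN is a weighted digraph on `N + 2` nodes: `N` core nodes
#' (internal energy forms), one input node and one output node.  The
#' adjacency matrix holds, in entry `A[i, j]`, the share of node `i`'s
#' outflow sent to node `j`, so every row with outgoing flow (the input
#' node and every core node) sums to exactly one and the output node's
#' row is all zero.  Self-loops are forbidden, nothing flows back into
#' the input, every core node is reachable from the input and the output
#' is reachable from every core node.  Dissipation through the output
#' makes the core submatrix strictly substochastic, so its spectral
#' radius is below one and steady states exist for any constant input.
#'
#' `fcdn()` wraps a full `(N+2) x (N+2)` weight matrix, with core nodes
#' in rows/columns `1..N`, the input node at `N + 1` and the output node
#' at `N + 2`.  The constructor checks structure (shape, node count);
#' use [validate_fcdn()] for the full invariant audit.
#'
#' @param adjacency Square numeric matrix of nonnegative weights,
#'   `(n_core + 2) x (n_core + 2)`, core nodes first, then input, then
#'   output.
#' @param labels Optional character vector of core-node names (length
#'   `n_core`).  Defaults to `n1..nN`; the boundary nodes are always
#'   labelled `"in"` and `"out"`.
#' @return An object of class `"fcdn"`: a list with elements
#'   `adjacency`, `n_core`, `input`, `output`, `labels`.
#' @seealso [random_fcdn()], [validate_fcdn()], [repair_fcdn()]
#' @examples
#' A <- matrix(0, 4, 4)
#' A[3, 1] <- 1            # in -> n1
#' A[1, 2] <- 0.5          # n1 -> n2
#' A[1, 4] <- 0.5          # n1 -> out
#' A[2, 4] <- 1            # n2 -> out
#' net <- fcdn(A)
#' net
#' @export
fcdn <- function(adjacency, labels = NULL) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency))
    stop("`adjacency` must be a numeric matrix", call. = FALSE)
  n_tot <- nrow(adjacency)
  if (ncol(adjacency) != n_tot)
    stop("`adjacency` must be square", call. = FALSE)
  n_core <- n_tot - 2L
  if (n_core < 1L)
    stop("an FCDN needs at least one core node (matrix of size >= 3)",
         call. = FALSE)
  if (is.null(labels)) {
    labels <- paste0("n", seq_len(n_core))
  } else if (length(labels) != n_core) {
    stop("`labels` must have length n_core = ", n_core, call. = FALSE)
  }
  dimnames(adjacency) <- rep(list(c(labels, "in", "out")), 2L)
  structure(
    list(adjacency = adjacency, n_core = n_core,
         input = n_core + 1L, output = n_core + 2L, labels = labels),
    class = "fcdn"
  )
}

#' Number of core nodes of an FCDN
#' @param net An [fcdn] object.
#' @return Integer count of core nodes.
#' @export
n_core <- function(net) {
  stopifnot(inherits(net, "fcdn"))
  net$n_core
}

#' Core adjacency submatrix
#'
#' The `N x N` block of the adjacency matrix restricted to core nodes.
#' For every valid FCDN this matrix is substochastic with spectral
#' radius strictly below one, which drives both the existence of steady
#' states and the energy-flux decay rate (see [decay_rate()]).
#'
#' @param net An [fcdn] object.
#' @return Numeric `N x N` matrix.
#' @export
core_matrix <- function(net) {
  stopifnot(inherits(net, "fcdn"))
  n <- net$n_core
  net$adjacency[seq_len(n), seq_len(n), drop = FALSE]
}

#' @export
as.matrix.fcdn <- function(x, ...) x$adjacency

#' @export
print.fcdn <- function(x, ...) {
  n <- x$n_core
  A <- x$adjacency
  core <- seq_len(n)
  n_arcs <- sum(A[core, core] > 0)
  dens <- if (n > 1) n_arcs / (n * (n - 1)) else NA_real_
  cat(sprintf("FCDN with %d core nodes\n", n))
  cat(sprintf("  core-core arcs: %d (connectance %.3f)\n", n_arcs, dens))
  cat(sprintf("  input feeds %d core node(s); %d core node(s) reach output directly\n",
              sum(A[x$input, core] > 0), sum(A[core, x$output] > 0)))
  invisible(x)
}

# internal: index helpers used throughout the package
.core_idx <- function(net) seq_len(net$n_core)
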