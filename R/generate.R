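#' Row-normalize outflow shares
#'
#' Rescales each input/core row of a weight matrix so it sums to one,
#' turning raw weights into outflow shares.  The output node's row is
#' left untouched.  A core (or input) row that sums to zero cannot be
#' normalized and is an error; repair such matrices first with
#' [repair_fcdn()].
#'
#' @param mat Numeric matrix, either a full `(N+2) x (N+2)` FCDN weight
#'   matrix (input row `N+1`, output row `N+2`) or any matrix whose rows
#'   should all be normalized when `rows` is given.
#' @param rows Integer vector of rows to normalize.  Default: all rows
#'   except the last (the output row of a full FCDN matrix).
#' @return The matrix with the selected rows scaled to unit sum.
#' @examples
#' normalize_rows(matrix(c(1, 1, 2, 0, 0, 0), 2, 3, byrow = TRUE), rows = 1)
#' @export
normalize_rows <- function(mat, rows = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(mat < 0))
    stop("negative weights cannot be normalized", call. = FALSE)
  if (is.null(rows)) rows <- seq_len(nrow(mat) - 1L)
  s <- rowSums(mat[rows, , drop = FALSE])
  if (any(s <= 0)) {
    bad <- rows[s <= 0]
    stop("cannot normalize zero-sum row(s) at node(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mat[rows, ] <- mat[rows, , drop = FALSE] / s
  mat
}

# Directed reachability from `start` over arcs with positive weight,
# by frontier expansion on the adjacency matrix (transpose = FALSE) or
# its reverse (transpose = TRUE, i.e. which nodes can reach `start`).
.reachable <- function(A, start, transpose = FALSE) {
  if (transpose) A <- t(A)
  n <- nrow(A)
  seen <- logical(n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- which(colSums(A[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Repair a weight matrix into a valid FCDN
#'
#' Takes a nonnegative weight matrix with the FCDN node layout (core
#' nodes first, input at `N+1`, output at `N+2`) and makes the minimal
#' set of changes needed for validity: self-loops, flows into the input
#' and output-row entries are zeroed; an empty input row is given one
#' arc to a random core node; every core node with no outgoing arc is
#' wired to the output (weight 1); core nodes unreachable from the input
#' receive an arc from a uniformly chosen already-reachable node (weight
#' drawn from U(0,1)); core nodes that cannot reach the output receive
#' an arc to the output (weight drawn from U(0,1)); finally every
#' modified row is renormalized.  Already-valid networks are returned
#' unchanged (and consume no random numbers), so the repair is
#' idempotent.
#'
#' @param candidate Numeric `(N+2) x (N+2)` weight matrix or an [fcdn]
#'   object.
#' @param labels Optional core-node labels, passed to [fcdn()].
#' @return A valid [fcdn] object.
#' @examples
#' set.seed(1)
#' net <- repair_fcdn(matrix(0, 5, 5))  # all-zero 3-core matrix
#' validate_fcdn(net)$is_valid
#' @export
repair_fcdn <- function(candidate, labels = NULL) {
  if (inherits(candidate, "fcdn")) {
    if (is.null(labels)) labels <- candidate$labels
    candidate <- candidate$adjacency
  }
  stopifnot(is.matrix(candidate), is.numeric(candidate))
  if (any(candidate < 0))
    stop("cannot repair a matrix with negative weights", call. = FALSE)
  n <- nrow(candidate) - 2L
  if (n < 1L) stop("cannot repair: no core nodes", call. = FALSE)
  A <- .repair_A(unname(candidate), n)
  fcdn(A, labels = labels)
}

# Core of the repair procedure, on the raw matrix.  Renormalizes only
# rows it touches (callers renormalize rows they changed themselves).
.repair_A <- function(A, n) {
  core <- seq_len(n)
  inp <- n + 1L
  out <- n + 2L
  diag(A) <- 0
  A[, inp] <- 0
  A[out, ] <- 0

  # input must feed at least one core node
  A[inp, out] <- 0
  if (sum(A[inp, ]) <= 0) {
    A[inp, sample.int(n, 1L)] <- 1
  } else {
    A[inp, ] <- A[inp, ] / sum(A[inp, ])
  }

  # every core node needs an outgoing arc
  dangling <- core[rowSums(A[core, , drop = FALSE]) <= 0]
  A[dangling, out] <- 1

  # forward reachability from the input
  repeat {
    seen <- .reachable(A, inp)
    lost <- core[!seen[core]]
    if (!length(lost)) break
    # the input row is never touched here: it already feeds >= 1 core
    # node, so the reachable core set is nonempty
    donors <- core[seen[core]]
    donor <- donors[sample.int(length(donors), 1L)]
    A[donor, lost[1L]] <- stats::runif(1)
    A[donor, ] <- A[donor, ] / sum(A[donor, ])
  }

  # every core node must reach the output
  drains <- .reachable(A, out, transpose = TRUE)
  stuck <- core[!drains[core]]
  if (length(stuck)) {
    A[cbind(stuck, out)] <- stats::runif(length(stuck))
    A[stuck, ] <- A[stuck, , drop = FALSE] / rowSums(A[stuck, , drop = FALSE])
  }

  # renormalize any core row not already at unit sum
  s <- rowSums(A[core, , drop = FALSE])
  off <- core[abs(s - 1) > 1e-12]
  if (length(off))
    A[off, ] <- A[off, , drop = FALSE] / s[off]
  A
}

#' Generate a random FCDN
#'
#' Draws a random flowing connected directed network: each ordered
#' core-core pair (and each core-to-output arc) is present independently
#' with probability `connectance`, arc weights are drawn from U(0,1) and
#' row-normalized, and the input node feeds `max(1, round(connectance *
#' n_core))` uniformly chosen core nodes.  The draw is then passed
#' through the repair step of [repair_fcdn()] so the result is always a
#' valid FCDN.  Realized core-to-core density is tied to `connectance`
#' (binomially, plus the occasional repair arc), and stays within a few
#' percentage points of it for the network sizes used here.
#'
#' @param n_core Number of core nodes (at least 2).
#' @param connectance Target fraction of the `n_core * (n_core - 1)`
#'   possible core-to-core arcs, in (0, 1].
#' @param seed Optional integer seed; the draw is deterministic given
#'   the seed.
#' @return A valid [fcdn] object.
#' @examples
#' net <- random_fcdn(30, connectance = 0.2, seed = 7)
#' validate_fcdn(net)$is_valid
#' @export
random_fcdn <- function(n_core, connectance = 0.2, seed = NULL) {
  n_core <- as.integer(n_core)
  if (n_core < 2L)
    stop("`n_core` must be at least 2", call. = FALSE)
  if (!is.numeric(connectance) || connectance <= 0 || connectance > 1)
    stop("`connectance` must lie in (0, 1]", call. = FALSE)
  if (connectance * n_core * (n_core - 1L) < n_core)
    stop("infeasible connectance: ", connectance, " * ", n_core, " * ",
         n_core - 1L, " < ", n_core,
         " leaves some core node without an arc", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- n_core
  core <- seq_len(n)
  inp <- n + 1L
  out <- n + 2L
  A <- matrix(0, n + 2L, n + 2L)

  # core-core arcs: independent Bernoulli(connectance), U(0,1) weights
  present <- matrix(stats::runif(n * n) < connectance, n, n)
  diag(present) <- FALSE
  A[core, core][present] <- stats::runif(sum(present))

  # each core node dissipates to the output with the same probability
  leaks <- stats::runif(n) < connectance
  A[core[leaks], out] <- stats::runif(sum(leaks))

  # the input feeds ~connectance * n core nodes (at least one)
  k_in <- max(1L, as.integer(round(connectance * n)))
  fed <- sample.int(n, k_in)
  A[inp, fed] <- stats::runif(k_in)
  A[inp, ] <- A[inp, ] / sum(A[inp, ])

  norm <- rowSums(A[core, , drop = FALSE])
  pos <- core[norm > 0]
  A[pos, ] <- A[pos, , drop = FALSE] / norm[pos]

  fcdn(.repair_A(A, n))
}
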