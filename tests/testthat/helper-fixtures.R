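# Reference toy networks (input rate 1) used across the suite.
#
# chain: in -> n1 (1.0); n1 -> n2 (0.5), n1 -> out (0.5); n2 -> out (1.0)
toy_chain <- function() {
  A <- matrix(0, 4, 4)
  A[3, 1] <- 1
  A[1, 2] <- 0.5
  A[1, 4] <- 0.5
  A[2, 4] <- 1
  fcdn(A)
}

# cycle: as chain but n2 returns half its flow to n1
toy_cycle <- function() {
  A <- matrix(0, 4, 4)
  A[3, 1] <- 1
  A[1, 2] <- 0.5
  A[1, 4] <- 0.5
  A[2, 1] <- 0.5
  A[2, 4] <- 0.5
  fcdn(A)
}

# random network with a connectance that is always feasible for n
random_net <- function(n, connectance = 0.25) {
  random_fcdn(n, min(1, max(connectance, 1.2 / (n - 1))))
}

# independent steady-state oracle: plain fixed-point iteration of
# x <- x A_core + u, never touching the package's linear solve
fp_steady <- function(net, input_rate = 1, steps = 200) {
  A <- unname(as.matrix(net))
  n <- n_core(net)
  core <- seq_len(n)
  Ac <- A[core, core, drop = FALSE]
  u <- input_rate * A[n + 1, core]
  x <- numeric(n)
  for (i in seq_len(steps)) x <- drop(x %*% Ac) + u
  x
}

# independent cycle-count oracle: naive DFS that enumerates each
# directed simple cycle once, anchored at its smallest vertex
brute_count_cycles <- function(adj) {
  n <- nrow(adj)
  adj <- adj != 0
  diag(adj) <- FALSE
  count <- 0L
  visit <- function(v, start, onpath) {
    for (w in which(adj[v, ])) {
      if (w == start) count <<- count + 1L
      else if (w > start && !onpath[w]) {
        onpath[w] <- TRUE
        visit(w, start, onpath)
        onpath[w] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    onpath <- logical(n)
    onpath[s] <- TRUE
    visit(s, s, onpath)
  }
  count
}

# closed form: number of directed simple cycles in the complete
# digraph on n nodes
complete_digraph_cycles <- function(n) {
  sum(vapply(2:n, function(k) choose(n, k) * factorial(k - 1), 0))
}
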