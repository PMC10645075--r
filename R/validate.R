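#' Validate an FCDN against all structural invariants
#'
#' Audits every defining rule of a flowing connected directed network
#' and reports all violations (not just the first):
#' \itemize{
#'   \item no self-loops (zero diagonal);
#'   \item all weights in \[0, 1\];
#'   \item input and core rows sum to exactly 1 (within `tol`); the
#'     output row is all zero;
#'   \item nothing flows into the input node (zero input column);
#'   \item every core node is reachable from the input, and the output
#'     is reachable from every core node, over positive-weight arcs;
#'   \item the core submatrix has spectral radius strictly below one
#'     (dissipativity).
#' }
#' Malformed networks yield a report, never an error.
#'
#' @param net An [fcdn] object (or a full weight matrix, which is
#'   wrapped first).
#' @param tol Numeric tolerance for the row-sum check.
#' @return A list of class `"fcdn_validation"` with elements
#'   `is_valid` (logical) and `violations` (data frame with columns
#'   `rule` and `where`).
#' @examples
#' validate_fcdn(random_fcdn(10, 0.3, seed = 1))
#' @export
validate_fcdn <- function(net, tol = 1e-9) {
  if (!inherits(net, "fcdn")) net <- fcdn(net)
  A <- net$adjacency
  n <- net$n_core
  core <- seq_len(n)
  inp <- net$input
  out <- net$output
  lab <- c(net$labels, "in", "out")
  rules <- character()
  where <- character()
  add <- function(rule, nodes) {
    rules <<- c(rules, rep(rule, length(nodes)))
    where <<- c(where, nodes)
  }

  loops <- which(diag(A) != 0)
  if (length(loops)) add("self-loop", lab[loops])

  bad_w <- which(A < 0 | A > 1, arr.ind = TRUE)
  if (nrow(bad_w))
    add("weight outside [0,1]",
        paste0(lab[bad_w[, 1]], "->", lab[bad_w[, 2]]))

  rs <- rowSums(A)
  off <- c(core, inp)[abs(rs[c(core, inp)] - 1) > tol]
  if (length(off)) add("row sum != 1", lab[off])
  if (rs[out] != 0) add("output row not zero", lab[out])

  if (any(A[, inp] != 0))
    add("flow into input", lab[which(A[, inp] != 0)])

  seen <- .reachable(A, inp)
  lost <- core[!seen[core]]
  if (length(lost)) add("unreachable from input", lab[lost])

  drains <- .reachable(A, out, transpose = TRUE)
  stuck <- core[!drains[core]]
  if (length(stuck)) add("cannot reach output", lab[stuck])

  if (n >= 1) {
    rho <- max(Mod(eigen(A[core, core, drop = FALSE],
                         only.values = TRUE)$values))
    if (!is.finite(rho) || rho >= 1)
      add("core spectral radius >= 1", sprintf("rho = %.6g", rho))
  }

  structure(
    list(is_valid = length(rules) == 0L,
         violations = data.frame(rule = rules, where = where,
                                 stringsAsFactors = FALSE)),
    class = "fcdn_validation"
  )
}

#' @export
print.fcdn_validation <- function(x, ...) {
  if (x$is_valid) {
    cat("valid FCDN (all invariants hold)\n")
  } else {
    cat(sprintf("invalid FCDN: %d violation(s)\n", nrow(x$violations)))
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}
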