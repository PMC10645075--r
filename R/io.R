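#' Read an FCDN from a weighted edge list
#'
#' Reads a tab-separated file with header `source`, `target`, `weight`.
#' The reserved node names `"in"` and `"out"` mark the input and output
#' boundary nodes; every other name is a core node (ordered by first
#' appearance).  Duplicate edges, weights outside \[0, 1\], self-loops,
#' arcs into `"in"` or out of `"out"`, and files without an input or
#' output node are parse errors that report the offending line.
#'
#' The file is read structurally; run [validate_fcdn()] on the result to
#' audit flow invariants such as row normalization and reachability.
#'
#' @param path Path to a TSV edge list.
#' @return An [fcdn] object.
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(df)))
    stop("edge list must have columns source, target, weight", call. = FALSE)
  df$source <- as.character(df$source)
  df$target <- as.character(df$target)
  lineno <- seq_len(nrow(df)) + 1L  # +1 for the header line
  bad <- function(msg, i)
    stop(sprintf("parse error at line %d: %s", lineno[i], msg), call. = FALSE)

  if (anyNA(df$weight) || !is.numeric(df$weight))
    bad("non-numeric weight", which(is.na(df$weight))[1L])
  if (any(df$weight < 0 | df$weight > 1))
    bad("weight outside [0,1]", which(df$weight < 0 | df$weight > 1)[1L])
  key <- paste(df$source, df$target, sep = "\r")
  if (anyDuplicated(key))
    bad("duplicate edge", which(duplicated(key))[1L])
  if (any(df$source == df$target))
    bad("self-loop", which(df$source == df$target)[1L])
  if (any(df$target == "in"))
    bad("arc into the input node", which(df$target == "in")[1L])
  if (any(df$source == "out"))
    bad("arc out of the output node", which(df$source == "out")[1L])
  if (!any(df$source == "in"))
    stop("parse error: no input node (\"in\" never appears as a source)",
         call. = FALSE)
  if (!any(df$target == "out"))
    stop("parse error: no output node (\"out\" never appears as a target)",
         call. = FALSE)

  nodes <- unique(c(df$source, df$target))
  labels <- setdiff(nodes, c("in", "out"))
  if (!length(labels))
    stop("parse error: no core nodes", call. = FALSE)
  n <- length(labels)
  idx <- stats::setNames(seq_len(n + 2L), c(labels, "in", "out"))
  A <- matrix(0, n + 2L, n + 2L)
  A[cbind(idx[df$source], idx[df$target])] <- df$weight
  fcdn(A, labels = labels)
}

#' Write an FCDN as a weighted edge list
#'
#' Writes all positive-weight arcs as a TSV with header `source`,
#' `target`, `weight`, using the reserved labels `"in"` and `"out"` for
#' the boundary nodes.  [read_edge_list()] of the written file restores
#' the network exactly (weights to full double precision).
#'
#' @param net An [fcdn] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "fcdn"))
  A <- net$adjacency
  lab <- c(net$labels, "in", "out")
  pos <- which(A > 0, arr.ind = TRUE)
  ord <- order(pos[, 1L], pos[, 2L])
  pos <- pos[ord, , drop = FALSE]
  df <- data.frame(source = lab[pos[, 1L]], target = lab[pos[, 2L]],
                   weight = sprintf("%.17g", A[pos]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export the dense adjacency matrix as CSV
#'
#' @param net An [fcdn] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_adjacency_csv <- function(net, path) {
  stopifnot(inherits(net, "fcdn"))
  utils::write.csv(net$adjacency, path, row.names = TRUE)
  invisible(path)
}
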