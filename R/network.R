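# Fixed-density thresholding of synchronization matrices into directed,
# binary brain graphs.

#' Network density, percent
#'
#' Density convention used for the printed percentages of this analysis:
#' `100 * K / N^2` (denominator counts all ordered pairs including the
#' diagonal).  The standard directed-graph density `100 * K / (N * (N - 1))`
#' is returned as attribute `standard_pct`.
#'
#' @param K number of edges.
#' @param N number of nodes.
#' @return density in percent (numeric scalar; round only for display).
#' @examples
#' round(density_percent(500, 57), 2)  # 15.39
#' @export
density_percent <- function(K, N) {
  if (K < 0 || N < 2) stop_rwenet("need K >= 0 and N >= 2", "rwenet_parameter_error")
  structure(100 * K / N^2, standard_pct = 100 * K / (N * (N - 1)))
}

#' Threshold a synchronization matrix into a fixed-edge-count directed graph
#'
#' Places directed edges at the K smallest off-diagonal RWE values (smaller
#' RWE = stronger synchronization), i.e. the adaptive per-participant
#' threshold that gives every participant a graph with exactly the same number
#' of edges.  Ties at the K-th smallest value are broken deterministically by
#' (value, row index, column index).
#'
#' @param sync a `sync_matrix`.
#' @param K number of edges, `0 < K <= N^2 - N`.
#' @return object of class `brain_graph`: binary `adjacency` (1 = edge
#'   row -> col, zero diagonal, exactly `K` ones), `labels`, `K`,
#'   `density_pct` (the `N^2` convention) and `density_std_pct`
#'   (`N * (N - 1)` convention).
#' @export
threshold_to_graph <- function(sync, K) {
  stopifnot(inherits(sync, "sync_matrix"))
  N <- nrow(sync$values)
  K <- as.integer(K)
  if (K < 1 || K > N^2 - N) {
    stop_rwenet(sprintf("K must be in 1..%d (N^2 - N); got %d", N^2 - N, K),
                "rwenet_parameter_error")
  }
  off <- which(row(sync$values) != col(sync$values))
  v <- sync$values[off]
  ri <- row(sync$values)[off]
  ci <- col(sync$values)[off]
  ord <- order(v, ri, ci)
  A <- matrix(0L, N, N, dimnames = list(sync$labels, sync$labels))
  sel <- off[ord[seq_len(K)]]
  A[sel] <- 1L
  d <- density_percent(K, N)
  structure(list(adjacency = A, labels = sync$labels, K = K,
                 density_pct = as.numeric(d),
                 density_std_pct = attr(d, "standard_pct")),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("<brain_graph> %d nodes, %d directed edges (density %.2f%% by N^2; %.2f%% by N(N-1))\n",
              nrow(x$adjacency), x$K, x$density_pct, x$density_std_pct))
  invisible(x)
}

as_igraph <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "directed")
}

#' Export a brain graph
#'
#' @param g a `brain_graph`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_graph_csv <- function(g, path) {
  stopifnot(inherits(g, "brain_graph"))
  utils::write.csv(as.data.frame(g$adjacency), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_graph_csv
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "brain_graph"))
  idx <- which(g$adjacency == 1L, arr.ind = TRUE)
  utils::write.csv(data.frame(src = g$labels[idx[, 1]], dst = g$labels[idx[, 2]]),
                   path, row.names = FALSE)
  invisible(path)
}
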