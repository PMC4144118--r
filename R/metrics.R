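# Global (L, C, lambda, gamma, sigma) and nodal (betweenness, hubs, anterior
# hub ratio) characteristics of directed brain graphs.

#' Characteristic path length
#'
#' Mean directed shortest-path length (in edges) over all ordered pairs of
#' distinct nodes that are reachable from one another.  Fixed-density directed
#' graphs can be weakly disconnected, so unreachable pairs are excluded from
#' the mean; their count is returned as attribute `n_unreachable`.
#'
#' @param g a `brain_graph`.
#' @return positive scalar with attribute `n_unreachable`.
#' @export
char_path_length <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  if (nrow(g$adjacency) < 2) {
    stop_rwenet("graph needs at least 2 nodes", "rwenet_parameter_error")
  }
  D <- igraph::distances(as_igraph(g), mode = "out")
  d <- D[row(D) != col(D)]
  fin <- is.finite(d)
  if (!any(fin)) {
    stop_rwenet("no reachable node pairs: characteristic path length undefined",
                "rwenet_metric_error")
  }
  structure(mean(d[fin]), n_unreachable = sum(!fin))
}

#' Clustering coefficient (directed, union neighbourhood)
#'
#' The neighbourhood of node i is the union of its in- and out-neighbours
#' (excluding i itself); `C_i` is the number of directed edges present among
#' those neighbours divided by the `n_i * (n_i - 1)` possible ones, and 0 when
#' the node has fewer than two neighbours.  The network value `C` is the mean
#' over all nodes.
#'
#' @param g a `brain_graph`.
#' @return mean clustering coefficient in `[0, 1]`, with per-node values in
#'   attribute `C_i`.
#' @export
cluster_coefficient <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  A <- g$adjacency != 0L
  N <- nrow(A)
  Ci <- numeric(N)
  nb_mat <- A | t(A)
  for (i in seq_len(N)) {
    nb <- which(nb_mat[i, ])
    nb <- nb[nb != i]
    n_i <- length(nb)
    if (n_i < 2) next
    Ci[i] <- sum(A[nb, nb]) / (n_i * (n_i - 1))
  }
  structure(mean(Ci), C_i = stats::setNames(Ci, g$labels))
}

#' Analytic random-graph reference values
#'
#' Closed-form expectations for a random directed graph with the same number
#' of nodes and mean degree: `L_rand = ln(N) / ln(k)` and `C_rand = k / N`,
#' with `k = K / N` the mean (out-)degree.  Note `C_rand` equals the `N^2`
#' density convention of [density_percent()] expressed as a fraction.
#'
#' @param N number of nodes.
#' @param k mean degree (must exceed 1 for `ln k > 0`).
#' @return list with `L_rand` and `C_rand`.
#' @export
random_reference <- function(N, k) {
  if (N < 2) stop_rwenet("need N >= 2", "rwenet_parameter_error")
  if (k <= 1) {
    stop_rwenet("mean degree k must exceed 1 (ln k <= 0 otherwise)",
                "rwenet_parameter_error")
  }
  list(L_rand = log(N) / log(k), C_rand = k / N)
}

#' Small-world characteristics of a brain graph
#'
#' Combines the measured characteristic path length `L` and mean clustering
#' coefficient `C` with the analytic references of a size- and degree-matched
#' random graph into `lambda = L / L_rand`, `gamma = C / C_rand` and the
#' small-world coefficient `sigma = gamma / lambda`; `sigma > 1` indicates
#' small-world organization.
#'
#' @param g a `brain_graph`.
#' @return one-row data.frame of class `graph_metrics` with columns `K`, `L`,
#'   `C`, `L_rand`, `C_rand`, `lambda`, `gamma`, `sigma`, `n_unreachable`.
#' @export
small_world <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  L <- char_path_length(g)
  C <- cluster_coefficient(g)
  N <- nrow(g$adjacency)
  ref <- random_reference(N, g$K / N)
  lambda <- as.numeric(L) / ref$L_rand
  gma <- as.numeric(C) / ref$C_rand
  structure(data.frame(K = g$K, L = as.numeric(L), C = as.numeric(C),
                       L_rand = ref$L_rand, C_rand = ref$C_rand,
                       lambda = lambda, gamma = gma, sigma = gma / lambda,
                       n_unreachable = attr(L, "n_unreachable")),
            class = c("graph_metrics", "data.frame"))
}

#' Betweenness centrality and functional hubs
#'
#' Directed shortest-path betweenness (fractional shortest-path-count
#' weighting) for every node, normalized by the network mean so the normalized
#' values average exactly 1; nodes at or above `hub_threshold` are flagged as
#' functional hubs.
#'
#' @param g a `brain_graph`.
#' @param hub_threshold normalized-betweenness cutoff; the flag is inclusive
#'   (`>=`).
#' @return data.frame of class `hub_table` with columns `label`, `B`
#'   (raw betweenness), `b` (normalized), `is_hub`.
#' @export
betweenness_hubs <- function(g, hub_threshold = 1.5) {
  stopifnot(inherits(g, "brain_graph"))
  B <- igraph::betweenness(as_igraph(g), directed = TRUE)
  if (all(B == 0)) {
    stop_rwenet(paste("all betweenness values are zero (every pair adjacent or",
                      "no transit paths); normalized betweenness undefined"),
                "rwenet_metric_error")
  }
  b <- B / mean(B)
  structure(data.frame(label = g$labels, B = as.numeric(B), b = as.numeric(b),
                       is_hub = b >= hub_threshold, row.names = NULL),
            class = c("hub_table", "data.frame"),
            hub_threshold = hub_threshold)
}

#' Anterior hub ratio
#'
#' Ratio of summed normalized betweenness centrality over a left-anterior
#' electrode list to that over a right-anterior list (the right list includes
#' the midline sites exactly as used in the reference analysis).  Values above
#' 1 indicate relatively stronger recruitment of left-frontal sites.
#'
#' @param hubs a `hub_table` from [betweenness_hubs()].
#' @param left,right electrode label lists forming numerator and denominator.
#' @return positive scalar.
#' @export
anterior_hub_ratio <- function(hubs,
                               left = c("F3", "FC1", "AF3", "F1", "FC3"),
                               right = c("F2", "F4", "Fz", "AFz", "FCz",
                                         "FC2", "FC4")) {
  stopifnot(inherits(hubs, "hub_table"))
  missing <- setdiff(c(left, right), hubs$label)
  if (length(missing)) {
    stop_rwenet(sprintf("electrode(s) not present in the graph: %s",
                        paste(missing, collapse = ", ")), "rwenet_data_error")
  }
  num <- sum(hubs$b[match(left, hubs$label)])
  den <- sum(hubs$b[match(right, hubs$label)])
  if (den <= 0) {
    stop_rwenet("right-anterior normalized betweenness sums to zero; ratio undefined",
                "rwenet_metric_error")
  }
  num / den
}
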