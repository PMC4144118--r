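# Independent brute-force graph oracles used to cross-check the package's
# metric implementations.  Deliberately naive: Floyd-Warshall distances,
# DP shortest-path counting, explicit neighbour-pair loops.

bf_distances <- function(A) {
  N <- nrow(A)
  D <- matrix(Inf, N, N)
  D[A != 0] <- 1
  diag(D) <- 0
  for (k in seq_len(N)) {
    for (i in seq_len(N)) {
      nd <- D[i, k] + D[k, ]
      upd <- nd < D[i, ]
      D[i, upd] <- nd[upd]
    }
  }
  D
}

bf_path_length <- function(A) {
  D <- bf_distances(A)
  d <- D[row(D) != col(D)]
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_real_)
  mean(d)
}

bf_clustering <- function(A) {
  N <- nrow(A)
  Ci <- numeric(N)
  for (i in seq_len(N)) {
    nb <- integer()
    for (j in seq_len(N)) {
      if (j != i && (A[i, j] != 0 || A[j, i] != 0)) nb <- c(nb, j)
    }
    if (length(nb) < 2) next
    e <- 0L
    for (u in nb) for (v in nb) if (u != v && A[u, v] != 0) e <- e + 1L
    Ci[i] <- e / (length(nb) * (length(nb) - 1))
  }
  list(C = mean(Ci), C_i = Ci)
}

# number of shortest s->t paths for all ordered pairs, by DP over distance
bf_path_counts <- function(A, D) {
  N <- nrow(A)
  S <- matrix(0, N, N)
  diag(S) <- 1
  maxd <- max(D[is.finite(D)])
  if (maxd >= 1) {
    for (d in seq_len(maxd)) {
      for (s in seq_len(N)) for (t in seq_len(N)) {
        if (D[s, t] == d) {
          preds <- which(A[, t] != 0 & D[s, ] == d - 1)
          S[s, t] <- sum(S[s, preds])
        }
      }
    }
  }
  S
}

bf_betweenness <- function(A) {
  N <- nrow(A)
  D <- bf_distances(A)
  S <- bf_path_counts(A, D)
  B <- numeric(N)
  for (v in seq_len(N)) {
    for (s in seq_len(N)) for (t in seq_len(N)) {
      if (s == t || s == v || t == v) next
      if (!is.finite(D[s, t]) || S[s, t] == 0) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        B[v] <- B[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  B
}

# wrap an adjacency matrix as a brain_graph without going through thresholding
adj_graph <- function(A, labels = NULL) {
  N <- nrow(A)
  labels <- labels %||% paste0("N", seq_len(N))
  dimnames(A) <- list(labels, labels)
  structure(list(adjacency = A, labels = labels, K = sum(A != 0),
                 density_pct = 100 * sum(A != 0) / N^2,
                 density_std_pct = 100 * sum(A != 0) / (N * (N - 1))),
            class = "brain_graph")
}

# all directed graphs (no self-loops) on N nodes, as adjacency matrices
all_digraphs <- function(N) {
  off <- which(row(matrix(0, N, N)) != col(matrix(0, N, N)))
  m <- length(off)
  lapply(0:(2^m - 1), function(code) {
    A <- matrix(0L, N, N)
    A[off] <- as.integer(intToBits(code)[seq_len(m)])
    A
  })
}

random_digraph <- function(N, p = 0.3) {
  A <- matrix(as.integer(stats::runif(N * N) < p), N, N)
  diag(A) <- 0L
  A
}

# uniform random points on the 5-simplex (energy distributions)
random_simplex <- function(n = 1, d = 5) {
  x <- matrix(stats::rexp(n * d), n, d)
  x / rowSums(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
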