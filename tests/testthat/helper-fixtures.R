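# Small synthetic fixtures shared across test files.  Everything is built in
# code at test time; nothing is read from disk.

# a compact two-cluster recording fast enough for per-test generation
small_cluster_config <- function(n_channels = 12, duration_s = 45, rho = 0.9,
                                 noise_sd = 1, seed = 101, ...) {
  generator_config(n_channels = n_channels, duration_s = duration_s,
                   clusters = rep(1:2, each = n_channels / 2), rho = rho,
                   noise_sd = noise_sd, hub_channels = NULL, seed = seed, ...)
}

# deterministic random sync matrix with all-distinct off-diagonal values
random_sync <- function(N = 57, seed = 5) {
  V <- with_seed_test(seed, matrix(stats::runif(N * N), N, N))
  diag(V) <- 0
  labels <- if (N == 57) labels_1010_57() else paste0("E", seq_len(N))
  dimnames(V) <- list(labels, labels)
  structure(list(values = V, labels = labels, n_windows_aggregated = 1L,
                 n_floored = 0L),
            class = "sync_matrix")
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# hand-built hub table (for ratio arithmetic tests)
fake_hub_table <- function(labels, b) {
  structure(data.frame(label = labels, B = b * 10, b = b, is_hub = b >= 1.5,
                       row.names = NULL),
            class = c("hub_table", "data.frame"), hub_threshold = 1.5)
}
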