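complete_graph <- function(N) {
  A <- matrix(1L, N, N); diag(A) <- 0L
  adj_graph(A)
}

test_that("characteristic path length handles canonical graphs", {
  expect_equal(as.numeric(char_path_length(complete_graph(6))), 1)
  # directed 4-cycle: distances 1, 2, 3 from every node
  A <- matrix(0L, 4, 4)
  A[cbind(1:4, c(2, 3, 4, 1))] <- 1L
  expect_equal(as.numeric(char_path_length(adj_graph(A))), 2)
  # two isolated mutual dyads: cross-pairs unreachable and excluded
  B <- matrix(0L, 4, 4)
  B[cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))] <- 1L
  L <- char_path_length(adj_graph(B))
  expect_equal(as.numeric(L), 1)
  expect_identical(attr(L, "n_unreachable"), 8L)
  # empty graph: undefined
  expect_error(char_path_length(adj_graph(matrix(0L, 3, 3))),
               class = "rwenet_metric_error")
})

test_that("clustering coefficient matches its definition on canonical graphs", {
  expect_equal(as.numeric(cluster_coefficient(complete_graph(7))), 1)
  A <- matrix(0L, 5, 5)
  A[cbind(1:5, c(2:5, 1))] <- 1L          # directed cycle: no neighbour links
  expect_equal(as.numeric(cluster_coefficient(adj_graph(A))), 0)
})

test_that("L, C and betweenness agree with brute-force oracles", {
  # exhaustive: every directed graph on 3 nodes, and every one on 4 nodes
  for (N in c(3, 4)) {
    for (A in all_digraphs(N)) {
      g <- adj_graph(A)
      bfL <- bf_path_length(A)
      if (is.na(bfL)) {
        expect_error(char_path_length(g), class = "rwenet_metric_error")
      } else {
        expect_equal(as.numeric(char_path_length(g)), bfL, tolerance = 1e-12)
      }
      expect_equal(as.numeric(cluster_coefficient(g)), bf_clustering(A)$C,
                   tolerance = 1e-12)
      B <- bf_betweenness(A)
      if (any(B > 0)) {
        expect_equal(betweenness_hubs(g)$B, B, tolerance = 1e-9)
      } else if (sum(A) > 0) {
        expect_error(betweenness_hubs(g), class = "rwenet_metric_error")
      }
    }
  }
  # randomized: larger graphs
  set.seed(12)
  for (i in 1:30) {
    N <- sample(5:12, 1)
    A <- random_digraph(N, p = runif(1, 0.15, 0.5))
    g <- adj_graph(A)
    if (!is.na(bf_path_length(A))) {
      expect_equal(as.numeric(char_path_length(g)), bf_path_length(A),
                   tolerance = 1e-12)
    }
    expect_equal(as.numeric(cluster_coefficient(g)), bf_clustering(A)$C,
                 tolerance = 1e-12)
    B <- bf_betweenness(A)
    if (any(B > 0)) expect_equal(betweenness_hubs(g)$B, B, tolerance = 1e-9)
  }
})

test_that("analytic random references follow the closed forms", {
  ref <- random_reference(57, 500 / 57)
  expect_equal(ref$C_rand, 0.1539, tolerance = 1e-3)
  expect_equal(ref$C_rand, 500 / 57^2, tolerance = 1e-12)
  expect_equal(ref$L_rand, log(57) / log(500 / 57), tolerance = 1e-12)
  expect_equal(ref$L_rand, 1.862, tolerance = 1e-3)
  expect_equal(random_reference(exp(1), exp(1))$L_rand, 1, tolerance = 1e-12)
  expect_error(random_reference(57, 1), class = "rwenet_parameter_error")
  expect_error(random_reference(1, 3), class = "rwenet_parameter_error")
})

test_that("small_world composes its parts and is deterministic", {
  g <- threshold_to_graph(random_sync(20, seed = 8), 60)
  m1 <- small_world(g)
  m2 <- small_world(g)
  expect_identical(m1, m2)
  expect_equal(m1$lambda, m1$L / m1$L_rand, tolerance = 1e-12)
  expect_equal(m1$gamma, m1$C / m1$C_rand, tolerance = 1e-12)
  expect_equal(m1$sigma, m1$gamma / m1$lambda, tolerance = 1e-12)
  expect_true(m1$C >= 0 && m1$C <= 1)
  expect_gte(m1$L, 1)
})

test_that("a clustered graph with few shortcuts is small-world", {
  # two dense modules plus a handful of cross links
  A <- matrix(0L, 14, 14)
  A[1:7, 1:7] <- 1L; A[8:14, 8:14] <- 1L; diag(A) <- 0L
  A[7, 8] <- 1L; A[8, 7] <- 1L; A[1, 14] <- 1L; A[14, 1] <- 1L
  expect_gt(small_world(adj_graph(A))$sigma, 1)
})

test_that("betweenness normalization averages to one and flags hubs inclusively", {
  g <- threshold_to_graph(random_sync(30, seed = 13), 120)
  ht <- betweenness_hubs(g)
  expect_equal(mean(ht$b), 1, tolerance = 1e-9)
  expect_identical(ht$is_hub, ht$b >= 1.5)
  # directed cycle: perfect symmetry puts every node exactly at b = 1,
  # so an inclusive threshold of 1 flags all and anything above flags none
  A <- matrix(0L, 6, 6)
  A[cbind(1:6, c(2:6, 1))] <- 1L
  expect_true(all(betweenness_hubs(adj_graph(A), hub_threshold = 1)$is_hub))
  expect_false(any(betweenness_hubs(adj_graph(A),
                                    hub_threshold = 1 + 1e-9)$is_hub))
})

test_that("a mutual star concentrates betweenness on its centre", {
  N <- 7
  A <- matrix(0L, N, N)
  A[1, 2:N] <- 1L; A[2:N, 1] <- 1L
  ht <- betweenness_hubs(adj_graph(A))
  expect_true(ht$is_hub[1])
  expect_false(any(ht$is_hub[-1]))
  expect_true(all(ht$B[-1] == 0))
  # complete graph: no transit paths at all -> normalization undefined
  expect_error(betweenness_hubs(complete_graph(5)),
               class = "rwenet_metric_error")
})

test_that("anterior hub ratio is the left/right sum of normalized betweenness", {
  labs <- c("F3", "FC1", "AF3", "F1", "FC3",
            "F2", "F4", "Fz", "AFz", "FCz", "FC2", "FC4", "O1")
  # equal left and right sums -> 1
  b <- c(rep(1.4, 5), rep(1.0, 7), 0.6)
  expect_equal(anterior_hub_ratio(fake_hub_table(labs, b)), 1)
  # left 2, right 4 -> 0.5
  b2 <- c(rep(0.4, 5), c(1, 1, 0.5, 0.5, 0.5, 0.25, 0.25), 3)
  expect_equal(anterior_hub_ratio(fake_hub_table(labs, b2)), 0.5)
  # betweenness planted on the left list only -> ratio far above 1
  b3 <- c(rep(2, 5), rep(0.1, 7), 0.5)
  expect_gt(anterior_hub_ratio(fake_hub_table(labs, b3)), 1)
  expect_error(anterior_hub_ratio(fake_hub_table(labs, b),
                                  left = c("F3", "NOPE")),
               "NOPE", class = "rwenet_data_error")
  expect_error(anterior_hub_ratio(fake_hub_table(labs, c(rep(1, 5), rep(0, 7), 1))),
               class = "rwenet_metric_error")
})
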