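test_that("RWE matches hand-computed Kullback-Leibler values", {
  # identical distributions
  set.seed(3)
  for (i in 1:10) {
    p <- as.numeric(random_simplex(1))
    expect_equal(as.numeric(rwe(p, p)), 0)
  }
  # two-band reference against a four-band comparison: sum collapses to ln 2
  expect_equal(as.numeric(rwe(c(.5, .5, 0, 0, 0), c(.25, .25, .25, .25, 0))),
               log(2), tolerance = 1e-12)
  # single-band reference against uniform: ln 5
  expect_equal(as.numeric(rwe(c(1, 0, 0, 0, 0), rep(.2, 5))),
               log(5), tolerance = 1e-12)
  # oracle: direct term-by-term evaluation on random simplex pairs
  for (i in 1:20) {
    p <- as.numeric(random_simplex(1)); q <- as.numeric(random_simplex(1))
    expect_equal(as.numeric(rwe(p, q)), sum(p * log(p / q)), tolerance = 1e-12)
  }
})

test_that("RWE validates input distributions and reports flooring", {
  expect_error(rwe(c(.5, .5, .5, 0, 0), rep(.2, 5)),
               class = "rwenet_parameter_error")
  expect_error(rwe(c(.5, .5), rep(.2, 5)), class = "rwenet_parameter_error")
  v <- rwe(c(.5, .5, 0, 0, 0), c(1, 0, 0, 0, 0), eps = 1e-12)
  expect_identical(attr(v, "n_floored"), 1L)
  expect_true(is.finite(v) && v > 0)
})

test_that("Gibbs' inequality holds on random simplex pairs", {
  set.seed(99)
  P <- random_simplex(500); Q <- random_simplex(500)
  for (i in seq_len(500)) {
    v <- as.numeric(rwe(P[i, ], Q[i, ]))
    expect_gte(v, 0)
    if (max(abs(P[i, ] - Q[i, ])) > 1e-3) expect_gt(v, 0)
  }
})

test_that("pairwise matrices agree with a per-pair loop and count 3192 pairs at N=57", {
  set.seed(11)
  P3 <- random_simplex(3)
  dists <- lapply(1:3, function(i) relative_energy(P3[i, ] * 10,
                                                   label = paste0("E", i)))
  names(dists) <- paste0("E", 1:3)
  sm <- pairwise_sync(dists)
  for (i in 1:3) for (j in 1:3) {
    if (i == j) expect_identical(sm$values[i, j], 0)
    else expect_equal(sm$values[i, j],
                      as.numeric(rwe(dists[[i]], dists[[j]])),
                      tolerance = 1e-12)
  }
  # all electrodes sharing one distribution -> identically zero
  same <- lapply(1:4, function(i) relative_energy(c(5, 1, 1, 2, 1),
                                                  label = paste0("E", i)))
  names(same) <- paste0("E", 1:4)
  expect_true(all(pairwise_sync(same)$values == 0))
  # the 57-electrode montage: 57^2 entries, 3249 - 57 = 3192 informative
  P57 <- random_simplex(57)
  rownames(P57) <- labels_1010_57()
  sm57 <- pairwise_sync(P57)
  expect_identical(dim(sm57$values), c(57L, 57L))
  expect_identical(sum(row(sm57$values) != col(sm57$values)), 3192L)
  expect_true(all(diag(sm57$values) == 0))
  expect_true(all(sm57$values >= 0))
})

test_that("missing electrode distributions are reported by name", {
  P <- random_simplex(3)
  dists <- list(E1 = relative_energy(P[1, ]), E2 = NULL,
                E3 = relative_energy(P[3, ]))
  expect_error(pairwise_sync(dists), "E2", class = "rwenet_data_error")
})

test_that("aggregation is the window-weighted entrywise mean", {
  A <- random_sync(5, seed = 1)
  expect_equal(aggregate_sync(list(A))$values, A$values)
  B <- A; B$values <- 3 * A$values
  agg <- aggregate_sync(list(A, B))
  expect_equal(agg$values, 2 * A$values)
  expect_identical(agg$n_windows_aggregated, 2)
  # window-count weighting equals a flat mean over the underlying windows
  C1 <- A; C1$n_windows_aggregated <- 3L
  agg2 <- aggregate_sync(list(C1, B))
  expect_equal(agg2$values, (3 * A$values + B$values) / 4, tolerance = 1e-14)
  expect_error(aggregate_sync(list()), class = "rwenet_data_error")
  D <- random_sync(4, seed = 2)
  expect_error(aggregate_sync(list(A, D)), class = "rwenet_data_error")
})

test_that("streaming aggregation matches a two-pass mean over many windows", {
  cfg <- small_cluster_config(n_channels = 6, duration_s = 23, seed = 17)
  rec <- generate_recording(cfg)
  ep <- select_epochs(rec, n_epochs = 1, epoch_seconds = 20, seed = 1)
  sm <- sync_matrix(ep)
  # oracle: recompute every window's matrix independently and average
  d <- epoch_energy_distributions(ep[[1]])
  mats <- lapply(seq_len(dim(d$p)[2]), function(w) {
    dists <- lapply(seq_len(6), function(ch)
      relative_energy(d$p[ch, w, ] * d$E_tot[ch, w], label = rec$labels[ch]))
    names(dists) <- rec$labels
    pairwise_sync(dists)
  })
  expect_equal(sm$values, aggregate_sync(mats)$values, tolerance = 1e-10)
  expect_identical(sm$n_windows_aggregated, length(mats))
})

test_that("planted cluster coupling yields lower within-cluster RWE", {
  cfg <- small_cluster_config(seed = 23)
  rec <- generate_recording(cfg)
  sm <- sync_matrix(select_epochs(rec, n_epochs = 2, epoch_seconds = 20,
                                  seed = 2))
  cl <- cfg$clusters
  off <- row(sm$values) != col(sm$values)
  within <- outer(cl, cl, "==") & off
  obs <- mean(sm$values[!within & off]) - mean(sm$values[within])
  expect_gt(obs, 0)
  # one-sided resampling: permute channel-to-cluster assignment
  perm <- with_seed_test(77, replicate(999, {
    pcl <- sample(cl)
    pw <- outer(pcl, pcl, "==") & off
    mean(sm$values[!pw & off]) - mean(sm$values[pw])
  }))
  p <- (1 + sum(perm >= obs)) / 1000
  expect_lt(p, 0.01)
})

test_that("half-split aggregates converge as windows accumulate", {
  cfg <- small_cluster_config(n_channels = 6, duration_s = 125, seed = 31)
  rec <- generate_recording(cfg)
  eps <- select_epochs(rec, n_epochs = 6, epoch_seconds = 20, seed = 3)
  halves <- function(k) {
    a <- sync_matrix(eps[seq_len(k)])
    b <- sync_matrix(eps[seq_len(k) + k])
    mean(abs(a$values - b$values))
  }
  expect_lt(halves(3), halves(1))
})

test_that("sync matrices serialize to labeled CSV and back", {
  sm <- random_sync(6, seed = 9)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sync_csv(sm, f)
  back <- read_sync_csv(f)
  expect_identical(back$labels, sm$labels)
  expect_equal(back$values, sm$values, tolerance = 1e-12)
})
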