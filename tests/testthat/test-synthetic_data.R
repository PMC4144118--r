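test_that("the generator config validates its fields", {
  expect_error(generator_config(rho = 1.2), class = "rwenet_parameter_error")
  expect_error(generator_config(group_severity = -1),
               class = "rwenet_parameter_error")
  expect_error(generator_config(n_channels = 4, clusters = c(1, 1, 2)),
               class = "rwenet_parameter_error")
  expect_error(generator_config(band_weights = matrix(-1, 5, 5)),
               class = "rwenet_parameter_error")
  cfg <- generator_config()
  expect_identical(cfg$labels, labels_1010_57())
  expect_identical(length(unique(cfg$clusters)), 5L)
  expect_equal(rowSums(cfg$band_weights), rep(1, 5), ignore_attr = TRUE)
})

test_that("recordings are deterministic in the seed", {
  cfg <- small_cluster_config(n_channels = 6, duration_s = 8, seed = 5)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$data, r2$data)
  cfg2 <- small_cluster_config(n_channels = 6, duration_s = 8, seed = 6)
  expect_false(identical(r1$data, generate_recording(cfg2)$data))
})

test_that("perfect coupling with no noise makes cluster channels identical", {
  cfg <- generator_config(n_channels = 4, duration_s = 8,
                          clusters = c(1, 1, 2, 2), rho = 1, noise_sd = 0,
                          hub_channels = NULL, seed = 9)
  rec <- generate_recording(cfg)
  expect_equal(rec$data[1, ], rec$data[2, ], tolerance = 1e-12)
  # identical signals -> identical energy distributions -> RWE exactly 0
  sm <- sync_matrix(select_epochs(rec, n_epochs = 1, epoch_seconds = 5, seed = 1))
  expect_equal(sm$values[1, 2], 0, tolerance = 1e-12)
  expect_equal(sm$values[2, 1], 0, tolerance = 1e-12)
  expect_gt(sm$values[1, 3], 0)
})

test_that("without coupling, within- and between-cluster RWE are indistinguishable", {
  # equal band weights across clusters isolate the coupling effect
  cfg <- generator_config(n_channels = 12, duration_s = 45,
                          clusters = rep(1:2, each = 6), rho = 0,
                          band_weights = matrix(0.2, 2, 5), noise_sd = 1,
                          hub_channels = NULL, seed = 21)
  rec <- generate_recording(cfg)
  sm <- sync_matrix(select_epochs(rec, n_epochs = 2, epoch_seconds = 20,
                                  seed = 2))
  cl <- cfg$clusters
  off <- row(sm$values) != col(sm$values)
  within <- outer(cl, cl, "==") & off
  obs <- mean(sm$values[!within & off]) - mean(sm$values[within])
  perm <- with_seed_test(55, replicate(999, {
    pcl <- sample(cl)
    pw <- outer(pcl, pcl, "==") & off
    mean(sm$values[!pw & off]) - mean(sm$values[pw])
  }))
  p <- (1 + sum(perm >= obs)) / 1000
  expect_gt(p, 0.05)
})

test_that("within-cluster RWE separation grows monotonically with coupling", {
  sep <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(rho) {
    cfg <- generator_config(n_channels = 8, duration_s = 23,
                            clusters = rep(1:2, each = 4), rho = rho,
                            band_weights = matrix(0.2, 2, 5), noise_sd = 0.5,
                            hub_channels = NULL, seed = 40)
    rec <- generate_recording(cfg)
    sm <- sync_matrix(select_epochs(rec, n_epochs = 1, epoch_seconds = 20,
                                    seed = 4))
    cl <- cfg$clusters
    off <- row(sm$values) != col(sm$values)
    within <- outer(cl, cl, "==") & off
    mean(sm$values[within])
  }, numeric(1))
  expect_true(all(diff(sep) <= 1e-9))   # within-cluster RWE non-increasing
})

test_that("hub channels synchronize across clusters", {
  cfg <- generator_config(n_channels = 12, duration_s = 25,
                          clusters = rep(1:2, each = 6),
                          labels = c(paste0("L", 1:5), "HubA",
                                     paste0("R", 1:5), "HubB"),
                          hub_channels = c("HubA", "HubB"), hub_mix = 0.6,
                          rho = 0.9, noise_sd = 0.5, seed = 33)
  rec <- generate_recording(cfg)
  sm <- sync_matrix(select_epochs(rec, n_epochs = 1, epoch_seconds = 20,
                                  seed = 3))
  hub_cross <- sm$values["HubA", "HubB"]
  nonhub_cross <- mean(sm$values[paste0("L", 1:5), paste0("R", 1:5)])
  expect_lt(hub_cross, nonhub_cross)
})

test_that("cohorts are deterministic with severity-ordered scores", {
  co1 <- generate_cohort(5, severities = c(A = 0, B = 1, C = 2), seed = 3,
                         n_channels = 6, duration_s = 8,
                         clusters = rep(1:2, each = 3), hub_channels = NULL)
  co2 <- generate_cohort(5, severities = c(A = 0, B = 1, C = 2), seed = 3,
                         n_channels = 6, duration_s = 8,
                         clusters = rep(1:2, each = 3), hub_channels = NULL)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(cohort_recording(co1, 4)$data, cohort_recording(co2, 4)$data)
  gm <- aggregate(MMSE ~ group, co1$subjects, mean)
  expect_true(all(diff(gm$MMSE) < 0))
  gm2 <- aggregate(MoCA ~ group, co1$subjects, mean)
  expect_true(all(diff(gm2$MoCA) < 0))
  expect_true(all(co1$subjects$MMSE >= 0 & co1$subjects$MMSE <= 30))
  expect_error(generate_cohort(1), class = "rwenet_parameter_error")
})

test_that("severity weakens the planted coupling", {
  rwe_within <- function(sev) {
    cfg <- small_cluster_config(seed = 61, group_severity = sev)
    rec <- generate_recording(cfg)
    sm <- sync_matrix(select_epochs(rec, n_epochs = 1, epoch_seconds = 20,
                                    seed = 6))
    cl <- rep(1:2, each = 6)
    off <- row(sm$values) != col(sm$values)
    mean(sm$values[outer(cl, cl, "==") & off])
  }
  expect_lt(rwe_within(0), rwe_within(1.5))
})
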