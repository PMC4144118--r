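# Synthetic resting-state EEG with planted cluster-wise coupling.
#
# Every channel is a weighted mixture of band-limited noise processes in the
# five EEG rhythm bands.  Channels in the same cluster share the cluster's
# band processes with mixing fraction rho' = rho * exp(-group_severity), so
# within-cluster electrode pairs have matched relative band-energy
# distributions (low RWE) while between-cluster pairs differ both in their
# fluctuations and in their mean band weights.  Designated hub channels
# additionally mix a global process shared by everyone, turning them into
# long-range shortcuts between clusters -- the ingredient that makes the
# thresholded graphs small-world rather than merely modular.  The severity
# dial weakens the coupling multiplicatively (severity 0 reproduces the
# healthy model exactly), mimicking the loss of local synchronization
# observed in amnestic MCI and mild dementia.

#' Standard 57-channel 10-10 electrode montage
#'
#' Ordered roughly anterior to posterior, left to right within each row.
#'
#' @return character vector of 57 labels.
#' @export
labels_1010_57 <- function() {
  c("Fp1", "Fpz", "Fp2",
    "AF3", "AFz", "AF4",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO3", "POz", "PO4",
    "O1", "Oz", "O2")
}

# default per-cluster band weights (rows anterior -> posterior): slow rhythms
# dominate frontally, alpha dominates parieto-occipitally (eyes closed).
default_band_weights <- function(n_clusters) {
  base <- rbind(c(0.30, 0.25, 0.20, 0.15, 0.10),
                c(0.25, 0.25, 0.25, 0.15, 0.10),
                c(0.20, 0.20, 0.30, 0.20, 0.10),
                c(0.15, 0.15, 0.45, 0.15, 0.10),
                c(0.10, 0.12, 0.55, 0.13, 0.10))
  W <- base[round(seq(1, 5, length.out = n_clusters)), , drop = FALSE]
  dimnames(W) <- list(paste0("cluster", seq_len(n_clusters)), rwenet_band_names)
  W
}

#' Configuration of the synthetic EEG generator
#'
#' @param n_channels number of channels; 57 gives the standard montage.
#' @param fs sampling rate, Hz.
#' @param duration_s recording length in seconds.
#' @param labels channel labels; defaults to [labels_1010_57()] for 57
#'   channels, `Ch1..ChN` otherwise.
#' @param clusters integer cluster id per channel.  Default: 5 spatially
#'   contiguous anterior-to-posterior blocks.
#' @param rho within-cluster shared-signal fraction in `[0, 1]`.
#' @param band_weights `n_clusters x 5` nonnegative matrix of relative band
#'   powers (rows are renormalized to sum 1).
#' @param noise_sd white measurement noise, microvolts.
#' @param group_severity `>= 0`; coupling is scaled by `exp(-group_severity)`,
#'   so 0 is the healthy model and larger values disrupt it.
#' @param hub_channels labels that additionally mix the global shared process
#'   (cross-cluster shortcuts); `NULL` disables hubs.
#' @param hub_mix fraction of a hub channel's shared part drawn from the
#'   global process.
#' @param amplitude overall signal scale (standard deviation target), microvolts.
#' @param seed integer seed; identical seeds give identical recordings.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_channels = 57, fs = 500, duration_s = 220,
                             labels = NULL, clusters = NULL, rho = 0.8,
                             band_weights = NULL, noise_sd = 2,
                             group_severity = 0,
                             hub_channels = c("Fz", "Cz", "Pz"), hub_mix = 0.5,
                             amplitude = 20, seed = 1) {
  labels <- labels %||% if (n_channels == 57) labels_1010_57() else
    paste0("Ch", seq_len(n_channels))
  if (length(labels) != n_channels || anyDuplicated(labels)) {
    stop_rwenet("labels must be unique and match n_channels", "rwenet_parameter_error")
  }
  clusters <- clusters %||% as.integer(cut(seq_len(n_channels), breaks = 5,
                                           labels = FALSE))
  if (length(clusters) != n_channels || anyNA(clusters)) {
    stop_rwenet("every channel needs exactly one cluster id", "rwenet_parameter_error")
  }
  clusters <- as.integer(factor(clusters))
  n_cl <- max(clusters)
  band_weights <- band_weights %||% default_band_weights(n_cl)
  band_weights <- as.matrix(band_weights)
  if (nrow(band_weights) != n_cl || ncol(band_weights) != 5 ||
      any(band_weights < 0) || any(rowSums(band_weights) <= 0)) {
    stop_rwenet("band_weights must be a nonnegative n_clusters x 5 matrix",
                "rwenet_parameter_error")
  }
  band_weights <- band_weights / rowSums(band_weights)
  if (!(rho >= 0 && rho <= 1)) {
    stop_rwenet("rho must lie in [0, 1]", "rwenet_parameter_error")
  }
  if (group_severity < 0) {
    stop_rwenet("group_severity must be >= 0", "rwenet_parameter_error")
  }
  hub_channels <- intersect(hub_channels %||% character(), labels)
  structure(list(n_channels = n_channels, fs = fs, duration_s = duration_s,
                 labels = labels, clusters = clusters, rho = rho,
                 band_weights = band_weights, noise_sd = noise_sd,
                 group_severity = group_severity, hub_channels = hub_channels,
                 hub_mix = hub_mix, amplitude = amplitude, seed = seed),
            class = "generator_config")
}

# unit-variance band-limited Gaussian noise, synthesized spectrally: i.i.d.
# complex Gaussian amplitudes on the Fourier bins inside the band, Hermitian
# symmetry, inverse FFT.  Exact band limits, stationary, no filter
# transients, and much cheaper than time-domain filtering.  The delta band's
# lower edge is lifted to 0.5 Hz (no DC component).
band_noise <- function(n_rows, n, fs, edges) {
  freq <- seq_len(ceiling(n / 2) - 1L) * fs / n
  lo <- max(edges[1], 0.5)
  hi <- min(edges[2], fs / 2 * 0.999)
  k <- which(freq >= lo & freq < hi)
  if (!length(k)) {
    stop_rwenet(sprintf("band %g-%g Hz has no Fourier support at n=%d, fs=%g",
                        lo, hi, n, fs), "rwenet_parameter_error")
  }
  z <- stats::rnorm(2L * length(k) * n_rows)
  dim(z) <- c(length(k), 2L, n_rows)
  X <- matrix(0 + 0i, n, n_rows)
  X[k + 1L, ] <- complex(real = z[, 1L, ], imaginary = z[, 2L, ])
  X[n - k + 1L, ] <- Conj(X[k + 1L, , drop = FALSE])
  x <- Re(stats::mvfft(X, inverse = TRUE))
  for (j in seq_len(n_rows)) x[, j] <- x[, j] / stats::sd(x[, j])
  x                       # n x n_rows; columns are the processes
}

#' Generate a synthetic resting-state EEG recording
#'
#' @param cfg a [generator_config()].
#' @return an [eeg_recording()] whose `meta` records the configuration.
#' @examples
#' cfg <- generator_config(n_channels = 6, duration_s = 22,
#'                         clusters = rep(1:2, each = 3),
#'                         hub_channels = NULL, seed = 42)
#' rec <- generate_recording(cfg)
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- round(cfg$fs * cfg$duration_s)
  scheme <- band_scheme(cfg$fs)
  if (n < scheme$window_n) {
    stop_rwenet("duration too short for a single analysis window", "rwenet_data_error")
  }
  rho_eff <- cfg$rho * exp(-cfg$group_severity)
  n_cl <- max(cfg$clusters)
  hub_idx <- match(cfg$hub_channels, cfg$labels)
  h <- cfg$hub_mix
  out <- matrix(0, n, cfg$n_channels)        # samples x channels while mixing
  with_seed(cfg$seed, {
    for (b in seq_len(5)) {
      edges <- scheme$edges_hz[b, ]
      G <- band_noise(1L, n, cfg$fs, edges)            # global (hub) process
      S <- band_noise(n_cl, n, cfg$fs, edges)          # cluster-shared
      P <- band_noise(cfg$n_channels, n, cfg$fs, edges)  # channel-private
      # linear shared/private mixing, re-standardized so the band weight is
      # preserved whatever rho_eff is
      X <- (rho_eff * S[, cfg$clusters, drop = FALSE] + (1 - rho_eff) * P) /
        sqrt(rho_eff^2 + (1 - rho_eff)^2)
      if (length(hub_idx)) {
        X[, hub_idx] <- ((1 - h) * X[, hub_idx, drop = FALSE] +
                           h * as.vector(G)) / sqrt((1 - h)^2 + h^2)
      }
      out <- out + X * rep(sqrt(cfg$band_weights[cfg$clusters, b]), each = n)
    }
    out <- cfg$amplitude * out
    if (cfg$noise_sd > 0) {
      out <- out + stats::rnorm(length(out), sd = cfg$noise_sd)
    }
  })
  eeg_recording(t(out), cfg$fs, cfg$labels, meta = list(generator = unclass(cfg)))
}

#' Generate a multi-group synthetic cohort with cognitive scores
#'
#' Builds one generator configuration per subject (group-specific severity,
#' subject-specific seed) plus MMSE- and MoCA-like screening scores that
#' decrease linearly with severity.  Recordings are materialized lazily with
#' [cohort_recording()] so arbitrarily large cohorts fit in memory.
#'
#' Score models (points on the usual 0-30 scales, truncated and rounded):
#' `MMSE = 28 - 2.85 * severity + N(0, 2.3)`,
#' `MoCA = 26 - 4.3 * severity + N(0, 3)` — chosen to span the typical
#' healthy-to-mild-dementia range.
#'
#' @param n_per_group subjects per group (`>= 2`).
#' @param severities named numeric vector, one severity per group; names
#'   become group labels.
#' @param seed master seed; subject seeds and scores derive from it.
#' @param ... further arguments passed to [generator_config()] (e.g.
#'   `duration_s`, `rho`).
#' @return object of class `eeg_cohort`: `subjects` (data.frame with subject,
#'   group, severity, seed, MMSE, MoCA) and `configs` (list of
#'   [generator_config()]).
#' @export
generate_cohort <- function(n_per_group,
                            severities = c(Healthy = 0, aMCI = 1, MD = 2),
                            seed = 1, ...) {
  if (n_per_group < 2) {
    stop_rwenet("need at least 2 subjects per group", "rwenet_parameter_error")
  }
  groups <- names(severities) %||% paste0("Group", seq_along(severities))
  n_total <- n_per_group * length(severities)
  subjects <- data.frame(
    subject = sprintf("S%03d", seq_len(n_total)),
    group = factor(rep(groups, each = n_per_group), levels = groups),
    severity = rep(as.numeric(severities), each = n_per_group),
    seed = seed + seq_len(n_total))
  scores <- with_seed(seed, {
    mmse <- 28 - 2.85 * subjects$severity + stats::rnorm(n_total, sd = 2.3)
    moca <- 26 - 4.30 * subjects$severity + stats::rnorm(n_total, sd = 3.0)
    data.frame(MMSE = round(pmin(pmax(mmse, 0), 30)),
               MoCA = round(pmin(pmax(moca, 0), 30)))
  })
  subjects <- cbind(subjects, scores)
  configs <- lapply(seq_len(n_total), function(i) {
    generator_config(group_severity = subjects$severity[i],
                     seed = subjects$seed[i], ...)
  })
  structure(list(subjects = subjects, configs = configs), class = "eeg_cohort")
}

#' @rdname generate_cohort
#' @param cohort an `eeg_cohort`.
#' @param i subject index or subject id.
#' @export
cohort_recording <- function(cohort, i) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  if (is.character(i)) i <- match(i, cohort$subjects$subject)
  generate_recording(cohort$configs[[i]])
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d subjects in %d group(s)\n",
              nrow(x$subjects), nlevels(x$subjects$group)))
  print(stats::aggregate(cbind(MMSE, MoCA) ~ group, x$subjects, mean))
  invisible(x)
}
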