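#' Fit the RWE brain-network model to a recording
#'
#' The full per-participant analysis: (optional) zero-phase Butterworth
#' filtering, randomized selection of non-overlapping artifact-free epochs,
#' per-window wavelet band-energy distributions, directed Relative Wavelet
#' Entropy for every ordered electrode pair averaged over all windows, and
#' fixed-edge-count thresholding into binary directed graphs whose global
#' small-world characteristics and betweenness-centrality hub structure are
#' summarised at each requested density.
#'
#' @param rec an [eeg_recording()].
#' @param edges integer vector of fixed edge counts at which graphs are
#'   formed (densities).
#' @param n_epochs,epoch_seconds,seed epoch selection, see [select_epochs()].
#' @param filter apply [filter_recording()] first? Set `FALSE` for data that
#'   are already filtered.
#' @param hp_hz,notch_hz,filter_order filtering parameters.
#' @param wavelet_family,window_ms,eps wavelet and RWE parameters, see
#'   [decompose_window()] and [rwe()].
#' @param hub_threshold normalized-betweenness hub cutoff.
#' @param ahr_left,ahr_right anterior electrode lists for the anterior hub
#'   ratio; the ratio is skipped (NA) when the montage lacks any of them.
#' @return object of class `rwe_connectome` with elements `sync`
#'   (the aggregated `sync_matrix`), `graphs` (list of `brain_graph` per
#'   density), `metrics` (data.frame, one row per density: K, density_pct, L,
#'   C, L_rand, C_rand, lambda, gamma, sigma, AHR, n_hubs), `hubs` (list of
#'   `hub_table` per density), and `settings`.
#' @seealso [small_world()], [betweenness_hubs()], [threshold_to_graph()]
#' @examples
#' cfg <- generator_config(n_channels = 12, duration_s = 44,
#'                         clusters = rep(1:2, each = 6),
#'                         hub_channels = NULL, seed = 7)
#' fit <- rwe_connectome(generate_recording(cfg), edges = c(20, 30),
#'                       n_epochs = 2, seed = 7)
#' fit$metrics
#' @export
rwe_connectome <- function(rec, edges = c(500, 600, 700, 800),
                           n_epochs = 75, epoch_seconds = 20, seed = 1,
                           filter = TRUE, hp_hz = 1, notch_hz = 50,
                           filter_order = 3,
                           wavelet_family = "bior5.5", window_ms = 128,
                           eps = 1e-12, hub_threshold = 1.5,
                           ahr_left = c("F3", "FC1", "AF3", "F1", "FC3"),
                           ahr_right = c("F2", "F4", "Fz", "AFz", "FCz",
                                         "FC2", "FC4")) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (filter) {
    rec <- filter_recording(rec, hp_hz = hp_hz, notch_hz = notch_hz,
                            order = filter_order)
  }
  epochs <- select_epochs(rec, n_epochs = n_epochs,
                          epoch_seconds = epoch_seconds, seed = seed)
  sync <- sync_matrix(epochs, wavelet_family = wavelet_family,
                      window_ms = window_ms, eps = eps)
  ahr_possible <- all(c(ahr_left, ahr_right) %in% rec$labels)
  graphs <- list(); hubs <- list(); rows <- list()
  for (K in sort(as.integer(edges))) {
    g <- threshold_to_graph(sync, K)
    m <- small_world(g)
    ht <- tryCatch(betweenness_hubs(g, hub_threshold),
                   rwenet_metric_error = function(e) NULL)
    ahr <- if (!is.null(ht) && ahr_possible) {
      tryCatch(anterior_hub_ratio(ht, ahr_left, ahr_right),
               rwenet_metric_error = function(e) NA_real_)
    } else NA_real_
    key <- as.character(K)
    graphs[[key]] <- g
    hubs[key] <- list(ht)      # [[<- would drop the entry when ht is NULL
    rows[[key]] <- cbind(data.frame(density_pct = g$density_pct), m,
                         data.frame(AHR = ahr,
                                    n_hubs = if (is.null(ht)) NA_integer_
                                             else sum(ht$is_hub)))
  }
  metrics <- do.call(rbind, c(rows, make.row.names = FALSE))
  metrics <- metrics[c("K", "density_pct", "L", "C", "L_rand", "C_rand",
                       "lambda", "gamma", "sigma", "AHR", "n_hubs",
                       "n_unreachable")]
  structure(list(sync = sync, graphs = graphs, metrics = metrics, hubs = hubs,
                 settings = list(edges = sort(as.integer(edges)),
                                 n_epochs = n_epochs,
                                 epoch_seconds = epoch_seconds, seed = seed,
                                 filtered = filter,
                                 wavelet_family = wavelet_family,
                                 window_ms = window_ms, eps = eps,
                                 hub_threshold = hub_threshold),
                 call = match.call()),
            class = "rwe_connectome")
}

#' @export
print.rwe_connectome <- function(x, ...) {
  cat(sprintf("RWE connectome fit: %d electrodes, %d windows aggregated\n",
              length(x$sync$labels), x$sync$n_windows_aggregated))
  print(x$metrics[c("K", "density_pct", "L", "C", "sigma")], row.names = FALSE,
        digits = 4)
  invisible(x)
}

#' @export
summary.rwe_connectome <- function(object, ...) {
  structure(list(metrics = object$metrics,
                 hubs = lapply(object$hubs, function(h) {
                   if (is.null(h)) character() else h$label[h$is_hub]
                 }),
                 settings = object$settings,
                 n_windows = object$sync$n_windows_aggregated),
            class = "summary.rwe_connectome")
}

#' @export
print.summary.rwe_connectome <- function(x, ...) {
  cat(sprintf("RWE connectome fit (%d windows of %g ms; wavelet %s)\n",
              x$n_windows, x$settings$window_ms, x$settings$wavelet_family))
  cat("\nGlobal characteristics per density:\n")
  print(x$metrics, row.names = FALSE, digits = 4)
  cat("\nFunctional hubs (normalized betweenness >=",
      x$settings$hub_threshold, "):\n")
  for (k in names(x$hubs)) {
    cat(sprintf("  K=%s: %s\n", k,
                if (length(x$hubs[[k]])) paste(x$hubs[[k]], collapse = " ")
                else "(none)"))
  }
  invisible(x)
}

#' @export
coef.rwe_connectome <- function(object, ...) {
  m <- as.matrix(object$metrics[c("L", "C", "lambda", "gamma", "sigma")])
  rownames(m) <- object$metrics$K
  m
}

#' @export
plot.rwe_connectome <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  V <- x$sync$values
  graphics::image(seq_len(nrow(V)), seq_len(ncol(V)),
                  t(V)[, rev(seq_len(nrow(V)))],
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "electrode (q)", ylab = "electrode (p)",
                  main = "RWE synchronization matrix", useRaster = TRUE)
  graphics::plot(x$metrics$K, x$metrics$sigma, type = "b", pch = 19,
                 xlab = "edges (K)", ylab = expression(sigma),
                 main = "small-world coefficient")
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}

#' Subject-by-density metrics table for a synthetic cohort
#'
#' Runs [rwe_connectome()] on every subject of a [generate_cohort()] cohort
#' (recordings are generated on the fly) and assembles the tidy table used by
#' [anova_with_posthoc()] and [correlate_cognition()].  The mean normalized
#' betweenness of a reference hub set is reported per subject and density;
#' by default the set is identified from the first (reference) group's mean
#' normalized betweenness at the lowest density.
#'
#' @param cohort an `eeg_cohort`.
#' @param edges fixed edge counts, as in [rwe_connectome()].
#' @param n_epochs,epoch_seconds,seed epoch selection per subject.
#' @param hub_set optional electrode label vector to use as the reference hub
#'   set; `NULL` derives it from the reference group.
#' @param hub_threshold cutoff for hub identification.
#' @param ... further arguments passed to [rwe_connectome()].
#' @return data.frame with one row per subject x density: `subject`, `group`,
#'   `K`, `L`, `C`, `sigma`, `hub_bi` (mean normalized betweenness over the
#'   reference hub set), `AHR`, `MMSE`, `MoCA`.  The reference hub set is
#'   attached as attribute `hub_set`.
#' @export
cohort_metrics <- function(cohort, edges = c(500, 600, 700, 800),
                           n_epochs = 10, epoch_seconds = 20, seed = 1,
                           hub_set = NULL, hub_threshold = 1.5, ...) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  subj <- cohort$subjects
  fits_hub_b <- list()   # per subject: matrix [densities x electrodes] of b
  rows <- list()
  for (i in seq_len(nrow(subj))) {
    fit <- rwe_connectome(cohort_recording(cohort, i), edges = edges,
                          n_epochs = n_epochs, epoch_seconds = epoch_seconds,
                          seed = seed + i, hub_threshold = hub_threshold, ...)
    bmat <- do.call(rbind, lapply(fit$hubs, function(h) {
      if (is.null(h)) rep(NA_real_, length(fit$sync$labels))
      else h$b[match(fit$sync$labels, h$label)]
    }))
    colnames(bmat) <- fit$sync$labels
    fits_hub_b[[i]] <- bmat
    rows[[i]] <- data.frame(subject = subj$subject[i], group = subj$group[i],
                            fit$metrics[c("K", "L", "C", "sigma", "AHR")],
                            MMSE = subj$MMSE[i], MoCA = subj$MoCA[i])
  }
  if (is.null(hub_set)) {
    ref_group <- levels(subj$group)[1]
    ref_idx <- which(subj$group == ref_group)
    lowK <- as.character(min(edges))
    ref_b <- colMeans(do.call(rbind, lapply(fits_hub_b[ref_idx],
                                            function(m) m[lowK, ])), na.rm = TRUE)
    hub_set <- names(ref_b)[!is.na(ref_b) & ref_b >= hub_threshold]
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$hub_bi <- unlist(lapply(seq_len(nrow(subj)), function(i) {
    rowMeans(fits_hub_b[[i]][, hub_set, drop = FALSE])
  }))
  attr(out, "hub_set") <- hub_set
  out
}
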