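# Relative Wavelet Entropy synchronization.

#' Relative Wavelet Entropy between two band-energy distributions
#'
#' Directed Kullback-Leibler divergence between the relative band-energy
#' distributions of a reference electrode `p` and a comparison electrode `q`:
#' `sum_j p_j * ln(p_j / q_j)`, with the conventions `0 * ln(0/.) = 0` and
#' `q_j` floored at `eps` to keep the measure finite when a band of `q`
#' carries no energy.  The value is nonnegative (Gibbs' inequality), zero iff
#' the two distributions coincide, asymmetric in general, and *smaller* for
#' *more* synchronized electrode pairs.
#'
#' @param p,q [relative_energy()] objects, or bare numeric 5-vectors summing
#'   to 1.
#' @param eps floor applied to the components of `q` (not renormalized).
#' @return nonnegative scalar in nats.  Attribute `n_floored` counts the terms
#'   where the floor was active.
#' @examples
#' rwe(c(.5, .5, 0, 0, 0), c(.25, .25, .25, .25, 0))  # = ln 2
#' @export
rwe <- function(p, q, eps = 1e-12) {
  pv <- if (inherits(p, "energy_distribution")) p$p else as.numeric(p)
  qv <- if (inherits(q, "energy_distribution")) q$p else as.numeric(q)
  if (length(pv) != length(qv)) {
    stop_rwenet("p and q must have the same number of bands", "rwenet_parameter_error")
  }
  if (any(pv < 0) || any(qv < 0) ||
      abs(sum(pv) - 1) > 1e-6 || abs(sum(qv) - 1) > 1e-6) {
    stop_rwenet("p and q must be probability distributions (nonnegative, sum 1)",
                "rwenet_parameter_error")
  }
  floored <- qv < eps & pv > 0
  qf <- pmax(qv, eps)
  pos <- pv > 0
  val <- max(0, sum(pv[pos] * log(pv[pos] / qf[pos])))
  structure(val, n_floored = sum(floored))
}

#' All ordered-pair synchronization values for one window
#'
#' Builds the N x N directed synchronization matrix for one analysis window:
#' entry (p, q) is `rwe(dist_p, dist_q)` with the row electrode as the
#' reference distribution; the diagonal is exactly zero and does not take part
#' in any later computation.  For the 57-electrode montage this yields
#' 57 * 57 - 57 = 3192 informative ordered pairs.
#'
#' @param dists list of [relative_energy()] objects (one per electrode) or a
#'   numeric matrix with one row per electrode and 5 columns.
#' @param labels electrode labels; defaults to names/rownames of `dists`.
#' @param eps floor passed to the KL evaluation, see [rwe()].
#' @return object of class `sync_matrix`: `values` (N x N, zero diagonal,
#'   nonnegative), `labels`, `n_windows_aggregated = 1`, `n_floored`.
#' @export
pairwise_sync <- function(dists, labels = NULL, eps = 1e-12) {
  if (is.list(dists) && !is.matrix(dists)) {
    bad <- vapply(dists, function(d) !inherits(d, "energy_distribution"), logical(1))
    if (any(bad)) {
      nm <- names(dists)[bad] %||% which(bad)
      stop_rwenet(sprintf("missing or invalid energy distribution for electrode(s): %s",
                          paste(nm, collapse = ", ")), "rwenet_data_error")
    }
    labels <- labels %||% names(dists) %||%
      vapply(dists, function(d) d$label, character(1))
    P <- do.call(rbind, lapply(dists, function(d) d$p))
  } else {
    P <- as.matrix(dists)
    labels <- labels %||% rownames(P)
  }
  if (anyNA(P)) {
    stop_rwenet(sprintf("missing energy distribution for electrode(s): %s",
                        paste(unique(labels[which(is.na(P), arr.ind = TRUE)[, 1]]),
                              collapse = ", ")), "rwenet_data_error")
  }
  labels <- labels %||% paste0("E", seq_len(nrow(P)))
  V <- rwe_matrix(P, eps)
  structure(list(values = `dimnames<-`(V$values, list(labels, labels)),
                 labels = labels, n_windows_aggregated = 1L,
                 n_floored = V$n_floored),
            class = "sync_matrix")
}

# vectorized KL over all ordered row pairs of P (rows = electrodes, cols = bands)
rwe_matrix <- function(P, eps = 1e-12) {
  Qf <- pmax(P, eps)
  s <- rowSums(ifelse(P > 0, P * log(P), 0))          # sum_j p ln p
  V <- s - P %*% t(log(Qf))                           # minus sum_j p ln q
  # number of off-diagonal terms where the q-floor was active
  M <- (P > 0) %*% t(P < eps)
  n_floored <- sum(M) - sum(diag(M))
  # flooring keeps KL finite; clamp the O(eps) negative slack it introduces
  V[V < 0] <- 0
  diag(V) <- 0
  list(values = V, n_floored = n_floored)
}

#' Aggregate synchronization matrices over windows and epochs
#'
#' Entrywise mean over all valid windows of all epochs (weighted by the number
#' of windows each input already aggregates), preserving the per-window
#' synchronization structure.
#'
#' @param mats list of `sync_matrix` objects with identical shape and labels.
#' @return a `sync_matrix` whose `n_windows_aggregated` is the total window
#'   count.
#' @export
aggregate_sync <- function(mats) {
  if (length(mats) == 0) {
    stop_rwenet("no synchronization matrices to aggregate", "rwenet_data_error")
  }
  lab <- mats[[1]]$labels
  ok <- vapply(mats, function(m) inherits(m, "sync_matrix") &&
                 identical(m$labels, lab) &&
                 identical(dim(m$values), dim(mats[[1]]$values)), logical(1))
  if (!all(ok)) {
    stop_rwenet("all matrices must be sync_matrix objects with identical labels/shape",
                "rwenet_data_error")
  }
  w <- vapply(mats, function(m) as.numeric(m$n_windows_aggregated), numeric(1))
  V <- Reduce(`+`, Map(function(m, wi) m$values * wi, mats, w)) / sum(w)
  diag(V) <- 0
  structure(list(values = V, labels = lab,
                 n_windows_aggregated = sum(w),
                 n_floored = sum(vapply(mats, function(m) m$n_floored %||% 0L,
                                        numeric(1)))),
            class = "sync_matrix")
}

#' @export
print.sync_matrix <- function(x, ...) {
  v <- x$values[row(x$values) != col(x$values)]
  cat(sprintf("<sync_matrix> %d x %d RWE values over %d window(s); off-diagonal mean %.4f [%.4f, %.4f]\n",
              nrow(x$values), ncol(x$values), x$n_windows_aggregated,
              mean(v), min(v), max(v)))
  invisible(x)
}

#' Synchronization matrix of a set of epochs
#'
#' The full per-participant synchronization computation: every epoch is cut
#' into non-overlapping analysis windows, each electrode's relative
#' band-energy distribution is computed per window, the directed RWE matrix of
#' every window is formed, and all windows of all epochs are averaged
#' entrywise.  Windows in which any electrode has zero retained energy are
#' excluded from the average (with a warning).
#'
#' @param epochs list of `eeg_epoch` objects from [select_epochs()] (a single
#'   epoch or an `eeg_recording` is also accepted).
#' @param wavelet_family,window_ms passed to the wavelet cascade.
#' @param eps KL floor, see [rwe()].
#' @return a `sync_matrix` aggregated over all valid windows.
#' @export
sync_matrix <- function(epochs, wavelet_family = "bior5.5", window_ms = 128,
                        eps = 1e-12) {
  if (inherits(epochs, "eeg_recording") || inherits(epochs, "eeg_epoch")) {
    epochs <- list(epochs)
  }
  acc <- NULL
  n_win <- 0L
  n_deg <- 0L
  n_floored <- 0L
  labels <- epochs[[1]]$labels
  for (ep in epochs) {
    d <- epoch_energy_distributions(ep, wavelet_family, window_ms)
    for (w in seq_len(dim(d$p)[2])) {
      if (any(d$degenerate[, w])) {
        n_deg <- n_deg + 1L
        next
      }
      V <- rwe_matrix(d$p[, w, ], eps)
      acc <- if (is.null(acc)) V$values else acc + V$values
      n_floored <- n_floored + V$n_floored
      n_win <- n_win + 1L
    }
  }
  if (n_win == 0L) {
    stop_rwenet("no valid (non-degenerate) analysis windows", "rwenet_data_error")
  }
  if (n_deg > 0L) {
    warning(sprintf("%d degenerate (zero-energy) window(s) excluded from the synchronization average",
                    n_deg))
  }
  V <- acc / n_win
  diag(V) <- 0
  structure(list(values = `dimnames<-`(V, list(labels, labels)),
                 labels = labels, n_windows_aggregated = n_win,
                 n_degenerate = n_deg, n_floored = n_floored),
            class = "sync_matrix")
}

#' Write / read a synchronization matrix as labeled CSV
#'
#' @param sync a `sync_matrix`.
#' @param path CSV path; row and column headers are the electrode labels.
#' @return `path` (write) or a `sync_matrix` (read).
#' @export
write_sync_csv <- function(sync, path) {
  stopifnot(inherits(sync, "sync_matrix"))
  utils::write.csv(as.data.frame(sync$values), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_sync_csv
#' @export
read_sync_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  V <- as.matrix(df)
  structure(list(values = V, labels = rownames(V),
                 n_windows_aggregated = NA_integer_, n_floored = NA_integer_),
            class = "sync_matrix")
}
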