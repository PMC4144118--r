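# Periodized discrete wavelet cascade for per-window EEG rhythm decomposition.
#
# Each 128-ms window (64 samples at 500 Hz) runs through a recursive low/high
# pass split.  At 500 Hz six levels are needed: the two finest detail levels
# (62.5-125 and 125-250 Hz) lie above the gamma band and are computed but
# discarded; the retained levels carry gamma (31.25-62.5 Hz, 8 coefficients),
# beta (4), alpha (2), theta (1) and the final approximation, delta (1).
# Circular (periodized) boundary handling is the one mode that keeps exactly
# n/2 coefficients per split -- the only scheme consistent with those printed
# counts -- while preserving perfect reconstruction.

# Analysis/synthesis filter pairs.  Published constants for the standard
# spline-biorthogonal 5/5 pair (both orientations) and the orthogonal
# 5-vanishing-moment Daubechies filter.
wavelet_filters <- function(family) {
  f <- switch(family,
    "bior5.5" = list(
      dec_lo = c(0, 0, 0.03968708834740544, 0.007948108637240322,
                 -0.05446378846823691, 0.34560528195603346, 0.7366601814282105,
                 0.34560528195603346, -0.05446378846823691, 0.007948108637240322,
                 0.03968708834740544, 0),
      dec_hi = c(-0.013456709459118716, -0.002694966880111507,
                 0.13670658466432914, -0.09350469740093886, -0.47680326579848425,
                 0.8995061097486484, -0.47680326579848425, -0.09350469740093886,
                 0.13670658466432914, -0.002694966880111507,
                 -0.013456709459118716, 0),
      rec_lo = c(0.013456709459118716, -0.002694966880111507,
                 -0.13670658466432914, -0.09350469740093886, 0.47680326579848425,
                 0.8995061097486484, 0.47680326579848425, -0.09350469740093886,
                 -0.13670658466432914, -0.002694966880111507,
                 0.013456709459118716, 0),
      rec_hi = c(0, 0, 0.03968708834740544, -0.007948108637240322,
                 -0.05446378846823691, -0.34560528195603346, 0.7366601814282105,
                 -0.34560528195603346, -0.05446378846823691,
                 -0.007948108637240322, 0.03968708834740544, 0),
      orthogonal = FALSE),
    "rbio5.5" = list(
      dec_lo = c(0, 0.013456709459118716, -0.002694966880111507,
                 -0.13670658466432914, -0.09350469740093886, 0.47680326579848425,
                 0.8995061097486484, 0.47680326579848425, -0.09350469740093886,
                 -0.13670658466432914, -0.002694966880111507,
                 0.013456709459118716),
      dec_hi = c(0, 0.03968708834740544, -0.007948108637240322,
                 -0.05446378846823691, -0.34560528195603346, 0.7366601814282105,
                 -0.34560528195603346, -0.05446378846823691,
                 -0.007948108637240322, 0.03968708834740544, 0, 0),
      rec_lo = c(0, 0.03968708834740544, 0.007948108637240322,
                 -0.05446378846823691, 0.34560528195603346, 0.7366601814282105,
                 0.34560528195603346, -0.05446378846823691, 0.007948108637240322,
                 0.03968708834740544, 0, 0),
      rec_hi = c(0, -0.013456709459118716, -0.002694966880111507,
                 0.13670658466432914, -0.09350469740093886, -0.47680326579848425,
                 0.8995061097486484, -0.47680326579848425, -0.09350469740093886,
                 0.13670658466432914, -0.002694966880111507,
                 -0.013456709459118716),
      orthogonal = FALSE),
    "db5" = list(
      dec_lo = c(0.0033357252854737712, -0.012580751999081999,
                 -0.006241490212798274, 0.07757149384004572,
                 -0.032244869584638375, -0.24229488706638203,
                 0.13842814590132074, 0.7243085284377729, 0.6038292697971896,
                 0.16010239797419293),
      dec_hi = c(-0.16010239797419293, 0.6038292697971896, -0.7243085284377729,
                 0.13842814590132074, 0.24229488706638203, -0.032244869584638375,
                 -0.07757149384004572, -0.006241490212798274,
                 0.012580751999081999, 0.0033357252854737712),
      rec_lo = c(0.16010239797419293, 0.6038292697971896, 0.7243085284377729,
                 0.13842814590132074, -0.24229488706638203,
                 -0.032244869584638375, 0.07757149384004572,
                 -0.006241490212798274, -0.012580751999081999,
                 0.0033357252854737712),
      rec_hi = c(0.0033357252854737712, 0.012580751999081999,
                 -0.006241490212798274, -0.07757149384004572,
                 -0.032244869584638375, 0.24229488706638203, 0.13842814590132074,
                 -0.7243085284377729, 0.6038292697971896, -0.16010239797419293),
      orthogonal = TRUE),
    stop_rwenet(sprintf("unknown wavelet family '%s' (use bior5.5, rbio5.5 or db5)",
                        family), "rwenet_parameter_error"))
  f$family <- family
  f
}

rwenet_band_names <- c("delta", "theta", "alpha", "beta", "gamma")

#' Band scheme of the per-window wavelet cascade
#'
#' Derives, for a sampling rate and window length, the depth of the cascade,
#' the number of discarded high-frequency detail levels, the per-band
#' coefficient counts and the band edges in Hz.  At 500 Hz and 128 ms the
#' scheme is the canonical one: a 6-level cascade on 64 samples, levels 1-2
#' (above ~62.5 Hz) discarded, and coefficient counts
#' gamma 8, beta 4, alpha 2, theta 1, delta 1.
#'
#' @param fs sampling rate in Hz.
#' @param window_ms analysis window length in milliseconds.
#' @return a list of class `band_scheme`: `bands` (names ordered slow to
#'   fast), `counts` (coefficients per band per window), `edges_hz` (5 x 2
#'   matrix), `levels` (wavelet level carrying each band), `n_discard`
#'   (discarded finest levels), `J` (cascade depth), `window_n` (samples per
#'   window), `index` (per-coefficient band assignment used internally).
#' @export
band_scheme <- function(fs, window_ms = 128) {
  if (fs <= 0) stop_rwenet("fs must be positive", "rwenet_parameter_error")
  # number of detail levels above the gamma band (upper gamma edge ~fs/2^(n+1))
  n_discard <- max(0L, as.integer(round(log2(fs / 125))))
  J <- n_discard + 4L
  window_n <- round(fs * window_ms / 1000)
  # periodization needs 2^J | window_n; snap to the nearest usable length
  window_n <- as.integer(max(2^J, round(window_n / 2^J) * 2^J))
  counts <- c(1L, 1L, 2L, 4L, 8L)                     # delta..gamma
  levels <- c(J, J, J - 1L, J - 2L, J - 3L)           # delta at approx level J
  edges <- rbind(c(0, fs / 2^(J + 1)),
                 t(vapply(2:5, function(b) fs / 2^(levels[b] + c(1, 0)),
                          numeric(2))))
  dimnames(edges) <- list(rwenet_band_names, c("lower_hz", "upper_hz"))
  # coefficient layout of the cascade output vector:
  # [A_J (delta) | D_J (theta) | D_{J-1} (alpha) | ... | D_1]
  idx <- character(window_n)
  pos <- 1L
  lens <- window_n / 2^c(J, J:1)
  parts <- c("delta", "theta", "alpha", "beta", "gamma",
             paste0("discard", seq_len(n_discard)))
  for (i in seq_along(lens)) {
    idx[pos:(pos + lens[i] - 1L)] <- parts[i]
    pos <- pos + lens[i]
  }
  structure(list(bands = rwenet_band_names,
                 counts = stats::setNames(counts, rwenet_band_names),
                 edges_hz = edges, levels = stats::setNames(levels, rwenet_band_names),
                 n_discard = n_discard, J = J, window_n = window_n, fs = fs,
                 index = idx),
            class = "band_scheme")
}

# single-level periodized analysis matrix (n x n): rows = [lowpass; highpass]
# y_lo[k] = sum_m h[m] x[(2k + m - d) mod n], d = floor(L/2)
periodized_split <- function(filt, n) {
  L <- length(filt$dec_lo)
  d <- L %/% 2
  A <- matrix(0, n, n)
  for (k in 0:(n / 2 - 1)) {
    for (m in 0:(L - 1)) {
      j <- (2 * k + m - d) %% n
      A[k + 1, j + 1] <- A[k + 1, j + 1] + filt$dec_lo[m + 1]
      A[n / 2 + k + 1, j + 1] <- A[n / 2 + k + 1, j + 1] + filt$dec_hi[m + 1]
    }
  }
  A
}

# single-level periodized synthesis matrix (n x n), true convolution with the
# reconstruction filters at offset e = L - 1 - floor(L/2)
periodized_merge <- function(filt, n) {
  L <- length(filt$rec_lo)
  e <- L - 1L - L %/% 2
  S <- matrix(0, n, n)
  for (k in 0:(n / 2 - 1)) {
    for (m in 0:(L - 1)) {
      i <- (2 * k - m + e) %% n
      S[i + 1, k + 1] <- S[i + 1, k + 1] + filt$rec_lo[m + 1]
      S[i + 1, n / 2 + k + 1] <- S[i + 1, n / 2 + k + 1] + filt$rec_hi[m + 1]
    }
  }
  S
}

.dwt_cache <- new.env(parent = emptyenv())

# full-cascade analysis (W) and synthesis (S) matrices; S %*% W = I.
# Rows of W are ordered [A_J, D_J, D_{J-1}, ..., D_1] matching band_scheme$index.
dwt_matrices <- function(fs, window_ms = 128, family = "bior5.5") {
  key <- sprintf("%s|%g|%g", family, fs, window_ms)
  if (!is.null(.dwt_cache[[key]])) return(.dwt_cache[[key]])
  scheme <- band_scheme(fs, window_ms)
  filt <- wavelet_filters(family)
  n <- scheme$window_n
  W <- diag(n)
  len <- n
  for (j in seq_len(scheme$J)) {
    M <- diag(n)
    M[1:len, 1:len] <- periodized_split(filt, len)
    W <- M %*% W
    len <- len / 2L
  }
  S <- diag(n)
  len <- n / 2^scheme$J
  for (j in scheme$J:1) {
    M <- diag(n)
    M[1:(2 * len), 1:(2 * len)] <- periodized_merge(filt, 2L * len)
    S <- M %*% S
    len <- 2L * len
  }
  out <- list(W = W, S = S, scheme = scheme, family = family)
  .dwt_cache[[key]] <- out
  out
}

#' Wavelet decomposition of one analysis window
#'
#' Runs the periodized low/high-pass cascade on a single window and returns
#' the coefficients grouped by EEG rhythm, with the detail levels above the
#' gamma band kept but marked discarded.
#'
#' @param x numeric vector of window samples; its length must match
#'   `round(fs * window_ms / 1000)` within one sample.
#' @param fs sampling rate in Hz.
#' @param wavelet_family `"bior5.5"` (default), `"rbio5.5"` or `"db5"`.
#' @param window_ms window duration in ms.
#' @return a list of class `window_coefficients`: `coefficients` (named list
#'   of per-band numeric vectors), `discarded` (coefficients of the
#'   super-gamma levels), `scheme`, `family`.
#' @examples
#' wc <- decompose_window(rnorm(64), fs = 500)
#' lengths(wc$coefficients)  # delta 1, theta 1, alpha 2, beta 4, gamma 8
#' @export
decompose_window <- function(x, fs, wavelet_family = "bior5.5", window_ms = 128) {
  mats <- dwt_matrices(fs, window_ms, wavelet_family)
  n <- mats$scheme$window_n
  if (abs(length(x) - round(fs * window_ms / 1000)) > 1) {
    stop_rwenet(sprintf("window has %d samples; expected %d (= %g ms at %g Hz)",
                        length(x), n, window_ms, fs), "rwenet_parameter_error")
  }
  if (length(x) > n) x <- x[seq_len(n)]
  if (length(x) < n) x <- c(x, rep(x[length(x)], n - length(x)))
  cf <- drop(mats$W %*% x)
  idx <- mats$scheme$index
  coefs <- lapply(rwenet_band_names, function(b) unname(cf[idx == b]))
  names(coefs) <- rwenet_band_names
  structure(list(coefficients = coefs,
                 discarded = unname(cf[grepl("^discard", idx)]),
                 scheme = mats$scheme, family = wavelet_family),
            class = "window_coefficients")
}

#' Reconstruct a window from all of its wavelet coefficients
#'
#' Inverse of [decompose_window()] using the synthesis filter bank; with the
#' discarded levels included the reconstruction is exact (perfect
#' reconstruction of the cascade).
#'
#' @param wc a `window_coefficients` object.
#' @return numeric vector of window samples.
#' @export
reconstruct_window <- function(wc) {
  stopifnot(inherits(wc, "window_coefficients"))
  mats <- dwt_matrices(wc$scheme$fs, 1000 * wc$scheme$window_n / wc$scheme$fs,
                       wc$family)
  cf <- numeric(wc$scheme$window_n)
  idx <- wc$scheme$index
  for (b in rwenet_band_names) cf[idx == b] <- wc$coefficients[[b]]
  cf[grepl("^discard", idx)] <- wc$discarded
  drop(mats$S %*% cf)
}

#' Absolute band energies of a decomposed window
#'
#' The energy of each rhythm is the sum of its squared wavelet coefficients.
#'
#' @param wc a `window_coefficients` object from [decompose_window()].
#' @return named numeric vector of 5 nonnegative energies (delta..gamma).
#' @export
band_energy <- function(wc) {
  stopifnot(inherits(wc, "window_coefficients"))
  vapply(wc$coefficients, function(ck) sum(ck^2), numeric(1))
}

#' Relative band-energy distribution
#'
#' Normalizes the five band energies by the total retained energy, giving the
#' probability distribution that the synchronization measure compares between
#' electrodes.
#'
#' @param E named numeric vector of 5 nonnegative band energies.
#' @param label optional electrode label carried along.
#' @param window optional window index carried along.
#' @return object of class `energy_distribution`: `p` (5 probabilities summing
#'   to 1), `E_tot`, `label`, `window`.
#' @export
relative_energy <- function(E, label = NA_character_, window = NA_integer_) {
  if (length(E) != 5L || any(E < 0) || any(!is.finite(E))) {
    stop_rwenet("E must be 5 nonnegative finite energies", "rwenet_parameter_error")
  }
  tot <- sum(E)
  if (tot <= 0) {
    stop_rwenet("degenerate window: total band energy is zero, relative energies undefined",
                "rwenet_degenerate_window")
  }
  structure(list(p = stats::setNames(as.numeric(E) / tot, rwenet_band_names),
                 E_tot = tot, label = label, window = window),
            class = "energy_distribution")
}

#' Tidy table of per-window relative band energies
#'
#' Exports the intermediate quantity of the pipeline — one relative
#' band-energy distribution per electrode per 128-ms window — as a tidy
#' data.frame suitable for CSV export or inspection.
#'
#' @param epochs list of `eeg_epoch` objects (or a single epoch/recording).
#' @param wavelet_family,window_ms passed to the wavelet cascade.
#' @return data.frame with columns `epoch`, `window`, `electrode`,
#'   `p_delta` .. `p_gamma`, `E_tot`; degenerate windows carry NA
#'   probabilities.
#' @export
band_energy_table <- function(epochs, wavelet_family = "bior5.5",
                              window_ms = 128) {
  if (inherits(epochs, "eeg_recording") || inherits(epochs, "eeg_epoch")) {
    epochs <- list(epochs)
  }
  out <- lapply(seq_along(epochs), function(e) {
    d <- epoch_energy_distributions(epochs[[e]], wavelet_family, window_ms)
    n_ch <- dim(d$p)[1]; n_win <- dim(d$p)[2]
    df <- data.frame(epoch = e,
                     window = rep(seq_len(n_win), each = n_ch),
                     electrode = rep(epochs[[e]]$labels, n_win))
    pm <- matrix(d$p, n_ch * n_win, 5)   # channel fastest, then window
    colnames(pm) <- paste0("p_", rwenet_band_names)
    cbind(df, pm, E_tot = as.vector(d$E_tot))
  })
  do.call(rbind, out)
}

# Vectorized per-epoch energy distributions: returns list(
#   p     = array [n_channels x n_windows x 5] of relative band energies,
#   E_tot = matrix [n_channels x n_windows],
#   degenerate = logical matrix [n_channels x n_windows])
# One matrix multiply per channel batch; windows are non-overlapping and a
# trailing partial window is dropped.
epoch_energy_distributions <- function(epoch, wavelet_family = "bior5.5",
                                       window_ms = 128) {
  mats <- dwt_matrices(epoch$fs, window_ms, wavelet_family)
  n <- mats$scheme$window_n
  n_ch <- nrow(epoch$data)
  n_win <- floor(ncol(epoch$data) / n)
  if (n_win < 1) {
    stop_rwenet("epoch shorter than one analysis window", "rwenet_data_error")
  }
  keep <- mats$scheme$index %in% rwenet_band_names
  Wk <- mats$W[keep, , drop = FALSE]
  bandf <- factor(mats$scheme$index[keep], levels = rwenet_band_names)
  p <- array(NA_real_, c(n_ch, n_win, 5),
             dimnames = list(epoch$labels, NULL, rwenet_band_names))
  E_tot <- matrix(NA_real_, n_ch, n_win)
  for (ch in seq_len(n_ch)) {
    X <- matrix(epoch$data[ch, seq_len(n * n_win)], nrow = n)
    E <- rowsum((Wk %*% X)^2, bandf)                  # 5 x n_win
    tot <- colSums(E)
    E_tot[ch, ] <- tot
    ok <- tot > 0
    p[ch, ok, ] <- t(E[, ok, drop = FALSE]) / tot[ok]
  }
  list(p = p, E_tot = E_tot, degenerate = E_tot <= 0)
}
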