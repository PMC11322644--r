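#' Line length of a signal window
#'
#' Mean absolute first difference scaled to per-millisecond units:
#' `LL = sum(|x_i - x_(i-1)|) / N * sf / 1000`, with `N` the number of
#' samples in the window and `sf` the sampling frequency in Hz. Line length
#' quantifies the excursion of an iEEG trace and serves both as the
#' evoked-response magnitude (250 ms post-pulse window) and as a passive
#' signature (4 s epochs).
#'
#' @param x numeric signal window (at least 2 samples).
#' @param sampling_rate_hz sampling frequency in Hz.
#' @return Line length in signal units per millisecond.
#' @examples
#' line_length(c(0, 1, 0, 1), 2000)  # 1.5
#' @export
line_length <- function(x, sampling_rate_hz) {
  if (length(x) < 2) stop("line length needs at least 2 samples")
  sum(abs(diff(x))) / length(x) * sampling_rate_hz / 1000
}

#' Population variance of an epoch
#'
#' Variance with the `1/N` normalisation (not the sample `1/(N-1)` form).
#'
#' @param x numeric epoch.
#' @return Variance in squared signal units.
#' @export
epoch_variance <- function(x) {
  mean((x - mean(x))^2)
}

#' Adjusted Fisher--Pearson skewness of an epoch
#'
#' The third standardised moment with the `sqrt(N(N-1))/(N-2)` small-sample
#' adjustment, computed with the population standard deviation.
#'
#' @param x numeric epoch with at least 3 samples.
#' @return Dimensionless skewness.
#' @export
epoch_skewness <- function(x) {
  n <- length(x)
  if (n < 3) stop("skewness needs at least 3 samples")
  s <- sqrt(epoch_variance(x))
  if (s == 0) stop("skewness undefined for a constant epoch (zero variance)")
  sqrt(n * (n - 1)) / (n - 2) * mean((x - mean(x))^3) / s^3
}

#' Autocorrelation half-width of an epoch
#'
#' Normalised autocorrelation function (lag-`k` autocovariance divided by
#' the lag-0 value) and its width at half maximum: the first lag at which
#' the function drops below 0.5, linearly interpolated between integer lags
#' for resolution at short half-widths. Critical slowing lengthens the
#' half-width.
#'
#' @param x numeric epoch (non-constant).
#' @param sampling_rate_hz sampling frequency; when given, the half-width is
#'   returned in milliseconds, otherwise in lag samples.
#' @param max_lag largest lag examined.
#' @return Half-width (ms if `sampling_rate_hz` is given, else samples), or
#'   `NA` if the function never drops below 0.5 within `max_lag`.
#' @examples
#' set.seed(1)
#' autocorr_halfwidth(rnorm(4000))  # white noise: < 1 lag
#' @export
autocorr_halfwidth <- function(x, sampling_rate_hz = NULL,
                               max_lag = min(length(x) - 1, 500)) {
  if (stats::sd(x) == 0) stop("autocorrelation undefined for a constant epoch")
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  below <- which(a < 0.5)
  if (!length(below)) return(NA_real_)
  k <- below[1]                       # acf index; lag = k - 1
  hw <- if (k == 1) 0 else (k - 2) + (a[k - 1] - 0.5) / (a[k - 1] - a[k])
  if (is.null(sampling_rate_hz)) hw else hw * 1000 / sampling_rate_hz
}

#' Mean pairwise spatial correlation
#'
#' Pearson correlation for every unordered channel pair over the same
#' epoch, averaged across pairs. Pairs involving a constant channel are
#' skipped with a warning.
#'
#' @param signal channels x samples matrix.
#' @return Mean pairwise Pearson r.
#' @export
spatial_correlation <- function(signal) {
  if (nrow(signal) < 2) stop("spatial correlation needs >= 2 channels")
  sds <- apply(signal, 1, stats::sd)
  if (any(sds == 0)) {
    warning("skipping ", sum(sds == 0), " constant channel(s)")
    signal <- signal[sds > 0, , drop = FALSE]
    if (nrow(signal) < 2) return(NA_real_)
  }
  cm <- stats::cor(t(signal))
  mean(cm[upper.tri(cm)])
}

#' Narrow-band filter used for the passive signatures
#'
#' Zero-phase 4th-order Butterworth band-pass whose edges are fixed in
#' normalised frequency (cycles per sample): 0.00025--0.05, i.e. the
#' 0.5--100 Hz band at the 2 kHz acquisition rate of the in-vivo pipeline.
#' Expressing the band per sample keeps the filter response identical for
#' signals at other rates (notably the 100 Hz simulation proxy), so
#' variance, skewness and autocorrelation are measured on the same relative
#' passband everywhere. Line length is deliberately computed on the
#' unfiltered (wide-band) signal, as in the evoked-response pipeline.
#'
#' @param x numeric signal.
#' @param band_norm band edges in cycles/sample.
#' @return Filtered signal.
#' @export
narrowband_filter <- function(x, band_norm = c(0.00025, 0.05)) {
  bf <- signal::butter(4, band_norm * 2, type = "pass")
  # demean first: the high-pass edge is so low that a DC offset would
  # otherwise leak in as an edge transient on short segments
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Extract stimulation-free passive epochs
#'
#' Non-overlapping windows of `epoch_s` seconds whose start lies at least
#' `min_gap_pre_s` after the preceding stimulation event and whose end lies
#' at least `min_gap_post_s` before the next one (so an epoch sits "between
#' two pulses", 4 s away from the last).
#'
#' @param rec an [ieeg_recording()] (or any list with `signal`, `fs`,
#'   `events$onset_sample`).
#' @param epoch_s epoch length in seconds.
#' @param min_gap_pre_s required clearance after the previous event.
#' @param min_gap_post_s required clearance before the next event.
#' @return Tibble with columns `start_sample`, `end_sample` (inclusive).
#' @export
extract_passive_epochs <- function(rec, epoch_s = 4, min_gap_pre_s = 4,
                                   min_gap_post_s = 0) {
  fs <- rec$fs
  n <- ncol(rec$signal)
  len <- round(epoch_s * fs)
  ev <- sort(rec$events$onset_sample)
  starts <- integer(0)
  # candidate segments between consecutive events (and record edges)
  bounds <- c(0, ev, n + 1)
  for (i in seq_len(length(bounds) - 1)) {
    lo <- bounds[i] + if (i == 1) 0 else round(min_gap_pre_s * fs)
    hi <- bounds[i + 1] - 1 - round(min_gap_post_s * fs)
    s <- lo + 1
    while (s + len - 1 <= hi) {
      starts <- c(starts, s)
      s <- s + len
    }
  }
  if (!length(starts))
    message("no eligible passive epoch found")
  tibble::tibble(start_sample = starts, end_sample = starts + len - 1L)
}

# The four univariate passive signatures of one epoch. Line length uses the
# wide-band signal; the other three the narrow-band filtered version.
epoch_signatures <- function(x, sampling_rate_hz, filtered = NULL) {
  if (is.null(filtered)) filtered <- narrowband_filter(x)
  c(line_length = line_length(x, sampling_rate_hz),
    variance = epoch_variance(filtered),
    skewness = epoch_skewness(filtered),
    autocorr_halfwidth = autocorr_halfwidth(filtered, sampling_rate_hz))
}

#' Passive critical-slowing signatures of a recording
#'
#' Computes the per-channel univariate signatures (line length, variance,
#' skewness, autocorrelation half-width) on every stimulation-free epoch,
#' plus the epoch's mean spatial correlation across channels, and returns
#' them in tidy form. The narrow-band convention of [narrowband_filter()]
#' applies to variance/skewness/autocorrelation; line length uses the
#' wide-band signal.
#'
#' @param rec an [ieeg_recording()].
#' @param epochs optional epoch table from [extract_passive_epochs()].
#' @param ... passed to [extract_passive_epochs()].
#' @return Tibble with columns `epoch`, `channel`, `signature`, `value`
#'   (spatial correlation appears once per epoch with `channel = NA`).
#' @export
passive_signatures <- function(rec, epochs = NULL, ...) {
  if (is.null(epochs)) epochs <- extract_passive_epochs(rec, ...)
  fs <- rec$fs
  labs <- rec$channel_labels
  purrr::map_dfr(seq_len(nrow(epochs)), function(i) {
    idx <- epochs$start_sample[i]:epochs$end_sample[i]
    seg <- rec$signal[, idx, drop = FALSE]
    per_ch <- purrr::map_dfr(seq_len(nrow(seg)), function(ch) {
      s <- epoch_signatures(seg[ch, ], fs)
      tibble::tibble(epoch = i, channel = labs[ch],
                     signature = names(s), value = unname(s))
    })
    sc <- if (nrow(seg) >= 2) {
      filt <- t(apply(seg, 1, narrowband_filter))
      suppressWarnings(spatial_correlation(filt))
    } else NA_real_
    dplyr::bind_rows(per_ch,
                     tibble::tibble(epoch = i, channel = NA_character_,
                                    signature = "spatial_correlation",
                                    value = sc))
  })
}

#' Write a tidy signature table to CSV
#'
#' @param signatures tibble from [passive_signatures()].
#' @param path output CSV path.
#' @param session,condition optional identifiers added as columns.
#' @return `path`, invisibly.
#' @export
write_signature_table <- function(signatures, path, session = NA,
                                  condition = NA) {
  out <- dplyr::mutate(signatures, session = session,
                       condition = condition, .before = 1)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
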