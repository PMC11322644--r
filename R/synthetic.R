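#' Multi-channel iEEG recording container
#'
#' Common container for synthetic, simulated and imported recordings:
#' a channels x samples signal matrix (microvolts), sampling rate, channel
#' labels (lead letter + contact number, e.g. `"A1"`), a stimulation-event
#' table, a condition label and the montage type.
#'
#' @param signal channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one per row of `signal`.
#' @param events tibble with columns `onset_sample`, `onset_s`, `site`,
#'   `intensity` (normalised to `[0, 1]`), `pulse_width_ms`, `protocol`.
#' @param condition condition label (`"low"`, `"normal"`, `"high"`, ...).
#' @param montage `"monopolar"` or `"bipolar"`.
#' @param meta free-form metadata list (seed, generating config, log).
#' @return An object of class `ieeg_recording`.
#' @export
ieeg_recording <- function(signal, fs, channel_labels = NULL, events = NULL,
                           condition = NA_character_, montage = "monopolar",
                           meta = list()) {
  signal <- as.matrix(signal)
  if (is.null(channel_labels))
    channel_labels <- paste0(rep(LETTERS, each = 9)[seq_len(nrow(signal))],
                             rep(1:9, length.out = nrow(signal)))
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  if (is.null(events))
    events <- tibble::tibble(event_id = integer(0), onset_sample = integer(0),
                             onset_s = numeric(0), site = character(0),
                             intensity = numeric(0), pulse_width_ms = numeric(0),
                             protocol = character(0))
  stopifnot(fs > 0, length(channel_labels) == nrow(signal),
            all(events$onset_sample >= 1),
            all(events$onset_sample <= ncol(signal)))
  structure(list(signal = signal, fs = fs, channel_labels = channel_labels,
                 events = events, condition = condition, montage = montage,
                 meta = meta),
            class = "ieeg_recording")
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat("<ieeg_recording> ", nrow(x$signal), "channels x", ncol(x$signal),
      "samples @", x$fs, "Hz (", round(ncol(x$signal) / x$fs, 1), "s )\n")
  cat("  montage:", x$montage, " condition:", x$condition, " events:",
      nrow(x$events), "\n")
  invisible(x)
}

#' Configuration of the synthetic iEEG generator
#'
#' Describes a mouse-like stimulation session: 12 depth-electrode channels
#' at 2 kHz, single pulses at graded intensities with 8--12 s inter-stimulus
#' intervals, AR(1) background whose lag-1 autocorrelation and evoked
#' response gain depend on the excitability condition, 50 Hz line noise,
#' per-channel propagation delays and amplitudes, and a high-amplitude
#' stimulation artifact in the -2..10 ms peri-stimulus window.
#'
#' Condition defaults encode the ground-truth ordering low < normal < high
#' for both the evoked gain and the background autocorrelation, so
#' downstream metrics have a known direction.
#'
#' @param n_channels number of channels (>= 2).
#' @param sampling_rate_hz sampling rate.
#' @param condition `"low"`, `"normal"` or `"high"` excitability.
#' @param backend `"parametric"` (phenomenological templates) or
#'   `"epileptor"` (stochastic model proxy mixed to channels).
#' @param evoked_gain evoked-response multiplier; default by condition
#'   (0.6 / 1 / 1.6).
#' @param ar_coefficient lag-1 autocorrelation of the AR(1) background;
#'   default by condition (0.90 / 0.92 / 0.94).
#' @param background_sd_uv standard deviation of the AR(1) innovations; the
#'   stationary background SD is `background_sd_uv / sqrt(1 - phi^2)`, so
#'   higher-autocorrelation conditions also carry higher variance (the
#'   critical-slowing direction).
#' @param evoked_amp_uv evoked template peak amplitude at unit gain.
#' @param propagation_delays_ms per-channel delay of the evoked response.
#' @param channel_weights per-channel evoked amplitude weights.
#' @param line_noise_hz,line_noise_uv mains frequency and amplitude.
#' @param artifact_uv stimulation-artifact amplitude.
#' @param isi_range_s inter-stimulus interval range (uniform).
#' @param sigmoid_mid,sigmoid_slope parameters of the saturating
#'   intensity-to-amplitude logistic map.
#' @param seed RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 12, sampling_rate_hz = 2000,
                             condition = c("normal", "low", "high"),
                             backend = c("parametric", "epileptor"),
                             evoked_gain = NULL, ar_coefficient = NULL,
                             background_sd_uv = 20, evoked_amp_uv = 250,
                             propagation_delays_ms = NULL,
                             channel_weights = NULL,
                             line_noise_hz = 50, line_noise_uv = 5,
                             artifact_uv = 1500,
                             isi_range_s = c(8, 12),
                             sigmoid_mid = 0.4, sigmoid_slope = 0.12,
                             seed = 1L) {
  condition <- match.arg(condition)
  backend <- match.arg(backend)
  if (is.null(evoked_gain))
    evoked_gain <- c(low = 0.6, normal = 1, high = 1.6)[[condition]]
  if (is.null(ar_coefficient))
    ar_coefficient <- c(low = 0.90, normal = 0.92, high = 0.94)[[condition]]
  if (is.null(propagation_delays_ms))
    propagation_delays_ms <- seq(0, 6, length.out = n_channels)
  if (is.null(channel_weights))
    channel_weights <- seq(1, 0.4, length.out = n_channels)
  stopifnot(n_channels >= 2, ar_coefficient >= 0, ar_coefficient < 1,
            all(propagation_delays_ms >= 0), all(channel_weights >= 0),
            isi_range_s[1] <= isi_range_s[2])
  structure(list(n_channels = n_channels, sampling_rate_hz = sampling_rate_hz,
                 condition = condition, backend = backend,
                 evoked_gain = evoked_gain, ar_coefficient = ar_coefficient,
                 background_sd_uv = background_sd_uv,
                 evoked_amp_uv = evoked_amp_uv,
                 propagation_delays_ms = propagation_delays_ms,
                 channel_weights = channel_weights,
                 line_noise_hz = line_noise_hz, line_noise_uv = line_noise_uv,
                 artifact_uv = artifact_uv, isi_range_s = isi_range_s,
                 sigmoid_mid = sigmoid_mid, sigmoid_slope = sigmoid_slope,
                 seed = seed),
            class = "synthetic_config")
}

# default labels: leads A, B, C, ... with 2 contacts each
synthetic_labels <- function(n_channels) {
  leads <- rep(LETTERS, each = 2)[seq_len(n_channels)]
  contacts <- rep(1:2, length.out = n_channels)
  paste0(leads, contacts)
}

#' Saturating intensity-to-amplitude map
#'
#' Scaled logistic in normalised intensity, anchored so that intensity 0
#' maps to 0 and intensity 1 to 1. Mirrors the sigmoid shape of the
#' in-silico input-output curve.
#'
#' @param intensity values in `[0, 1]`.
#' @param mid,slope logistic midpoint and slope.
#' @return Values in `[0, 1]`, monotone non-decreasing in `intensity`.
#' @export
intensity_saturation <- function(intensity, mid = 0.4, slope = 0.12) {
  l <- function(x) stats::plogis(x, location = mid, scale = slope)
  (l(intensity) - l(0)) / (l(1) - l(0))
}

# CCEP-like evoked template: two negative deflections over ~250 ms,
# unit peak amplitude.
evoked_template <- function(fs, duration_ms = 250) {
  t <- seq(0, duration_ms / 1000, by = 1 / fs)
  doe <- function(t0, tr, td) {
    u <- pmax(t - t0, 0)
    exp(-u / td) - exp(-u / tr)
  }
  w <- -(doe(0.005, 0.004, 0.020) + 0.45 * doe(0.080, 0.025, 0.060))
  w / max(abs(w))
}

# biphasic high-amplitude artifact spanning the [-2, 10] ms window
artifact_template <- function(fs) {
  pre <- round(0.002 * fs)
  post <- round(0.010 * fs)
  t <- seq(-pre, post) / fs
  a <- ifelse(t < 0, 1, -exp(-t / 0.003))
  list(offsets = seq(-pre, post), shape = a)
}

ar1_background <- function(n, phi, innov_sd) {
  ar1_noise_cpp(n, phi, innov_sd)
}

#' Generate a synthetic stimulation session
#'
#' Background per channel is AR(1) noise with the condition's lag-1
#' autocorrelation plus common-mode line noise; each stimulation event adds
#' a CCEP-like damped evoked template scaled by
#' `evoked_gain * channel_weight * intensity_saturation(intensity)` and
#' delayed by the channel's propagation delay, plus a brief high-amplitude
#' artifact in the -2..10 ms peri-stimulus window. Deterministic given the
#' config seed.
#'
#' @param cfg a [synthetic_config()].
#' @param protocol `"single_pulse"`, `"paired_pulse"` or `"train"`.
#' @param n_stimulations number of stimulation events (for trains: pulses).
#' @param intensities normalised intensity grid in `[0, 1]`, recycled over
#'   events in randomised order.
#' @param ipi_ms paired-pulse inter-pulse interval.
#' @param train_hz train frequency.
#' @return An [ieeg_recording()].
#' @examples
#' rec <- generate_session(synthetic_config(seed = 7), n_stimulations = 5)
#' rec
#' @export
generate_session <- function(cfg, protocol = c("single_pulse", "paired_pulse",
                                               "train"),
                             n_stimulations = 60,
                             intensities = seq(1, 12) / 12,
                             ipi_ms = 50, train_hz = 20) {
  protocol <- match.arg(protocol)
  stopifnot(all(intensities >= 0), all(intensities <= 1))
  fs <- cfg$sampling_rate_hz
  set.seed(cfg$seed)

  isi <- stats::runif(n_stimulations, cfg$isi_range_s[1], cfg$isi_range_s[2])
  lead_in <- 5
  onset_s <- switch(protocol,
    single_pulse = lead_in + cumsum(isi) - isi[1],
    paired_pulse = {
      first <- lead_in + cumsum(isi) - isi[1]
      sort(c(first, first + ipi_ms / 1000))
    },
    train = lead_in + seq(0, by = 1 / train_hz,
                          length.out = n_stimulations))
  n_events <- length(onset_s)
  intens <- rep(sample(rep(intensities,
                           length.out = n_stimulations)),
                length.out = n_events)
  onset_sample <- round(onset_s * fs) + 1L
  dur_s <- max(onset_s) + lead_in
  n <- ceiling(dur_s * fs)

  tmpl <- evoked_template(fs)
  # within a pair (or a train) evoked templates may superpose by design;
  # distinct stimulation groups must stay separated
  group_gap <- switch(protocol,
                      single_pulse = diff(sort(onset_sample)),
                      paired_pulse = diff(sort(onset_sample)[c(TRUE, FALSE)]),
                      train = Inf)
  if (any(group_gap <= length(tmpl)))
    stop("stimulation events closer than the evoked-template duration")
  art <- artifact_template(fs)
  tvec <- seq_len(n) / fs
  line <- cfg$line_noise_uv * sin(2 * pi * cfg$line_noise_hz * tvec)
  sig <- matrix(0, cfg$n_channels, n)
  sat <- intensity_saturation(intens, cfg$sigmoid_mid, cfg$sigmoid_slope)
  for (ch in seq_len(cfg$n_channels)) {
    x <- ar1_background(n, cfg$ar_coefficient, cfg$background_sd_uv) + line
    delay <- round(cfg$propagation_delays_ms[ch] / 1000 * fs)
    amp <- cfg$evoked_gain * cfg$channel_weights[ch] * cfg$evoked_amp_uv
    for (e in seq_len(n_events)) {
      idx <- onset_sample[e] + delay + seq_along(tmpl) - 1L
      ok <- idx <= n
      x[idx[ok]] <- x[idx[ok]] + amp * sat[e] * tmpl[ok]
      aidx <- onset_sample[e] + art$offsets
      ok <- aidx >= 1 & aidx <= n
      x[aidx[ok]] <- x[aidx[ok]] + cfg$artifact_uv * art$shape[ok]
    }
    sig[ch, ] <- x
  }
  events <- tibble::tibble(event_id = seq_len(n_events),
                           onset_sample = as.integer(onset_sample),
                           onset_s = onset_s, site = "S1",
                           intensity = intens, pulse_width_ms = 3,
                           protocol = protocol)
  ieeg_recording(sig, fs, synthetic_labels(cfg$n_channels), events,
                 condition = cfg$condition,
                 meta = list(seed = cfg$seed, config = unclass(cfg)))
}

#' Generate a session from the stochastic Epileptor backend
#'
#' Uses the stochastic Epileptor's iEEG proxy (at its native 100 Hz
#' sampling) as the common source, linearly mixed to channels:
#' `channel_i = weight_i * proxy(t - delay_i) + AR(1) noise`. Stimulation
#' events are forwarded from the simulated pulse train, with the pulse
#' amplitude scale recorded as the normalised intensity. The condition
#' label derives from `x0` (-2.30 low, -2.25 normal, -2.20 high).
#'
#' @param cfg a [synthetic_config()] (channel count, AR background, weights
#'   and delays are used; the sampling rate is the proxy's 100 Hz).
#' @param params an [epileptor_params()].
#' @param n_stimulations number of single pulses.
#' @param intensities normalised intensity grid (amplitude scale on the
#'   stimulation inputs), recycled in randomised order.
#' @param noise_sd_uv standard deviation of the additive channel noise, in
#'   the units of the scaled proxy.
#' @param scale_uv multiplicative conversion of the dimensionless proxy.
#' @return An [ieeg_recording()].
#' @export
generate_epileptor_backend_session <- function(cfg, params,
                                               n_stimulations = 24,
                                               intensities = seq(1, 12) / 12,
                                               noise_sd_uv = 2,
                                               scale_uv = 100) {
  fs <- 1000 / params$ms_per_unit
  set.seed(cfg$seed)
  isi <- stats::runif(n_stimulations, cfg$isi_range_s[1], cfg$isi_range_s[2])
  onset_s <- 5 + cumsum(isi) - isi[1]
  onset_s <- round(onset_s * fs) / fs      # align pulses to the output grid
  intens <- sample(rep(intensities, length.out = n_stimulations))
  dur_s <- max(onset_s) + 5

  init <- initial_state(params)
  # segment-wise integration so each pulse carries its own amplitude scale
  seg_bounds <- c(0, onset_s * 1000, dur_s * 1000)
  state <- init
  trace <- NULL
  for (i in seq_len(length(seg_bounds) - 1)) {
    seg_ms <- seg_bounds[i + 1] - seg_bounds[i]
    if (seg_ms <= 0) next
    if (i == 1) {
      stim <- NULL
    } else {
      stim <- build_stimulus("single-pulse",
                             intensity_scale = intens[i - 1])
      stim$onsets_ms <- 0
    }
    sim <- simulate_epileptor(params, duration_s = seg_ms / 1000,
                              stim = stim, initial = state,
                              stochastic = TRUE, detect = FALSE)
    state <- unlist(sim$trace[nrow(sim$trace),
                              c("x1", "y1", "z", "x2", "y2", "g")])
    trace <- c(trace, sim$trace$ieeg)
  }
  proxy <- trace * scale_uv
  proxy <- proxy - mean(proxy)
  n <- length(proxy)
  sig <- matrix(0, cfg$n_channels, n)
  for (ch in seq_len(cfg$n_channels)) {
    delay <- round(cfg$propagation_delays_ms[ch] / 1000 * fs)
    shifted <- c(rep(proxy[1], delay), proxy)[seq_len(n)]
    noise <- if (noise_sd_uv > 0)
      ar1_background(n, cfg$ar_coefficient, noise_sd_uv) else 0
    sig[ch, ] <- cfg$channel_weights[ch] * shifted + noise
  }
  onset_sample <- pmin(round(onset_s * fs) + 1L, n)
  events <- tibble::tibble(event_id = seq_along(onset_s),
                           onset_sample = as.integer(onset_sample),
                           onset_s = onset_s, site = "S1",
                           intensity = intens, pulse_width_ms = 3,
                           protocol = "single_pulse")
  condition <- if (params$x0 <= -2.30) "low" else
    if (params$x0 >= -2.20) "high" else "normal"
  ieeg_recording(sig, fs, synthetic_labels(cfg$n_channels), events,
                 condition = condition,
                 meta = list(seed = cfg$seed, x0 = params$x0,
                             backend = "epileptor"))
}

#' Derive a stage seed from a master seed
#'
#' Deterministic counter scheme: `(master * 10007 + index) mod (2^31 - 1)`,
#' with named stages mapped to fixed indices, so any pipeline stage can be
#' re-run in isolation.
#'
#' @param master master seed (integer).
#' @param index stage counter or stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(master, index) {
  if (is.character(index))
    index <- sum(utf8ToInt(index))
  as.integer((as.numeric(master) * 10007 + as.numeric(index)) %% (2^31 - 1))
}

#' Generate a balanced labelled dataset
#'
#' `n_sessions_per_condition` synthetic sessions for each excitability
#' condition (low, normal, high), with per-session seeds derived
#' deterministically from the master seed.
#'
#' @param n_sessions_per_condition sessions per class.
#' @param cfg_base a [synthetic_config()] whose condition/seed are
#'   overridden per session.
#' @param seed master seed.
#' @param ... passed to [generate_session()].
#' @return List of [ieeg_recording()] objects with balanced condition labels.
#' @export
generate_labelled_dataset <- function(n_sessions_per_condition, cfg_base = NULL,
                                      seed = 1, ...) {
  stopifnot(n_sessions_per_condition >= 1)
  if (is.null(cfg_base)) cfg_base <- synthetic_config()
  conds <- c("low", "normal", "high")
  idx <- 0
  recs <- list()
  for (cond in conds) {
    for (i in seq_len(n_sessions_per_condition)) {
      idx <- idx + 1
      cfg <- cfg_base
      cfg$condition <- cond
      cfg$evoked_gain <- c(low = 0.6, normal = 1, high = 1.6)[[cond]]
      cfg$ar_coefficient <- c(low = 0.90, normal = 0.92, high = 0.94)[[cond]]
      cfg$seed <- derive_seed(seed, idx)
      recs[[idx]] <- generate_session(cfg, ...)
      recs[[idx]]$meta$session <- idx
    }
  }
  recs
}

#' Write / read a recording as CSV plus JSON sidecar
#'
#' The signal is written as a samples x channels CSV (column names are the
#' channel labels), the events as `<path>_events.csv`, and the metadata
#' (sampling rate, condition, montage, meta) as `<path>.json`.
#'
#' @param rec an [ieeg_recording()].
#' @param path base path of the CSV.
#' @return `path` invisibly (`write_recording`); an [ieeg_recording()]
#'   (`read_recording`).
#' @export
write_recording <- function(rec, path) {
  m <- t(rec$signal)
  colnames(m) <- rec$channel_labels
  utils::write.csv(m, path, row.names = FALSE)
  utils::write.csv(rec$events, sub("\\.csv$", "_events.csv", path),
                   row.names = FALSE)
  jsonlite::write_json(list(fs = rec$fs, condition = rec$condition,
                            montage = rec$montage, meta = rec$meta,
                            package_version =
                              as.character(utils::packageVersion("epiprobe"))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  m <- utils::read.csv(path, check.names = FALSE)
  ev <- utils::read.csv(sub("\\.csv$", "_events.csv", path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sig <- t(as.matrix(m))
  dimnames(sig) <- NULL
  ieeg_recording(sig, meta$fs, colnames(m),
                 tibble::as_tibble(ev), condition = meta$condition,
                 montage = meta$montage, meta = as.list(meta$meta))
}
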