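#' In-silico passive-signature contrasts
#'
#' Simulates the stochastic Epileptor at lowered, baseline and raised
#' excitability (`x0` = -2.30 / -2.25 / -2.20), chops the stationary iEEG
#' proxy into `n_epochs` four-second epochs per condition, computes the
#' four univariate passive signatures per epoch (line length on the
#' wide-band proxy; variance, skewness and autocorrelation half-width on
#' the narrow-band filtered proxy, see [narrowband_filter()]), and
#' bootstraps the mean percent change of each signature against baseline.
#'
#' @param n_epochs epochs per condition (790 by default, the full-scale
#'   experiment).
#' @param x0 named vector of excitability levels (`low`, `normal`, `high`).
#' @param epoch_s epoch length in seconds.
#' @param burn_s discarded initial transient per condition.
#' @param n_resamples bootstrap resamples.
#' @param seed master seed (per-condition seeds derived from it).
#' @return List of class `insilico_signatures`: `contrasts` (tibble:
#'   `condition`, `signature`, `pct_change`, `ci_low`, `ci_high`),
#'   `epoch_stats` (per-epoch signature values), `n_epochs`, `seed`.
#' @examples
#' \donttest{
#' run_insilico_signatures(n_epochs = 50, seed = 1)$contrasts
#' }
#' @export
run_insilico_signatures <- function(n_epochs = 790,
                                    x0 = c(low = -2.30, normal = -2.25,
                                           high = -2.20),
                                    epoch_s = 4, burn_s = 20,
                                    n_resamples = 5000, seed = 1) {
  stopifnot(all(c("low", "normal", "high") %in% names(x0)))
  sig_names <- c("line_length", "variance", "skewness",
                 "autocorr_halfwidth")
  per_cond <- purrr::imap(x0, function(x0i, cond) {
    p <- epileptor_params(x0 = x0i)
    fs <- 1000 / p$ms_per_unit
    dur_s <- burn_s + n_epochs * epoch_s
    sim <- simulate_epileptor(p, duration_s = dur_s, stochastic = TRUE,
                              seed = derive_seed(seed, cond),
                              detect = FALSE)
    proxy <- sim$trace$ieeg[-seq_len(round(burn_s * fs))]
    filt <- narrowband_filter(proxy)
    len <- round(epoch_s * fs)
    nfull <- length(proxy) %/% len
    purrr::map_dfr(seq_len(nfull), function(i) {
      idx <- ((i - 1) * len + 1):(i * len)
      s <- epoch_signatures(proxy[idx], fs, filtered = filt[idx])
      tibble::tibble(condition = cond, epoch = i, signature = names(s),
                     value = unname(s))
    })
  })
  stats_tab <- dplyr::bind_rows(per_cond)
  base <- stats_tab[stats_tab$condition == "normal", ]
  contrasts <- purrr::map_dfr(c("low", "high"), function(cond) {
    purrr::map_dfr(sig_names, function(sg) {
      a <- stats_tab$value[stats_tab$condition == cond &
                             stats_tab$signature == sg]
      b <- base$value[base$signature == sg]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      bs <- bootstrap_difference(a, b, pairing = "percent",
                                 n_resamples = n_resamples,
                                 seed = derive_seed(seed,
                                                    paste0(cond, sg)))
      tibble::tibble(condition = cond, signature = sg,
                     pct_change = bs$mean_difference,
                     ci_low = bs$ci_low, ci_high = bs$ci_high)
    })
  })
  structure(list(contrasts = contrasts, epoch_stats = stats_tab,
                 n_epochs = n_epochs, seed = seed),
            class = "insilico_signatures")
}

#' @export
print.insilico_signatures <- function(x, ...) {
  cat("<insilico_signatures>", x$n_epochs, "epochs/condition\n")
  print(x$contrasts, n = Inf)
  invisible(x)
}

#' In-silico probing: input-output curves, time-to-seizure and the
#' pre-ictal response ramp
#'
#' Three model experiments: (1) noise-free single-pulse input-output
#' curves at each excitability level (responses normalised to a reference
#' shared across levels, so curves compare amplitudes); (2)
#' time-to-seizure under a 20 Hz train at each level; (3) a ramp
#' experiment in the epileptogenic regime (`x0 = -2.0`), started from an
#' elevated (post-ictal-like) permittivity: repeated maximal single pulses
#' every 8--12 s show growing responses as the system drifts toward the
#' critical point, until a seizure occurs.
#'
#' @param x0 excitability grid for the IOC / time-to-seizure arms.
#' @param intensities normalised intensity grid.
#' @param frequency_hz train frequency for time-to-seizure.
#' @param max_train_s train duration cap.
#' @param ramp_duration_s length of the ramp simulation.
#' @param seed master seed.
#' @return List of class `insilico_probing`: `ioc` (tibble x0/ioc),
#'   `tts` (tibble x0/time_to_seizure_s), `ramp` (tibble pulse/t_s/ll with
#'   attribute `slope`), `seed`.
#' @export
run_insilico_probing <- function(x0 = c(-2.30, -2.25, -2.20),
                                 intensities = seq(1, 12) / 12,
                                 frequency_hz = 20, max_train_s = 60,
                                 ramp_duration_s = 400, seed = 1) {
  cfg <- synthetic_config(n_channels = 2, isi_range_s = c(8, 12),
                          propagation_delays_ms = c(0, 0),
                          channel_weights = c(1, 1))
  # noise-free dose-response of the model: one single pulse per intensity
  # per excitability level, response = proxy line length over 250 ms minus
  # the pre-pulse baseline line length
  resp_per_x0 <- purrr::map(x0, function(x0i) {
    p <- epileptor_params(x0 = x0i)
    fs <- 1000 / p$ms_per_unit
    win <- round(0.25 * fs)
    purrr::map_dfr(intensities, function(a) {
      st <- build_stimulus("single-pulse", intensity_scale = a)
      st$onsets_ms <- 1000
      s <- simulate_epileptor(p, duration_s = 2.5, stim = st,
                              detect = FALSE)
      i0 <- which(s$trace$t_ms >= 1000)[1]
      ll <- line_length(s$trace$ieeg[i0:(i0 + win - 1)], fs)
      ll0 <- line_length(s$trace$ieeg[(i0 - win):(i0 - 1)], fs)
      tibble::tibble(intensity = a, ll = max(ll - ll0, 0))
    })
  })
  # conditions share one normalisation reference (the block-wise maximum
  # mean response), so the IOC compares amplitudes, not just curve shapes
  ref <- max(purrr::map_dbl(resp_per_x0, function(r) max(r$ll)))
  ioc_tab <- purrr::map2_dfr(x0, resp_per_x0, function(x0i, r) {
    ioc <- input_output_curve(r, normalization = "reference",
                              reference = ref)
    tibble::tibble(x0 = x0i, ioc = attr(ioc, "ioc"))
  })
  tts_tab <- purrr::map_dfr(x0, function(x0i) {
    tibble::tibble(x0 = x0i,
                   time_to_seizure_s = time_to_seizure(
                     epileptor_params(x0 = x0i),
                     frequency_hz = frequency_hz,
                     max_duration_s = max_train_s))
  })
  ramp <- ramp_experiment(duration_s = ramp_duration_s,
                          seed = derive_seed(seed, "ramp"))
  structure(list(ioc = ioc_tab, tts = tts_tab, ramp = ramp, seed = seed),
            class = "insilico_probing")
}

# mean line length of pre-stimulus windows, as a response baseline
baseline_ll <- function(rec, channel, window_ms = 250) {
  fs <- rec$fs
  n <- round(window_ms / 1000 * fs)
  chi <- match(channel, rec$channel_labels)
  lls <- vapply(rec$events$onset_sample, function(on) {
    idx <- (on - n):(on - 1)
    if (min(idx) < 1) return(NA_real_)
    line_length(rec$signal[chi, idx], fs)
  }, 0)
  mean(lls, na.rm = TRUE)
}

# single pulses at 8-12 s intervals in the epileptogenic regime until a
# seizure; per-pulse response LL and its pre-ictal trend. The run starts
# with the permittivity z elevated (post-ictal-like), so the system drifts
# slowly toward the critical point while being probed.
ramp_experiment <- function(x0 = -2.0, duration_s = 400, z_start = 4.2,
                            seed = 1) {
  p <- epileptor_params(x0 = x0)
  fs <- 1000 / p$ms_per_unit
  set.seed(seed)
  isi <- stats::runif(ceiling(duration_s / 8), 8, 12)
  onsets_s <- 5 + cumsum(isi) - isi[1]
  onsets_s <- onsets_s[onsets_s < duration_s - 1]
  stim <- build_stimulus("single-pulse")
  stim$onsets_ms <- onsets_s * 1000
  # interictal state consistent with an elevated permittivity
  r <- polyroot(c(z_start - p$y0 - p$I1_base, 0, 2, 1))
  r <- sort(Re(r[abs(Im(r)) < 1e-8]))
  x1 <- r[r < -4 / 3][1]
  init <- c(x1, p$y0 - 5 * x1^2, z_start, -0.78, 0, x1 / p$gamma)
  sim <- simulate_epileptor(p, duration_s = duration_s, stim = stim,
                            initial = init, stochastic = TRUE,
                            seed = derive_seed(seed, "rampsim"),
                            detect = FALSE)
  onset_ms <- detect_seizure(sim, dwell_s = 5)
  win <- round(0.25 * fs)
  ll_tab <- purrr::map_dfr(seq_along(onsets_s), function(i) {
    i0 <- round(onsets_s[i] * fs) + 1
    idx <- i0:(i0 + win - 1)
    if (max(idx) > nrow(sim$trace)) return(NULL)
    tibble::tibble(pulse = i, t_s = onsets_s[i],
                   ll = line_length(sim$trace$ieeg[idx], fs))
  })
  pre <- if (is.na(onset_ms)) ll_tab else
    ll_tab[ll_tab$t_s * 1000 < onset_ms, ]
  slope <- if (nrow(pre) >= 3)
    unname(stats::coef(stats::lm(ll ~ t_s, data = pre))[2]) else NA_real_
  attr(ll_tab, "slope") <- slope
  attr(ll_tab, "seizure_onset_s") <- onset_ms / 1000
  ll_tab
}

#' End-to-end decoding rehearsal on synthetic data
#'
#' Generates a balanced labelled dataset, removes stimulation artifacts,
#' band-pass/notch filters, builds the active, passive and combined
#' feature sets, and runs the cross-validated classifiers with
#' label-permutation tests.
#'
#' @param n_sessions_per_condition sessions per excitability class.
#' @param n_pulses single pulses per session.
#' @param n_perm label permutations per classifier.
#' @param seed master seed.
#' @param cfg_base base [synthetic_config()].
#' @param preprocess run artifact removal and filtering?
#' @param n_folds cross-validation folds.
#' @return List of class `synthetic_decoding` with `classifier_report`
#'   elements `active`, `passive`, `combined` and a `summary` tibble.
#' @export
run_synthetic_decoding <- function(n_sessions_per_condition = 5,
                                   n_pulses = 12, n_perm = 30, seed = 1,
                                   cfg_base = NULL, preprocess = TRUE,
                                   n_folds = 5) {
  recs <- generate_labelled_dataset(n_sessions_per_condition, cfg_base,
                                    seed = derive_seed(seed, "dataset"),
                                    n_stimulations = n_pulses)
  if (preprocess) {
    pc <- preprocess_config("mouse")
    recs <- purrr::imap(recs, function(r, i) {
      r <- remove_stim_artifact(r, seed = derive_seed(seed, 100 + i))
      filter_and_resample(r, pc)
    })
  }
  act <- build_active_features(recs)
  pas <- build_passive_features(recs)
  cmb <- combine_features(act, pas)
  reports <- purrr::map(list(active = act, passive = pas, combined = cmb),
                        function(f)
                          permutation_test(f, n_perm = n_perm,
                                           seed = derive_seed(seed, f$kind),
                                           n_folds = n_folds))
  summary <- purrr::map_dfr(reports, glance)
  structure(c(reports, list(summary = summary, seed = seed)),
            class = "synthetic_decoding")
}

#' @export
print.synthetic_decoding <- function(x, ...) {
  cat("<synthetic_decoding>\n")
  print(x$summary)
  invisible(x)
}
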