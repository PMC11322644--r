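#' Evoked responses to stimulation pulses
#'
#' Line length of the 250 ms post-onset window for every stimulation event
#' and channel. Recordings should already be artifact-interpolated (see
#' [remove_stim_artifact()]).
#'
#' @param rec an [ieeg_recording()].
#' @param window_ms response window relative to the trigger.
#' @param channels channel labels to include (default all).
#' @return Tibble with columns `event_id`, `channel`, `intensity`, `ll`.
#' @export
evoked_response <- function(rec, window_ms = c(0, 250), channels = NULL) {
  if (!nrow(rec$events)) stop("recording has no stimulation events")
  fs <- rec$fs
  if (is.null(channels)) channels <- rec$channel_labels
  chi <- match(channels, rec$channel_labels)
  if (anyNA(chi)) stop("unknown channel label(s)")
  i0 <- round(window_ms[1] / 1000 * fs)
  i1 <- round(window_ms[2] / 1000 * fs) - 1
  purrr::map_dfr(seq_len(nrow(rec$events)), function(e) {
    idx <- rec$events$onset_sample[e] + i0:i1
    if (max(idx) > ncol(rec$signal))
      stop("response window of event ", e, " truncated by the record end")
    tibble::tibble(event_id = rec$events$event_id[e],
                   channel = channels,
                   intensity = rec$events$intensity[e],
                   ll = vapply(chi, function(ch)
                     line_length(rec$signal[ch, idx], fs), 0))
  })
}

#' Input-output curve and its area (IOC)
#'
#' Mean response per stimulation intensity, normalised to a reference, with
#' the area under the curve over the normalised intensity axis. The IOC
#' summarises excitability in one number: 0 means no response at any
#' intensity, 1 maximal response already at minimal intensity.
#'
#' @param responses tibble with columns `intensity` and `ll` (or a value
#'   column named by `value_col`).
#' @param normalization `"max"` (divide by the maximum mean response,
#'   default), `"reference"` (divide by `reference`), or `"none"`.
#' @param reference normalising constant for `normalization = "reference"`
#'   (e.g. the block-wise maximum across sessions, making conditions
#'   comparable to control).
#' @param baseline value subtracted before normalisation (e.g. baseline
#'   line length, so a flat curve yields IOC 0); default 0.
#' @param value_col name of the response column.
#' @return An object of class `ioc`: tibble with `intensity` and `response`
#'   (normalised), plus attributes `ioc` (area in `[0, 1]`) and
#'   `normalization`.
#' @examples
#' r <- tibble::tibble(intensity = rep(c(.2, .5, 1), each = 4),
#'                     ll = rep(c(.2, .5, 1), each = 4))
#' attr(input_output_curve(r), "ioc")
#' @export
input_output_curve <- function(responses,
                               normalization = c("max", "reference", "none"),
                               reference = NULL, baseline = 0,
                               value_col = "ll") {
  normalization <- match.arg(normalization)
  stopifnot(value_col %in% names(responses))
  curve <- responses |>
    dplyr::group_by(.data$intensity) |>
    dplyr::summarise(response = mean(.data[[value_col]]), .groups = "drop") |>
    dplyr::arrange(.data$intensity)
  if (nrow(curve) < 3) stop("need >= 3 intensity levels")
  curve$response <- pmax(curve$response - baseline, 0)
  ref <- switch(normalization,
                max = max(curve$response),
                reference = { stopifnot(!is.null(reference)); reference },
                none = 1)
  if (ref > 0) curve$response <- curve$response / ref
  # trapezoidal area over the intensity span, rescaled to [0, 1]
  x <- curve$intensity; y <- curve$response
  span <- diff(range(x))
  area <- if (span == 0) 0 else
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / span
  structure(curve, class = c("ioc", class(curve)), ioc = area,
            normalization = normalization)
}

#' @export
print.ioc <- function(x, ...) {
  cat("<input-output curve>  IOC area =", round(attr(x, "ioc"), 4),
      " (normalization:", attr(x, "normalization"), ")\n")
  NextMethod()
}

#' @export
glance.ioc <- function(x, ...) {
  tibble::tibble(ioc = attr(x, "ioc"), n_intensities = nrow(x),
                 normalization = attr(x, "normalization"))
}

#' @export
tidy.ioc <- function(x, ...) tibble::as_tibble(unclass(x))

#' Minimal detectable stimulation intensity (rheobase)
#'
#' The smallest intensity whose mean response exceeds the baseline mean
#' plus `k` baseline standard deviations.
#'
#' @param responses tibble with `intensity` and `ll` columns (low-intensity
#'   sweep).
#' @param baseline_ll numeric vector of baseline line-length values (e.g.
#'   from pre-stimulus windows).
#' @param k detection threshold in baseline SDs (2 by default).
#' @return The rheobase intensity, or `NA` if no level is detectable.
#' @export
estimate_rheobase <- function(responses, baseline_ll, k = 2) {
  thr <- mean(baseline_ll) + k * stats::sd(baseline_ll)
  curve <- responses |>
    dplyr::group_by(.data$intensity) |>
    dplyr::summarise(response = mean(.data$ll), .groups = "drop") |>
    dplyr::arrange(.data$intensity)
  hit <- which(curve$response > thr)
  if (!length(hit)) NA_real_ else curve$intensity[hit[1]]
}

#' Time-to-seizure of a train-protocol session
#'
#' For a session whose events describe stimulation trains of increasing
#' duration, returns the duration of the first train that provoked a
#' seizure (from a supplied seizure onset time, e.g. an annotation or
#' in-silico detection).
#'
#' @param trains tibble with columns `start_s` and `duration_s`, one row
#'   per train, in presentation order.
#' @param seizure_onset_s onset of the (first) seizure, or `NA`.
#' @return Duration (s) of the provoking train, or `NA`.
#' @export
session_time_to_seizure <- function(trains, seizure_onset_s) {
  if (is.na(seizure_onset_s)) return(NA_real_)
  hit <- which(trains$start_s <= seizure_onset_s)
  if (!length(hit)) return(NA_real_)
  trains$duration_s[max(hit)]
}

#' Bootstrap estimate of a condition difference
#'
#' Mean difference between two sets of values with a percentile 95%
#' confidence interval from `n_resamples` bootstrap resamples. Pairing
#' modes: `"paired"` resamples index pairs of equal-length vectors;
#' `"unpaired"` resamples the two groups independently; `"percent"`
#' resamples independently and reports the difference as a percentage of
#' the (resampled) control mean, the normalised-to-control convention.
#'
#' @param a,b numeric vectors (condition, control).
#' @param pairing `"unpaired"`, `"paired"` or `"percent"`.
#' @param n_resamples number of bootstrap resamples (5000 by default).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return An object of class `bootstrap_estimate` with fields
#'   `mean_difference`, `ci_low`, `ci_high`, `n_resamples`, `pairing`,
#'   `resamples`.
#' @examples
#' bootstrap_difference(rnorm(30, 1), rnorm(30), seed = 1)
#' @export
bootstrap_difference <- function(a, b,
                                 pairing = c("unpaired", "paired", "percent"),
                                 n_resamples = 5000, seed = NULL,
                                 conf = 0.95) {
  pairing <- match.arg(pairing)
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 observations per group")
  if (pairing == "paired" && length(a) != length(b))
    stop("paired bootstrap needs equal lengths")
  if (!is.null(seed)) set.seed(seed)
  stat <- switch(pairing,
    paired = function(ia, ib) mean(a[ia] - b[ia]),
    unpaired = function(ia, ib) mean(a[ia]) - mean(b[ib]),
    percent = function(ia, ib) 100 * (mean(a[ia]) - mean(b[ib])) / abs(mean(b[ib])))
  point <- stat(seq_along(a), seq_along(b))
  res <- vapply(seq_len(n_resamples), function(i) {
    stat(sample.int(length(a), replace = TRUE),
         sample.int(length(b), replace = TRUE))
  }, 0)
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(res, c(alpha, 1 - alpha)))
  structure(list(mean_difference = point, ci_low = ci[1], ci_high = ci[2],
                 n_resamples = n_resamples, pairing = pairing,
                 resamples = res),
            class = "bootstrap_estimate")
}

#' @export
print.bootstrap_estimate <- function(x, ...) {
  cat(sprintf("<bootstrap_estimate> %s: %.4g [%.4g, %.4g] (95%% CI, %d resamples)\n",
              x$pairing, x$mean_difference, x$ci_low, x$ci_high,
              x$n_resamples))
  invisible(x)
}

#' @export
tidy.bootstrap_estimate <- function(x, ...) {
  tibble::tibble(estimate = x$mean_difference, conf.low = x$ci_low,
                 conf.high = x$ci_high, n_resamples = x$n_resamples,
                 pairing = x$pairing)
}
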