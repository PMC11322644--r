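test_that("line length matches the hand-evaluated definition", {
  expect_equal(line_length(c(0, 1, 0, 1), 2000), 1.5)
  expect_equal(line_length(rep(3, 100), 1000), 0)
  x <- rnorm(50)
  expect_equal(line_length(2 * x, 500), 2 * line_length(x, 500))
  expect_error(line_length(1, 100), "2 samples")
})

test_that("variance and skewness use the population forms", {
  expect_equal(epoch_variance(c(0, 2)), 1)
  expect_equal(epoch_skewness(c(-1, 0, 1)), 0)
  expect_equal(epoch_variance(rep(5, 10)), 0)
  expect_error(epoch_skewness(rep(5, 10)), "constant")
  # adjusted Fisher-Pearson against a direct evaluation
  x <- c(1, 2, 2, 3, 10)
  n <- length(x); m <- mean(x); s <- sqrt(mean((x - m)^2))
  expect_equal(epoch_skewness(x),
               sqrt(n * (n - 1)) / (n - 2) * mean((x - m)^3) / s^3)
})

test_that("autocorrelation half-width follows the AR(1) closed form", {
  set.seed(1)
  # white noise decorrelates within the first lag
  expect_lt(autocorr_halfwidth(rnorm(4000)), 2)
  # AR(1): rho(k) = phi^k gives half-max at log(0.5)/log(phi)
  for (phi in c(0.5, 0.9)) {
    hw <- vapply(1:8, function(i) {
      set.seed(i)
      x <- as.numeric(stats::arima.sim(list(ar = phi), 20000))
      autocorr_halfwidth(x)
    }, 0)
    expect_equal(mean(hw), log(0.5) / log(phi), tolerance = 0.15)
  }
  # stronger autocorrelation, larger half-width
  set.seed(2)
  x9 <- as.numeric(stats::arima.sim(list(ar = 0.9), 5000))
  x5 <- as.numeric(stats::arima.sim(list(ar = 0.5), 5000))
  expect_gt(autocorr_halfwidth(x9), autocorr_halfwidth(x5))
  expect_gt(autocorr_halfwidth(cumsum(rep(1, 100))),
            autocorr_halfwidth(rnorm(100)))
  expect_error(autocorr_halfwidth(rep(1, 100)), "constant")
  # in milliseconds when a sampling rate is given
  set.seed(3); x <- as.numeric(stats::arima.sim(list(ar = 0.8), 5000))
  expect_equal(autocorr_halfwidth(x, 1000), autocorr_halfwidth(x))
})

test_that("spatial correlation averages pairwise Pearson r", {
  set.seed(4)
  x <- rnorm(2000)
  dup <- rbind(x, x, x)
  expect_equal(spatial_correlation(dup), 1)
  ind <- matrix(rnorm(8 * 5000), 8)
  expect_lt(abs(spatial_correlation(ind)), 0.05)
  # two channels equal the definition formula
  a <- rnorm(100); b <- rnorm(100)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2)) * sqrt(sum((b - mean(b))^2))
  expect_equal(spatial_correlation(rbind(a, b)), num / den,
               tolerance = 1e-12)
  expect_warning(sc <- spatial_correlation(rbind(a, b, rep(1, 100))),
                 "constant")
  expect_equal(sc, num / den, tolerance = 1e-12)
})

test_that("passive epochs avoid stimulation events with the stated geometry", {
  mk <- function(onsets_s, dur_s = 60, fs = 100) {
    ev <- tibble::tibble(event_id = seq_along(onsets_s),
                         onset_sample = as.integer(round(onsets_s * fs) + 1),
                         onset_s = onsets_s, site = "S1",
                         intensity = 1, pulse_width_ms = 3,
                         protocol = "single_pulse")
    if (!length(onsets_s)) ev <- ev[0, ]
    ieeg_recording(matrix(rnorm(2 * dur_s * fs), 2), fs,
                   c("A1", "A2"), ev)
  }
  # no events: floor(T / 4) epochs
  expect_equal(nrow(extract_passive_epochs(mk(numeric(0)))), 15)
  # events every 5 s with a 4 s clearance: no room for a 4 s epoch
  expect_message(
    ep <- extract_passive_epochs(mk(seq(2, 58, by = 5))),
    "no eligible")
  expect_equal(nrow(ep), 0)
  # 8-12 s intervals leave one epoch between most pulses
  rec <- generate_session(tiny_config(seed = 3), n_stimulations = 6)
  ep <- extract_passive_epochs(rec)
  expect_gte(nrow(ep), 4)
  # epochs never contain an event and start >= 4 s after the previous one
  for (i in seq_len(nrow(ep))) {
    inside <- rec$events$onset_sample >= ep$start_sample[i] &
      rec$events$onset_sample <= ep$end_sample[i]
    expect_false(any(inside))
    prev <- rec$events$onset_sample[rec$events$onset_sample <
                                      ep$start_sample[i]]
    if (length(prev))
      expect_gte(ep$start_sample[i] - max(prev), 4 * rec$fs)
  }
})

test_that("signatures respond to offset and amplitude scaling as expected", {
  set.seed(5)
  x <- as.numeric(stats::arima.sim(list(ar = 0.7), 2000))
  filt <- function(v) narrowband_filter(v)
  s1 <- epiprobe:::epoch_signatures(x, 2000)
  s2 <- epiprobe:::epoch_signatures(x + 100, 2000)
  expect_equal(s1, s2, tolerance = 1e-2)
  s3 <- epiprobe:::epoch_signatures(3 * x, 2000)
  expect_equal(unname(s3["line_length"]), unname(3 * s1["line_length"]))
  expect_equal(unname(s3["variance"]), unname(9 * s1["variance"]),
               tolerance = 1e-4)
  expect_equal(unname(s3["skewness"]), unname(s1["skewness"]),
               tolerance = 1e-2)
  expect_equal(unname(s3["autocorr_halfwidth"]),
               unname(s1["autocorr_halfwidth"]), tolerance = 1e-4)
})

test_that("tidy signature tables cover every channel, epoch and signature", {
  rec <- cached_session
  tab <- passive_signatures(rec)
  expect_true(all(c("line_length", "variance", "skewness",
                    "autocorr_halfwidth", "spatial_correlation") %in%
                    tab$signature))
  per_epoch <- table(tab$epoch)
  expect_true(all(per_epoch == 4 * nrow(rec$signal) + 1))
  path <- file.path(tempdir(), "sigs.csv")
  write_signature_table(tab, path, session = 1, condition = rec$condition)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$condition[1], "normal")
})
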