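# Small shared fixtures. Sessions are deliberately tiny (few pulses, short
# inter-stimulus intervals where the geometry allows) so the suite stays fast;
# full-scale study conditions are exercised in test-acceptance.R.

tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_channels = 4, seed = seed,
                   propagation_delays_ms = c(0, 1, 2, 3),
                   channel_weights = c(1, 0.8, 0.6, 0.4), ...)
}

# cache: one preprocessed 4-channel session reused across tests
local({
  cfg <- tiny_config(seed = 11)
  rec <- generate_session(cfg, n_stimulations = 8)
  assign("cached_session", rec, envir = topenv())
  assign("cached_clean",
         remove_stim_artifact(rec, seed = 2), envir = topenv())
})

tiny_dataset <- function(n = 2, seed = 5, n_pulses = 6) {
  cfg <- tiny_config()
  generate_labelled_dataset(n, cfg, seed = seed, n_stimulations = n_pulses)
}

expect_monotone_increasing <- function(x, strict = TRUE) {
  if (strict) expect_true(all(diff(x) > 0)) else expect_true(all(diff(x) >= 0))
}
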