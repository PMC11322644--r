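# small separable feature set: 3 classes, gaussian clusters
toy_features <- function(n_per_class = 20, n_sessions = 4, sep = 3,
                         n_feat = 6, seed = 1) {
  set.seed(seed)
  classes <- c("low", "normal", "high")
  x <- NULL; y <- character(0); sess <- integer(0)
  s_id <- 0
  for (cl in seq_along(classes)) {
    mu <- rep(0, n_feat); mu[cl] <- sep
    for (s in seq_len(n_sessions)) {
      s_id <- s_id + 1
      n <- ceiling(n_per_class / n_sessions)
      x <- rbind(x, matrix(rnorm(n * n_feat), n) +
                   matrix(mu, n, n_feat, byrow = TRUE))
      y <- c(y, rep(classes[cl], n))
      sess <- c(sess, rep(s_id, n))
    }
  }
  feature_set(x, y, sess, kind = "toy")
}

test_that("feature sets have the documented dimensions", {
  recs <- tiny_dataset(n = 1, seed = 41, n_pulses = 4)
  act <- build_active_features(recs)
  # 4 channels x 500 samples of the 250 ms window at 2 kHz
  expect_equal(ncol(act$x), 4 * 500)
  expect_equal(nrow(act$x), 3 * 4)
  expect_equal(unname(table(act$y)), rep(4L, 3), ignore_attr = TRUE)
  pas <- build_passive_features(recs)
  expect_equal(ncol(pas$x), 4 * 4 + 1)
  sub <- build_passive_features(recs, signatures = "variance")
  expect_equal(ncol(sub$x), 4)
  cmb <- combine_features(act, pas)
  expect_equal(ncol(cmb$x), ncol(act$x) + ncol(pas$x))
  expect_error(feature_set(matrix(NA_real_, 2, 2), c("a", "b"), 1:2),
               "missing")
})

test_that("softmax probabilities are a proper distribution per trial", {
  fs <- toy_features(seed = 2)
  set.seed(9)
  idx <- sample(nrow(fs$x))
  tr <- idx[1:40]; te <- idx[41:60]
  fp <- epiprobe:::fit_predict_multinomial(fs$x[tr, ], fs$y[tr],
                                           fs$x[te, ], l2 = 1)
  expect_true(all(abs(rowSums(fp$prob) - 1) < 1e-9))
  expect_s3_class(fp$class, "factor")
})

test_that("cross-validated accuracy separates signal from noise", {
  fs <- toy_features(sep = 5, seed = 3)
  rep1 <- train_crossvalidated(fs, seed = 1)
  expect_equal(rep1$mean_accuracy, 1)
  # pooled confusion counts agree with the plain correct fraction
  conf <- rep1$confusion
  micro <- sum(conf$tp) / (sum(conf$tp) + sum(conf$fn))
  expect_equal(micro, rep1$mean_accuracy)
  # pure-noise features: accuracy in the chance band around 1/3
  accs <- vapply(1:5, function(i) {
    fs0 <- toy_features(sep = 0, n_per_class = 40, n_sessions = 5,
                        seed = 10 + i)
    train_crossvalidated(fs0, seed = i)$mean_accuracy
  }, 0)
  expect_true(all(accs >= 0.2 & accs <= 0.47))
  expect_gt(mean(accs), 0.2)
})

test_that("accuracy identity holds on hand confusion counts", {
  expect_equal(accuracy_from_counts(8, 16, 2, 2), 24 / 28)
  conf <- tibble::tibble(tp = c(3, 4), tn = c(7, 6), fp = c(1, 2),
                         fn = c(2, 1))
  expect_equal(accuracy_from_counts(sum(conf$tp), sum(conf$tn),
                                    sum(conf$fp), sum(conf$fn)),
               (3 + 4 + 7 + 6) / (3 + 4 + 7 + 6 + 1 + 2 + 2 + 1))
})

test_that("fold construction stratifies and respects session grouping", {
  fs <- toy_features(n_per_class = 20, n_sessions = 5, seed = 4)
  rep1 <- train_crossvalidated(fs, n_folds = 5, seed = 2)
  pred <- rep1$predictions
  for (f in 1:5) {
    sess_in_fold <- unique(pred$session[pred$fold == f])
    sess_elsewhere <- unique(pred$session[pred$fold != f])
    expect_length(intersect(sess_in_fold, sess_elsewhere), 0)
  }
  # a class missing from the training folds errors
  fs_bad <- toy_features(n_sessions = 1, seed = 5)
  expect_error(train_crossvalidated(fs_bad, n_folds = 2, seed = 1),
               "absent")
})

test_that("the permutation p-value follows its closed form", {
  fs <- toy_features(sep = 5, n_per_class = 10, n_sessions = 5, seed = 6)
  rep1 <- permutation_test(fs, n_perm = 10, seed = 3, n_folds = 5)
  perm <- rep1$permutation
  C <- sum(perm$null_scores >= perm$true_score)
  expect_equal(perm$p_value, (C + 1) / (length(perm$null_scores) + 1))
  expect_gt(perm$p_value, 0)
  expect_lte(perm$p_value, 1)
  # perfectly separable: no permutation matches the true score
  expect_equal(perm$p_value, 1 / 11)
  # trial-level permutation is supported
  rep2 <- permutation_test(fs, n_perm = 5, seed = 3, permute = "trial",
                           n_folds = 5)
  expect_lte(rep2$permutation$p_value, 1)
})

test_that("the permutation test keeps its size under the null", {
  pvals <- vapply(1:15, function(i) {
    fs0 <- toy_features(sep = 0, n_per_class = 8, n_sessions = 4,
                        n_feat = 4, seed = 100 + i)
    permutation_test(fs0, n_perm = 19, seed = i,
                     n_folds = 4)$permutation$p_value
  }, 0)
  # nominal 0.05 => at most C = 0 of 19; allow generous simulation error
  expect_lte(mean(pvals <= 0.05), 0.27)
  expect_gt(min(pvals), 0)
})

test_that("time-resolved decoding finds the evoked window, not the baseline", {
  recs <- tiny_dataset(n = 2, seed = 43, n_pulses = 5)
  recs <- lapply(recs, remove_stim_artifact, seed = 1)
  tr <- timepoint_decoding(recs, range_ms = c(-60, 80), step_ms = 20,
                           n_perm = 12, seed = 2, n_folds = 2)
  expect_s3_class(tr, "accuracy_trace")
  pre <- tr[tr$time_ms < 0, ]
  post <- tr[tr$time_ms >= 20 & tr$time_ms <= 80, ]
  # baseline accuracy sits at chance (inside the permutation band on
  # average), evoked timepoints rise above it
  expect_lte(mean(pre$accuracy), max(pre$chance_hi))
  expect_true(any(post$accuracy > post$chance_hi))
})

test_that("single-channel recordings still decode per timepoint", {
  recs <- tiny_dataset(n = 2, seed = 44, n_pulses = 4)
  recs <- lapply(recs, function(r) {
    r$signal <- r$signal[1, , drop = FALSE]
    r$channel_labels <- r$channel_labels[1]
    r
  })
  tr <- timepoint_decoding(recs, range_ms = c(10, 30), step_ms = 20,
                           n_perm = 0, seed = 1, n_folds = 2)
  expect_equal(nrow(tr), 2)
  expect_true(all(tr$accuracy >= 0 & tr$accuracy <= 1))
})

test_that("active probing dominates passive signatures when only the gain differs", {
  # Epileptor-backend-style contrast: evoked gain differs by condition,
  # background identical across conditions
  mk <- function(cond, gain, seed) {
    cfg <- tiny_config(seed = seed, condition = cond, evoked_gain = gain,
                       ar_coefficient = 0.92)
    generate_session(cfg, n_stimulations = 6, intensities = c(0.8, 1))
  }
  recs <- list()
  i <- 0
  for (s in 1:3) {
    recs[[i <- i + 1]] <- mk("low", 0.4, 50 + i)
    recs[[i <- i + 1]] <- mk("normal", 1, 50 + i)
    recs[[i <- i + 1]] <- mk("high", 2.2, 50 + i)
  }
  recs <- purrr::imap(recs, function(r, j) {
    r$meta$session <- j
    remove_stim_artifact(r, seed = j)
  })
  act <- train_crossvalidated(build_active_features(recs), n_folds = 3,
                              seed = 1)
  pas <- train_crossvalidated(build_passive_features(recs), n_folds = 3,
                              seed = 1)
  expect_gte(act$mean_accuracy, pas$mean_accuracy)
  expect_gt(act$mean_accuracy, 1 / 3)
})

test_that("classifier reports tidy into confusion and summary tables", {
  fs <- toy_features(seed = 8)
  rep1 <- train_crossvalidated(fs, seed = 1)
  expect_named(tidy(rep1), c("class", "tp", "tn", "fp", "fn"))
  g <- glance(rep1)
  expect_true(is.na(g$p_value))
  expect_equal(g$mean_accuracy, rep1$mean_accuracy)
})
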