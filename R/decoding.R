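#' Feature sets for excitability decoding
#'
#' Containers pairing a trials x features matrix with condition labels and
#' session identifiers. The active set is the raw multi-channel voltage of
#' the 250 ms post-pulse window (no feature extraction); the passive set is
#' the per-channel critical-slowing signatures of 4 s inter-pulse epochs
#' plus the epoch's mean spatial correlation; the combined set concatenates
#' both.
#'
#' @param x trials x features matrix.
#' @param y condition label per trial.
#' @param session session identifier per trial.
#' @param kind `"active"`, `"passive"` or `"combined"`.
#' @param feature_names optional column names.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(x, y, session, kind = "custom",
                        feature_names = colnames(x)) {
  x <- as.matrix(x)
  y <- factor(y)
  stopifnot(nrow(x) == length(y), length(session) == length(y))
  if (anyNA(x)) stop("feature matrix contains missing values")
  structure(list(x = x, y = y, session = session, kind = kind,
                 feature_names = feature_names),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set:", x$kind, "> ", nrow(x$x), "trials x", ncol(x$x),
      "features;", nlevels(x$y), "classes (",
      paste(table(x$y), collapse = "/"), ")\n")
  invisible(x)
}

#' @rdname feature_set
#' @param recordings list of [ieeg_recording()] objects with equal channel
#'   counts and stimulation events.
#' @param window_ms post-stimulus window for the active features.
#' @return `build_active_features()`: a `feature_set` whose trials are
#'   single-pulse events and whose features are the concatenated raw
#'   voltage samples of all channels over the window.
#' @export
build_active_features <- function(recordings, window_ms = c(0, 250)) {
  if (inherits(recordings, "ieeg_recording")) recordings <- list(recordings)
  nch <- vapply(recordings, function(r) nrow(r$signal), 0L)
  if (length(unique(nch)) != 1)
    stop("recordings have unequal channel counts")
  rows <- list(); y <- character(0); sess <- integer(0)
  for (s in seq_along(recordings)) {
    rec <- recordings[[s]]
    fs <- rec$fs
    i0 <- round(window_ms[1] / 1000 * fs)
    i1 <- round(window_ms[2] / 1000 * fs) - 1
    for (e in seq_len(nrow(rec$events))) {
      idx <- rec$events$onset_sample[e] + i0:i1
      if (max(idx) > ncol(rec$signal) || min(idx) < 1) next
      rows[[length(rows) + 1]] <- as.vector(t(rec$signal[, idx]))
      y <- c(y, rec$condition)
      sess <- c(sess, rec$meta$session %||% s)
    }
  }
  feature_set(do.call(rbind, rows), y, sess, kind = "active")
}

#' @rdname feature_set
#' @param signatures `"all"`, or a subset of `c("line_length", "variance",
#'   "skewness", "autocorr_halfwidth", "spatial_correlation")` for
#'   single-signature classifiers.
#' @param epoch_s passive epoch length.
#' @return `build_passive_features()`: a `feature_set` whose trials are
#'   stimulation-free epochs.
#' @export
build_passive_features <- function(recordings, signatures = "all",
                                   epoch_s = 4) {
  if (inherits(recordings, "ieeg_recording")) recordings <- list(recordings)
  univ <- c("line_length", "variance", "skewness", "autocorr_halfwidth")
  if (identical(signatures, "all")) signatures <- c(univ, "spatial_correlation")
  rows <- list(); y <- character(0); sess <- integer(0)
  for (s in seq_along(recordings)) {
    rec <- recordings[[s]]
    tab <- passive_signatures(rec, epoch_s = epoch_s)
    for (ep in unique(tab$epoch)) {
      sub <- tab[tab$epoch == ep, ]
      feats <- c()
      for (sg in intersect(signatures, univ)) {
        v <- sub$value[sub$signature == sg]
        names(v) <- paste0(sg, ".", sub$channel[sub$signature == sg])
        feats <- c(feats, v)
      }
      if ("spatial_correlation" %in% signatures)
        feats <- c(feats,
                   spatial_correlation =
                     sub$value[sub$signature == "spatial_correlation"])
      if (anyNA(feats)) { message("epoch dropped (signature failure)"); next }
      rows[[length(rows) + 1]] <- feats
      y <- c(y, rec$condition)
      sess <- c(sess, rec$meta$session %||% s)
    }
  }
  fx <- do.call(rbind, rows)
  feature_set(fx, y, sess, kind = "passive", feature_names = colnames(fx))
}

#' @rdname feature_set
#' @param active,passive feature sets built from the same recordings.
#' @return `combine_features()`: the combined `feature_set` (trials matched
#'   per session up to the smaller trial count).
#' @export
combine_features <- function(active, passive) {
  rows_a <- list(); rows_p <- list(); y <- character(0); sess <- integer(0)
  for (s in unique(active$session)) {
    ia <- which(active$session == s)
    ip <- which(passive$session == s)
    n <- min(length(ia), length(ip))
    if (n == 0) next
    rows_a[[length(rows_a) + 1]] <- active$x[ia[seq_len(n)], , drop = FALSE]
    rows_p[[length(rows_p) + 1]] <- passive$x[ip[seq_len(n)], , drop = FALSE]
    y <- c(y, as.character(active$y[ia[seq_len(n)]]))
    sess <- c(sess, rep(s, n))
  }
  feature_set(cbind(do.call(rbind, rows_a), do.call(rbind, rows_p)),
              y, sess, kind = "combined")
}

# stratified fold assignment; grouped = sessions never straddle folds
make_folds <- function(y, session, n_folds, group_by_session, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  if (group_by_session) {
    st <- unique(tibble::tibble(session = session, y = y))
    for (cl in unique(st$y)) {
      ses <- sample(st$session[st$y == cl])
      f <- rep(seq_len(n_folds), length.out = length(ses))
      for (i in seq_along(ses)) fold[session == ses[i]] <- f[i]
    }
  } else {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
    }
  }
  fold
}

# multinomial L2 logistic regression: fit on standardized training data,
# return class predictions and softmax probabilities for the test split
fit_predict_multinomial <- function(x_train, y_train, x_test, l2) {
  if (nlevels(droplevels(y_train)) < nlevels(y_train))
    stop("a class is absent from a training fold")
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- scale(x_train, mu, sdv)
  xt <- scale(x_test, mu, sdv)
  if (ncol(xs) == 1) {            # glmnet needs >= 2 columns
    xs <- cbind(xs, 0)
    xt <- cbind(xt, 0)
  }
  lambda <- 1 / (nrow(x_train) * l2)
  # suppress glmnet's small-sample advisory; fold sizes are validated above
  fit <- suppressWarnings(
    glmnet::glmnet(xs, y_train, family = "multinomial", alpha = 0,
                   lambda = lambda, standardize = FALSE))
  prob <- drop(stats::predict(fit, xt, type = "response"))
  if (is.null(dim(prob))) prob <- matrix(prob, nrow = 1,
                                         dimnames = list(NULL, levels(y_train)))
  cls <- colnames(prob)[max.col(prob)]
  list(class = factor(cls, levels = levels(y_train)), prob = prob)
}

#' Cross-validated excitability classifier
#'
#' Multinomial logistic regression with L2 regularisation (softmax link),
#' trained and evaluated with stratified k-fold cross-validation. By
#' default folds are additionally grouped by session, so trials of the
#' same session never straddle the train/test split. Features are z-scored
#' with means and SDs fitted on the training folds only. Accuracy is the
#' fraction of correctly labelled held-out trials, equivalently the
#' micro-averaged `(TP + TN) / (TP + TN + FP + FN)` over one-vs-rest
#' confusion counts.
#'
#' @param features a [feature_set()].
#' @param n_folds folds (5 by default).
#' @param l2 inverse regularisation strength (the penalty weight is
#'   `1 / (n * l2)` in the glmnet objective; larger `l2` = weaker penalty).
#' @param seed RNG seed for fold assignment.
#' @param group_by_session group folds by session?
#' @return Object of class `classifier_report`: `fold_accuracy`,
#'   `mean_accuracy`, `confusion` (per-class one-vs-rest counts),
#'   `predictions` tibble, plus the settings.
#' @export
train_crossvalidated <- function(features, n_folds = 5, l2 = 1, seed = 1,
                                 group_by_session = TRUE) {
  y <- features$y
  if (min(table(y)) < n_folds && !group_by_session)
    stop("need at least n_folds trials per class")
  fold <- make_folds(y, features$session, n_folds, group_by_session, seed)
  preds <- factor(rep(NA, length(y)), levels = levels(y))
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    fp <- fit_predict_multinomial(features$x[tr, , drop = FALSE], y[tr],
                                  features$x[te, , drop = FALSE],
                                  l2)
    preds[te] <- fp$class
  }
  fold_acc <- vapply(seq_len(n_folds), function(f) {
    te <- fold == f
    if (!any(te)) NA_real_ else mean(preds[te] == y[te])
  }, 0)
  confusion <- purrr::map_dfr(levels(y), function(cl) {
    tibble::tibble(class = cl,
                   tp = sum(preds == cl & y == cl, na.rm = TRUE),
                   tn = sum(preds != cl & y != cl, na.rm = TRUE),
                   fp = sum(preds == cl & y != cl, na.rm = TRUE),
                   fn = sum(preds != cl & y == cl, na.rm = TRUE))
  })
  structure(list(fold_accuracy = fold_acc,
                 mean_accuracy = mean(preds == y, na.rm = TRUE),
                 confusion = confusion,
                 predictions = tibble::tibble(truth = y, predicted = preds,
                                              fold = fold,
                                              session = features$session),
                 n_folds = n_folds, l2 = l2, seed = seed,
                 group_by_session = group_by_session, kind = features$kind,
                 permutation = NULL),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report:", x$kind, "> accuracy",
      round(x$mean_accuracy, 3), "(folds:",
      paste(round(x$fold_accuracy, 2), collapse = ", "), ")\n")
  if (!is.null(x$permutation))
    cat("  permutation test: p =", signif(x$permutation$p_value, 3),
        "over", length(x$permutation$null_scores), "permutations\n")
  invisible(x)
}

#' @export
tidy.classifier_report <- function(x, ...) x$confusion

#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(kind = x$kind, mean_accuracy = x$mean_accuracy,
                 n_folds = x$n_folds, l2 = x$l2,
                 p_value = x$permutation$p_value %||% NA_real_)
}

#' Classification accuracy from confusion counts
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return Accuracy in `[0, 1]`.
#' @examples
#' accuracy_from_counts(8, 16, 2, 2)
#' @export
accuracy_from_counts <- function(tp, tn, fp, fn) {
  (tp + tn) / (tp + tn + fp + fn)
}

#' Label-permutation test of a classifier
#'
#' Repeats the full cross-validation on `n_perm` label permutations and
#' compares the true accuracy against the null scores:
#' `p = (C + 1) / (n_perm + 1)` with `C` the number of permutations whose
#' score is at least the true score. Labels are permuted at the session
#' level by default (all trials of a session keep a common, shuffled
#' label), respecting the grouped fold structure; trial-level permutation
#' is available via `permute`.
#'
#' @param features a [feature_set()].
#' @param n_perm number of permutations (100 by default).
#' @param seed RNG seed.
#' @param permute `"session"` or `"trial"`.
#' @param report optional precomputed [train_crossvalidated()] report for
#'   the true labels.
#' @param ... passed to [train_crossvalidated()].
#' @return The `classifier_report` with a `permutation` element
#'   (`p_value`, `null_scores`, `true_score`).
#' @export
permutation_test <- function(features, n_perm = 100, seed = 1,
                             permute = c("session", "trial"),
                             report = NULL, ...) {
  permute <- match.arg(permute)
  if (is.null(report)) report <- train_crossvalidated(features, seed = seed,
                                                      ...)
  true_score <- report$mean_accuracy
  null_scores <- vapply(seq_len(n_perm), function(i) {
    set.seed(derive_seed(seed, 5000 + i))
    fp <- features
    if (permute == "session") {
      st <- unique(tibble::tibble(session = features$session,
                                  y = as.character(features$y)))
      st$y_perm <- sample(st$y)
      fp$y <- factor(st$y_perm[match(features$session, st$session)],
                     levels = levels(features$y))
    } else {
      fp$y <- sample(features$y)
    }
    tryCatch(train_crossvalidated(fp, seed = seed, ...)$mean_accuracy,
             error = function(e) NA_real_)
  }, 0)
  null_scores <- null_scores[!is.na(null_scores)]
  C <- sum(null_scores >= true_score)
  report$permutation <- list(p_value = (C + 1) / (length(null_scores) + 1),
                             null_scores = null_scores,
                             true_score = true_score)
  report
}

#' Time-resolved decoding
#'
#' Trains one classifier per peri-stimulus timepoint (features are the
#' voltage of all channels at that sample) and returns the accuracy trace
#' with a permutation chance band per timepoint.
#'
#' @param recordings list of [ieeg_recording()] objects.
#' @param range_ms peri-stimulus range.
#' @param step_ms spacing of decoded timepoints.
#' @param n_perm permutations per timepoint for the chance band (0 = none).
#' @param band_quantiles chance-band quantiles of the null scores.
#' @param seed RNG seed.
#' @param ... passed to [train_crossvalidated()].
#' @return Tibble with `time_ms`, `accuracy`, `chance_lo`, `chance_hi`,
#'   `p_value`, of class `accuracy_trace`.
#' @export
timepoint_decoding <- function(recordings, range_ms = c(-100, 250),
                               step_ms = 10, n_perm = 20,
                               band_quantiles = c(0.025, 0.975), seed = 1,
                               ...) {
  if (inherits(recordings, "ieeg_recording")) recordings <- list(recordings)
  fs <- recordings[[1]]$fs
  times <- seq(range_ms[1], range_ms[2], by = step_ms)
  out <- purrr::map_dfr(times, function(tm) {
    rows <- list(); y <- character(0); sess <- integer(0)
    off <- round(tm / 1000 * fs)
    for (s in seq_along(recordings)) {
      rec <- recordings[[s]]
      for (e in seq_len(nrow(rec$events))) {
        idx <- rec$events$onset_sample[e] + off
        if (idx < 1 || idx > ncol(rec$signal)) next
        rows[[length(rows) + 1]] <- rec$signal[, idx]
        y <- c(y, rec$condition)
        sess <- c(sess, rec$meta$session %||% s)
      }
    }
    fsx <- feature_set(do.call(rbind, rows), y, sess, kind = "timepoint")
    rep <- train_crossvalidated(fsx, seed = seed, ...)
    if (n_perm > 0) {
      rep <- permutation_test(fsx, n_perm = n_perm, seed = seed,
                              report = rep, ...)
      band <- stats::quantile(rep$permutation$null_scores, band_quantiles)
      tibble::tibble(time_ms = tm, accuracy = rep$mean_accuracy,
                     chance_lo = band[1], chance_hi = band[2],
                     p_value = rep$permutation$p_value)
    } else {
      tibble::tibble(time_ms = tm, accuracy = rep$mean_accuracy,
                     chance_lo = NA_real_, chance_hi = NA_real_,
                     p_value = NA_real_)
    }
  })
  class(out) <- c("accuracy_trace", class(out))
  out
}
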