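#' Stack evoked responses into a channels x stimulations matrix
#'
#' Line-length responses of every channel to every single-pulse
#' stimulation, across one or several recordings, stacked into the
#' non-negative input matrix `V` (channels x stimulations) with per-column
#' metadata. Trials failing the automated artifact screen are excluded.
#'
#' @param recordings an [ieeg_recording()] or list of them (equal channel
#'   sets).
#' @param window_ms response window.
#' @param screen apply [screen_trials()]?
#' @param screen_k MAD multiplier for the screen.
#' @return List of class `response_matrix`: `V` (matrix), `meta` (tibble
#'   with `stimulation`, `session`, `condition`, `intensity`), `channels`.
#' @export
build_response_matrix <- function(recordings, window_ms = c(0, 250),
                                  screen = TRUE, screen_k = 5) {
  if (inherits(recordings, "ieeg_recording")) recordings <- list(recordings)
  if (!length(recordings)) stop("no recordings")
  channels <- recordings[[1]]$channel_labels
  cols <- list(); meta <- list()
  for (s in seq_along(recordings)) {
    rec <- recordings[[s]]
    if (!identical(rec$channel_labels, channels))
      stop("recordings have different channel sets")
    if (!nrow(rec$events)) stop("recording ", s, " has no stimulation events")
    resp <- evoked_response(rec, window_ms)
    wide <- resp |>
      tidyr::pivot_wider(names_from = "channel", values_from = "ll") |>
      dplyr::arrange(.data$event_id)
    if (screen) {
      trial_ll <- rowMeans(wide[, channels])
      keep <- screen_trials(tibble::tibble(intensity = wide$intensity,
                                           ll = trial_ll), k = screen_k)
      wide <- wide[keep, , drop = FALSE]
    }
    cols[[s]] <- t(as.matrix(wide[, channels]))
    meta[[s]] <- tibble::tibble(session = s, condition = rec$condition,
                                intensity = wide$intensity)
  }
  V <- do.call(cbind, cols)
  rownames(V) <- channels
  meta <- dplyr::bind_rows(meta)
  meta$stimulation <- seq_len(nrow(meta))
  structure(list(V = V, meta = meta, channels = channels),
            class = "response_matrix")
}

# one multiplicative-update NMF run (Frobenius objective)
nmf_run <- function(V, rank, max_iter, tol) {
  n <- nrow(V); m <- ncol(V)
  eps <- .Machine$double.eps
  W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank)
  H <- matrix(stats::runif(rank * m, 0.1, 1), rank, m)
  err <- norm(V - W %*% H, "F")
  errs <- err
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    new_err <- norm(V - W %*% H, "F")
    errs <- c(errs, new_err)
    if (abs(err - new_err) <= tol * max(err, eps)) { err <- new_err; break }
    err <- new_err
  }
  list(W = W, H = H, error = err, trace = errs)
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorises the non-negative response matrix `V` (channels x
#' stimulations) as `V ~ W %*% H` with `W >= 0` (channels x rank: the
#' sub-network weights) and `H >= 0` (rank x stimulations: activation
#' coefficients), minimising the Frobenius reconstruction error with the
#' Lee--Seung multiplicative updates. The best of `n_restarts` seeded
#' random initialisations is returned. `W` columns are normalised to unit
#' sum (the compensating scale moved into `H`), so `H` carries amplitude.
#'
#' @param V non-negative matrix, or a `response_matrix`.
#' @param rank number of sub-networks (<= min(dim(V))).
#' @param n_restarts random restarts.
#' @param max_iter,tol update iterations and relative-error tolerance.
#' @param seed RNG seed.
#' @return Object of class `nmf_decomposition`: `W`, `H`, `rank`,
#'   `reconstruction_error`, `error_trace` (per-iteration error of the best
#'   run), `n_restarts`, `seed`, and `meta` if `V` was a `response_matrix`.
#' @export
nmf_decompose <- function(V, rank, n_restarts = 20, max_iter = 1000,
                          tol = 1e-6, seed = 1) {
  meta <- NULL
  if (inherits(V, "response_matrix")) { meta <- V$meta; V <- V$V }
  if (any(V < 0)) stop("V must be non-negative")
  if (rank > min(dim(V))) stop("rank exceeds matrix dimensions")
  # drop dead channels, reinstate as zero weights afterwards
  alive <- rowSums(V) > 0
  Vf <- V[alive, , drop = FALSE]
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, r))
    run <- nmf_run(Vf, rank, max_iter, tol)
    if (is.null(best) || run$error < best$error) best <- run
  }
  W <- matrix(0, nrow(V), rank, dimnames = list(rownames(V), NULL))
  W[alive, ] <- best$W
  H <- best$H
  scl <- colSums(W)
  scl[scl == 0] <- 1
  W <- sweep(W, 2, scl, "/")
  H <- sweep(H, 1, scl, "*")
  structure(list(W = W, H = H, rank = rank,
                 reconstruction_error = best$error,
                 error_trace = best$trace, n_restarts = n_restarts,
                 seed = seed, meta = meta),
            class = "nmf_decomposition")
}

#' @export
print.nmf_decomposition <- function(x, ...) {
  cat("<nmf_decomposition> rank", x$rank, "|", nrow(x$W), "channels x",
      ncol(x$H), "stimulations | Frobenius error",
      signif(x$reconstruction_error, 4), "\n")
  invisible(x)
}

#' @export
tidy.nmf_decomposition <- function(x, ...) {
  W <- x$W
  tibble::tibble(channel = rep(rownames(W) %||% seq_len(nrow(W)), ncol(W)),
                 component = rep(seq_len(ncol(W)), each = nrow(W)),
                 weight = as.vector(W))
}

#' @export
glance.nmf_decomposition <- function(x, ...) {
  tibble::tibble(rank = x$rank, reconstruction_error = x$reconstruction_error,
                 n_iter = length(x$error_trace) - 1, n_restarts = x$n_restarts)
}

# optimal greedy pairing of W columns by cosine similarity
match_components <- function(A, B) {
  cs <- function(u, v) sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)) +
                                       .Machine$double.eps)
  k <- ncol(A)
  simmat <- outer(seq_len(k), seq_len(k),
                  Vectorize(function(i, j) cs(A[, i], B[, j])))
  sims <- numeric(k)
  for (s in seq_len(k)) {
    best <- which(simmat == max(simmat), arr.ind = TRUE)[1, ]
    sims[s] <- simmat[best[1], best[2]]
    simmat[best[1], ] <- -Inf
    simmat[, best[2]] <- -Inf
  }
  mean(sims)
}

#' Rank selection by restart stability
#'
#' For each candidate rank, factorises `V` from several random restarts and
#' scores how reproducible the `W` columns are across restarts (mean
#' best-match cosine similarity after greedy pairing against the
#' lowest-error run). Returns the largest rank whose stability exceeds the
#' threshold; if none passes, rank 1 with a warning.
#'
#' @param V non-negative matrix or `response_matrix`.
#' @param ranks candidate ranks (2..8 by default).
#' @param n_restarts restarts per rank.
#' @param threshold stability threshold (0.95): high enough that
#'   overfit ranks, whose restart-to-restart weight patterns begin to
#'   diverge, are rejected.
#' @param seed RNG seed.
#' @return Selected rank, with attribute `stability` (tibble rank/score).
#' @export
select_rank_stability <- function(V, ranks = 2:8, n_restarts = 20,
                                  threshold = 0.95, seed = 1) {
  if (inherits(V, "response_matrix")) V <- V$V
  ranks <- ranks[ranks <= min(dim(V))]
  scores <- vapply(ranks, function(k) {
    runs <- lapply(seq_len(n_restarts), function(r) {
      set.seed(derive_seed(seed, k * 1000 + r))
      nmf_run(V, k, max_iter = 500, tol = 1e-6)
    })
    ref <- runs[[which.min(vapply(runs, `[[`, 0, "error"))]]
    mean(vapply(runs, function(r) match_components(ref$W, r$W), 0))
  }, 0)
  tab <- tibble::tibble(rank = ranks, stability = scores)
  pass <- ranks[scores >= threshold]
  out <- if (length(pass)) max(pass) else {
    warning("no rank reaches stability ", threshold, "; returning 1")
    1L
  }
  attr(out, "stability") <- tab
  out
}

#' Select responsive sub-networks
#'
#' Keeps the components whose mean activation per intensity increases with
#' stimulation intensity: positive Spearman rank correlation between
#' intensity level and mean `H`, one-sided test at level `alpha`.
#'
#' @param decomp an `nmf_decomposition` with intensity metadata (or supply
#'   `intensities`).
#' @param intensities per-stimulation intensities (defaults to
#'   `decomp$meta$intensity`).
#' @param alpha one-sided significance level.
#' @return Integer vector of responsive component indices, with attribute
#'   `stats` (tibble of correlations and p-values).
#' @export
select_responsive_subnetworks <- function(decomp, intensities = NULL,
                                          alpha = 0.05) {
  if (is.null(intensities)) intensities <- decomp$meta$intensity
  stopifnot(length(intensities) == ncol(decomp$H))
  stats_tab <- purrr::map_dfr(seq_len(decomp$rank), function(k) {
    means <- tapply(decomp$H[k, ], intensities, mean)
    lv <- as.numeric(names(means))
    ct <- suppressWarnings(stats::cor.test(lv, as.numeric(means),
                                           method = "spearman",
                                           alternative = "greater",
                                           exact = FALSE))
    tibble::tibble(component = k, rho = unname(ct$estimate),
                   p_value = ct$p.value)
  })
  keep <- stats_tab$component[stats_tab$p_value < alpha]
  attr(keep, "stats") <- stats_tab
  keep
}

#' Network-level input-output curve
#'
#' Mean activation coefficient of one sub-network per stimulation
#' intensity (optionally within one condition), turned into an
#' [input_output_curve()].
#'
#' @param decomp an `nmf_decomposition` with metadata.
#' @param component component index.
#' @param condition optional condition filter.
#' @param ... passed to [input_output_curve()].
#' @return An `ioc` object.
#' @export
network_ioc <- function(decomp, component = 1, condition = NULL, ...) {
  meta <- decomp$meta
  if (is.null(meta)) stop("decomposition carries no stimulation metadata")
  h <- decomp$H[component, ]
  keep <- rep(TRUE, length(h))
  if (!is.null(condition)) keep <- meta$condition == condition
  counts <- table(meta$intensity[keep])
  if (any(counts == 0)) message("intensity level(s) without trials dropped")
  input_output_curve(tibble::tibble(intensity = meta$intensity[keep],
                                    ll = h[keep]), ...)
}

#' Export an NMF decomposition
#'
#' Writes `W` and `H` as CSV files (`<base>_W.csv`, `<base>_H.csv`) with
#' channel/stimulation identifiers and a JSON component report.
#'
#' @param decomp an `nmf_decomposition`.
#' @param base base path (no extension).
#' @return `base`, invisibly.
#' @export
write_nmf <- function(decomp, base) {
  utils::write.csv(data.frame(channel = rownames(decomp$W) %||%
                                seq_len(nrow(decomp$W)), decomp$W),
                   paste0(base, "_W.csv"), row.names = FALSE)
  H <- data.frame(t(decomp$H))
  names(H) <- paste0("component_", seq_len(decomp$rank))
  if (!is.null(decomp$meta)) H <- cbind(decomp$meta, H)
  utils::write.csv(H, paste0(base, "_H.csv"), row.names = FALSE)
  jsonlite::write_json(list(rank = decomp$rank,
                            reconstruction_error = decomp$reconstruction_error,
                            n_restarts = decomp$n_restarts,
                            seed = decomp$seed),
                       paste0(base, "_report.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}
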