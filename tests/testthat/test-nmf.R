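# well-separated sub-networks: disjoint channel blocks, each stimulation
# driving predominantly one sub-network (as a stimulation site would)
planted_V <- function(n_ch = 12, n_stim = 60, rank = 3, noise = 0.05,
                      seed = 1) {
  set.seed(seed)
  W <- matrix(0, n_ch, rank)
  blocks <- split(seq_len(n_ch), rep(seq_len(rank), length.out = n_ch))
  for (k in seq_len(rank)) W[blocks[[k]], k] <- runif(length(blocks[[k]]),
                                                      0.8, 1.2)
  dom <- rep(seq_len(rank), length.out = n_stim)
  H <- matrix(runif(rank * n_stim, 0, 0.15), rank, n_stim)
  H[cbind(dom, seq_len(n_stim))] <- runif(n_stim, 1, 2)
  V <- W %*% H + noise * matrix(abs(rnorm(n_ch * n_stim)), n_ch)
  list(V = V, W = W, H = H)
}

test_that("response matrices stack channels by stimulations", {
  rec <- cached_clean
  rm_ <- build_response_matrix(rec, screen = FALSE)
  expect_equal(dim(rm_$V), c(4, 8))
  expect_equal(rownames(rm_$V), rec$channel_labels)
  expect_true(all(rm_$V >= 0))
  expect_equal(nrow(rm_$meta), 8)
  # Epileptor-backend responses grow with intensity on average
  cfg <- synthetic_config(n_channels = 2, seed = 8,
                          propagation_delays_ms = c(0, 0),
                          channel_weights = c(1, 1), isi_range_s = c(5, 7))
  reb <- generate_epileptor_backend_session(
    cfg, epileptor_params(x0 = -2.20), n_stimulations = 12,
    intensities = c(0.25, 1), noise_sd_uv = 0.2)
  rb <- build_response_matrix(reb, screen = FALSE)
  m <- tapply(colMeans(rb$V), rb$meta$intensity, mean)
  expect_gt(m["1"], m["0.25"])
})

test_that("multiplicative updates recover an exact rank-1 factorisation", {
  set.seed(2)
  w <- runif(6, 0.5, 2); h <- runif(20, 0.5, 2)
  V <- outer(w, h)
  d <- nmf_decompose(V, 1, n_restarts = 5, seed = 3)
  expect_lt(d$reconstruction_error / norm(V, "F"), 1e-6)
  # capacity nesting on a generic matrix, and reproducibility
  set.seed(5)
  Vr <- matrix(abs(rnorm(6 * 20)), 6)
  e1 <- nmf_decompose(Vr, 1, n_restarts = 3, seed = 3)$reconstruction_error
  ef <- nmf_decompose(Vr, 6, n_restarts = 3, seed = 3)$reconstruction_error
  expect_lte(ef, e1)
  d2 <- nmf_decompose(V, 1, n_restarts = 5, seed = 3)
  expect_identical(d$W, d2$W)
  expect_identical(d$H, d2$H)
  expect_error(nmf_decompose(-V, 1), "non-negative")
  expect_error(nmf_decompose(V, 10), "rank exceeds")
})

test_that("updates keep factors non-negative and never increase the objective", {
  set.seed(4)
  for (i in 1:5) {
    V <- matrix(abs(rnorm(8 * 15)), 8)
    d <- nmf_decompose(V, 3, n_restarts = 1, seed = i)
    expect_true(all(d$W >= 0))
    expect_true(all(d$H >= 0))
    expect_true(all(diff(d$error_trace) <= 1e-10))
  }
})

test_that("W columns are sum-normalised with amplitude carried by H", {
  pv <- planted_V()
  d <- nmf_decompose(pv$V, 3, n_restarts = 5, seed = 5)
  expect_equal(unname(colSums(d$W)), rep(1, 3))
  expect_lt(norm(pv$V - d$W %*% d$H, "F") / norm(pv$V, "F"), 0.05)
})

test_that("dead channels are reinstated as zero weights", {
  pv <- planted_V(n_ch = 6, rank = 2)
  V <- pv$V
  V[3, ] <- 0
  d <- nmf_decompose(V, 2, n_restarts = 3, seed = 6)
  expect_true(all(d$W[3, ] == 0))
})

test_that("planted sub-networks are recovered with high cosine similarity", {
  pv <- planted_V(noise = 0.02, seed = 7)
  d <- nmf_decompose(pv$V, 3, n_restarts = 10, seed = 8)
  sim <- epiprobe:::match_components(pv$W, d$W)
  expect_gt(sim, 0.95)
})

test_that("stability analysis selects the planted rank", {
  pv <- planted_V(noise = 0.02, seed = 9)
  r <- select_rank_stability(pv$V, ranks = 2:5, n_restarts = 8, seed = 10)
  expect_equal(as.integer(r), 3L)
  # rank-1 structure: stability near 1 at rank 1 is trivial; additional
  # ranks fit noise and destabilise
  v1 <- planted_V(rank = 1, noise = 0.05, seed = 11)
  expect_warning(
    r1 <- select_rank_stability(v1$V, ranks = 2:4, n_restarts = 8,
                                seed = 12, threshold = 0.9999),
    "returning 1")
  expect_equal(as.integer(r1), 1L)
})

test_that("responsive sub-networks are the intensity-coupled ones", {
  set.seed(13)
  n_stim <- 60
  intens <- rep(seq(0.1, 1, length.out = 6), each = 10)
  H <- rbind(2 * intens + 0.2 + abs(rnorm(n_stim, 0, 0.1)),
             abs(rnorm(n_stim, 1, 0.3)))
  W <- matrix(runif(12 * 2, 0.5, 1), 12)
  d <- structure(list(W = W, H = H, rank = 2,
                      meta = tibble::tibble(intensity = intens)),
                 class = "nmf_decomposition")
  keep <- select_responsive_subnetworks(d)
  expect_equal(as.integer(keep), 1L)
  # all-noise activations rarely pass the one-sided screen
  fp <- vapply(1:50, function(i) {
    set.seed(100 + i)
    dn <- d; dn$H <- rbind(abs(rnorm(n_stim)), abs(rnorm(n_stim)))
    length(select_responsive_subnetworks(dn))
  }, 0)
  expect_lte(mean(fp) / 2, 0.12)   # per-component false-positive rate
})

test_that("the network IOC agrees with the channel-mean IOC at rank 1", {
  set.seed(14)
  intens <- rep(seq(0.2, 1, length.out = 5), each = 8)
  resp <- 3 * intensity_saturation(intens) + 0.2
  w <- runif(6, 0.5, 1.5)
  V <- outer(w, resp) * matrix(runif(6 * 40, 0.97, 1.03), 6)
  meta <- tibble::tibble(session = 1, condition = "normal",
                         intensity = intens,
                         stimulation = seq_along(intens))
  rm_ <- structure(list(V = V, meta = meta, channels = as.character(1:6)),
                   class = "response_matrix")
  d <- nmf_decompose(rm_, 1, n_restarts = 5, seed = 15)
  net <- network_ioc(d, 1)
  chan <- input_output_curve(tibble::tibble(intensity = intens,
                                            ll = colMeans(V)))
  expect_equal(attr(net, "ioc"), attr(chan, "ioc"), tolerance = 0.05)
  # zero activations give a zero IOC
  dz <- d; dz$H[] <- 0
  expect_equal(attr(network_ioc(dz, 1), "ioc"), 0)
})

test_that("backend sessions at raised excitability yield a larger network IOC", {
  mk <- function(x0) {
    cfg <- synthetic_config(n_channels = 2, seed = 16,
                            propagation_delays_ms = c(0, 0),
                            channel_weights = c(1, 1),
                            isi_range_s = c(5, 7))
    rec <- generate_epileptor_backend_session(
      cfg, epileptor_params(x0 = x0), n_stimulations = 12,
      intensities = seq(0.2, 1, length.out = 4), noise_sd_uv = 0.2)
    d <- nmf_decompose(build_response_matrix(rec, screen = FALSE), 1,
                       n_restarts = 5, seed = 17)
    # shared normalisation so amplitudes are comparable across conditions
    attr(network_ioc(d, 1, normalization = "reference", reference = 1,
                     baseline = 0), "ioc")
  }
  expect_gt(mk(-2.20), mk(-2.30))
})

test_that("NMF exports write factor tables and a report", {
  pv <- planted_V(n_ch = 4, n_stim = 10, rank = 2)
  d <- nmf_decompose(pv$V, 2, n_restarts = 2, seed = 18)
  base <- file.path(tempdir(), "nmf")
  write_nmf(d, base)
  W <- utils::read.csv(paste0(base, "_W.csv"))
  expect_equal(nrow(W), 4)
  rep <- jsonlite::read_json(paste0(base, "_report.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$rank, 2)
})
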