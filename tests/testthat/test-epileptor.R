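test_that("the piecewise nonlinearities evaluate as printed", {
  p <- epileptor_params(x0 = -2.25)
  # x1 < 0 branch: f1(-1, .) = (-1)^3 - 3(-1)^2 = -4, entering dx1 as -f1
  st <- c(x1 = -1, y1 = 0, z = 3, x2 = 0, y2 = 0, g = 0)
  d <- epileptor_derivative(st, p)
  expect_equal(unname(d["x1"]), 0 - (-4) - 3 + 3.1)
  # f2 branches via dy2 = (-y2 + f2) / tau2
  st2 <- st; st2["x2"] <- -0.5
  expect_equal(unname(epileptor_derivative(st2, p)["y2"]), 0)
  st3 <- st; st3["x2"] <- 0
  expect_equal(unname(epileptor_derivative(st3, p)["y2"]), 6 * 0.25 / 10)
  # auxiliary filter dg = x1 - gamma g
  st4 <- st; st4["g"] <- 100
  expect_equal(unname(epileptor_derivative(st4, p)["g"]), -1 - 0.01 * 100)
  expect_error(epileptor_derivative(c(Inf, 0, 0, 0, 0, 0), p), "finite")
})

test_that("the stable non-ictal fixed point exists below the critical point", {
  for (x0 in c(-2.30, -2.25, -2.20)) {
    p <- epileptor_params(x0 = x0)
    fp <- find_fixed_point(p)
    expect_lt(attr(fp, "residual"), 1e-8)
    expect_true(all(Re(attr(fp, "eigenvalues")) < 0))
    expect_lt(max(abs(epileptor_derivative(fp, p))), 1e-8)
  }
  expect_error(find_fixed_point(epileptor_params(x0 = -2.0)),
               "critical point")
})

test_that("small perturbations of the fixed point decay back", {
  p <- epileptor_params(x0 = -2.25)
  fp <- find_fixed_point(p)
  pert <- fp + c(1e-3, 0, 0, 1e-3, 0, 0)
  sim <- simulate_epileptor(p, duration_s = 20, initial = pert,
                            detect = FALSE)
  end <- unlist(sim$trace[nrow(sim$trace),
                          c("x1", "y1", "z", "x2", "y2", "g")])
  expect_lt(max(abs(end - fp)), 1e-3)
})

test_that("deterministic integration is reproducible and guards blow-ups", {
  p <- epileptor_params(x0 = -2.25)
  s1 <- simulate_epileptor(p, 5, detect = FALSE)
  s2 <- simulate_epileptor(p, 5, detect = FALSE)
  expect_identical(s1$trace, s2$trace)
  bad <- c(1e7, 0, 0, 0, 0, 0)
  expect_error(simulate_epileptor(p, 1, initial = bad), "blow-up")
})

test_that("zero-noise stochastic runs collapse onto the RK4 trajectory", {
  p <- epileptor_params(x0 = -2.25,
                        noise_var = c(0, 0, 0))
  init <- find_fixed_point(p) + c(0.05, 0, 0, 0, 0, 0)
  det <- simulate_epileptor(p, 100, initial = init, detect = FALSE)
  sto <- simulate_epileptor(p, 100, initial = init, stochastic = TRUE,
                            seed = 1, detect = FALSE)
  dif <- max(abs(as.matrix(det$trace[, 2:7]) - as.matrix(sto$trace[, 2:7])))
  expect_lt(dif, 1e-6)
})

test_that("stochastic runs are seed-reproducible and scheme backends agree in law", {
  p <- epileptor_params(x0 = -2.25)
  a <- simulate_epileptor(p, 10, stochastic = TRUE, seed = 42, detect = FALSE)
  b <- simulate_epileptor(p, 10, stochastic = TRUE, seed = 42, detect = FALSE)
  expect_identical(a$trace, b$trace)
  # epoch variance of the proxy positive and stable across seeds
  vars <- vapply(1:5, function(sd) {
    s <- simulate_epileptor(p, 60, stochastic = TRUE, seed = sd,
                            detect = FALSE)
    stats::var(s$trace$ieeg[-(1:500)])
  }, 0)
  expect_true(all(vars > 0))
  expect_lt(stats::sd(vars) / mean(vars), 0.5)
  # Heun and Euler-Maruyama give the same stationary variance scale
  for (sch in c("heun", "euler-maruyama")) {
    s <- simulate_epileptor(p, 60, stochastic = TRUE, seed = 1, scheme = sch,
                            detect = FALSE)
    v <- stats::var(s$trace$ieeg[-(1:500)])
    expect_gt(v, mean(vars) / 4)
    expect_lt(v, mean(vars) * 4)
  }
})

test_that("RK4 step-halving converges with observed order of at least three", {
  fp <- find_fixed_point(epileptor_params(x0 = -2.25))
  init <- fp + c(0.05, 0, 0, 0.05, 0, 0)
  endpt <- function(dt) {
    p <- epileptor_params(x0 = -2.25, dt = dt)
    s <- simulate_epileptor(p, duration_s = 0.5, initial = init,
                            detect = FALSE)
    unlist(s$trace[nrow(s$trace), c("x1", "y1", "z", "x2", "y2", "g")])
  }
  ref <- endpt(0.00625)
  errs <- vapply(c(0.1, 0.05, 0.025), function(dt) max(abs(endpt(dt) - ref)),
                 0)
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders >= 3))
})

test_that("no spontaneous seizures below the critical point, recurrence above", {
  for (x0 in c(-2.30, -2.25, -2.20)) {
    sim <- simulate_epileptor(epileptor_params(x0), 500)
    expect_true(is.na(sim$seizure_onset_ms))
  }
  sim <- simulate_epileptor(epileptor_params(-2.0), 1000, detect = FALSE)
  bouts <- epiprobe:::seizure_bouts(sim$trace$x1, sim$trace$t_ms)
  expect_gte(nrow(bouts), 2)
})

test_that("seizure detection follows the dwell rule and matches a brute-force scan", {
  t_ms <- seq(0, 100000, by = 10)
  x1 <- rep(-1.5, length(t_ms))
  sim0 <- list(trace = tibble::tibble(t_ms = t_ms, x1 = x1))
  expect_true(is.na(detect_seizure(sim0)))
  # a 5 s excursion is below the 10 s dwell
  x1b <- x1; x1b[t_ms >= 20000 & t_ms < 25000] <- 0.5
  expect_true(is.na(detect_seizure(list(trace = tibble::tibble(t_ms = t_ms,
                                                               x1 = x1b)))))
  # a 15 s excursion with brief sub-threshold dips is one seizure
  x1c <- x1; x1c[t_ms >= 30000 & t_ms < 45000] <- 0.5
  x1c[t_ms >= 33000 & t_ms < 33500] <- -0.2
  onset <- detect_seizure(list(trace = tibble::tibble(t_ms = t_ms, x1 = x1c)))
  expect_equal(onset, 30000)
  # brute-force oracle on a real epileptogenic run: first sample from which
  # a 10 s window (2 s gap closing) stays ictal
  sim <- simulate_epileptor(epileptor_params(-2.0), 600, detect = FALSE)
  got <- detect_seizure(sim)
  scan <- with(sim$trace, {
    above <- x1 > 0
    hit <- NA_real_
    for (i in which(above)) {
      j <- i
      while (j < length(above)) {
        nxt <- which(above[(j + 1):length(above)])[1]
        if (is.na(nxt) || nxt * 10 > 2000) break
        j <- j + nxt
      }
      if (t_ms[j] - t_ms[i] >= 10000) { hit <- t_ms[i]; break }
    }
    hit
  })
  expect_equal(got, scan)
})

test_that("stimulus builders produce the printed geometries", {
  tr <- build_stimulus("train", frequency_hz = 20, duration_s = 1)
  expect_length(tr$onsets_ms, 20)
  expect_true(all(diff(tr$onsets_ms) == 50))
  pp <- build_stimulus("paired-pulse", ipi_ms = 6)
  expect_equal(diff(pp$onsets_ms), 6)
  # arrhythmic: seeded count, mean rate over many seeds
  ns <- vapply(1:100, function(sd)
    length(build_stimulus("arrhythmic", frequency_hz = 20, duration_s = 1,
                          seed = sd)$onsets_ms), 0L)
  expect_true(all(ns == 20))
  spans <- vapply(1:100, function(sd) {
    o <- build_stimulus("arrhythmic", frequency_hz = 20, duration_s = 1,
                        seed = sd)$onsets_ms
    mean(diff(o))
  }, 0)
  expect_equal(mean(spans), 50, tolerance = 0.1)
  expect_error(build_stimulus("nope"), "arg")
})

test_that("time-to-seizure is monotone in excitability and frequency", {
  # frequencies above the model's integration threshold (~18 Hz): below it
  # the fast subsystem relaxes fully between pulses and no train provokes
  tts <- outer(c(-2.30, -2.25, -2.20), c(20, 30, 40),
               Vectorize(function(x0, f)
                 time_to_seizure(epileptor_params(x0), frequency_hz = f,
                                 max_duration_s = 30)))
  expect_true(all(is.finite(tts)))
  for (j in 1:3) expect_true(all(diff(tts[, j]) < 0))   # rising x0
  for (i in 1:3) expect_true(all(diff(tts[i, ]) < 0))   # rising frequency
  expect_true(is.na(time_to_seizure(epileptor_params(-2.25),
                                    intensity_scale = 0)))
})

test_that("the fast-subsystem diagram is S-shaped with a fold near z = 2.9", {
  p <- epileptor_params(x0 = -2.25)
  bd <- bifurcation_diagram(p)
  fold <- attr(bd, "fold")
  expect_equal(unname(fold["z"]), 4.1 - (-(4/3)^3 + 2 * (4/3)^2),
               tolerance = 1e-6)
  # bistable interval: some z with two stable equilibria on distinct branches
  per_z <- split(bd, bd$z)
  nstable <- vapply(per_z, function(d) sum(d$stable), 0L)
  branches <- vapply(per_z, function(d)
    length(unique(d$branch[d$stable])), 0L)
  expect_true(any(nstable >= 2 & branches == 2))
  # below the fold only the ictal equilibrium remains stable
  low <- bd[bd$z < fold["z"] - 0.3, ]
  expect_true(all(low$branch[low$stable] == "ictal"))
  expect_error(bifurcation_diagram(p, z_range = c(4, 4.5)), "bracket")
})

test_that("single-pulse responses grow as excitability approaches the critical point", {
  lls <- vapply(c(-2.45, -2.40, -2.35, -2.30, -2.25, -2.20), function(x0) {
    p <- epileptor_params(x0)
    st <- build_stimulus("single-pulse")
    st$onsets_ms <- 1000
    s <- simulate_epileptor(p, 2.5, stim = st, detect = FALSE)
    idx <- which(s$trace$t_ms >= 1000 & s$trace$t_ms < 1250)
    line_length(s$trace$ieeg[idx], 100)
  }, 0)
  expect_monotone_increasing(lls)
})

test_that("configuration blocks round-trip through YAML", {
  p <- epileptor_params(x0 = -2.20, y0 = 0.9, noise_var = c(0.01, 1e-4, 2e-4))
  f <- tempfile(fileext = ".yaml")
  write_epileptor_config(p, f)
  p2 <- read_epileptor_config(f)
  expect_equal(p2, p)
  cfg <- preprocess_config("human", notch_q = 80)
  f2 <- tempfile(fileext = ".yaml")
  write_preprocess_config(cfg, f2)
  expect_equal(read_preprocess_config(f2), cfg)
  cfgm <- preprocess_config("mouse")
  write_preprocess_config(cfgm, f2)
  expect_true(is.na(read_preprocess_config(f2)$resample_hz))
})

test_that("simulation export round-trips through CSV + JSON", {
  p <- epileptor_params(x0 = -2.25)
  sim <- simulate_epileptor(p, 2, stochastic = TRUE, seed = 3,
                            detect = FALSE)
  path <- file.path(tempdir(), "sim.csv")
  write_simulation(sim, path)
  back <- utils::read.csv(path)
  expect_equal(back$ieeg, sim$trace$ieeg)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(meta$params$x0, -2.25)
  expect_equal(meta$seed, 3)
})
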