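#' Epileptor model parameters
#'
#' Builds the parameter set of the five-dimensional Epileptor neural-mass
#' model. The model couples a fast subsystem (`x1`, `y1`) generating ictal
#' discharges, a slower spike-wave subsystem (`x2`, `y2`), and a very slow
#' permittivity variable `z` that mediates the switch between interictal and
#' ictal regimes through a fold (saddle-node) bifurcation. An auxiliary
#' variable `g` realises the exponentially weighted integral of `x1` that
#' drives the spike-wave subsystem.
#'
#' The excitability (epileptogenicity) parameter `x0` is the control
#' parameter: `x0 = -2.25` is the non-ictal baseline, `-2.20` a raised
#' ("PTZ-like") and `-2.30` a lowered ("BZD-like") excitability level, and
#' `-2.0` an epileptogenic state with spontaneous recurrent seizures.
#'
#' Time correspondence: one model time unit equals `ms_per_unit` milliseconds
#' of real time (10 ms by default). Integration proceeds internally at step
#' `dt` model units (0.1 by default, i.e. 1 ms of real time), so that a 3 ms
#' stimulation pulse spans three internal steps; trajectories are returned on
#' the 1-unit (10 ms) grid.
#'
#' @param x0 excitability control parameter (dimensionless).
#' @param y0 fast-subsystem offset. The value 1 is the convention of the
#'   original Epileptor formulation.
#' @param tau0 slow permittivity timescale (model time units).
#' @param tau2 spike-wave subsystem timescale.
#' @param I1_base,I2_base tonic drives of the fast and spike-wave subsystems.
#' @param gamma decay rate of the exponentially weighted integral `g`.
#' @param noise_var additive white-noise variances per unit model time on
#'   `x1`, `x2` and `y2`, in that order.
#' @param stim_amp stimulation amplitudes added to `I1` and `I2` while a
#'   pulse is on.
#' @param dt internal integration step in model time units.
#' @param ms_per_unit real-time milliseconds per model time unit.
#' @param proxy simulated iEEG proxy: `"x1+x2"` (default) or `"-x1+x2"`.
#'
#' @return An object of class `epileptor_params`.
#' @examples
#' p <- epileptor_params(x0 = -2.25)
#' find_fixed_point(p)
#' @export
epileptor_params <- function(x0 = -2.25, y0 = 1, tau0 = 20000, tau2 = 10,
                             I1_base = 3.1, I2_base = 0.45, gamma = 0.01,
                             noise_var = c(x1 = 0.005, x2 = 1e-4, y2 = 1e-4),
                             stim_amp = c(2, 5), dt = 0.1, ms_per_unit = 10,
                             proxy = c("x1+x2", "-x1+x2")) {
  proxy <- match.arg(proxy)
  stopifnot(tau0 > 0, tau2 > 0, gamma > 0, dt > 0, ms_per_unit > 0,
            length(noise_var) == 3, all(noise_var >= 0),
            length(stim_amp) == 2)
  structure(list(x0 = x0, y0 = y0, tau0 = tau0, tau2 = tau2,
                 I1_base = I1_base, I2_base = I2_base, gamma = gamma,
                 noise_var = unname(noise_var), stim_amp = unname(stim_amp),
                 dt = dt, ms_per_unit = ms_per_unit, proxy = proxy),
            class = "epileptor_params")
}

#' @export
print.epileptor_params <- function(x, ...) {
  cat("<epileptor_params>  x0 =", x$x0, " y0 =", x$y0,
      " tau0 =", x$tau0, " tau2 =", x$tau2, "\n")
  cat("  noise var (x1,x2,y2):", paste(x$noise_var, collapse = ", "),
      "  stim amp (I1,I2):", paste(x$stim_amp, collapse = ", "), "\n")
  cat("  dt =", x$dt, "model units; 1 unit =", x$ms_per_unit, "ms; proxy:",
      x$proxy, "\n")
  invisible(x)
}

par_vec <- function(p) {
  c(p$x0, p$y0, p$tau0, p$tau2, p$I1_base, p$I2_base, p$gamma)
}

state_names <- c("x1", "y1", "z", "x2", "y2", "g")

as_state <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 6) stop("an Epileptor state has 6 components: ",
                           paste(state_names, collapse = ", "))
  stats::setNames(s, state_names)
}

#' Right-hand side of the Epileptor equations
#'
#' Evaluates the deterministic time derivative of the six-component state
#' (the five model variables plus the auxiliary integral `g`, realised as the
#' linear filter `dg/dt = x1 - gamma * g`). The fast-subsystem nonlinearity
#' switches branch at `x1 = 0` and the spike-wave nonlinearity at
#' `x2 = -0.25`.
#'
#' @param state numeric state vector `(x1, y1, z, x2, y2, g)`.
#' @param params an [epileptor_params()] object.
#' @param istim1,istim2 stimulation drives added to `I1` and `I2`.
#' @return Named numeric vector of derivatives.
#' @export
epileptor_derivative <- function(state, params, istim1 = 0, istim2 = 0) {
  state <- as_state(state)
  if (!all(is.finite(state))) stop("non-finite state: numerical blow-up?")
  stats::setNames(epileptor_rhs_cpp(state, par_vec(params), istim1, istim2),
                  state_names)
}

epileptor_jacobian <- function(state, params, h = 1e-6) {
  state <- as_state(state)
  J <- matrix(0, 6, 6, dimnames = list(state_names, state_names))
  for (j in 1:6) {
    sp <- state; sm <- state
    sp[j] <- sp[j] + h; sm[j] <- sm[j] - h
    J[, j] <- (epileptor_derivative(sp, params) -
                 epileptor_derivative(sm, params)) / (2 * h)
  }
  J
}

#' Stable non-ictal fixed point of the Epileptor
#'
#' Solves the deterministic equilibrium analytically. With `x1 < 0` the fast
#' subsystem decouples from the spike-wave pair, so the equilibrium reduces
#' to a cubic in `x1` (the non-ictal branch requires `x1 < -4/3`, below the
#' knee of the fold) and a cubic in `x2`, for which the stable node on the
#' quiescent branch (`x2 < -0.25`, `y2 = 0`) is returned. Stability is
#' verified through the eigenvalues of the finite-difference Jacobian.
#'
#' @param params an [epileptor_params()] object.
#' @param tol residual tolerance for the returned root.
#' @return Named state vector with attributes `eigenvalues` (full Jacobian
#'   spectrum) and `residual` (max absolute derivative component).
#' @examples
#' fp <- find_fixed_point(epileptor_params(x0 = -2.25))
#' max(abs(epileptor_derivative(fp, epileptor_params(x0 = -2.25))))
#' @export
find_fixed_point <- function(params, tol = 1e-8) {
  p <- params
  real_roots <- function(coefs) {
    r <- polyroot(coefs)
    sort(Re(r[abs(Im(r)) < 1e-8]))
  }
  # x1^3 + 2 x1^2 + 4 x1 - (y0 + I1 + 4 x0) = 0 on the x1 < 0 branch
  rx1 <- real_roots(c(-(p$y0 + p$I1_base + 4 * p$x0), 4, 2, 1))
  rx1 <- rx1[rx1 < -4 / 3]
  if (!length(rx1))
    stop("no stable non-ictal fixed point: x0 = ", p$x0,
         " appears to be beyond the critical point")
  x1 <- rx1[1]
  y1 <- p$y0 - 5 * x1^2
  z <- 4 * (x1 - p$x0)
  g <- x1 / p$gamma
  c2 <- p$I2_base + 0.002 * g - 0.3 * (z - 3.5)
  # quiescent branch (y2 = 0): x2 - x2^3 + c2 = 0; stable node has
  # 1 - 3 x2^2 < 0, i.e. the most negative root
  rA <- real_roots(c(c2, 1, 0, -1))
  rA <- rA[rA < -0.25 & (1 - 3 * rA^2) < 0]
  if (length(rA)) {
    x2 <- rA[1]; y2 <- 0
  } else {
    rB <- real_roots(c(c2 - 1.5, -5, 0, -1))
    rB <- rB[rB >= -0.25]
    if (!length(rB)) stop("no spike-wave equilibrium found")
    x2 <- rB[1]; y2 <- 6 * (x2 + 0.25)
  }
  st <- as_state(c(x1, y1, z, x2, y2, g))
  resid <- max(abs(epileptor_derivative(st, params)))
  if (resid > tol) stop("fixed-point residual ", signif(resid, 3),
                        " exceeds tolerance ", tol)
  ev <- eigen(epileptor_jacobian(st, params), only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    stop("no stable non-ictal fixed point: x0 = ", p$x0,
         " appears to be beyond the critical point")
  attr(st, "eigenvalues") <- ev
  attr(st, "residual") <- resid
  st
}

#' Default initial state for a simulation
#'
#' Returns the stable non-ictal fixed point when one exists. In the
#' epileptogenic regime (no stable fixed point, e.g. `x0 = -2.0`) the
#' non-ictal equilibrium root is returned with a small downward offset on
#' `x1`, placing the system in the interictal basin from which the slow
#' permittivity dynamics generate recurrent seizures.
#'
#' @param params an [epileptor_params()] object.
#' @return Named state vector.
#' @export
initial_state <- function(params) {
  fp <- tryCatch(find_fixed_point(params), error = function(e) NULL)
  if (!is.null(fp)) return(fp)
  p <- params
  r <- polyroot(c(-(p$y0 + p$I1_base + 4 * p$x0), 4, 2, 1))
  r <- sort(Re(r[abs(Im(r)) < 1e-8]))
  x1 <- r[1] - 0.05
  as_state(c(x1, p$y0 - 5 * x1^2, 4 * (x1 - p$x0), -0.78, 0, x1 / p$gamma))
}

#' Stimulation protocols
#'
#' Builds a stimulus train: pulse onset times (real milliseconds), pulse
#' width and amplitude scaling. Protocols mirror common probing designs:
#' a single pulse, a paired pulse at a configurable inter-pulse interval
#' (6--2000 ms), a rhythmic train at a fixed frequency, or an arrhythmic
#' train with exponentially distributed inter-pulse intervals at the same
#' mean rate.
#'
#' @param protocol one of `"single-pulse"`, `"paired-pulse"`, `"train"`,
#'   `"arrhythmic"`.
#' @param frequency_hz pulse rate for (ar)rhythmic trains.
#' @param duration_s train duration in seconds.
#' @param ipi_ms inter-pulse interval for paired pulses (milliseconds).
#' @param pulse_width_ms pulse width in milliseconds (3 ms default).
#' @param intensity_scale multiplier on the stimulation amplitudes.
#' @param start_ms onset of the first pulse.
#' @param seed RNG seed for arrhythmic trains.
#' @return An object of class `stimulus_train` with fields `onsets_ms`,
#'   `pulse_width_ms`, `amplitude_scale`, `label`.
#' @examples
#' build_stimulus("train", frequency_hz = 20, duration_s = 1)
#' @export
build_stimulus <- function(protocol = c("single-pulse", "paired-pulse",
                                        "train", "arrhythmic"),
                           frequency_hz = 20, duration_s = 1, ipi_ms = 50,
                           pulse_width_ms = 3, intensity_scale = 1,
                           start_ms = 0, seed = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(pulse_width_ms > 0, intensity_scale >= 0)
  onsets <- switch(protocol,
    "single-pulse" = start_ms,
    "paired-pulse" = c(start_ms, start_ms + ipi_ms),
    "train" = {
      stopifnot(frequency_hz * duration_s >= 1)
      start_ms + seq(0, by = 1000 / frequency_hz,
                     length.out = floor(frequency_hz * duration_s))
    },
    "arrhythmic" = {
      stopifnot(frequency_hz * duration_s >= 1)
      n <- floor(frequency_hz * duration_s)
      if (!is.null(seed)) set.seed(seed)
      ipi <- stats::rexp(n, rate = frequency_hz / 1000)
      start_ms + cumsum(ipi) - ipi[1]
    })
  if (is.unsorted(onsets, strictly = TRUE)) stop("onsets must be strictly increasing")
  structure(list(onsets_ms = onsets, pulse_width_ms = pulse_width_ms,
                 amplitude_scale = intensity_scale, label = protocol),
            class = "stimulus_train")
}

#' Simulate the Epileptor
#'
#' Integrates the model with a fixed internal step. Deterministic runs use
#' classical fourth-order Runge--Kutta; stochastic runs add white Gaussian
#' increments (variances from `params$noise_var`, scaled per unit model time)
#' on `x1`, `x2` and `y2`. The default stochastic scheme applies the additive
#' increments on top of the RK4 drift step and therefore reproduces the
#' deterministic trajectory exactly when all noise variances are zero;
#' stochastic Heun and Euler--Maruyama backends are available as
#' cross-checks. Stimulation adds `stim_amp[1]`/`stim_amp[2]` (times the
#' train's amplitude scale) to `I1`/`I2` during pulse windows.
#'
#' @param params an [epileptor_params()] object.
#' @param duration_s simulated real time in seconds.
#' @param stim optional [build_stimulus()] train.
#' @param initial initial state; defaults to [initial_state()].
#' @param stochastic logical; add noise?
#' @param seed RNG seed used for stochastic runs.
#' @param scheme integration scheme for stochastic runs.
#' @param detect detect the first ictal transition (see [detect_seizure()])?
#' @return An object of class `epileptor_sim`: a list with `trace` (a tibble
#'   with columns `t_ms`, the six state variables, `ieeg` and `stim`),
#'   `seizure_onset_ms`, `params`, `seed` and `scheme`. The trace is sampled
#'   on the 1-model-unit grid (10 ms by default).
#' @examples
#' p <- epileptor_params(x0 = -2.25)
#' sim <- simulate_epileptor(p, duration_s = 10, stochastic = TRUE, seed = 1)
#' head(sim$trace)
#' @export
simulate_epileptor <- function(params, duration_s, stim = NULL,
                               initial = NULL, stochastic = FALSE,
                               seed = NULL,
                               scheme = c("rk4-additive", "heun",
                                          "euler-maruyama"),
                               detect = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(duration_s > 0)
  p <- params
  if (is.null(initial)) initial <- initial_state(p)
  initial <- as_state(initial)
  if (!all(is.finite(initial))) stop("non-finite initial state")

  units_total <- duration_s * 1000 / p$ms_per_unit
  n_steps <- max(1, round(units_total / p$dt))
  thin <- max(1L, as.integer(round(1 / p$dt)))

  if (is.null(stim)) {
    onsets <- integer(0); pw_steps <- 0L; amp1 <- 0; amp2 <- 0
  } else {
    onset_units <- stim$onsets_ms / p$ms_per_unit
    onsets <- as.integer(round(onset_units / p$dt))
    onsets <- onsets[onsets < n_steps]
    pw_steps <- max(1L, as.integer(round(stim$pulse_width_ms /
                                           p$ms_per_unit / p$dt)))
    amp1 <- p$stim_amp[1] * stim$amplitude_scale
    amp2 <- p$stim_amp[2] * stim$amplitude_scale
  }

  scheme_code <- if (!stochastic) 0L else
    c("rk4-additive" = 1L, "heun" = 2L, "euler-maruyama" = 3L)[[scheme]]
  nv <- if (stochastic) p$noise_var else c(0, 0, 0)
  if (stochastic && !is.null(seed)) set.seed(seed)

  res <- epileptor_integrate_cpp(initial, par_vec(p), p$dt, n_steps, thin,
                                 onsets, pw_steps, amp1, amp2, nv,
                                 scheme_code)
  st <- res$states
  ieeg <- if (p$proxy == "x1+x2") st[, "x1"] + st[, "x2"] else
    -st[, "x1"] + st[, "x2"]
  trace <- tibble::tibble(
    t_ms = res$time * p$ms_per_unit,
    x1 = st[, "x1"], y1 = st[, "y1"], z = st[, "z"],
    x2 = st[, "x2"], y2 = st[, "y2"], g = st[, "g"],
    ieeg = ieeg, stim = res$stim)
  out <- structure(list(trace = trace, params = p, seed = seed,
                        scheme = if (stochastic) scheme else "rk4",
                        stochastic = stochastic,
                        seizure_onset_ms = NA_real_),
                   class = "epileptor_sim")
  if (detect) out$seizure_onset_ms <- detect_seizure(out)
  out
}

#' @export
print.epileptor_sim <- function(x, ...) {
  cat("<epileptor_sim> ", nrow(x$trace), "samples,",
      round(max(x$trace$t_ms) / 1000, 2), "s;",
      if (x$stochastic) paste0("stochastic (", x$scheme, ")") else
        "deterministic (rk4)", "\n")
  cat("  x0 =", x$params$x0, "; seizure onset:",
      if (is.na(x$seizure_onset_ms)) "none" else
        paste0(round(x$seizure_onset_ms / 1000, 2), " s"), "\n")
  invisible(x)
}

#' Detect the first ictal transition in a simulation
#'
#' A sample is ictal when `x1` exceeds `threshold` (0 by default, the branch
#' point of the fast-subsystem nonlinearity). Because ictal discharges
#' oscillate around the threshold, above-threshold runs separated by gaps
#' shorter than `gap_tol_s` are merged; the onset of the first merged run
#' lasting at least `dwell_s` (10 s of real time by default, mirroring the
#' sustained-activity rule used by experimenters) is returned.
#'
#' @param sim an `epileptor_sim` object.
#' @param threshold ictal threshold on `x1`.
#' @param dwell_s minimum sustained duration (seconds).
#' @param gap_tol_s maximum sub-threshold gap merged into an ictal run.
#' @return Onset time in milliseconds, or `NA` if no seizure is detected.
#' @export
detect_seizure <- function(sim, threshold = 0, dwell_s = 10, gap_tol_s = 2) {
  x1 <- sim$trace$x1
  t_ms <- sim$trace$t_ms
  onsets <- seizure_bouts(x1, t_ms, threshold, dwell_s * 1000,
                          gap_tol_s * 1000)
  if (nrow(onsets) == 0) NA_real_ else onsets$onset_ms[1]
}

# All ictal bouts satisfying the dwell rule, as a tibble.
seizure_bouts <- function(x1, t_ms, threshold = 0, dwell_ms = 10000,
                          gap_tol_ms = 2000) {
  above <- x1 > threshold
  if (!any(above)) return(tibble::tibble(onset_ms = numeric(0),
                                         offset_ms = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble::tibble(start = starts[r$values], end = ends[r$values])
  # merge above-threshold runs separated by short gaps
  merged <- list()
  cur <- c(runs$start[1], runs$end[1])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap_ms <- t_ms[runs$start[i]] - t_ms[cur[2]]
      if (gap_ms <= gap_tol_ms) cur[2] <- runs$end[i]
      else { merged[[length(merged) + 1]] <- cur; cur <- c(runs$start[i], runs$end[i]) }
    }
  }
  merged[[length(merged) + 1]] <- cur
  m <- do.call(rbind, merged)
  keep <- (t_ms[m[, 2]] - t_ms[m[, 1]]) >= dwell_ms
  tibble::tibble(onset_ms = t_ms[m[keep, 1]], offset_ms = t_ms[m[keep, 2]])
}

#' Fast-subsystem bifurcation diagram
#'
#' Treats the slow permittivity `z` as a parameter and returns the
#' equilibria of the fast subsystem (`x1`, `y1`) over a grid of `z` values,
#' with linear stability labels, together with the fold point where the
#' stable and unstable non-ictal branches collide. On the non-ictal side
#' (`x1 < 0`) equilibria solve `x1^3 + 2 x1^2 = y0 + I1 - z`; the ictal
#' branch (`x1 >= 0`) uses the upper nonlinearity with the spike-wave
#' variable held at `x2_fixed`.
#'
#' @param params an [epileptor_params()] object.
#' @param z_range range of `z` to scan (must bracket the fold).
#' @param n grid size.
#' @param x2_fixed value at which `x2` is held for the ictal branch;
#'   defaults to the spike-wave equilibrium of the full fixed point.
#' @return A tibble with columns `z`, `x1`, `branch` (`"non-ictal"` /
#'   `"ictal"`) and `stable`, with attribute `fold` = `c(z, x1)` at the fold.
#' @export
bifurcation_diagram <- function(params, z_range = c(2.0, 4.5), n = 201,
                                x2_fixed = NULL) {
  p <- params
  stopifnot(length(z_range) == 2, z_range[1] < z_range[2])
  if (is.null(x2_fixed)) x2_fixed <- -0.78
  # fold of the non-ictal branch: d/dx1 (x1^3 + 2x1^2) = 0 at x1 = -4/3
  x1_fold <- -4 / 3
  z_fold <- p$y0 + p$I1_base - (x1_fold^3 + 2 * x1_fold^2)
  if (z_fold <= z_range[1] || z_fold >= z_range[2])
    stop("z_range does not bracket the fold at z = ", signif(z_fold, 5))
  zs <- seq(z_range[1], z_range[2], length.out = n)
  rows <- purrr::map_dfr(zs, function(z) {
    out <- list()
    # non-ictal equilibria: roots of x1^3 + 2 x1^2 + (z - y0 - I1), x1 < 0
    r <- polyroot(c(z - p$y0 - p$I1_base, 0, 2, 1))
    r <- Re(r[abs(Im(r)) < 1e-8])
    r <- r[r < 0]
    for (x1 in r) {
      # 2x2 Jacobian of (x1, y1): [[6x1 - 3x1^2, 1], [-10x1, -1]]
      a <- 6 * x1 - 3 * x1^2
      stable <- (a - 1) < 0 && (-a + 10 * x1) > 0
      out[[length(out) + 1]] <- tibble::tibble(z = z, x1 = x1,
                                               branch = "non-ictal",
                                               stable = stable)
    }
    # ictal equilibria: 0 = y0 - 5x1^2 - (x2 - 0.6 (z-4)^2) x1 - z + I1
    b <- x2_fixed - 0.6 * (z - 4)^2
    ri <- polyroot(c(p$y0 - z + p$I1_base, -b, -5))
    ri <- Re(ri[abs(Im(ri)) < 1e-8])
    ri <- ri[ri >= 0]
    for (x1 in ri) {
      # 2x2 Jacobian on the ictal branch: [[-b, 1], [-10 x1, -1]]
      stable <- (-b - 1) < 0 && (b + 10 * x1) > 0
      out[[length(out) + 1]] <- tibble::tibble(z = z, x1 = x1,
                                               branch = "ictal",
                                               stable = stable)
    }
    dplyr::bind_rows(out)
  })
  # two-sided bisection on existence of a stable non-ictal equilibrium
  has_stable <- function(z) {
    r <- polyroot(c(z - p$y0 - p$I1_base, 0, 2, 1))
    r <- Re(r[abs(Im(r)) < 1e-8])
    any(r < -4 / 3)
  }
  lo <- z_range[1]; hi <- z_range[2]
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (has_stable(mid)) hi <- mid else lo <- mid
  }
  attr(rows, "fold") <- c(z = (lo + hi) / 2, x1 = x1_fold)
  rows
}

#' Stimulation duration needed to provoke a seizure
#'
#' Simulates a continuous train at the given frequency and intensity and
#' returns the stimulation duration elapsed at the detected ictal onset
#' (seconds of real time), or `NA` if no seizure occurs within
#' `max_duration_s`. Near-critical excitability and higher train frequencies
#' shorten the time-to-seizure; this is the model's operational measure of
#' seizure resilience.
#'
#' @param params an [epileptor_params()] object.
#' @param frequency_hz train frequency.
#' @param intensity_scale multiplier on the stimulation amplitudes.
#' @param max_duration_s maximum train duration.
#' @param dwell_s,gap_tol_s seizure-detection settings (see
#'   [detect_seizure()]); the dwell is capped at the remaining simulated
#'   time after onset.
#' @param pulse_width_ms pulse width (3 ms default).
#' @return Time-to-seizure in seconds, or `NA`.
#' @examples
#' \donttest{
#' time_to_seizure(epileptor_params(x0 = -2.20), frequency_hz = 20)
#' }
#' @export
time_to_seizure <- function(params, frequency_hz = 20, intensity_scale = 1,
                            max_duration_s = 60, dwell_s = 10,
                            gap_tol_s = 2, pulse_width_ms = 3) {
  if (intensity_scale <= 0) return(NA_real_)
  stim <- build_stimulus("train", frequency_hz = frequency_hz,
                         duration_s = max_duration_s,
                         pulse_width_ms = pulse_width_ms,
                         intensity_scale = intensity_scale)
  # simulate past the train end so the dwell criterion can be satisfied
  sim <- simulate_epileptor(params, duration_s = max_duration_s + dwell_s +
                              5, stim = stim, detect = FALSE)
  onset <- detect_seizure(sim, dwell_s = dwell_s, gap_tol_s = gap_tol_s)
  if (is.na(onset) || onset > max_duration_s * 1000) NA_real_
  else onset / 1000
}

#' @rdname simulate_epileptor
#' @param x an `epileptor_sim` object.
#' @param ... unused.
#' @export
tidy.epileptor_sim <- function(x, ...) x$trace

#' @export
glance.epileptor_sim <- function(x, ...) {
  tibble::tibble(x0 = x$params$x0, n_samples = nrow(x$trace),
                 duration_s = max(x$trace$t_ms) / 1000,
                 stochastic = x$stochastic, scheme = x$scheme,
                 seizure_onset_s = x$seizure_onset_ms / 1000)
}

#' Export a simulation trace to CSV with a JSON sidecar
#'
#' Writes the trajectory as plain CSV (columns `t_ms`, state variables,
#' `ieeg`, `stim`) and the parameters, seed and scheme as a JSON sidecar
#' next to it.
#'
#' @param sim an `epileptor_sim` object.
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path) {
  utils::write.csv(sim$trace, path, row.names = FALSE)
  meta <- list(params = unclass(sim$params), seed = sim$seed,
               scheme = sim$scheme, stochastic = sim$stochastic,
               seizure_onset_ms = sim$seizure_onset_ms,
               package_version =
                 as.character(utils::packageVersion("epiprobe")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
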