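# Stochastic simulation: OU input noise, trajectory integration, and evoked
# event protocols.

#' Ornstein-Uhlenbeck input noise
#'
#' Forward-Euler realization of the OU update
#' `xi[k+1] = xi[k] - theta xi[k] dt + sigma sqrt(2 theta dt) z[k]`
#' on the noise grid, starting from zero. The realization is fully
#' determined by `seed`.
#'
#' @param params an [ou_params()] object.
#' @param n_steps number of grid steps (>= 1).
#' @param seed integer RNG seed.
#' @return Numeric vector of length `n_steps`.
#' @examples
#' xi <- ou_noise(ou_params(), n_steps = 1e5, seed = 1)
#' sd(xi) # close to sigma = 0.25
#' @export
ou_noise <- function(params, n_steps, seed) {
  stopifnot(inherits(params, "ou_params"), n_steps >= 1)
  if (params$sigma == 0) return(numeric(n_steps))
  set.seed(seed)
  z <- rnorm(n_steps)
  dt <- params$dt_noise
  innov <- params$sigma * sqrt(2 * params$theta * dt) * z
  # linear AR(1) recursion xi[k] = (1 - theta dt) xi[k-1] + innov[k]
  as.numeric(stats::filter(innov, 1 - params$theta * dt,
                           method = "recursive"))
}

#' A brief drive pulse
#'
#' @param amplitude signed pulse height in drive units.
#' @param onset pulse onset time.
#' @param width pulse width (> 0), same units as the simulation time.
#' @param target population receiving the pulse: `"r"` for the two-variable
#'   model, `"r_e"` or `"r_i"` for the E-I model.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(amplitude, onset, width, target = "r") {
  stopifnot(is.finite(amplitude), is.finite(onset), width > 0,
            target %in% c("r", "r_e", "r_i"))
  structure(list(amplitude = amplitude, onset = onset, width = width,
                 target = target), class = "pulse_spec")
}

pulse_drive <- function(pulse, times) {
  if (is.null(pulse)) return(numeric(length(times)))
  ifelse(times >= pulse$onset & times < pulse$onset + pulse$width,
         pulse$amplitude, 0)
}

# split one user seed into independent sub-seeds (kept below 2^31)
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate the population model with precomputed noise
#'
#' Integrates the two-variable model (or the E-I model for `ei_params`)
#' with Heun's method on the noise grid. The OU input is precomputed on that
#' grid from `seed` and held piecewise constant over each step, so a given
#' `(params, noise, seed)` triple fully determines the trajectory. For the
#' E-I model independent noise realizations drive the two populations.
#'
#' @param params a [rate_pop_params()] or [ei_params()] object.
#' @param noise an [ou_params()] object, or `NULL` for a noise-free run.
#' @param duration total simulated time (model units / ms); must comfortably
#'   exceed `tau_a`.
#' @param seed integer RNG seed for the noise realization.
#' @param pulse optional [pulse_spec()] added to the drive.
#' @param init optional named initial state: `r`, `a` and, for the E-I
#'   model, `r_i`.
#' @return An object of class `sim_trace`: `time`, `r`, `a` (plus `r_i`),
#'   `dt`, `duration`, `seed`, and the generating `params`.
#' @export
simulate_rate <- function(params, noise = ou_params(), duration = 60000,
                          seed = 1, pulse = NULL, init = NULL) {
  if (is.null(noise)) noise <- ou_params(sigma = 0)
  stopifnot(inherits(noise, "ou_params"))
  dt <- noise$dt_noise
  if (duration < 5 * params$tau_a)
    warning("duration is short relative to tau_a")
  n <- ceiling(duration / dt)
  times <- (seq_len(n) - 1) * dt
  if (inherits(params, "rate_pop_params")) {
    xi <- ou_noise(noise, n, seed)
    drive <- params$I +
      if (!is.null(pulse) && pulse$target == "r")
        pulse_drive(pulse, times) else 0
    drive <- rep_len(drive, n)
    if (is.null(init)) {
      fps <- steady_states(params)
      st <- fps[startsWith(fps$stability, "stable"), , drop = FALSE]
      init <- if (nrow(st)) c(r = st$r_star[1], a = st$a_star[1])
      else c(r = 0.5 * params$r_inf$max, a = 0.5 * params$a_inf$max)
    }
    tr <- cpp_simulate_ra(xi, drive, dt, params$w, params$b,
                          params$tau_r, params$tau_a,
                          params$r_inf$gain, params$r_inf$half,
                          params$r_inf$max,
                          params$a_inf$gain, params$a_inf$half,
                          params$a_inf$max,
                          init[["r"]], init[["a"]])
    out <- list(time = c(times, n * dt), r = tr[, 1], a = tr[, 2],
                dt = dt, duration = duration, seed = seed, params = params)
  } else if (inherits(params, "ei_params")) {
    sub <- derive_seeds(seed, 2)
    xi_e <- ou_noise(noise, n, sub[1])
    xi_i <- ou_noise(noise, n, sub[2])
    de <- params$I_e +
      if (!is.null(pulse) && pulse$target == "r_e")
        pulse_drive(pulse, times) else 0
    di <- params$I_i +
      if (!is.null(pulse) && pulse$target == "r_i")
        pulse_drive(pulse, times) else 0
    if (is.null(init)) init <- c(r = 0, a = 0, r_i = 0)
    tr <- cpp_simulate_ei(xi_e, xi_i, rep_len(de, n), rep_len(di, n), dt,
                          params$w_ee, params$w_ei, params$w_ie, params$w_ii,
                          params$b, params$tau_e, params$tau_i, params$tau_a,
                          params$io_e$gain, params$io_e$thresh,
                          params$io_e$expo,
                          params$io_i$gain, params$io_i$thresh,
                          params$io_i$expo,
                          params$a_inf$gain, params$a_inf$half,
                          params$a_inf$max,
                          init[["r"]], init[["r_i"]], init[["a"]],
                          params$r_cap)
    out <- list(time = c(times, n * dt), r = tr[, 1], r_i = tr[, 2],
                a = tr[, 3], dt = dt, duration = duration, seed = seed,
                params = params)
  } else {
    stop("params must be rate_pop_params or ei_params")
  }
  structure(out, class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("simulated trace: %g time units at dt = %g (seed %d)\n",
              x$duration, x$dt, x$seed))
  invisible(x)
}

#' Solver accuracy check
#'
#' Re-runs a reference simulation at half the step size and reports the
#' relative change in UP/DOWN duration statistics. The same noise seed is
#' used; the coarse-grid noise is repeated onto the fine grid so both runs
#' see the same realization.
#'
#' @param params,noise,duration,seed as in [simulate_rate()].
#' @return Named numeric vector of relative changes in mean and CV of UP and
#'   DOWN durations.
#' @export
solver_accuracy <- function(params, noise = ou_params(), duration = 20000,
                            seed = 1) {
  run <- function(refine) {
    dtn <- noise$dt_noise
    n <- ceiling(duration / dtn)
    xi <- ou_noise(noise, n, seed)
    dt <- if (refine) dtn / 2 else dtn
    if (refine) xi <- rep(xi, each = 2)
    drive <- rep(params$I, length(xi))
    tr <- cpp_simulate_ra(xi, drive, dt, params$w, params$b,
                          params$tau_r, params$tau_a,
                          params$r_inf$gain, params$r_inf$half,
                          params$r_inf$max,
                          params$a_inf$gain, params$a_inf$half,
                          params$a_inf$max,
                          0.5 * params$r_inf$max, 0.5 * params$a_inf$max)
    structure(list(time = seq(0, by = dt, length.out = nrow(tr)),
                   r = tr[, 1], a = tr[, 2], dt = dt, duration = duration,
                   seed = seed, params = params), class = "sim_trace")
  }
  s1 <- duration_stats(detect_updown(run(FALSE)))
  s2 <- duration_stats(detect_updown(run(TRUE)))
  keys <- c("mean_up", "mean_down", "cv_up", "cv_down")
  v1 <- unlist(s1[keys]); v2 <- unlist(s2[keys])
  abs(v2 - v1) / abs(v1)
}

# threshold rates used to flag a branch switch for evoked protocols
transition_marks <- function(params) {
  if (inherits(params, "rate_pop_params")) {
    folds <- nullcline_folds(params)
    if (is.null(folds)) stop("model is unfolded; no transitions defined")
    folds
  } else {
    folds <- ei_fold_rates(params,
                           drive_range = c(params$I_e - params$b *
                                             params$a_inf$max - 1,
                                           params$I_e + 1))
    if (is.null(folds)) stop("E-I effective I/O has no folds; no transitions defined")
    folds
  }
}

#' Evoked transition protocol
#'
#' Applies a brief drive pulse and reports whether a state transition
#' occurs within `5 * tau_a` of pulse onset. A transition is a crossing of
#' the rate (excitatory rate for the E-I model) from the starting branch
#' past the far fold of the nullcline (effective I/O curve).
#'
#' @param params model parameters, normally in an excitable regime.
#' @param pulse a [pulse_spec()].
#' @param noise an [ou_params()] or `NULL` for a deterministic probe.
#' @param seed RNG seed.
#' @param settle lead time simulated before pulse evaluation begins.
#' @return A list: the `sim_trace` in `trace`, logical `event`, and the
#'   `window` (in time units) inspected after pulse onset.
#' @export
evoked_response <- function(params, pulse, noise = NULL, seed = 1,
                            settle = 5 * params$tau_a) {
  window <- 5 * params$tau_a
  duration <- pulse$onset + window + params$tau_a
  tr <- simulate_rate(params, noise, duration = duration, seed = seed,
                      pulse = pulse)
  marks <- transition_marks(params)
  rr <- if (inherits(params, "rate_pop_params")) tr$r else tr$r
  pre <- rr[tr$time >= max(0, pulse$onset - settle / 2) &
              tr$time < pulse$onset]
  start_up <- mean(pre) > mean(marks)
  win <- rr[tr$time >= pulse$onset & tr$time <= pulse$onset + window]
  event <- if (start_up) any(win < marks[1]) else any(win > marks[2])
  list(trace = tr, event = event, window = window)
}

#' Probability of evoking a transition vs pulse amplitude
#'
#' Repeats [evoked_response()] over independent noise realizations for each
#' pulse amplitude and returns the fraction of trials with an evoked
#' transition.
#'
#' @param params model parameters.
#' @param noise an [ou_params()] (use `sigma = 0` for the deterministic
#'   threshold curve).
#' @param pulse a template [pulse_spec()]; its amplitude is replaced.
#' @param amplitudes numeric vector of pulse amplitudes.
#' @param n_trials trials per amplitude (>= 1).
#' @param seed RNG seed; trial seeds are derived from it.
#' @return Data frame with columns `amplitude`, `probability`, `n_trials`.
#' @export
evoked_probability <- function(params, noise, pulse, amplitudes,
                               n_trials = 100, seed = 1) {
  stopifnot(n_trials >= 1)
  seeds <- derive_seeds(seed, n_trials * length(amplitudes))
  k <- 0
  prob <- vapply(amplitudes, function(amp) {
    p <- pulse; p$amplitude <- amp
    hits <- vapply(seq_len(n_trials), function(j) {
      k <<- k + 1
      evoked_response(params, p, noise, seed = seeds[k])$event
    }, logical(1))
    mean(hits)
  }, numeric(1))
  data.frame(amplitude = amplitudes, probability = prob, n_trials = n_trials)
}
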