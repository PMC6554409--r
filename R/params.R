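#' Parameters of the adapting recurrent population model
#'
#' Container for the two-variable rate model
#' \deqn{\tau_r \dot r = -r + R_\infty(w r - b a + I + \xi(t))}
#' \deqn{\tau_a \dot a = -a + A_\infty(r)}
#' where `r` is the mean population rate and `a` a slow adaptation variable.
#' `w` is the recurrent excitation weight, `b` the adaptation gain and `I`
#' the tonic drive; all are dimensionless. Time is measured in units of the
#' rate time constant (`tau_r = 1` by default); the adaptation time constant
#' must be slower (`tau_a > tau_r`), reflecting the slow-adaptation
#' assumption underlying the phase-plane analysis. A physiological mapping of
#' one model time unit to roughly 5 ms puts the default `tau_a = 40` at the
#' ~200 ms recovery time scale of the adaptation processes implicated in
#' neocortical DOWN states.
#'
#' The default transfer functions are logistic sigmoids calibrated so that
#' the model reproduces the published regime anchors (bistable at
#' `w = 6.3, I = 2.35`; Excitable_DOWN at `w = 6, I = 2.4`; oscillatory at
#' `w = 6, I = 2.5`, all at `b = 1`). With these defaults the effective I/O
#' curve of a population with recurrence `w` is symmetric about the drive
#' `I = 5 - w/2 + b/2`.
#'
#' @param w recurrent excitation weight (>= 0).
#' @param b adaptation gain (>= 0).
#' @param I tonic drive.
#' @param tau_r rate time constant (> 0, model time units).
#' @param tau_a adaptation time constant (> tau_r).
#' @param r_inf [sigmoid_spec()] for the rate relation R_inf(input).
#' @param a_inf [sigmoid_spec()] for the adaptation relation A_inf(r).
#' @return An object of class `rate_pop_params`.
#' @examples
#' p <- rate_pop_params(w = 6.3, b = 1, I = 2.35)
#' steady_states(p)
#' @export
rate_pop_params <- function(w, b, I, tau_r = 1, tau_a = 40,
                            r_inf = sigmoid_spec(gain = 1, half = 5, max = 1),
                            a_inf = sigmoid_spec(gain = 9, half = 0.5,
                                                 max = 1)) {
  vals <- c(w = w, b = b, I = I, tau_r = tau_r, tau_a = tau_a)
  if (!all(is.finite(vals)))
    stop("non-finite model parameter: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (w < 0 || b < 0) stop("w and b must be non-negative")
  if (tau_r <= 0 || tau_a <= 0) stop("time constants must be positive")
  if (tau_a <= tau_r)
    stop("tau_a must exceed tau_r (slow adaptation assumption)")
  stopifnot(inherits(r_inf, "transfer_spec"), r_inf$kind == "sigmoid",
            inherits(a_inf, "transfer_spec"), a_inf$kind == "sigmoid")
  structure(list(w = w, b = b, I = I, tau_r = tau_r, tau_a = tau_a,
                 r_inf = r_inf, a_inf = a_inf),
            class = "rate_pop_params")
}

#' @export
print.rate_pop_params <- function(x, ...) {
  cat(sprintf(
    "adapting recurrent population: w = %g, b = %g, I = %g (tau_r = %g, tau_a = %g)\n",
    x$w, x$b, x$I, x$tau_r, x$tau_a))
  invisible(x)
}

#' Parameters of the adapting inhibition-stabilized network
#'
#' Container for the three-variable E-I model in which a fast inhibitory
#' population stabilizes a low-rate UP state and slow adaptation acts on the
#' excitatory population:
#' \deqn{\tau_e \dot r_e = -r_e + R_{e,\infty}(w_{ee} r_e - w_{ei} r_i - b a + I_e + \xi_e)}
#' \deqn{\tau_i \dot r_i = -r_i + R_{i,\infty}(w_{ie} r_e - w_{ii} r_i + I_i + \xi_i)}
#' \deqn{\tau_a \dot a = -a + A_\infty(r_e)}
#' Transfer functions are threshold power laws (exponent 2 by default), the
#' supralinear in-vivo-like transfer under which recurrent excitation can
#' create bistability at low drive while inhibition bounds the UP state.
#' Weights are labelled by source and target (`w_ei` is the inhibitory
#' weight onto E). The captioned weight pair "w_e = 4, w_i = 3" is read as
#' source-labelled weights: both populations receive excitation with weight
#' 4 and inhibition with weight 3.
#'
#' Time is in milliseconds: `tau_e = tau_i = 5`, `tau_a = 200`.
#'
#' @param w_ee,w_ei,w_ie,w_ii synaptic weights (>= 0).
#' @param I_e,I_i tonic drives to the E and I population.
#' @param tau_e,tau_i,tau_a time constants (ms); `tau_a` must dominate.
#' @param b adaptation gain.
#' @param io_e,io_i [powerlaw_spec()] transfer for the E and I population.
#' @param a_inf [sigmoid_spec()] adaptation relation A_inf(r_e).
#' @param r_cap admissible rate ceiling used by solvers and simulation.
#' @return An object of class `ei_params`.
#' @export
ei_params <- function(w_ee = 4, w_ei = 3, w_ie = 4, w_ii = 2,
                      I_e = 0.3, I_i = -1,
                      tau_e = 5, tau_i = 5, tau_a = 200, b = 0.7,
                      io_e = powerlaw_spec(gain = 1, thresh = 0, expo = 2),
                      io_i = powerlaw_spec(gain = 3, thresh = 0, expo = 2),
                      a_inf = sigmoid_spec(gain = 10, half = 0.35, max = 1),
                      r_cap = 10) {
  wts <- c(w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii)
  if (!all(is.finite(c(wts, I_e, I_i, tau_e, tau_i, tau_a, b, r_cap))))
    stop("non-finite E-I parameter")
  if (any(wts < 0)) stop("synaptic weights must be non-negative")
  if (tau_e <= 0 || tau_i <= 0 || tau_a <= 0)
    stop("time constants must be positive")
  if (tau_a <= 5 * max(tau_e, tau_i))
    stop("tau_a must be much slower than tau_e, tau_i")
  stopifnot(inherits(io_e, "transfer_spec"), io_e$kind == "powerlaw",
            inherits(io_i, "transfer_spec"), io_i$kind == "powerlaw",
            inherits(a_inf, "transfer_spec"), a_inf$kind == "sigmoid",
            r_cap > 0)
  structure(list(w_ee = w_ee, w_ei = w_ei, w_ie = w_ie, w_ii = w_ii,
                 I_e = I_e, I_i = I_i, tau_e = tau_e, tau_i = tau_i,
                 tau_a = tau_a, b = b, io_e = io_e, io_i = io_i,
                 a_inf = a_inf, r_cap = r_cap),
            class = "ei_params")
}

#' @export
print.ei_params <- function(x, ...) {
  cat(sprintf(
    "adapting ISN: w_ee %g, w_ei %g, w_ie %g, w_ii %g; I_e %g, I_i %g; b %g\n",
    x$w_ee, x$w_ei, x$w_ie, x$w_ii, x$I_e, x$I_i, x$b))
  cat(sprintf("  tau_e %g ms, tau_i %g ms, tau_a %g ms\n",
              x$tau_e, x$tau_i, x$tau_a))
  invisible(x)
}

#' Ornstein-Uhlenbeck input-noise parameters
#'
#' The model's fluctuating input follows the discretized OU update
#' \deqn{\xi_{k+1} = \xi_k - \theta \xi_k \, dt + \sigma \sqrt{2 \theta dt}\, z_k}
#' with standard normal `z_k`, giving correlation time `1/theta` and
#' stationary standard deviation approaching `sigma`. Defaults are the study
#' conditions: `theta = 0.05`, `sigma = 0.25` on a `dt = 0.1` grid.
#'
#' @param theta inverse correlation time (> 0).
#' @param sigma stationary standard deviation (>= 0).
#' @param dt_noise noise grid step (> 0).
#' @return An object of class `ou_params`.
#' @export
ou_params <- function(theta = 0.05, sigma = 0.25, dt_noise = 0.1) {
  if (!all(is.finite(c(theta, sigma, dt_noise))))
    stop("non-finite OU parameter")
  if (theta <= 0) stop("theta must be positive")
  if (sigma < 0) stop("sigma must be non-negative")
  if (dt_noise <= 0) stop("dt_noise must be positive")
  structure(list(theta = theta, sigma = sigma, dt_noise = dt_noise),
            class = "ou_params")
}

#' Read or write model parameters as a config file
#'
#' Parameter sets travel as flat YAML key-value files whose keys mirror the
#' constructor arguments; transfer functions are nested blocks with a `kind`
#' field. `read_model_config()` dispatches on the `model` key
#' (`"rate_pop"`, `"ei"` or `"ou"`).
#'
#' @param params a `rate_pop_params`, `ei_params` or `ou_params` object.
#' @param path file path.
#' @return `read_model_config()` returns the reconstructed parameter object.
#' @export
write_model_config <- function(params, path) {
  to_plain <- function(x) {
    if (inherits(x, "transfer_spec")) unclass(x)
    else if (is.list(x)) lapply(x, to_plain)
    else x
  }
  model <- switch(class(params)[1],
                  rate_pop_params = "rate_pop", ei_params = "ei",
                  ou_params = "ou",
                  stop("unsupported parameter class"))
  yaml::write_yaml(c(list(model = model), to_plain(unclass(params))), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec_of <- function(x) {
    if (x$kind == "sigmoid") sigmoid_spec(x$gain, x$half, x$max)
    else powerlaw_spec(x$gain, x$thresh, x$expo)
  }
  switch(cfg$model,
    rate_pop = rate_pop_params(cfg$w, cfg$b, cfg$I, cfg$tau_r, cfg$tau_a,
                               spec_of(cfg$r_inf), spec_of(cfg$a_inf)),
    ei = ei_params(cfg$w_ee, cfg$w_ei, cfg$w_ie, cfg$w_ii, cfg$I_e, cfg$I_i,
                   cfg$tau_e, cfg$tau_i, cfg$tau_a, cfg$b,
                   spec_of(cfg$io_e), spec_of(cfg$io_i), spec_of(cfg$a_inf),
                   cfg$r_cap),
    ou = ou_params(cfg$theta, cfg$sigma, cfg$dt_noise),
    stop("unknown model kind in config: ", cfg$model))
}
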