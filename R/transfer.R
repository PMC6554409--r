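#' Sigmoidal and threshold power-law transfer functions
#'
#' Population steady-state input/output relations. `sigmoid_spec()` describes
#' a logistic function `max / (1 + exp(-gain * (x - half)))`, used for the
#' rate relation R_inf(input) and the adaptation relation A_inf(r) of the
#' two-variable population model. `powerlaw_spec()` describes a threshold
#' power law `gain * pmax(x - thresh, 0)^expo`, the supralinear transfer
#' appropriate for fluctuation-driven E-I populations.
#'
#' @param gain logistic steepness (per input unit) or power-law gain.
#' @param half input at half activation.
#' @param max saturation level (upper bound of the logistic).
#' @param thresh power-law threshold: output is zero below it.
#' @param expo power-law exponent (> 0).
#' @return An object of class `transfer_spec`.
#' @examples
#' f <- sigmoid_spec(gain = 1, half = 5, max = 1)
#' transfer_eval(f, 5) # 0.5
#' @export
sigmoid_spec <- function(gain = 1, half = 0, max = 1) {
  stopifnot(is.finite(gain), gain > 0, is.finite(half), is.finite(max), max > 0)
  structure(list(kind = "sigmoid", gain = gain, half = half, max = max),
            class = "transfer_spec")
}

#' @rdname sigmoid_spec
#' @export
powerlaw_spec <- function(gain = 1, thresh = 0, expo = 2) {
  stopifnot(is.finite(gain), gain > 0, is.finite(thresh),
            is.finite(expo), expo > 0)
  structure(list(kind = "powerlaw", gain = gain, thresh = thresh, expo = expo),
            class = "transfer_spec")
}

#' @rdname sigmoid_spec
#' @param spec a `transfer_spec`.
#' @param x input values.
#' @export
transfer_eval <- function(spec, x) {
  if (spec$kind == "sigmoid") {
    spec$max / (1 + exp(-spec$gain * (x - spec$half)))
  } else {
    u <- pmax(x - spec$thresh, 0)
    spec$gain * u^spec$expo
  }
}

#' @rdname sigmoid_spec
#' @export
transfer_deriv <- function(spec, x) {
  if (spec$kind == "sigmoid") {
    f <- transfer_eval(spec, x)
    spec$gain * f * (1 - f / spec$max)
  } else {
    u <- pmax(x - spec$thresh, 0)
    ifelse(u > 0, spec$gain * spec$expo * u^(spec$expo - 1), 0)
  }
}

#' @export
print.transfer_spec <- function(x, ...) {
  if (x$kind == "sigmoid") {
    cat(sprintf("logistic transfer: gain %g, half %g, max %g\n",
                x$gain, x$half, x$max))
  } else {
    cat(sprintf("threshold power law: gain %g, thresh %g, exponent %g\n",
                x$gain, x$thresh, x$expo))
  }
  invisible(x)
}
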