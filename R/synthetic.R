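# Ground-truthed synthetic recordings emulating the statistical structure of
# NREM LFP + spike data, so every detection stage is testable without any
# real recording.

#' Synthetic recording configuration
#'
#' Study-condition defaults emulate NREM neocortical data: UP states
#' lognormal with mean 1.7 s and CV 1.1, DOWN states gamma with mean
#' 0.21 s and CV 0.38 (the in-vivo dwell-time summary statistics), ~24
#' units firing at several Hz during UP and silent during DOWN, a 1250 Hz
#' LFP with a one-cycle raised-cosine delta deflection spanning each DOWN
#' state and broadband high-gamma activity during UP states. SWR defaults
#' give 60 ms ripple-coincident sharp waves separated by ~2 s exponential
#' inter-event intervals.
#'
#' @param length_s recording length (s).
#' @param rate LFP sampling rate (Hz).
#' @param n_units number of units.
#' @param n_channels number of LFP channels.
#' @param up_rate,down_rate per-unit firing rate (Hz) in UP/DOWN states.
#' @param up_gen,down_gen duration generators: lists
#'   `list(dist, mean, cv)` with `dist` one of `"lognormal"`, `"gamma"`,
#'   `"exponential"`, `"point"`.
#' @param delta_amp delta deflection amplitude during DOWN (signal units,
#'   relative to a unit-SD noise floor).
#' @param gamma_amp high-gamma amplitude during UP.
#' @param channel_scale per-channel multiplier on the delta/gamma content
#'   (length `n_channels`); channels with scale 0 carry only the noise
#'   floor.
#' @param noise_sd broadband noise floor SD.
#' @param swr_rate SWR event rate (events/s).
#' @param swr_dur SWR duration generator (as `up_gen`).
#' @param ripple_freq ripple oscillation frequency (Hz, inside 80-250).
#' @param sharp_amp sharp-wave amplitude on the deep channel.
#' @param burst_rate per-unit rate during an SWR (Hz).
#' @param baseline_rate per-unit rate between SWRs (Hz).
#' @param seed RNG seed; the seed and config fully determine the recording.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(length_s = 120, rate = 1250, n_units = 24,
                         n_channels = 1,
                         up_rate = 5, down_rate = 0,
                         up_gen = list(dist = "lognormal", mean = 1.7,
                                       cv = 1.1),
                         down_gen = list(dist = "gamma", mean = 0.21,
                                         cv = 0.38),
                         delta_amp = 4, gamma_amp = 1.5,
                         channel_scale = NULL, noise_sd = 1,
                         swr_rate = 0.45,
                         swr_dur = list(dist = "gamma", mean = 0.06,
                                        cv = 0.33),
                         ripple_freq = 150, sharp_amp = 6,
                         burst_rate = 30, baseline_rate = 2,
                         seed = 1) {
  stopifnot(length_s > 0, rate > 800, n_units >= 1,
            up_rate >= 0, down_rate >= 0, noise_sd >= 0,
            ripple_freq >= 80, ripple_freq <= 250)
  if (is.null(channel_scale)) channel_scale <- rep(1, n_channels)
  stopifnot(length(channel_scale) == n_channels)
  structure(as.list(environment()), class = "synth_config")
}

draw_durations <- function(gen, n) {
  m <- gen$mean; cv <- gen$cv
  switch(gen$dist,
    point = rep(m, n),
    exponential = rexp(n, rate = 1 / m),
    gamma = {
      shape <- 1 / cv^2
      rgamma(n, shape = shape, rate = shape / m)
    },
    lognormal = {
      s2 <- log(1 + cv^2)
      rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    },
    stop("unsupported distribution '", gen$dist,
         "'; supported: point, exponential, gamma, lognormal"))
}

# inhomogeneous Poisson spikes for one unit given a rate stepping across
# intervals
poisson_spikes_intervals <- function(iv, rates) {
  out <- numeric(0)
  for (k in seq_len(nrow(iv))) {
    if (rates[k] <= 0) next
    n <- rpois(1, rates[k] * (iv$stop[k] - iv$start[k]))
    if (n) out <- c(out, runif(n, iv$start[k], iv$stop[k]))
  }
  sort(out)
}

# band-limited noise burst: white noise bandpassed into [lo, hi]
band_noise <- function(n, rate, lo, hi) {
  if (n < 12) return(numeric(n))
  bandpass(rnorm(n), rate, c(lo, hi))
}

#' Synthetic UP/DOWN recording with ground truth
#'
#' Draws an alternating UP/DOWN tiling from the configured duration
#' generators, inhomogeneous-Poisson spikes with per-state rates, and an
#' LFP built from a broadband noise floor plus a one-cycle raised-cosine
#' delta deflection spanning each DOWN state and band-limited high-gamma
#' activity during each UP state. Channel k carries the delta/gamma content
#' scaled by `channel_scale[k]`.
#'
#' @param config a [synth_config()].
#' @return List of class `synth_recording`: `lfp` ([lfp_record()]),
#'   `spikes` ([spike_raster()]), `truth` (ground-truth UP/DOWN
#'   [interval_set()] in seconds), and the config.
#' @export
synth_updown_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  L <- config$length_s
  # draw alternating durations until the recording is tiled
  starts <- numeric(0); stops <- numeric(0); labs <- character(0)
  t <- 0; up <- TRUE
  while (t < L) {
    d <- draw_durations(if (up) config$up_gen else config$down_gen, 1)
    d <- max(d, 2 / config$rate)
    starts <- c(starts, t); stops <- c(stops, min(t + d, L))
    labs <- c(labs, if (up) "UP" else "DOWN")
    t <- t + d; up <- !up
  }
  if (length(starts) < 2) stop("config yields an empty or one-state recording")
  truth <- interval_set(starts, stops, labs, units = "s")
  n <- round(L * config$rate)
  times <- (seq_len(n) - 1) / config$rate
  spikes <- lapply(seq_len(config$n_units), function(u)
    poisson_spikes_intervals(truth,
                             ifelse(labs == "UP", config$up_rate,
                                    config$down_rate)))
  base <- matrix(rnorm(n * config$n_channels, sd = config$noise_sd),
                 n, config$n_channels)
  content <- numeric(n)
  for (k in which(labs == "DOWN")) {
    ix <- which(times >= starts[k] & times < stops[k])
    if (length(ix) < 4) next
    ph <- seq(0, 2 * pi, length.out = length(ix))
    content[ix] <- content[ix] + config$delta_amp * 0.5 * (1 - cos(ph))
  }
  gamma_env <- numeric(n)
  for (k in which(labs == "UP")) {
    ix <- which(times >= starts[k] & times < stops[k])
    gamma_env[ix] <- 1
  }
  gband <- band_noise(n, config$rate, 100, 400)
  gsd <- sd(gband)
  if (gsd > 0) gband <- gband / gsd
  content <- content + config$gamma_amp * gamma_env * gband
  sig <- base + outer(content, config$channel_scale)
  list(lfp = lfp_record(sig, rate = config$rate),
       spikes = spike_raster(spikes),
       truth = truth, config = config) |>
    structure(class = "synth_recording")
}

#' Synthetic sharp wave-ripple recording with ground truth
#'
#' Two LFP channels: the deep channel carries a raised-cosine sharp-wave
#' deflection at each truth event, the superficial channel a windowed
#' ripple-band oscillation; all units emit baseline Poisson spiking with a
#' burst during each event.
#'
#' @param config a [synth_config()].
#' @return List of class `synth_recording`: `lfp` (channels deep,
#'   superficial), `spikes`, `truth` (SWR [interval_set()]), config.
#' @export
synth_swr_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  L <- config$length_s
  n <- round(L * config$rate)
  times <- (seq_len(n) - 1) / config$rate
  # event onsets: exponential waiting times at the configured rate
  onsets <- numeric(0); t <- 0
  if (config$swr_rate > 0) {
    repeat {
      t <- t + rexp(1, config$swr_rate)
      if (t >= L - 1) break
      onsets <- c(onsets, t)
    }
  }
  if (length(onsets)) {
    # floor at 30 ms: in-vivo SWR duration samples are detector-defined and
    # contain no sub-25 ms events
    durs <- pmax(draw_durations(config$swr_dur, length(onsets)), 0.03)
    # drop overlapping events
    keep <- rep(TRUE, length(onsets))
    last_stop <- -Inf
    for (i in seq_along(onsets)) {
      if (onsets[i] < last_stop + 0.2) keep[i] <- FALSE
      else last_stop <- onsets[i] + durs[i]
    }
    onsets <- onsets[keep]; durs <- durs[keep]
  } else durs <- numeric(0)
  deep <- rnorm(n, sd = config$noise_sd)
  sup <- rnorm(n, sd = config$noise_sd)
  for (i in seq_along(onsets)) {
    ix <- which(times >= onsets[i] & times < onsets[i] + durs[i])
    if (length(ix) < 4) next
    ph <- seq(0, 1, length.out = length(ix))
    # Tukey (flat-top) envelope: cosine ramps over the outer 10%, so the
    # oscillation fills the event rather than tapering through most of it
    env <- rep(1, length(ix))
    ramp <- ph < 0.1
    env[ramp] <- 0.5 * (1 - cos(pi * ph[ramp] / 0.1))
    ramp <- ph > 0.9
    env[ramp] <- 0.5 * (1 - cos(pi * (1 - ph[ramp]) / 0.1))
    deep[ix] <- deep[ix] + config$sharp_amp * env
    sup[ix] <- sup[ix] + config$sharp_amp * 0.6 * env *
      sin(2 * pi * config$ripple_freq * (times[ix] - times[ix[1]]))
  }
  if (length(onsets)) {
    iv <- data.frame(start = c(0, onsets + durs),
                     stop = c(onsets, L))
    iv <- iv[iv$stop > iv$start, ]
    spikes <- lapply(seq_len(config$n_units), function(u) {
      s1 <- poisson_spikes_intervals(iv, rep(config$baseline_rate, nrow(iv)))
      s2 <- poisson_spikes_intervals(
        data.frame(start = onsets, stop = onsets + durs),
        rep(config$burst_rate, length(onsets)))
      sort(c(s1, s2))
    })
    truth <- interval_set(onsets, onsets + durs,
                          rep("SWR", length(onsets)), units = "s")
  } else {
    spikes <- lapply(seq_len(config$n_units), function(u)
      sort(runif(rpois(1, config$baseline_rate * L), 0, L)))
    truth <- interval_set(units = "s")
  }
  list(lfp = lfp_record(cbind(deep, sup), rate = config$rate,
                        channels = c("deep", "superficial")),
       spikes = spike_raster(spikes),
       truth = truth, config = config) |>
    structure(class = "synth_recording")
}

#' Reproducible parametric duration samples
#'
#' Draws UP and DOWN dwell-time multisets from named parametric generators,
#' for testing the distribution-matching machinery.
#'
#' @param up_gen,down_gen generator lists `list(dist, mean, cv)`; `dist`
#'   one of `"point"`, `"exponential"`, `"gamma"`, `"lognormal"`.
#' @param n draws per label (>= 1).
#' @param seed RNG seed.
#' @param units declared units of the sample.
#' @return A [duration_sample()].
#' @export
synth_durations <- function(up_gen, down_gen = up_gen, n, seed = 1,
                            units = "model") {
  stopifnot(n >= 1)
  set.seed(seed)
  duration_sample(up = draw_durations(up_gen, n),
                  down = draw_durations(down_gen, n), units = units)
}

#' @export
print.synth_recording <- function(x, ...) {
  cat("synthetic recording:\n  ")
  print(x$lfp)
  cat("  ")
  print(x$spikes)
  cat(sprintf("  truth: %d interval(s)\n", nrow(x$truth)))
  invisible(x)
}
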